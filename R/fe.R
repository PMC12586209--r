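#' Sideways-fall loading configuration
#'
#' Loading geometry and solver controls for the quasi-static femoral
#' strength simulation: adduction angle (default -5 deg) and internal
#' rotation (default 0 deg) define the fall posture; the femoral head is
#' driven along the global downward axis in displacement increments up to
#' `max_displacement`. `prescribed_speed` (1 m/s) is the nominal loading
#' rate of the scenario being represented; in this quasi-static solver it
#' is metadata only and enters the material response solely through the
#' calibration's `rate_factor`.
#'
#' @param adduction_angle degrees.
#' @param internal_rotation degrees, about the shaft axis.
#' @param prescribed_speed nominal head-support speed, m/s (metadata).
#' @param max_displacement total driven head displacement, mm.
#' @param n_increments number of displacement increments (>= 1).
#' @param tangent_fraction post-yield tangent modulus as a fraction of E.
#' @param patch_radius support/drive patch radius around landmarks, mm.
#' @param max_bisections increment halvings allowed on non-convergence.
#' @param max_iterations secant iterations per increment.
#' @param tol relative convergence tolerance on element secant moduli.
#' @return Object of class `fall_config`.
#' @export
fall_config <- function(adduction_angle = -5, internal_rotation = 0,
                        prescribed_speed = 1, max_displacement = 5,
                        n_increments = 20, tangent_fraction = 0.05,
                        patch_radius = 8, max_bisections = 5,
                        max_iterations = 60, tol = 1e-5) {
  if (n_increments < 1) stop("n_increments must be >= 1")
  if (max_displacement < 0) stop("max_displacement must be >= 0")
  if (tangent_fraction < 0 || tangent_fraction >= 1)
    stop("tangent_fraction must be in [0, 1)")
  structure(list(adduction_angle = adduction_angle,
                 internal_rotation = internal_rotation,
                 prescribed_speed = prescribed_speed,
                 max_displacement = max_displacement,
                 n_increments = n_increments,
                 tangent_fraction = tangent_fraction,
                 patch_radius = patch_radius,
                 max_bisections = max_bisections,
                 max_iterations = max_iterations, tol = tol,
                 load_axis = c(0, 0, -1)),
            class = "fall_config")
}

#' Pose a femur mesh in the sideways-fall configuration
#'
#' Applies a pure rigid rotation built from the mesh landmarks: the shaft
#' axis is aligned with global +x (distal end at low x), the neck axis is
#' brought into the x-z plane with its off-shaft component pointing up
#' (+z), then the internal rotation is applied about the shaft axis and
#' the adduction rotation about the horizontal y axis. After posing, the
#' drive direction for the femoral head is global -z. Pairwise distances
#' are preserved exactly (rotation only, no scaling or translation).
#'
#' @param mesh a [tet_mesh()] whose landmarks include `shaft_axis` and
#'   `neck_axis` (and the point landmarks used later for supports).
#' @param cfg a [fall_config()].
#' @return The rotated [tet_mesh()], with landmarks rotated consistently.
#' @export
pose_femur <- function(mesh, cfg = fall_config()) {
  stopifnot(inherits(mesh, "tet_mesh"))
  lm <- mesh$landmarks
  if (is.null(lm$shaft_axis) || is.null(lm$neck_axis))
    stop("missing landmark: pose requires shaft_axis and neck_axis")
  e1 <- lm$shaft_axis / sqrt(sum(lm$shaft_axis^2))
  nk <- lm$neck_axis - sum(lm$neck_axis * e1) * e1
  if (sqrt(sum(nk^2)) < 1e-12)
    stop("neck axis parallel to shaft axis: pose frame undefined")
  e3 <- nk / sqrt(sum(nk^2))
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  M <- rbind(e1, e2, e3)
  phi <- cfg$internal_rotation * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(phi), -sin(phi)),
              c(0, sin(phi), cos(phi)))
  th <- cfg$adduction_angle * pi / 180
  Ry <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  R <- Ry %*% Rx %*% M
  rot_pt <- function(p) as.vector(R %*% p)
  mesh$nodes <- mesh$nodes %*% t(R)
  for (nm in names(lm)) lm[[nm]] <- rot_pt(lm[[nm]])
  mesh$landmarks <- lm
  mesh
}

# isotropic elasticity matrix for unit Young's modulus (Voigt order
# xx, yy, zz, xy, yz, zx; engineering shear strains)
.D_unit <- function(nu) {
  c1 <- 1 / ((1 + nu) * (1 - 2 * nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- nu * c1
  diag(D)[1:3] <- (1 - nu) * c1
  diag(D)[4:6] <- 1 / (2 * (1 + nu))
  D
}

# B matrix (6 x 3n) from shape-function gradients g (n x 3)
.B_from_grads <- function(g) {
  n <- nrow(g)
  B <- matrix(0, 6, 3 * n)
  ix <- 3 * (seq_len(n) - 1)
  B[1, ix + 1] <- g[, 1]
  B[2, ix + 2] <- g[, 2]
  B[3, ix + 3] <- g[, 3]
  B[4, ix + 1] <- g[, 2]; B[4, ix + 2] <- g[, 1]
  B[5, ix + 2] <- g[, 3]; B[5, ix + 3] <- g[, 2]
  B[6, ix + 1] <- g[, 3]; B[6, ix + 3] <- g[, 1]
  B
}

# 4-point tetrahedral Gauss rule in barycentric coordinates (degree 2)
.tet_gauss4 <- local({
  a <- 0.5854101966249685
  b <- 0.1381966011250105
  rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a))
})

# Precompute, for a mesh + Poisson ratio: per-element dof map, unit-modulus
# stiffness triplets, a sparse strain operator G (6m x 3N) evaluating the
# element (mean) strain, and element volumes.
.fe_structure <- function(mesh, nu) {
  el <- mesh$elements
  m <- nrow(el)
  nn <- ncol(el)                     # 4 or 10
  vol <- .tet_volumes(mesh$nodes, el)
  D1 <- .D_unit(nu)
  ndof <- 3L * nrow(mesh$nodes)
  dofs <- matrix(0L, m, 3 * nn)
  for (q in seq_len(nn)) {
    dofs[, 3 * (q - 1) + 1:3] <- cbind(3L * el[, q] + 1L, 3L * el[, q] + 2L,
                                       3L * el[, q] + 3L)
  }
  blk <- (3 * nn)^2
  Ki <- matrix(0L, blk, m)
  Kj <- matrix(0L, blk, m)
  Kx <- matrix(0, blk, m)
  Gx <- matrix(0, 6 * 3 * nn, m)     # element-mean B entries
  p1 <- mesh$nodes[el[, 1] + 1, , drop = FALSE]
  J1 <- mesh$nodes[el[, 2] + 1, , drop = FALSE] - p1
  J2 <- mesh$nodes[el[, 3] + 1, , drop = FALSE] - p1
  J3 <- mesh$nodes[el[, 4] + 1, , drop = FALSE] - p1
  for (e in seq_len(m)) {
    J <- rbind(J1[e, ], J2[e, ], J3[e, ])
    Jin <- solve(J)                  # columns: grad L2, L3, L4
    gcorner <- t(cbind(-rowSums(Jin), Jin))  # 4 x 3: grads of L1..L4
    if (nn == 4L) {
      B <- .B_from_grads(gcorner)
      Ke <- vol[e] * crossprod(B, D1 %*% B)
      Gx[, e] <- as.vector(B)
    } else {
      ed <- rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(2, 4), c(3, 4))
      Ke <- matrix(0, 30, 30)
      Bsum <- matrix(0, 6, 30)
      for (q in 1:4) {
        L <- .tet_gauss4[q, ]
        g <- matrix(0, 10, 3)
        g[1:4, ] <- (4 * L - 1) * gcorner
        for (s in 1:6) {
          i <- ed[s, 1]; j <- ed[s, 2]
          g[4 + s, ] <- 4 * (L[i] * gcorner[j, ] + L[j] * gcorner[i, ])
        }
        B <- .B_from_grads(g)
        Ke <- Ke + (vol[e] / 4) * crossprod(B, D1 %*% B)
        Bsum <- Bsum + B / 4
      }
      Gx[, e] <- as.vector(Bsum)
    }
    dd <- dofs[e, ]
    Ki[, e] <- rep(dd, times = 3 * nn)
    Kj[, e] <- rep(dd, each = 3 * nn)
    Kx[, e] <- as.vector(Ke)
  }
  Gi <- matrix(0L, 6 * 3 * nn, m)
  Gj <- matrix(0L, 6 * 3 * nn, m)
  for (e in seq_len(m)) {
    Gi[, e] <- rep(6L * (e - 1L) + 1:6, times = 3 * nn)
    Gj[, e] <- rep(dofs[e, ], each = 6L)
  }
  G <- Matrix::sparseMatrix(i = as.vector(Gi), j = as.vector(Gj),
                            x = as.vector(Gx), dims = c(6 * m, ndof))
  list(Ki = as.vector(Ki), Kj = as.vector(Kj), Kx = Kx, G = G,
       vol = vol, ndof = ndof, m = m, blk = blk, nu = nu)
}

.assemble_from_structure <- function(st, E) {
  x <- st$Kx * rep(E, each = st$blk)
  Matrix::sparseMatrix(i = st$Ki, j = st$Kj, x = as.vector(x),
                       dims = c(st$ndof, st$ndof))
}

#' Assemble the global stiffness matrix
#'
#' Small-strain linear-elastic stiffness for a tetrahedral mesh with
#' per-element Young's moduli and a shared Poisson ratio. Linear (4-node)
#' elements use the exact constant-strain formulation; quadratic (10-node)
#' elements a four-point Gauss rule. The operator is symmetric and, before
#' constraints, has exactly the six rigid-body zero-energy modes. It is
#' linear in the element moduli: doubling every E doubles the matrix.
#'
#' @param mesh a [tet_mesh()].
#' @param mat a `material_field` (one row per element) or list with
#'   `young_modulus` and `poisson_ratio`.
#' @return Sparse symmetric stiffness matrix (N/mm), `Matrix::dgCMatrix`.
#' @export
assemble_stiffness <- function(mesh, mat) {
  stopifnot(inherits(mesh, "tet_mesh"))
  E <- mat$young_modulus
  if (length(E) != nrow(mesh$elements))
    stop("one material entry per element required")
  if (any(E == 0)) warning(sum(E == 0), " element(s) with zero modulus ",
                           "contribute no stiffness")
  nu <- attr(mat, "poisson_ratio")
  if (is.null(nu)) nu <- mat$poisson_ratio
  st <- .fe_structure(mesh, nu)
  .assemble_from_structure(st, E)
}

#' Element strains and stresses for a displacement field
#'
#' Evaluates the (element-mean) small strain, the stress for the given
#' material field, the von Mises equivalent stress and the volumetric
#' strain. Used by the solver's yield update and exposed for verification
#' (patch tests against closed-form constant-strain solutions).
#'
#' @param mesh a [tet_mesh()].
#' @param mat a `material_field`.
#' @param u displacement vector, length 3 * n_nodes (mm), dof order
#'   (x1, y1, z1, x2, ...).
#' @return List with `strain` (6 x m, Voigt xx, yy, zz, xy, yz, zx with
#'   engineering shears), `stress` (6 x m, MPa), `von_mises` (m),
#'   `volumetric_strain` (m).
#' @export
element_stress <- function(mesh, mat, u) {
  nu <- attr(mat, "poisson_ratio")
  st <- .fe_structure(mesh, nu)
  eps <- matrix(as.vector(st$G %*% u), nrow = 6)
  .stress_state(eps, mat$young_modulus, nu)
}

.stress_state <- function(eps, E, nu) {
  D1 <- .D_unit(nu)
  sig <- (D1 %*% eps) * rep(E, each = 6)
  vm <- sqrt(0.5 * ((sig[1, ] - sig[2, ])^2 + (sig[2, ] - sig[3, ])^2 +
                      (sig[3, ] - sig[1, ])^2) +
               3 * (sig[4, ]^2 + sig[5, ]^2 + sig[6, ]^2))
  list(strain = eps, stress = sig, von_mises = vm,
       volumetric_strain = eps[1, ] + eps[2, ] + eps[3, ])
}

# locate support/drive node sets from landmarks on a posed mesh
.define_supports <- function(mesh, cfg) {
  lm <- mesh$landmarks
  for (nm in c("head_center", "gt_point", "distal_point"))
    if (is.null(lm[[nm]]))
      stop("missing landmark '", nm, "' needed to define supports")
  nd <- mesh$nodes
  r <- cfg$patch_radius
  tol <- 1e-6                        # robust to rotation round-off
  edge <- if (is.na(mesh$target_edge)) r else mesh$target_edge
  # ball patch of radius r anchored at the centroid of the extreme node
  # layer (a centroid anchor is stable under rigid-motion round-off, where
  # a single arg-max node is not)
  ball_patch <- function(center, reach, top) {
    near <- which(sqrt(rowSums(sweep(nd, 2, center)^2)) <= reach + tol)
    if (!length(near)) return(integer(0))
    z <- nd[near, 3]
    layer <- if (top) near[z >= max(z) - 0.5 * edge - tol] else
      near[z <= min(z) + 0.5 * edge + tol]
    anchor <- colMeans(nd[layer, , drop = FALSE])
    which(sqrt(rowSums(sweep(nd, 2, anchor)^2)) <= r + tol) - 1L
  }
  # head drive patch: around the topmost layer of the femoral head
  head_set <- ball_patch(lm$head_center, 4 * r, top = TRUE)
  if (!length(head_set)) stop("no mesh nodes near the head landmark")
  # trochanter support: around the lowest layer near the GT landmark
  troch_set <- ball_patch(lm$gt_point, 4 * r, top = FALSE)
  if (!length(troch_set)) stop("no mesh nodes near the greater-trochanter ",
                               "landmark")
  # distal hinge: nodes close to the horizontal line through the distal
  # point along y (the hinge axis, perpendicular to the shaft)
  dxz <- sqrt((nd[, 1] - lm$distal_point[1])^2 +
                (nd[, 3] - lm$distal_point[3])^2)
  hinge_set <- which(dxz <= 0.75 * edge + tol) - 1L
  if (!length(hinge_set))
    hinge_set <- which.min(dxz) - 1L
  list(head = head_set, trochanter = troch_set, hinge = hinge_set)
}

#' Femoral strength by incremental sideways-fall simulation
#'
#' Displacement-controlled quasi-static solve on a posed mesh: the femoral
#' head patch is driven along global -z in increments, the trochanter
#' patch rests on a frictionless support (constrained along the load axis
#' only), and the distal hinge nodes are constrained transversely so the
#' bone can rotate only about the horizontal axis perpendicular to the
#' shaft. Elements follow a bilinear elastic-plastic law (secant-stiffness
#' iteration): an element yields when its von Mises stress exceeds the
#' tension or compression yield stress, selected by the sign of its
#' volumetric strain; the post-yield tangent is `tangent_fraction * E`.
#' Non-converged increments are bisected (up to `max_bisections`) and
#' flagged. Femoral strength is the peak resultant head reaction over the
#' run, in kN.
#'
#' @param mesh a posed [tet_mesh()]. Node sets `head`, `trochanter` and
#'   optionally `hinge` are taken from `mesh$node_sets` when present,
#'   otherwise derived from the landmarks. When no hinge set exists (e.g.
#'   verification columns), a minimal statically determinate lateral
#'   restraint is added on the trochanter patch.
#' @param mat a `material_field`.
#' @param cfg a [fall_config()].
#' @return Object of class `strength_result`: `displacement` (mm, starts
#'   at 0), `force` (N, head reaction resultant), `femoral_strength` (kN),
#'   `converged` and `yield_fraction` per increment, `reactions` (head,
#'   trochanter, hinge z-sums at the final increment).
#' @export
solve_strength <- function(mesh, mat, cfg = fall_config()) {
  stopifnot(inherits(mesh, "tet_mesh"))
  E <- mat$young_modulus
  if (length(E) != nrow(mesh$elements))
    stop("one material entry per element required")
  nu <- attr(mat, "poisson_ratio")
  sets <- mesh$node_sets
  if (is.null(sets$head) || is.null(sets$trochanter))
    sets <- .define_supports(mesh, cfg)
  head_n <- sets$head; troch_n <- sets$trochanter; hinge_n <- sets$hinge
  if (!length(head_n) || !length(troch_n))
    stop("empty head or trochanter node set")

  st <- .fe_structure(mesh, nu)
  zdof <- function(n) 3L * n + 3L
  xdof <- function(n) 3L * n + 1L
  ydof <- function(n) 3L * n + 2L

  presc <- zdof(head_n)
  fixed <- zdof(troch_n)
  if (length(hinge_n)) {
    fixed <- c(fixed, xdof(hinge_n), zdof(hinge_n))
    cen <- colMeans(mesh$nodes[hinge_n + 1, , drop = FALSE])
    pin <- hinge_n[which.min(rowSums(sweep(mesh$nodes[hinge_n + 1, ,
                                                      drop = FALSE],
                                           2, cen)^2))]
    fixed <- c(fixed, ydof(pin))
  } else {
    # statically determinate lateral restraint on the support patch
    n1 <- troch_n[1]
    fixed <- c(fixed, xdof(n1), ydof(n1))
    if (length(troch_n) > 1) {
      p <- mesh$nodes[troch_n + 1, , drop = FALSE]
      d2 <- (p[, 1] - p[1, 1])^2 + (p[, 2] - p[1, 2])^2
      n2 <- troch_n[which.max(d2)]
      t <- mesh$nodes[n2 + 1, 1:2] - mesh$nodes[n1 + 1, 1:2]
      fixed <- c(fixed, if (abs(t[1]) >= abs(t[2])) ydof(n2) else xdof(n2))
    }
  }
  fixed <- setdiff(unique(fixed), presc)
  con <- unique(c(presc, fixed))
  free <- setdiff(seq_len(st$ndof), con)

  if (cfg$max_displacement == 0) {
    return(structure(list(displacement = 0, force = 0,
                          femoral_strength = 0, converged = TRUE,
                          yield_fraction = 0, reactions = NULL,
                          config = cfg),
                     class = "strength_result"))
  }

  sy_t <- mat$yield_stress_tension
  sy_c <- mat$yield_stress_compression
  # void (zero-modulus) elements would orphan their nodes; stabilize them
  # at a negligible stiffness, far below every reported tolerance
  void <- E <= 0
  if (any(void)) {
    if (all(void)) stop("singular system: every element has zero modulus")
    warning(sum(void), " zero-modulus element(s) stabilized at 1e-9 of ",
            "the peak modulus")
    E[void] <- 1e-9 * max(E)
    sy_t[void] <- Inf
    sy_c[void] <- Inf
  }
  eta <- cfg$tangent_fraction
  Esec <- E

  solve_at <- function(d, Esec) {
    K <- .assemble_from_structure(st, Esec)
    u <- numeric(st$ndof)
    u[presc] <- -d
    rhs <- -(K[free, con, drop = FALSE] %*% u[con])
    uf <- tryCatch(Matrix::solve(K[free, free], rhs),
                   error = function(e)
                     stop("singular system after constraints: ",
                          conditionMessage(e), call. = FALSE))
    u[free] <- as.vector(uf)
    list(u = u, K = K)
  }

  update_secant <- function(u, Esec) {
    eps <- matrix(as.vector(st$G %*% u), nrow = 6)
    ss <- .stress_state(eps, rep(1, st$m), nu)   # unit-modulus stress
    e_eq <- ss$von_mises                         # equivalent strain measure
    # tension/compression yield selected by the volumetric strain sign,
    # blended smoothly near zero so the fixed-point map stays continuous
    # (a hard switch makes near-isochoric elements flicker between the
    # two yield stresses and the iteration cycle)
    e0 <- pmax(0.2 * sy_t / E, 1e-12)
    wc <- 0.5 * (1 - tanh(ss$volumetric_strain / e0))
    sy <- sy_t + (sy_c - sy_t) * wc
    sy[is.infinite(sy_t) | is.infinite(sy_c)] <-
      pmin(sy_t, sy_c)[is.infinite(sy_t) | is.infinite(sy_c)]
    sy[!is.finite(sy)] <- Inf
    ey <- sy / E
    yielded <- is.finite(ey) & e_eq > ey
    target <- ifelse(yielded, sy + eta * E * (e_eq - ey), E * e_eq)
    Enew <- E
    nz <- e_eq > 0
    Enew[nz & yielded] <- target[nz & yielded] / e_eq[nz & yielded]
    list(Esec = pmax(Enew, eta * E, 1e-12 * E), yielded = yielded)
  }

  disp <- 0; force <- 0; convs <- TRUE; yfrac <- 0
  d_cur <- 0
  base_step <- cfg$max_displacement / cfg$n_increments
  step <- base_step
  last_sol <- NULL
  n_fail <- 0
  while (d_cur < cfg$max_displacement - 1e-12) {
    d_try <- min(d_cur + step, cfg$max_displacement)
    Etrial <- Esec
    ok <- FALSE
    prev_delta <- Inf
    for (it in seq_len(cfg$max_iterations)) {
      sol <- solve_at(d_try, Etrial)
      up <- update_secant(sol$u, Etrial)
      delta <- max(abs(up$Esec - Etrial) / E)
      # full fixed-point steps while the iteration contracts; under-relax
      # only when the residual grows (oscillatory mode)
      w <- if (delta <= prev_delta) 1 else 0.5
      prev_delta <- delta
      Etrial <- Etrial + w * (up$Esec - Etrial)
      if (delta < cfg$tol) { ok <- TRUE; break }
    }
    if (!ok && n_fail < cfg$max_bisections) {
      step <- step / 2
      n_fail <- n_fail + 1
      next
    }
    if (ok) n_fail <- 0
    # accept (flagged if not converged)
    sol <- solve_at(d_try, Etrial)
    Esec <- Etrial
    last_sol <- sol
    R <- as.vector(sol$K %*% sol$u)
    fz <- abs(sum(R[presc]))
    disp <- c(disp, d_try)
    force <- c(force, fz)
    convs <- c(convs, ok)
    yfrac <- c(yfrac, mean(Esec < E * (1 - 1e-9)))
    d_cur <- d_try
    step <- base_step
  }
  if (length(disp) == 1) stop("no increment could be solved")

  R <- as.vector(last_sol$K %*% last_sol$u)
  reactions <- list(head = sum(R[presc]),
                    trochanter = sum(R[zdof(troch_n)]),
                    hinge = if (length(hinge_n)) sum(R[zdof(hinge_n)])
                    else sum(R[setdiff(fixed, zdof(troch_n))]),
                    free_residual = max(abs(R[free])))
  structure(list(displacement = disp, force = force,
                 femoral_strength = max(force) / 1000, converged = convs,
                 yield_fraction = yfrac, reactions = reactions,
                 config = cfg),
            class = "strength_result")
}

#' @export
print.strength_result <- function(x, ...) {
  cat(sprintf("Femoral strength: %.3f kN (peak head reaction)\n",
              x$femoral_strength))
  cat(sprintf("  %d increments to %.3g mm; %d converged; final yield ",
              length(x$displacement) - 1, max(x$displacement),
              sum(x$converged[-1])))
  cat(sprintf("fraction %.1f%%\n", 100 * x$yield_fraction[length(
    x$yield_fraction)]))
  invisible(x)
}

#' @export
plot.strength_result <- function(x, ...) {
  plot(x$displacement, x$force / 1000, type = "b", pch = 16,
       xlab = "head displacement (mm)", ylab = "head reaction (kN)", ...)
  graphics::abline(h = x$femoral_strength, lty = 3)
  invisible(x)
}

#' Femoral strength as a function of density scaling
#'
#' Runs the full chain (phantom voxelization, areal-BMD projection, posing,
#' material mapping, incremental strength solve) for a series of uniform
#' density scale factors applied to one phantom, exposing the relationship
#' between areal BMD and simulated strength.
#'
#' @param spec a [femur_phantom_spec()].
#' @param scales positive density scale factors.
#' @param cal a [calibration_params()].
#' @param cfg a [fall_config()].
#' @param target_edge mesh edge length, mm.
#' @param seed phantom noise seed.
#' @return `data.frame` with columns `scale`, `abmd` (g/cm2) and
#'   `strength_kN`.
#' @export
strength_vs_density <- function(spec, scales, cal = calibration_params(),
                                cfg = fall_config(), target_edge = 8,
                                seed = 1) {
  if (any(scales <= 0)) stop("scales must be > 0")
  vol0 <- generate_femur_phantom(spec, seed = seed)
  mesh <- mesh_density_volume(vol0, target_edge = target_edge)
  posed <- pose_femur(mesh, cfg)
  out <- data.frame(scale = scales, abmd = NA_real_, strength_kN = NA_real_)
  for (i in seq_along(scales)) {
    vol <- vol0
    vol$values <- vol$values * scales[i]
    out$abmd[i] <- project_abmd(vol, "y")
    mat <- map_to_elements(vol, mesh, cal)
    # materials sampled on the unposed mesh, solved on the posed one:
    # density mapping is frame-independent
    res <- solve_strength(posed, mat, cfg)
    out$strength_kN[i] <- res$femoral_strength
  }
  out
}
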