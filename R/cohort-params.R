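#' @keywords internal
"_PACKAGE"

#' @importFrom stats sd rnorm setNames lm anova pf predict approx
#'   quantile lowess coef residuals
#' @importFrom utils read.csv write.csv write.table modifyList
#' @importFrom graphics lines polygon abline
#' @importFrom grDevices adjustcolor
#' @importFrom MASS mvrnorm
#' @importFrom Matrix sparseMatrix
NULL

# Variables drawn jointly per (sex, ethnicity) cell.  t_score, bmi, tstt_sup
# and tstt_standing are derived columns, never drawn.
COHORT_VARS <- c("age", "weight", "height", "tstt", "frax_hfp", "abmd",
                 "strength")

SEXES <- c("female", "male")
ETHNICITIES <- c("Chinese", "Indian", "Malay")

#' Default linear age-trend slopes
#'
#' Per-year change of each drawn variable's conditional mean, shared across
#' cells. Signs follow the expected age-related trajectories in older Asian
#' adults: areal BMD, soft-tissue thickness, body size and femoral strength
#' decline with age while the 10-year hip-fracture probability rises.
#'
#' @return Named numeric vector of slopes (units of the variable per year).
#' @export
default_age_slopes <- function() {
  c(weight = -0.2, height = -0.15, tstt = -0.02, frax_hfp = 0.1,
    abmd = -0.004, strength = -0.05)
}

#' Default cross-variable correlation matrix for one cell
#'
#' The source cohort publishes only marginal means and SDs, so the joint
#' structure is a documented, overridable modelling choice: aBMD-strength
#' +0.7, aBMD-FRAX -0.5, soft-tissue-thickness-weight +0.6 (adiposity link;
#' BMI itself is derived from weight and height, never drawn), all other
#' non-age pairs 0. Age correlations are implied by the age-trend slopes,
#' r(age, v) = slope_v * sd_age / sd_v, clipped to [-0.9, 0.9], so that
#' conditional means are linear in age with the requested slope while
#' marginal means and SDs stay at their calibrated values.
#'
#' @param sds named numeric vector of SDs for [COHORT_VARS].
#' @param age_slopes named slopes as in [default_age_slopes()].
#' @return Correlation matrix over the drawn variables.
#' @export
default_correlation <- function(sds, age_slopes = default_age_slopes()) {
  stopifnot(all(COHORT_VARS %in% names(sds)))
  R <- diag(length(COHORT_VARS))
  dimnames(R) <- list(COHORT_VARS, COHORT_VARS)
  set <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  for (v in names(age_slopes)) {
    if (!v %in% COHORT_VARS || sds[[v]] <= 0) next
    r <- age_slopes[[v]] * sds[["age"]] / sds[[v]]
    set("age", v, max(-0.9, min(0.9, r)))
  }
  set("abmd", "strength", 0.7)
  set("abmd", "frax_hfp", -0.5)
  set("tstt", "weight", 0.6)
  R
}

# Published per-cell marginals: row order age, weight, height, bmi, tstt,
# frax_hfp, abmd, t_score, strength; one (mean, sd) pair per cell.
.table1_cells <- function() {
  list(
    male = list(
      n = c(Chinese = 494, Indian = 213, Malay = 273),
      Chinese = rbind(
        age = c(73.70, 8.14), weight = c(65.29, 10.65),
        height = c(164.66, 6.74), bmi = c(24.09, 3.87),
        tstt = c(2.31, 0.60), frax_hfp = c(2.56, 2.05),
        abmd = c(0.86, 0.13), t_score = c(-1.57, 1.00),
        strength = c(4.56, 1.76)),
      Indian = rbind(
        age = c(73.32, 8.82), weight = c(71.17, 14.33),
        height = c(166.01, 7.06), bmi = c(25.71, 4.32),
        tstt = c(3.13, 0.69), frax_hfp = c(1.34, 1.27),
        abmd = c(0.95, 0.15), t_score = c(-0.88, 1.20),
        strength = c(5.89, 2.28)),
      Malay = rbind(
        age = c(73.10, 8.31), weight = c(70.37, 13.30),
        height = c(164.12, 6.41), bmi = c(26.08, 4.47),
        tstt = c(2.99, 0.67), frax_hfp = c(1.52, 1.34),
        abmd = c(0.91, 0.14), t_score = c(-1.22, 1.08),
        strength = c(5.05, 1.82))),
    female = list(
      n = c(Chinese = 594, Indian = 305, Malay = 325),
      Chinese = rbind(
        age = c(74.20, 8.30), weight = c(55.08, 9.50),
        height = c(152.84, 6.06), bmi = c(23.57, 3.83),
        tstt = c(2.95, 0.92), frax_hfp = c(5.64, 5.03),
        abmd = c(0.72, 0.11), t_score = c(-1.64, 0.99),
        strength = c(3.54, 1.13)),
      Indian = rbind(
        age = c(74.67, 8.61), weight = c(62.74, 12.84),
        height = c(152.07, 6.70), bmi = c(27.07, 4.98),
        tstt = c(4.21, 1.06), frax_hfp = c(2.66, 2.67),
        abmd = c(0.78, 0.13), t_score = c(-1.13, 1.11),
        strength = c(4.06, 1.39)),
      Malay = rbind(
        age = c(71.91, 8.01), weight = c(63.46, 15.39),
        height = c(149.41, 6.12), bmi = c(28.35, 6.31),
        tstt = c(4.25, 1.37), frax_hfp = c(3.14, 4.01),
        abmd = c(0.75, 0.13), t_score = c(-1.43, 1.12),
        strength = c(3.55, 1.24))))
}

#' Construct per-cell cohort parameters
#'
#' Bundles, for every sex-by-ethnicity cell, the group size, the marginal
#' mean and SD of each variable, the linear age-trend slopes and the
#' cross-variable correlation matrix that together define the generating
#' distribution of [generate_cohort()].
#'
#' @param cells named list `cells[[sex]][[ethnicity]]` of two-column
#'   (mean, sd) matrices with rows age, weight, height, bmi, tstt, frax_hfp,
#'   abmd, t_score, strength.
#' @param n named list `n[[sex]]` of named ethnicity counts.
#' @param age_slopes named slopes, see [default_age_slopes()].
#' @param corr either `NULL` (build [default_correlation()] per cell from
#'   that cell's SDs) or a fixed correlation matrix used for all cells.
#' @return Object of class `cohort_params`.
#' @export
cohort_params <- function(cells, n, age_slopes = default_age_slopes(),
                          corr = NULL) {
  for (sex in names(n)) {
    if (any(n[[sex]] < 0)) stop("group sizes must be >= 0")
    for (eth in names(n[[sex]])) {
      m <- cells[[sex]][[eth]]
      if (is.null(m)) stop("missing cell parameters for ", sex, "/", eth)
      if (any(m[, 2] < 0)) stop("standard deviations must be >= 0")
    }
  }
  obj <- structure(list(cells = cells, n = n, age_slopes = age_slopes,
                        corr = corr),
                   class = "cohort_params")
  # validate the correlation matrix of every cell up-front
  for (sex in names(n)) {
    for (eth in names(n[[sex]])) .cell_correlation(obj, sex, eth)
  }
  obj
}

.cell_correlation <- function(params, sex, eth) {
  m <- params$cells[[sex]][[eth]]
  sds <- setNames(m[COHORT_VARS, 2], COHORT_VARS)
  R <- if (is.null(params$corr)) {
    default_correlation(sds, params$age_slopes)
  } else {
    params$corr
  }
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-12))
    stop("correlation matrix must be symmetric with unit diagonal")
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("correlation matrix is not positive semidefinite (min eigenvalue ",
         format(min(ev)), ")")
  R
}

#' Cohort parameters calibrated to the published descriptive table
#'
#' Returns [cohort_params()] pre-filled with the per-sex, per-ethnicity
#' marginal means/SDs and group sizes of the multi-ethnic Singaporean cohort
#' of community-dwelling adults aged 60+ (980 males: 494 Chinese, 213
#' Indian, 273 Malay; 1224 females: 594 Chinese, 305 Indian, 325 Malay).
#'
#' @inheritParams cohort_params
#' @return Object of class `cohort_params`.
#' @export
table1_cohort_params <- function(age_slopes = default_age_slopes(),
                                 corr = NULL) {
  tab <- .table1_cells()
  cells <- list(male = tab$male[ETHNICITIES], female = tab$female[ETHNICITIES])
  n <- list(male = tab$male$n, female = tab$female$n)
  cohort_params(cells, n, age_slopes = age_slopes, corr = corr)
}

#' @export
print.cohort_params <- function(x, ...) {
  tot <- sum(unlist(x$n))
  cat("Cohort generating parameters:", tot, "subjects in",
      sum(lengths(x$n)), "sex x ethnicity cells\n")
  for (sex in names(x$n)) {
    cat(sprintf("  %-6s  %s\n", sex,
                paste(sprintf("%s=%d", names(x$n[[sex]]), x$n[[sex]]),
                      collapse = ", ")))
  }
  invisible(x)
}
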