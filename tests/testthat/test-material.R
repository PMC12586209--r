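test_that("density-to-modulus chain follows the calibration equations", {
  cal <- calibration_params()
  # input chosen so apparent density is exactly 1 g/cm3 -> E = coefficient
  rho1 <- (cal$ash_fraction * 1 - cal$ash_intercept) / cal$ash_slope
  out <- density_to_modulus(rho1, cal)
  expect_equal(out$rho_app, 1, tolerance = 1e-12)
  expect_equal(out$E, cal$modulus_coeff, tolerance = 1e-9)

  # strongly negative input clamps to zero apparent density and zero E
  z <- density_to_modulus(-10, cal)
  expect_equal(z$rho_app, 0)
  expect_equal(z$E, 0)
})

test_that("power-law scaling identity and monotonicity hold", {
  cal <- calibration_params(ash_intercept = 0)  # pure power law in density
  for (rho in c(0.2, 0.7, 1.3)) {
    r <- density_to_modulus(2 * rho, cal)$E / density_to_modulus(rho, cal)$E
    expect_equal(r, 2^cal$modulus_exponent, tolerance = 1e-12)
  }
  set.seed(4)
  x <- sort(runif(50, -0.2, 2))
  E <- density_to_modulus(x)$E
  expect_true(all(diff(E) >= 0))
})

test_that("partial-volume correction restores corrupted shells only", {
  spec <- small_phantom_spec(cortical_density = 0.9,
                             trabecular_density = 0.9)
  vol <- generate_femur_phantom(spec, seed = 1)
  mask <- vol$values > 0
  expect_identical(correct_partial_volume(vol, mask, depth = 0)$values,
                   vol$values)
  # uniform phantom: nothing to correct
  fixed <- correct_partial_volume(vol, mask, depth = 1)
  expect_equal(fixed$values, vol$values, tolerance = 1e-12)

  # halve the outermost shell, then restore it
  sh <- femfall:::.shifts6
  interior1 <- mask
  for (r in seq_len(nrow(sh)))
    interior1 <- interior1 & femfall:::.shift_array(mask, sh[r, ])
  shell <- mask & !interior1
  corrupted <- vol
  corrupted$values[shell] <- 0.45
  rec <- correct_partial_volume(corrupted, mask, depth = 1)
  expect_equal(rec$values[mask], rep(0.9, sum(mask)), tolerance = 1e-12)
  # interior untouched even when shell values differ
  expect_equal(rec$values[interior1], corrupted$values[interior1])
})

test_that("correction preserves the interior value range", {
  spec <- small_phantom_spec(noise_sd = 0.1)
  vol <- generate_femur_phantom(spec, seed = 3)
  mask <- vol$values > 0
  out <- correct_partial_volume(vol, mask, depth = 1)
  sh <- femfall:::.shifts6
  interior1 <- mask
  for (r in seq_len(nrow(sh)))
    interior1 <- interior1 & femfall:::.shift_array(mask, sh[r, ])
  expect_identical(out$values[interior1], vol$values[interior1])
  expect_gte(min(out$values[mask]), min(vol$values[interior1]) - 1e-12)
  expect_lte(max(out$values[mask]), max(vol$values[interior1]) + 1e-12)
})

test_that("a mask thinner than twice the depth is rejected", {
  arr <- array(1, dim = c(5, 5, 2))   # 2-voxel slab
  vol <- density_volume(arr, spacing = 1)
  expect_error(correct_partial_volume(vol, vol$values > 0, depth = 1),
               "correction impossible")
})

test_that("element mapping is exact for uniform and linear fields", {
  vol <- small_phantom()
  mesh <- small_femur_mesh()
  cal <- calibration_params()

  uni <- density_volume(array(0.6, dim = c(30, 30, 30)), spacing = 6,
                        origin = c(-60, -60, -30))
  mat <- map_to_elements(uni, mesh, cal)
  ref <- density_to_modulus(0.6, cal)
  expect_equal(unique(round(mat$young_modulus, 9)),
               round(ref$E, 9))
  expect_equal(mat$yield_stress_compression / mat$yield_stress_tension,
               rep(cal$asymmetry_ratio, nrow(mat)), tolerance = 1e-12)

  # density linear in x: trilinear sampling at centroids is exact
  lin <- uni
  gx <- lin$origin[1] + (seq_len(30) - 1) * 6
  lin$values <- array(rep(0.01 * (gx + 70), times = 900), dim = c(30, 30, 30))
  matl <- map_to_elements(lin, mesh, cal)
  cent <- (mesh$nodes[mesh$elements[, 1] + 1, ] +
             mesh$nodes[mesh$elements[, 2] + 1, ] +
             mesh$nodes[mesh$elements[, 3] + 1, ] +
             mesh$nodes[mesh$elements[, 4] + 1, ]) / 4
  expect_equal(matl$density, 0.01 * (cent[, 1] + 70), tolerance = 1e-9)
})

test_that("elements outside the volume get zero density with a warning", {
  mesh <- small_femur_mesh()
  off <- density_volume(array(1, dim = c(4, 4, 4)), spacing = 1,
                        origin = c(5000, 5000, 5000))
  expect_warning(mat <- map_to_elements(off, mesh), "outside")
  expect_true(all(mat$density == 0))
  expect_true(all(mat$young_modulus == 0))
})

test_that("modulus field scales as density^exponent under uniform scaling", {
  vol <- small_phantom()
  mesh <- small_femur_mesh()
  cal <- calibration_params(ash_intercept = 0)
  m1 <- map_to_elements(vol, mesh, cal)
  v2 <- vol
  v2$values <- 1.7 * vol$values
  m2 <- map_to_elements(v2, mesh, cal)
  keep <- m1$density > 0
  expect_equal(m2$young_modulus[keep] / m1$young_modulus[keep],
               rep(1.7^cal$modulus_exponent, sum(keep)), tolerance = 1e-9)
})

test_that("calibration parameter validation is strict", {
  expect_error(calibration_params(ash_fraction = 0), "in \\(0, 1\\]")
  expect_error(calibration_params(poisson_ratio = 0.5), "poisson")
  expect_error(calibration_params(yield_strain = 0), "yield_strain")
  expect_error(calibration_params(asymmetry_ratio = 0.9), "asymmetry")
})
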