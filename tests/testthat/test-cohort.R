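test_that("empty and deterministic generation contracts hold", {
  p <- table1_cohort_params()
  empty <- generate_cohort(p, n_override = 0, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("id", "age", "sex", "ethnicity", "bmi", "t_score",
                    "tstt_standing", "strength") %in% names(empty)))

  a <- generate_cohort(p, n_override = 25, seed = 42)
  b <- generate_cohort(p, n_override = 25, seed = 42)
  expect_identical(a, b)
  d <- generate_cohort(p, n_override = 25, seed = 43)
  expect_false(identical(a, d))
})

test_that("generated subjects satisfy the record invariants", {
  coh <- fixture_cohort()
  expect_equal(nrow(coh), 2204)
  expect_true(all(coh$age >= 60))
  expect_true(all(coh$weight >= 0 & coh$height > 0 & coh$abmd >= 0))
  expect_true(all(coh$frax_hfp >= 0 & coh$frax_hfp <= 100))
  expect_true(all(coh$tstt_sup >= 0 & coh$strength >= 0))
  expect_equal(coh$bmi, coh$weight / (coh$height / 100)^2, tolerance = 1e-9)
  # T-score is a deterministic linear map of aBMD within each sex
  for (sx in c("male", "female")) {
    sub <- coh[coh$sex == sx, ]
    expect_equal(cor(sub$t_score, sub$abmd), 1, tolerance = 1e-12)
  }
  # standing TSTT equals the prediction equation applied to supine TSTT
  expect_equal(coh$tstt_standing,
               standing_tstt(coh$tstt_sup, coh$sex, coh$ethnicity,
                             warn_range = FALSE),
               tolerance = 1e-12)
})

test_that("invalid parameters are rejected", {
  p <- table1_cohort_params()
  vars <- c("age", "weight", "height", "tstt", "frax_hfp", "abmd",
            "strength")
  badR <- diag(7)
  dimnames(badR) <- list(vars, vars)
  badR[1, 2] <- badR[2, 1] <- 1.5   # |r| > 1 -> not PSD
  expect_error(table1_cohort_params(corr = badR), "positive semidefinite")
  expect_error(generate_cohort(p, n_override = -3, seed = 1), ">= 0")
  expect_error(generate_cohort(p), "seed")
})

test_that("untruncated cell means recover their calibration targets", {
  # Chinese-female FRAX-HFP: mean parameter 5.64 %, sd 5.03, n = 594
  p <- table1_cohort_params()
  coh <- generate_cohort(p, seed = 3, truncate = FALSE)
  cf <- coh[coh$sex == "female" & coh$ethnicity == "Chinese", ]
  expect_equal(nrow(cf), 594)
  se <- 5.03 / sqrt(594)
  expect_lt(abs(mean(cf$frax_hfp) - 5.64), 3 * se)
})

test_that("calibration recovery holds across seeds at reduced n", {
  # reduced cell size with correspondingly widened z bound; a seed passes
  # when every (cell, variable) mean is within 3.5 standard errors
  p <- table1_cohort_params()
  vars <- c("age", "weight", "height", "frax_hfp", "abmd", "strength")
  colmap <- c(age = "age", weight = "weight", height = "height",
              frax_hfp = "frax_hfp", abmd = "abmd", strength = "strength")
  n_cell <- 150
  ok <- vapply(1:15, function(s) {
    coh <- generate_cohort(p, n_override = n_cell, seed = 100 + s,
                           truncate = FALSE)
    worst <- 0
    for (sx in c("male", "female")) for (eth in c("Chinese", "Indian",
                                                  "Malay")) {
      sub <- coh[coh$sex == sx & coh$ethnicity == eth, ]
      cell <- p$cells[[sx]][[eth]]
      for (v in vars) {
        z <- abs(mean(sub[[colmap[[v]]]]) - cell[v, 1]) /
          (cell[v, 2] / sqrt(n_cell))
        worst <- max(worst, z)
      }
    }
    worst <= 3.5
  }, logical(1))
  expect_gte(mean(ok), 0.85)
})

test_that("pooling generated cells matches the analytic weighted mean", {
  p <- table1_cohort_params()
  coh <- generate_cohort(p, seed = 9, truncate = FALSE)
  males <- coh[coh$sex == "male", ]
  target <- pooled_mean(p$n$male, vapply(c("Chinese", "Indian", "Malay"),
                                         function(e)
                                           p$cells$male[[e]]["strength", 1],
                                         0))
  # pooled sd ~2 kN, n = 980 -> 4 SE guard band
  expect_lt(abs(mean(males$strength) - target), 4 * 2 / sqrt(980))
})

test_that("age-trend slopes shape the conditional means", {
  p <- table1_cohort_params()
  coh <- generate_cohort(p, n_override = 800, seed = 5, truncate = FALSE)
  cf <- coh[coh$sex == "female" & coh$ethnicity == "Chinese", ]
  sl <- coef(lm(abmd ~ age, data = cf))[["age"]]
  expect_lt(abs(sl - default_age_slopes()[["abmd"]]), 0.002)
  expect_lt(sl, 0)  # aBMD declines with age
  sl_frax <- coef(lm(frax_hfp ~ age, data = cf))[["age"]]
  expect_gt(sl_frax, 0)  # FRAX-HFP rises with age
})
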