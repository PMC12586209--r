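.toy <- function(t, frax, s, sex = "male") {
  data.frame(t_score = t, frax_hfp = frax, strength = s, sex = sex,
             ethnicity = "Chinese", stringsAsFactors = FALSE)
}

test_that("threshold boundary conventions are as documented", {
  th <- risk_thresholds()
  # T exactly -2.5 is osteoporotic (inclusive)
  expect_equal(classify_subjects(.toy(-2.5, 1, 5), th)$bmd_class,
               "osteoporotic")
  expect_equal(classify_subjects(.toy(-1, 1, 5), th)$bmd_class, "normal")
  expect_equal(classify_subjects(.toy(-1.0001, 1, 5), th)$bmd_class,
               "osteopenic")
  # FRAX exactly 2 % is at risk (inclusive)
  expect_true(classify_subjects(.toy(0, 2, 5), th)$frax_at_risk)
  # strength exactly at the threshold is NOT fragile (strict <)
  expect_false(classify_subjects(.toy(0, 1, 3, "female"), th)$
                 strength_fragile)
  expect_true(classify_subjects(.toy(0, 1, 2.999, "female"), th)$
                strength_fragile)
  # sex-specific thresholds: 3.2 kN fragile for males, not for females
  expect_true(classify_subjects(.toy(0, 1, 3.2, "male"), th)$
                strength_fragile)
  expect_false(classify_subjects(.toy(0, 1, 3.2, "female"), th)$
                 strength_fragile)
})

test_that("the worked joint classification example holds", {
  lab <- classify_subjects(.toy(-1.8, 2.4, 3.2, "male"))
  expect_equal(lab$bmd_class, "osteopenic")
  expect_true(lab$frax_at_risk)
  expect_true(lab$strength_fragile)
  expect_equal(lab$joint_class, "both")
})

test_that("missing fields are an explicit error", {
  bad <- .toy(-1, 3, 2)
  bad$strength <- NA
  expect_error(classify_subjects(bad), "missing data")
  expect_error(classify_subjects(data.frame(t_score = 1)),
               "missing columns")
})

test_that("cross-tabulation matches a hand-counted toy cohort", {
  # 2 both / 3 frax_only / 1 strength_only / 4 neither
  coh <- data.frame(
    t_score = 0,
    frax_hfp = c(5, 5, 5, 5, 5, 1, 1, 1, 1, 1),
    strength = c(1, 1, 5, 5, 5, 1, 5, 5, 5, 5),
    sex = "male", ethnicity = "Chinese", stringsAsFactors = FALSE)
  ct <- cross_tabulate(coh)
  s <- ct$strata$male$Chinese
  expect_equal(unname(s$joint_pct), c(20, 30, 10, 40))
  expect_equal(s$frax_total, 5)       # both + frax_only
  expect_equal(s$strength_total, 3)   # both + strength_only
})

test_that("partition and marginal consistency hold on generated cohorts", {
  coh <- fixture_cohort()
  ct <- cross_tabulate(coh)
  for (sx in names(ct$strata)) for (eth in names(ct$strata[[sx]])) {
    s <- ct$strata[[sx]][[eth]]
    expect_equal(sum(s$joint_counts), s$n)
    if (s$n > 0) expect_equal(sum(s$joint_pct), 100, tolerance = 1e-9)
    expect_equal(s$frax_total,
                 unname(s$joint_counts["both"] +
                          s$joint_counts["frax_only"]))
    expect_equal(s$strength_total,
                 unname(s$joint_counts["both"] +
                          s$joint_counts["strength_only"]))
  }
  # pooled strata partition as well
  for (sx in names(ct$pooled))
    expect_equal(sum(ct$pooled[[sx]]$joint_counts), ct$pooled[[sx]]$n)
})

test_that("lowering the FRAX threshold never unflags anyone", {
  coh <- fixture_cohort()
  counts <- vapply(c(4, 3, 2, 1, 0.5), function(thr) {
    ct <- cross_tabulate(coh, risk_thresholds(frax_at_risk = thr))
    ct$pooled$female$frax_total
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("classification is invariant to row order", {
  coh <- fixture_cohort()
  o <- sample(nrow(coh))
  c1 <- cross_tabulate(coh)
  c2 <- cross_tabulate(coh[o, ])
  expect_equal(c1$strata, c2$strata)
})

test_that("a no-risk cohort is all 'neither' and empty strata report n=0", {
  coh <- data.frame(t_score = 1, frax_hfp = 0.5, strength = 9,
                    sex = rep(c("male", "female"), 5),
                    ethnicity = "Malay", stringsAsFactors = FALSE)
  ct <- cross_tabulate(coh)
  expect_equal(unname(ct$pooled$male$joint_pct), c(0, 0, 0, 100))
  # ethnicities absent from a sex stratum report n = 0, NA percentages
  coh2 <- coh
  coh2$ethnicity[coh2$sex == "female"] <- "Indian"
  ct2 <- cross_tabulate(coh2)
  expect_equal(ct2$strata$male$Indian$n, 0)
  expect_true(all(is.na(ct2$strata$male$Indian$joint_pct)))
  expect_error(cross_tabulate(coh[0, ]), "empty cohort")
})

test_that("threshold construction is validated", {
  expect_error(risk_thresholds(tscore_osteoporosis = -0.5), "below")
  expect_error(risk_thresholds(frax_at_risk = 0), "> 0")
})
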