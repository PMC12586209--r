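test_that("pooled mean and sd follow the closed forms", {
  expect_equal(pooled_mean(c(1, 1), c(0, 2)), 1)
  expect_equal(pooled_mean(c(3, 3, 3), c(5, 5, 5)), 5)
  expect_error(pooled_mean(c(0, 0), c(1, 2)), "zero")
  expect_error(pooled_mean(c(-1, 2), c(1, 2)), ">= 0")
  # pooled sd of two unit-variance groups with separated means
  expect_equal(pooled_sd(c(2, 2), c(-1, 1), c(1, 1)), sqrt(2))
})

test_that("one-way ANOVA matches hand computation and conventions", {
  # SSB = 1.5, SSW = 4, df (1, 4) -> F = 1.5 exactly
  a <- anova_oneway(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
  expect_equal(a$F, 1.5)
  expect_equal(a$df, c(1, 4))
  # identical groups -> F = 0
  expect_equal(anova_oneway(c(1, 2, 3, 1, 2, 3),
                            rep(c("a", "b"), each = 3))$F, 0)
  # zero within-variance, unequal means -> Inf / 0 convention
  z <- anova_oneway(c(1, 1, 2, 2), rep(c("a", "b"), each = 2))
  expect_equal(z$F, Inf)
  expect_equal(z$p, 0)
  # permutation within groups leaves F unchanged
  set.seed(8)
  v <- rnorm(30); g <- rep(c("x", "y", "z"), 10)
  F1 <- anova_oneway(v, g)$F
  vp <- v
  for (lev in unique(g)) vp[g == lev] <- sample(v[g == lev])
  expect_equal(anova_oneway(vp, g)$F, F1, tolerance = 1e-12)
})

test_that("two-group ANOVA equals the squared pooled t statistic", {
  set.seed(21)
  for (rep in 1:5) {
    v <- rnorm(24)
    g <- rep(c("A", "B"), each = 12)
    tt <- t.test(v ~ g, var.equal = TRUE)$statistic
    expect_equal(anova_oneway(v, g)$F, unname(tt^2), tolerance = 1e-9)
  }
})

test_that("ANCOVA age adjustment recovers constructed group structure", {
  set.seed(5)
  ages <- runif(90, 60, 90)
  g <- rep(c("A", "B", "C"), 30)
  # noiseless linear data: offsets recovered exactly, F explodes
  vals <- 2 * ages + c(A = 0, B = 5, C = -3)[g]
  fit <- age_adjust(vals, ages, g)
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(unname(fit$adjusted_means["B"] - fit$adjusted_means["A"]), 5,
               tolerance = 1e-9)
  expect_equal(unname(fit$adjusted_means["C"] - fit$adjusted_means["A"]),
               -3, tolerance = 1e-9)
  expect_gt(fit$F, 1e12)

  # values independent of age: adjusted means equal raw means within noise
  vals2 <- c(A = 1, B = 2, C = 3)[g] + rnorm(90, sd = 0.1)
  fit2 <- age_adjust(vals2, ages, g)
  raw <- as.vector(tapply(vals2, g, mean))
  expect_equal(unname(fit2$adjusted_means), raw, tolerance = 0.1)

  # shifting every age leaves adjusted means unchanged
  fit3 <- age_adjust(vals2, ages + 1000, g)
  expect_equal(fit3$adjusted_means, fit2$adjusted_means, tolerance = 1e-6)

  # constant ages fall back to plain ANOVA with a warning
  expect_warning(fb <- age_adjust(vals2, rep(70, 90), g), "unidentifiable")
  expect_equal(as.vector(fb$adjusted_means), raw)
})

test_that("balanced designs make adjustment a no-op", {
  # identical age sets in each group -> age orthogonal to group
  ages <- rep(seq(60, 80, length.out = 10), 2)
  g <- rep(c("A", "B"), each = 10)
  vals <- 0.5 * ages + c(A = 0, B = 4)[g]
  fit <- age_adjust(vals, ages, g)
  raw <- as.vector(tapply(vals, g, mean))
  expect_equal(unname(fit$adjusted_means), raw, tolerance = 1e-9)
})

test_that("LOWESS trajectories satisfy exactness and invariance", {
  x <- seq(60, 90, length.out = 40)
  # constant signal -> flat curve
  cf <- lowess_trajectory(x, rep(7, 40), n_boot = 0)
  expect_equal(cf$fit, rep(7, length(cf$age)), tolerance = 1e-9)
  # noiseless line at full span -> exact reproduction
  lf <- lowess_trajectory(x, 2 * x - 5, frac = 1, n_boot = 0)
  expect_equal(lf$fit, 2 * lf$age - 5, tolerance = 1e-6)
  # permutation invariance
  set.seed(10)
  y <- 0.1 * x + rnorm(40)
  o <- sample(40)
  f1 <- lowess_trajectory(x, y, n_boot = 0)
  f2 <- lowess_trajectory(x[o], y[o], n_boot = 0)
  expect_equal(f1$fit, f2$fit, tolerance = 1e-12)
  expect_error(lowess_trajectory(rep(70, 20), rnorm(20)), "identical")
  expect_error(lowess_trajectory(x[1:5], x[1:5]), "at least 10")
})

test_that("bootstrap bands are reproducible and widen with noise", {
  x <- seq(60, 90, length.out = 60)
  set.seed(3)
  base <- 0.2 * x
  y1 <- base + rnorm(60, sd = 0.5)
  y2 <- base + rnorm(60, sd = 2.5)
  b1 <- lowess_trajectory(x, y1, n_boot = 99, seed = 17)
  b1b <- lowess_trajectory(x, y1, n_boot = 99, seed = 17)
  expect_identical(b1$lower, b1b$lower)
  b2 <- lowess_trajectory(x, y2, n_boot = 99, seed = 17)
  expect_gt(mean(b2$upper - b2$lower), mean(b1$upper - b1$lower))
  expect_true(all(b1$lower <= b1$fit + 1e-9 & b1$fit <= b1$upper + 1e-9))
})

test_that("generated cohorts reproduce the ethnic trajectory ordering", {
  # Chinese curves should lie below Indian/Malay for aBMD and strength and
  # above them for FRAX-HFP, across the interior of the age range
  ok <- 0
  for (s in 1:2) {
    coh <- generate_cohort(table1_cohort_params(), seed = 300 + s)
    fem <- coh[coh$sex == "female", ]
    fits <- lapply(c("Chinese", "Indian", "Malay"), function(eth) {
      sub <- fem[fem$ethnicity == eth, ]
      lowess_trajectory(sub$age, sub$abmd, n_boot = 0, n_grid = 30)
    })
    grid <- seq(66, 84, length.out = 15)   # interior ages
    ch <- predict(fits[[1]], grid)
    below <- (ch < predict(fits[[2]], grid)) &
      (ch < predict(fits[[3]], grid) + 0.01)
    frax <- lapply(c("Chinese", "Indian", "Malay"), function(eth) {
      sub <- fem[fem$ethnicity == eth, ]
      lowess_trajectory(sub$age, sub$frax_hfp, n_boot = 0, n_grid = 30)
    })
    above <- predict(frax[[1]], grid) > pmax(predict(frax[[2]], grid),
                                             predict(frax[[3]], grid))
    if (mean(below) >= 0.9 && mean(above) >= 0.9) ok <- ok + 1
  }
  expect_gte(ok, 2)
})

test_that("group summaries pool correctly", {
  gs <- group_summary(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(gs$table$n, c(3, 3))
  expect_equal(gs$pooled[["mean"]], 6.5)
})
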