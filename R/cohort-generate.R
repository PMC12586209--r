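# Size-weighted pooling of per-sex cell marginals, used to back out the
# young-adult aBMD reference that links aBMD to T-score.
.pooled_cell_stats <- function(params, sex, var) {
  ns <- params$n[[sex]]
  eths <- names(ns)
  mu <- vapply(eths, function(e) params$cells[[sex]][[e]][var, 1], 0)
  sd <- vapply(eths, function(e) params$cells[[sex]][[e]][var, 2], 0)
  m <- pooled_mean(ns, mu)
  s <- pooled_sd(ns, mu, sd)
  c(mean = m, sd = s)
}

#' Young-adult aBMD reference implied by the cohort parameters
#'
#' The T-score is a configurable linear map of total-hip aBMD,
#' `t = (abmd - ref_mean) / ref_sd` per sex, so that the two biomarkers can
#' never disagree in the sign of the deviation. The default reference is
#' backed out of the pooled per-sex aBMD and T-score marginals:
#' `ref_sd = sd(abmd) / sd(t)`, `ref_mean = mean(abmd) - mean(t) * ref_sd`.
#'
#' @param params a [cohort_params()] object.
#' @return Named list per sex with `mean` (g/cm2) and `sd` (g/cm2).
#' @export
tscore_reference <- function(params) {
  out <- list()
  for (sex in names(params$n)) {
    ab <- .pooled_cell_stats(params, sex, "abmd")
    ts <- .pooled_cell_stats(params, sex, "t_score")
    ref_sd <- ab[["sd"]] / ts[["sd"]]
    out[[sex]] <- list(mean = ab[["mean"]] - ts[["mean"]] * ref_sd,
                       sd = ref_sd)
  }
  out
}

.subject_columns <- c("id", "age", "sex", "ethnicity", "weight", "height",
                      "bmi", "abmd", "t_score", "frax_hfp", "tstt_sup",
                      "tstt_standing", "strength")

.empty_cohort <- function() {
  df <- data.frame(id = character(), age = numeric(), sex = character(),
                   ethnicity = character(), weight = numeric(),
                   height = numeric(), bmi = numeric(), abmd = numeric(),
                   t_score = numeric(), frax_hfp = numeric(),
                   tstt_sup = numeric(), tstt_standing = numeric(),
                   strength = numeric(), stringsAsFactors = FALSE)
  df
}

# physical bounds used for truncation; age >= 60 because the cohort is
# restricted to adults aged 60 and above
.row_in_bounds <- function(x) {
  x[, "age"] >= 60 &
    x[, "weight"] >= 0 & x[, "height"] > 0 & x[, "tstt"] >= 0 &
    x[, "frax_hfp"] >= 0 & x[, "frax_hfp"] <= 100 &
    x[, "abmd"] >= 0 & x[, "strength"] >= 0
}

#' Generate a synthetic cohort table
#'
#' Draws, within each sex-by-ethnicity cell, the joint vector (age, weight,
#' height, supine TSTT, FRAX hip-fracture probability, total-hip aBMD,
#' femoral strength) from a multivariate normal with the cell's marginal
#' means/SDs and correlation matrix, optionally truncated to physical bounds
#' by rejection (age >= 60, non-negative measurements, FRAX <= 100 %).
#' BMI, T-score and standing TSTT are then derived: BMI from weight and
#' height, T-score from aBMD via the per-sex reference map, standing TSTT
#' from supine TSTT via the sex- and ethnicity-specific linear prediction
#' equation.
#'
#' @param params a [cohort_params()] object.
#' @param n_override optional single count replacing every cell's `n`.
#' @param seed integer seed; identical (params, seed) give identical tables.
#' @param truncate logical; if `FALSE` the raw (untruncated) normal draw is
#'   kept, so sample moments are unbiased for the cell parameters.
#' @param tscore_ref reference list as from [tscore_reference()]; default
#'   derives it from `params`.
#' @param coeffs standing-TSTT prediction coefficients,
#'   default [tstt_coefficients()].
#' @return `data.frame` with one row per subject (class `c("cohort",
#'   "data.frame")`), columns id, age, sex, ethnicity, weight, height, bmi,
#'   abmd, t_score, frax_hfp, tstt_sup, tstt_standing, strength.
#' @examples
#' params <- table1_cohort_params()
#' coh <- generate_cohort(params, n_override = 20, seed = 1)
#' summary(coh$abmd)
#' @export
generate_cohort <- function(params, n_override = NULL, seed,
                            truncate = TRUE,
                            tscore_ref = tscore_reference(params),
                            coeffs = tstt_coefficients()) {
  stopifnot(inherits(params, "cohort_params"))
  if (missing(seed)) stop("an explicit seed is required")
  if (!is.null(n_override) && n_override < 0) stop("n_override must be >= 0")

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  out <- list()
  for (sex in names(params$n)) {
    for (eth in names(params$n[[sex]])) {
      n <- if (is.null(n_override)) params$n[[sex]][[eth]] else n_override
      if (n == 0) next
      cellm <- params$cells[[sex]][[eth]]
      mu <- setNames(cellm[COHORT_VARS, 1], COHORT_VARS)
      sds <- setNames(cellm[COHORT_VARS, 2], COHORT_VARS)
      R <- .cell_correlation(params, sex, eth)
      Sigma <- diag(sds) %*% R %*% diag(sds)
      x <- MASS::mvrnorm(n, mu, Sigma)
      if (n == 1) x <- matrix(x, nrow = 1, dimnames = list(NULL, COHORT_VARS))
      if (truncate) {
        for (iter in seq_len(1000)) {
          bad <- which(!.row_in_bounds(x))
          if (!length(bad)) break
          x[bad, ] <- MASS::mvrnorm(length(bad), mu, Sigma)
        }
        bad <- which(!.row_in_bounds(x))
        if (length(bad))
          stop("truncation rejection did not converge; bounds nearly ",
               "incompatible with the cell parameters")
      }
      ref <- tscore_ref[[sex]]
      df <- data.frame(
        id = sprintf("%s-%s-%04d", toupper(substr(sex, 1, 1)),
                     substr(eth, 1, 3), seq_len(n)),
        age = x[, "age"], sex = sex, ethnicity = eth,
        weight = x[, "weight"], height = x[, "height"],
        bmi = x[, "weight"] / (x[, "height"] / 100)^2,
        abmd = x[, "abmd"],
        t_score = (x[, "abmd"] - ref$mean) / ref$sd,
        frax_hfp = x[, "frax_hfp"],
        tstt_sup = x[, "tstt"],
        # linear map applied directly: untruncated draws may be negative
        tstt_standing = {
          k <- which(coeffs$sex == sex & coeffs$ethnicity == eth)
          coeffs$slope[k] * x[, "tstt"] + coeffs$intercept[k]
        },
        strength = x[, "strength"],
        stringsAsFactors = FALSE)
      out[[paste(sex, eth)]] <- df
    }
  }
  res <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE)) else
    .empty_cohort()
  class(res) <- c("cohort", "data.frame")
  res
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x), "subjects\n")
  if (nrow(x)) {
    print(table(sex = x$sex, ethnicity = x$ethnicity))
  }
  invisible(x)
}
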