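#' Hip-fracture risk thresholds
#'
#' Clinical thresholds used for cross-classification: the densitometric
#' osteoporosis T-score threshold (-2.5) and osteopenia boundary (-1), the
#' 2 % threshold on the 10-year FRAX hip-fracture probability, and the
#' sex-specific femoral strength thresholds (3 kN females, 3.5 kN males;
#' derived from a Korean cohort and not validated against incident
#' fractures, so they carry that provenance caveat). Boundary conventions
#' are explicit package choices: T-score at exactly -2.5 is osteoporotic
#' (inclusive), FRAX at exactly 2 % is at risk (inclusive), strength at
#' exactly the threshold is not fragile (strict less-than).
#'
#' @param tscore_osteoporosis,tscore_normal T-score class boundaries.
#' @param frax_at_risk FRAX-HFP threshold, %.
#' @param strength_fragile_female,strength_fragile_male kN.
#' @return Object of class `risk_thresholds`.
#' @export
risk_thresholds <- function(tscore_osteoporosis = -2.5, tscore_normal = -1,
                            frax_at_risk = 2,
                            strength_fragile_female = 3,
                            strength_fragile_male = 3.5) {
  if (tscore_osteoporosis >= tscore_normal)
    stop("tscore_osteoporosis must be below tscore_normal")
  if (frax_at_risk <= 0) stop("frax_at_risk must be > 0")
  if (strength_fragile_female <= 0 || strength_fragile_male <= 0)
    stop("strength thresholds must be > 0")
  structure(list(tscore_osteoporosis = tscore_osteoporosis,
                 tscore_normal = tscore_normal,
                 frax_at_risk = frax_at_risk,
                 strength_fragile_female = strength_fragile_female,
                 strength_fragile_male = strength_fragile_male),
            class = "risk_thresholds")
}

#' Classify subjects by risk thresholds
#'
#' Applies the three biomarker thresholds to each row: BMD class from the
#' T-score (osteoporotic if T <= -2.5, osteopenic if -2.5 < T < -1, normal
#' if T >= -1), FRAX flag if frax_hfp >= threshold, fragile-strength flag
#' if strength is strictly below the sex-specific threshold, and the joint
#' class (both / frax_only / strength_only / neither). Missing values in
#' any required field are an explicit error; nothing is imputed.
#'
#' @param cohort `data.frame` with columns t_score, frax_hfp, strength, sex.
#' @param th a [risk_thresholds()].
#' @return `data.frame` with columns bmd_class, frax_at_risk,
#'   strength_fragile, joint_class (one row per subject).
#' @export
classify_subjects <- function(cohort, th = risk_thresholds()) {
  need <- c("t_score", "frax_hfp", "strength", "sex")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  for (col in need) {
    if (anyNA(cohort[[col]]))
      stop("missing data in '", col, "': classification requires ",
           "complete records")
  }
  t <- cohort$t_score
  bmd <- ifelse(t <= th$tscore_osteoporosis, "osteoporotic",
                ifelse(t < th$tscore_normal, "osteopenic", "normal"))
  frax <- cohort$frax_hfp >= th$frax_at_risk
  s_th <- ifelse(cohort$sex == "female", th$strength_fragile_female,
                 th$strength_fragile_male)
  fragile <- cohort$strength < s_th
  joint <- ifelse(frax & fragile, "both",
                  ifelse(frax, "frax_only",
                         ifelse(fragile, "strength_only", "neither")))
  data.frame(bmd_class = bmd, frax_at_risk = frax,
             strength_fragile = fragile, joint_class = joint,
             stringsAsFactors = FALSE)
}

JOINT_CLASSES <- c("both", "frax_only", "strength_only", "neither")
BMD_CLASSES <- c("osteoporotic", "osteopenic", "normal")

.stratum_counts <- function(lab) {
  n <- nrow(lab)
  joint <- vapply(JOINT_CLASSES, function(k) sum(lab$joint_class == k), 0L)
  bmd <- vapply(BMD_CLASSES, function(k) sum(lab$bmd_class == k), 0L)
  list(n = n,
       joint_counts = joint,
       joint_pct = if (n > 0) 100 * joint / n else
         setNames(rep(NA_real_, 4), JOINT_CLASSES),
       bmd_counts = bmd,
       bmd_pct = if (n > 0) 100 * bmd / n else
         setNames(rep(NA_real_, 3), BMD_CLASSES),
       # marginal views: total flagged by each biomarker (both + exclusive)
       frax_total = sum(lab$frax_at_risk),
       strength_total = sum(lab$strength_fragile),
       tscore_osteoporotic = bmd[["osteoporotic"]])
}

#' Cross-tabulate risk classes per stratum
#'
#' For every sex-by-ethnicity stratum (and per-sex pooled strata), counts
#' and percentages of the exclusive joint classes (both / frax_only /
#' strength_only / neither) and of the BMD classes, plus the marginal
#' totals flagged by each biomarker (`frax_total = both + frax_only`,
#' `strength_total = both + strength_only`). The exclusive-partition and
#' marginal views are both reported explicitly because published summaries
#' mix the two.
#'
#' @param cohort cohort `data.frame` (needs sex, ethnicity and the columns
#'   used by [classify_subjects()]).
#' @param th a [risk_thresholds()].
#' @return Object of class `risk_crosstab`: nested list
#'   `strata[[sex]][[ethnicity]]` and `pooled[[sex]]`, each with counts and
#'   percentages; empty strata report `n = 0` and `NA` percentages.
#' @export
cross_tabulate <- function(cohort, th = risk_thresholds()) {
  if (nrow(cohort) == 0) stop("empty cohort")
  lab <- cbind(cohort[c("sex", "ethnicity")],
               classify_subjects(cohort, th))
  strata <- list()
  for (sx in sort(unique(lab$sex))) {
    strata[[sx]] <- list()
    for (eth in sort(unique(lab$ethnicity))) {
      strata[[sx]][[eth]] <-
        .stratum_counts(lab[lab$sex == sx & lab$ethnicity == eth, ])
    }
  }
  pooled <- lapply(split(lab, lab$sex), .stratum_counts)
  structure(list(strata = strata, pooled = pooled, thresholds = th),
            class = "risk_crosstab")
}

#' @export
print.risk_crosstab <- function(x, ...) {
  cat("Risk cross-classification (percent of stratum)\n")
  fmt <- function(s) sprintf(
    "n=%4d  both %5.1f  frax_only %5.1f  strength_only %5.1f  neither %5.1f",
    s$n, s$joint_pct[["both"]], s$joint_pct[["frax_only"]],
    s$joint_pct[["strength_only"]], s$joint_pct[["neither"]])
  for (sx in names(x$pooled)) {
    cat(sprintf("  %-6s pooled   %s\n", sx, fmt(x$pooled[[sx]])))
    for (eth in names(x$strata[[sx]]))
      cat(sprintf("    %-10s   %s\n", eth, fmt(x$strata[[sx]][[eth]])))
  }
  invisible(x)
}
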