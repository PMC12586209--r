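#' Standing-TSTT prediction coefficients
#'
#' Sex- and ethnicity-specific slope/intercept pairs of the linear equation
#' predicting standing trochanteric soft tissue thickness (TSTT, cm) from
#' the supine measurement: `TSTT = slope * TSTT_SUP + intercept`. Defaults
#' are the published values for older Singaporean adults: slopes Chinese
#' 0.63 (m) / 0.59 (f), Indian 0.54 / 0.51, Malay 0.53 / 0.62; intercepts
#' (cm) Chinese 3.12 / 2.29, Indian 10.54 / 12.26, Malay 8.94 / 6.23.
#' Coefficients are plain data and can be replaced wholesale.
#'
#' @param table optional replacement `data.frame` with columns sex,
#'   ethnicity, slope, intercept covering all six cells.
#' @return `data.frame` with one row per (sex, ethnicity) cell.
#' @export
tstt_coefficients <- function(table = NULL) {
  if (is.null(table)) {
    table <- data.frame(
      sex = rep(c("male", "female"), each = 3),
      ethnicity = rep(c("Chinese", "Indian", "Malay"), 2),
      slope = c(0.63, 0.54, 0.53, 0.59, 0.51, 0.62),
      intercept = c(3.12, 10.54, 8.94, 2.29, 12.26, 6.23),
      stringsAsFactors = FALSE)
  }
  need <- c("sex", "ethnicity", "slope", "intercept")
  if (!all(need %in% names(table))) stop("coefficient table needs columns ",
                                         paste(need, collapse = ", "))
  if (any(table$slope <= 0)) stop("slopes must be positive")
  key <- interaction(table$sex, table$ethnicity, drop = TRUE)
  full <- expand.grid(sex = c("male", "female"),
                      ethnicity = c("Chinese", "Indian", "Malay"))
  missing <- !paste(full$sex, full$ethnicity) %in%
    paste(table$sex, table$ethnicity)
  if (any(missing)) stop("coefficient table is missing cells: ",
                         paste(paste(full$sex, full$ethnicity)[missing],
                               collapse = "; "))
  if (anyDuplicated(key)) stop("duplicate (sex, ethnicity) rows")
  table
}

#' Predict standing TSTT from supine TSTT
#'
#' Applies the sex- and ethnicity-specific linear prediction equation
#' cell by cell. Vectorized over all arguments; unknown (sex, ethnicity)
#' combinations are an error, never silently pooled.
#'
#' @param tstt_sup supine trochanteric soft tissue thickness, cm (>= 0).
#' @param sex "male" or "female" (recycled).
#' @param ethnicity "Chinese", "Indian" or "Malay" (recycled).
#' @param coeffs coefficient table from [tstt_coefficients()].
#' @param warn_range warn when inputs fall outside the 0-10 cm range over
#'   which the linear fit is considered trustworthy.
#' @return Standing TSTT, cm.
#' @examples
#' standing_tstt(2, "male", "Chinese")   # 0.63 * 2 + 3.12 = 4.38
#' @export
standing_tstt <- function(tstt_sup, sex, ethnicity,
                          coeffs = tstt_coefficients(), warn_range = TRUE) {
  n <- max(length(tstt_sup), length(sex), length(ethnicity))
  tstt_sup <- rep_len(tstt_sup, n)
  sex <- rep_len(as.character(sex), n)
  ethnicity <- rep_len(as.character(ethnicity), n)
  if (any(tstt_sup < 0)) stop("tstt_sup must be >= 0")
  idx <- match(paste(sex, ethnicity), paste(coeffs$sex, coeffs$ethnicity))
  if (anyNA(idx)) {
    bad <- unique(paste(sex, ethnicity)[is.na(idx)])
    stop("no TSTT coefficients for: ", paste(bad, collapse = "; "))
  }
  if (warn_range && any(tstt_sup > 10))
    warning("supine TSTT above 10 cm: outside the calibrated range of the ",
            "prediction equation")
  coeffs$slope[idx] * tstt_sup + coeffs$intercept[idx]
}

#' Planar DXA-like image container
#'
#' A minimal 2D areal-density image: a numeric matrix (rows = cranio-caudal,
#' columns = lateral) with a pixel spacing in mm, as produced by projecting
#' a density phantom or by a synthetic whole-body silhouette.
#'
#' @param values numeric matrix, non-negative.
#' @param pixel_spacing pixel size, mm.
#' @param trochanter_row optional row index where the greater trochanter is
#'   known to lie; when absent, measurement searches for the widest bone row.
#' @return Object of class `dxa_planar_image`.
#' @export
dxa_planar_image <- function(values, pixel_spacing = 1,
                             trochanter_row = NULL) {
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("image values must be finite and >= 0")
  if (pixel_spacing <= 0) stop("pixel_spacing must be > 0")
  structure(list(values = values, pixel_spacing = pixel_spacing,
                 trochanter_row = trochanter_row),
            class = "dxa_planar_image")
}

#' Measure supine TSTT on a planar image
#'
#' Simplified trochanteric soft-tissue measurement for phantom images: at
#' the greater-trochanter row (supplied, or detected as the row with the
#' widest bone extent within a configurable row band), the lateral distance
#' from the outer bone edge to the skin edge is returned in cm. "Bone" and
#' "body" are defined by two intensity thresholds. The procedure is a
#' documented stand-in validated only on synthetic phantoms; it makes no
#' attempt to reproduce a clinical image-processing chain.
#'
#' @param img a [dxa_planar_image()].
#' @param side "left" (lateral edge at low column index) or "right".
#' @param bone_threshold intensity at or above which a pixel counts as bone.
#' @param body_threshold intensity at or above which a pixel counts as body.
#' @param band optional integer range of rows to search (default all rows).
#' @return Supine TSTT, cm.
#' @export
measure_tstt_sup <- function(img, side = c("left", "right"),
                             bone_threshold = 1, body_threshold = 0.05,
                             band = NULL) {
  stopifnot(inherits(img, "dxa_planar_image"))
  side <- match.arg(side)
  v <- img$values
  if (is.null(band)) band <- seq_len(nrow(v))
  bone <- v >= bone_threshold
  body <- v >= body_threshold
  if (!is.null(img$trochanter_row)) {
    row <- img$trochanter_row
  } else {
    widths <- vapply(band, function(r) {
      cols <- which(bone[r, ])
      if (!length(cols)) 0L else diff(range(cols)) + 1L
    }, 0L)
    if (all(widths == 0)) stop("no bone pixels in the search band")
    row <- band[which.max(widths)]
  }
  bcols <- which(bone[row, ])
  scols <- which(body[row, ])
  if (!length(bcols)) stop("no bone pixels in the trochanter row")
  if (!length(scols)) stop("no body pixels in the trochanter row")
  if (side == "left") {
    bone_edge <- min(bcols)
    skin_edge <- min(scols)
    px <- bone_edge - skin_edge
  } else {
    bone_edge <- max(bcols)
    skin_edge <- max(scols)
    px <- skin_edge - bone_edge
  }
  if (px < 0) stop("skin edge lies medial to the bone edge: negative ",
                   "soft-tissue thickness")
  px * img$pixel_spacing / 10
}
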