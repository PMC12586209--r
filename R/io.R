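.cohort_mandatory <- c("id", "age", "sex", "ethnicity", "weight", "height",
                       "abmd", "t_score", "frax_hfp", "tstt_sup")

# documented normalization of case/spelling variants
.normalize_ethnicity <- function(x) {
  map <- c(chinese = "Chinese", indian = "Indian", malay = "Malay")
  lx <- tolower(trimws(x))
  out <- unname(map[lx])
  bad <- is.na(out)
  if (any(bad)) stop("unknown ethnicity value(s): ",
                     paste(unique(x[bad]), collapse = ", "))
  changed <- out != x
  if (any(changed))
    warning(sum(changed), " ethnicity value(s) normalized (e.g. '",
            x[changed][1], "' -> '", out[changed][1], "')")
  out
}

.normalize_sex <- function(x) {
  map <- c(male = "male", m = "male", female = "female", f = "female")
  lx <- tolower(trimws(x))
  out <- unname(map[lx])
  bad <- is.na(out)
  if (any(bad)) stop("unknown sex value(s): ",
                     paste(unique(x[bad]), collapse = ", "))
  changed <- out != x
  if (any(changed))
    warning(sum(changed), " sex value(s) normalized")
  out
}

#' Read a cohort table from CSV
#'
#' Comma-separated, "." decimal, UTF-8, mandatory header. Sex and ethnicity
#' case variants are normalized with a warning; unknown columns are kept as
#' passthrough. A missing mandatory column is a schema error naming the
#' column; an unparseable numeric cell is an error naming the line.
#'
#' @param path CSV file path.
#' @return Cohort `data.frame` (class `c("cohort", "data.frame")`).
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                 comment.char = "#")
  miss <- setdiff(.cohort_mandatory, names(df))
  if (length(miss))
    stop("schema error: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  df$sex <- .normalize_sex(df$sex)
  df$ethnicity <- .normalize_ethnicity(df$ethnicity)
  numcols <- setdiff(.cohort_mandatory, c("id", "sex", "ethnicity"))
  numcols <- c(numcols, intersect(c("bmi", "tstt_standing", "strength"),
                                  names(df)))
  for (col in numcols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad))
      stop("unparseable value in column '", col, "' at data line ",
           bad[1], ": '", df[[col]][bad[1]], "'")
    df[[col]] <- v
  }
  class(df) <- c("cohort", "data.frame")
  df
}

#' Write a cohort table to CSV
#'
#' @param cohort cohort `data.frame`.
#' @param path output CSV path.
#' @param config_hash optional run hash written as a leading `#` comment
#'   line (skipped on read).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, config_hash = NULL) {
  if (!is.null(config_hash))
    writeLines(paste0("# config_hash: ", config_hash), path)
  suppressWarnings(
    write.table(as.data.frame(cohort), path, row.names = FALSE,
                append = !is.null(config_hash), sep = ",", dec = ".",
                qmethod = "double", fileEncoding = "UTF-8"))
  invisible(path)
}

#' Write a tetrahedral mesh as legacy ASCII VTK
#'
#' Unstructured-grid export (cell types 10 / 24 for linear / quadratic
#' tetrahedra) with optional point data (e.g. displacement) and cell data
#' (e.g. modulus, yield flag), for inspection in standard viewers.
#'
#' @param mesh a [tet_mesh()].
#' @param path output `.vtk` path.
#' @param point_data named list of per-node scalars (length n) or n x 3
#'   vectors.
#' @param cell_data named list of per-element scalars.
#' @return `path`, invisibly.
#' @export
write_vtk_tet <- function(mesh, path, point_data = list(),
                          cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$elements)
  npe <- ncol(mesh$elements)
  w("# vtk DataFile Version 3.0")
  w("femfall tetrahedral mesh")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS ", n, " double")
  writeLines(apply(mesh$nodes, 1, paste, collapse = " "), con)
  w("CELLS ", m, " ", m * (npe + 1))
  writeLines(paste(npe, apply(mesh$elements, 1, paste, collapse = " ")),
             con)
  w("CELL_TYPES ", m)
  writeLines(rep(if (npe == 4) "10" else "24", m), con)
  if (length(point_data)) {
    w("POINT_DATA ", n)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v) && ncol(v) == 3) {
        w("VECTORS ", nm, " double")
        writeLines(apply(v, 1, paste, collapse = " "), con)
      } else {
        w("SCALARS ", nm, " double 1")
        w("LOOKUP_TABLE default")
        writeLines(format(v, trim = TRUE), con)
      }
    }
  }
  if (length(cell_data)) {
    w("CELL_DATA ", m)
    for (nm in names(cell_data)) {
      w("SCALARS ", nm, " double 1")
      w("LOOKUP_TABLE default")
      writeLines(format(cell_data[[nm]], trim = TRUE), con)
    }
  }
  invisible(path)
}

#' Write / read a density volume as a documented ASCII grid
#'
#' Plain-text format: a header with `dims`, `spacing`, `origin` and the
#' landmark lines, then the voxel values in x-fastest order, one z-slab of
#' whitespace-separated values per line group. Diff-friendly and
#' platform-independent.
#'
#' @param vol a [density_volume()].
#' @param path output path.
#' @return `path` (write) or a [density_volume()] (read).
#' @export
write_density_grid <- function(vol, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- dim(vol$values)
  writeLines(c("femfall density grid v1",
               paste("dims", paste(d, collapse = " ")),
               paste("spacing", paste(vol$spacing, collapse = " ")),
               paste("origin", paste(vol$origin, collapse = " "))), con)
  for (nm in names(vol$landmarks))
    writeLines(paste("landmark", nm,
                     paste(vol$landmarks[[nm]], collapse = " ")), con)
  writeLines("values", con)
  writeLines(paste(format(as.vector(vol$values), trim = TRUE,
                          digits = 10), collapse = " "), con)
  invisible(path)
}

#' @rdname write_density_grid
#' @export
read_density_grid <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "femfall density grid v1")
    stop("not a femfall density grid file")
  take <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)[1]
    as.numeric(strsplit(sub(paste0("^", key, " "), "", ln), " +")[[1]])
  }
  d <- as.integer(take("dims"))
  lms <- list()
  for (ln in grep("^landmark ", lines, value = TRUE)) {
    parts <- strsplit(ln, " +")[[1]]
    lms[[parts[2]]] <- as.numeric(parts[-(1:2)])
  }
  vi <- which(lines == "values")
  vals <- as.numeric(strsplit(paste(lines[(vi + 1):length(lines)],
                                    collapse = " "), " +")[[1]])
  density_volume(array(vals, dim = d), spacing = take("spacing"),
                 origin = take("origin"), landmarks = lms)
}
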