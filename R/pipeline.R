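# FNV-1a hash of a string -> 8 hex chars; used to stamp outputs so that
# files from different runs/configs are distinguishable
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

.config_hash <- function(cfg) {
  .fnv1a(jsonlite::toJSON(cfg[setdiff(names(cfg), "out_dir")],
                          auto_unbox = TRUE, digits = NA))
}

#' Pipeline configuration
#'
#' Builds (and eagerly validates) the configuration of [run_pipeline()]
#' from a named list or a YAML/JSON file. Recognized sections: `seed`
#' (master seed), `out_dir`, `cohort` (`n_override`, `truncate`, or
#' `csv` to read an existing table instead of simulating), `phantom`
#' (arguments of [femur_phantom_spec()]), `calibration`
#' ([calibration_params()] arguments), `fall` ([fall_config()] arguments),
#' `thresholds` ([risk_thresholds()] arguments), `fe` (`enabled`,
#' `scales`, `target_edge`), `trajectories` (`vars`, `frac`, `n_boot`).
#' Referenced files must exist at validation time, so a malformed run
#' fails before any compute.
#'
#' @param config named list, or path to a YAML (.yaml/.yml) or JSON file.
#' @param out_dir output directory (created by [run_pipeline()]).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list(), out_dir = config$out_dir) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config) else
      jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(
    seed = 1,
    out_dir = if (is.null(out_dir)) "femfall-out" else out_dir,
    cohort = list(n_override = NULL, truncate = TRUE, csv = NULL),
    phantom = list(),
    calibration = list(),
    fall = list(),
    thresholds = list(),
    fe = list(enabled = TRUE, scales = c(0.8, 1, 1.2), target_edge = 8),
    trajectories = list(vars = c("abmd", "frax_hfp", "tstt_sup",
                                 "strength"),
                        frac = 2 / 3, n_boot = 0))
  cfg <- modifyList(defaults, config)
  if (!is.null(cfg$cohort$csv) && !file.exists(cfg$cohort$csv))
    stop("cohort csv does not exist: ", cfg$cohort$csv)
  # constructor calls validate the parameter sections eagerly
  do.call(femur_phantom_spec, cfg$phantom)
  do.call(calibration_params, cfg$calibration)
  do.call(fall_config, cfg$fall)
  do.call(risk_thresholds, cfg$thresholds)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Mirrors the study's methods order: simulate (or read) the cohort,
#' derive standing TSTT, optionally run the phantom finite-element
#' strength chain, fit per-stratum LOWESS age trajectories, and
#' cross-classify risk. Each stage's outputs are written under `out_dir`
#' (cohort.csv, strength.json, trajectories/<var>_<sex>_<eth>.csv,
#' risk_summary.json) together with a run manifest (package version, seed,
#' config hash, per-stage status). Stage seeds are derived from the master
#' seed by a fixed counter (cohort +1, phantom +2, trajectories +3), so
#' any stage can be reproduced in isolation. A failing stage is recorded
#' in the manifest and later stages that do not depend on it still run;
#' outputs carry the config hash so mixed runs are detectable.
#'
#' @param cfg a [pipeline_config()] (or list / path accepted by it).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (!inherits(cfg, "pipeline_config")) cfg <- pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(cfg)
  seed <- as.integer(cfg$seed)
  manifest <- list(package = "femfall",
                   version = as.character(utils::packageVersion("femfall")),
                   seed = seed, config_hash = hash,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  note <- function(name, status, outputs = NULL, error = NULL) {
    manifest$stages[[name]] <<- list(status = status,
                                     outputs = as.list(outputs),
                                     error = error)
  }
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      note(name, "failed", error = conditionMessage(res))
      NULL
    } else {
      note(name, "ok", outputs = res$outputs)
      res$value
    }
  }

  cohort <- run_stage("cohort", function() {
    coh <- if (!is.null(cfg$cohort$csv)) {
      x <- read_cohort(cfg$cohort$csv)
      if (!"tstt_standing" %in% names(x))
        x$tstt_standing <- standing_tstt(x$tstt_sup, x$sex, x$ethnicity,
                                         warn_range = FALSE)
      x
    } else {
      generate_cohort(table1_cohort_params(),
                      n_override = cfg$cohort$n_override,
                      seed = seed + 1L, truncate = cfg$cohort$truncate)
    }
    f <- file.path(cfg$out_dir, "cohort.csv")
    write_cohort(coh, f, config_hash = hash)
    list(value = coh, outputs = f)
  })

  if (isTRUE(cfg$fe$enabled)) {
    run_stage("fe_strength", function() {
      spec <- do.call(femur_phantom_spec, cfg$phantom)
      tab <- strength_vs_density(spec, cfg$fe$scales,
                                 cal = do.call(calibration_params,
                                               cfg$calibration),
                                 cfg = do.call(fall_config, cfg$fall),
                                 target_edge = cfg$fe$target_edge,
                                 seed = seed + 2L)
      f <- file.path(cfg$out_dir, "strength.json")
      jsonlite::write_json(list(config_hash = hash, table = tab), f,
                           auto_unbox = TRUE, digits = NA)
      list(value = tab, outputs = f)
    })
  } else {
    note("fe_strength", "skipped")
  }

  if (!is.null(cohort)) {
    run_stage("trajectories", function() {
      dirn <- file.path(cfg$out_dir, "trajectories")
      dir.create(dirn, showWarnings = FALSE)
      fits <- cohort_trajectories(cohort, vars = cfg$trajectories$vars,
                                  frac = cfg$trajectories$frac,
                                  n_boot = cfg$trajectories$n_boot,
                                  seed = seed + 3L)
      files <- character()
      for (v in names(fits)) for (sx in names(fits[[v]]))
        for (eth in names(fits[[v]][[sx]])) {
          ft <- fits[[v]][[sx]][[eth]]
          f <- file.path(dirn, paste0(v, "_", sx, "_", eth, ".csv"))
          df <- data.frame(config_hash = hash, age = ft$age, fit = ft$fit)
          if (!is.null(ft$lower)) {
            df$lower <- ft$lower
            df$upper <- ft$upper
          }
          write.csv(df, f, row.names = FALSE)
          files <- c(files, f)
        }
      list(value = fits, outputs = files)
    })

    run_stage("classification", function() {
      th <- do.call(risk_thresholds, cfg$thresholds)
      ct <- cross_tabulate(cohort, th)
      risk <- cbind(cohort["id"], classify_subjects(cohort, th))
      f1 <- file.path(cfg$out_dir, "risk.csv")
      write.csv(cbind(config_hash = hash, risk), f1, row.names = FALSE)
      f2 <- file.path(cfg$out_dir, "risk_summary.json")
      jsonlite::write_json(list(config_hash = hash,
                                pooled = ct$pooled, strata = ct$strata),
                           f2, auto_unbox = TRUE, digits = NA)
      list(value = ct, outputs = c(f1, f2))
    })
  }

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
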