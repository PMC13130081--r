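#' Pipeline run configuration
#'
#' Bundles everything a full analysis run needs; the configuration is
#' serialized into the output directory for provenance and its MD5 hash is
#' stamped into every report CSV (first line, `# config_hash: ...`), so no
#' report can be mistaken as coming from a different configuration.
#'
#' @param preprocess a [preprocess_config()]
#' @param theoretical_max named per-game level maxima
#' @param exclude subject ids excluded from the validity correlations
#' @param seed seed recorded for any resampling-based statistics
#' @param min_prominence,min_separation repetition-segmentation thresholds
#'   forwarded to the exergame profiles
#' @return object of class `run_config`
#' @export
run_config <- function(preprocess = preprocess_config(),
                       theoretical_max = default_theoretical_max(),
                       exclude = character(), seed = 1L,
                       min_prominence = 10, min_separation = 0.4) {
  structure(list(preprocess = preprocess,
                 theoretical_max = theoretical_max,
                 exclude = exclude, seed = as.integer(seed),
                 min_prominence = min_prominence,
                 min_separation = min_separation),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              force = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

write_report_csv <- function(df, path, hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(as.data.frame(df), con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline report CSV
#'
#' @param path report file written by [run_pipeline()]
#' @return tibble; the config hash is attached as attribute `config_hash`
#' @export
read_report_csv <- function(path) {
  first <- readLines(path, n = 1)
  df <- tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                          stringsAsFactors = FALSE))
  attr(df, "config_hash") <- sub("^# config_hash: ", "", first)
  df
}

#' Run the full analysis pipeline
#'
#' Chains validation, pre-processing, feature extraction, level
#' aggregation, progression/NEI computation, the clinical validity
#' analysis, and the questionnaire analysis over a cohort, writing the
#' report bundle into `out_dir`:
#' `trial_features.csv`, `level_summary.csv`, `progression.csv`,
#' `nei.csv`, `level_distribution.csv`, `validity.csv`,
#' `questionnaire.csv`, plus `run_log.json` with the serialized
#' configuration. Fixed inputs, configuration, and seed give
#' byte-identical outputs.
#'
#' @param cohort either a cohort list as returned by [simulate_cohort()]
#'   (fields `trials`, optionally `records`, `clinical`, `questionnaire`)
#'   or a directory containing `trials/*.json`, `clinical.csv`, and
#'   `questionnaire.csv`
#' @param out_dir output directory (created if missing)
#' @param config a [run_config()]
#' @return invisibly, a named vector of the report paths
#' @export
run_pipeline <- function(cohort, out_dir, config = run_config()) {
  if (is.character(cohort)) {
    trial_files <- list.files(file.path(cohort, "trials"),
                              pattern = "\\.json$", full.names = TRUE)
    if (!length(trial_files)) stop("stage validate: no trial files in ", cohort)
    records <- lapply(trial_files, read_trial,
                      theoretical_max = config$theoretical_max)
    tabs <- read_cohort_tables(file.path(cohort, "clinical.csv"),
                               file.path(cohort, "questionnaire.csv"))
    cohort <- list(trials = as_trial_table(records), records = records,
                   clinical = tabs$clinical, questionnaire = tabs$questionnaire)
  }
  if (!nrow(cohort$trials)) stop("stage validate: cohort contains no trials")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  set.seed(config$seed)
  paths <- c()
  emit <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    write_report_csv(df, p, hash)
    paths[name] <<- p
  }

  # per-trial features (requires materialized trajectories)
  if (!is.null(cohort$records)) {
    feats <- lapply(cohort$records, function(tr) {
      prof <- exergame_profile(tr$exergame,
                               min_prominence = config$min_prominence,
                               min_separation = config$min_separation)
      fv <- tryCatch(extract_features(tr, config$preprocess, prof),
                     error = function(e) {
                       stop("stage features: trial ", tr$subject_id, "/",
                            tr$exergame, " s", tr$session_index, ": ",
                            conditionMessage(e))
                     })
      tibble::as_tibble(c(
        list(subject_id = tr$subject_id, exergame = tr$exergame,
             mode = if (is.null(tr$mode)) NA_character_ else tr$mode,
             level = tr$level, session_index = tr$session_index),
        as.list(fv)
      ))
    })
    features <- dplyr::bind_rows(feats)
    emit(features, "trial_features")
    emit(aggregate_by_level(features), "level_summary")
  } else {
    # metadata-only cohorts still produce the (empty) kinematic reports
    emit(tibble(note = "no trajectories materialized"), "trial_features")
    emit(tibble(note = "no trajectories materialized"), "level_summary")
  }

  progression <- extract_progression(cohort$trials, config$theoretical_max)
  emit(progression, "progression")
  nei <- nei_results(progression, config$theoretical_max)
  emit(nei, "nei")
  emit(level_distribution(cohort$trials), "level_distribution")

  subsc <- cohort_subscores(cohort$clinical)
  emit(nei_validity(nei, subsc, exclude = config$exclude), "validity")

  qa <- questionnaire_analysis(cohort$questionnaire, nei)
  qrep <- dplyr::bind_rows(
    dplyr::mutate(qa$item_summary, section = "item_summary",
                  bucket = NA_character_, rho = NA_real_, p = NA_real_),
    dplyr::mutate(qa$trend, section = "trend", rho = NA_real_, p = NA_real_),
    dplyr::mutate(qa$correlations, section = "nei_correlation",
                  bucket = NA_character_, mean = NA_real_, sd = NA_real_)
  )
  emit(qrep[, c("section", "item", "bucket", "mean", "sd", "rho", "p")],
       "questionnaire")

  log_path <- file.path(out_dir, "run_log.json")
  writeLines(jsonlite::toJSON(list(config = unclass(config),
                                   config_hash = hash,
                                   n_trials = nrow(cohort$trials),
                                   n_subjects = length(unique(cohort$trials$subject_id)),
                                   reports = as.list(basename(paths))),
                              auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                              digits = NA),
             log_path)
  paths["run_log"] <- log_path
  invisible(paths)
}

#' Write a simulated cohort to disk in the pipeline's input layout
#'
#' @param cohort result of [simulate_cohort()] (with trajectories)
#' @param dir target directory (gets `trials/*.json`, `clinical.csv`,
#'   `questionnaire.csv`, `ground_truth_progression.csv`)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  if (is.null(cohort$records)) {
    stop("cohort has no materialized trajectories; ",
         "use cohort_spec(with_trajectories = TRUE)")
  }
  dir.create(file.path(dir, "trials"), recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(cohort$records)) {
    tr <- cohort$records[[k]]
    fn <- sprintf("%s_%s_s%02d_%03d.json", tr$subject_id, tr$exergame,
                  tr$session_index, k)
    write_trial(tr, file.path(dir, "trials", fn))
  }
  write_cohort_tables(cohort$clinical, cohort$questionnaire,
                      file.path(dir, "clinical.csv"),
                      file.path(dir, "questionnaire.csv"))
  utils::write.csv(as.data.frame(cohort$progression),
                   file.path(dir, "ground_truth_progression.csv"),
                   row.names = FALSE)
  invisible(dir)
}
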