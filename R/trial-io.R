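#' Write a trial record to JSON
#'
#' Serializes a trial to the package's JSON trial schema (UTF-8, one trial
#' per file): top-level keys `meta`, `landmarks` (array of `{t, xyz[33][3]}`),
#' and `events`. Timestamps and coordinates are written as decimal numbers at
#' full precision so that [read_trial()] restores the logical content within
#' float round-trip error. A machine-readable description of the schema ships
#' in `inst/extdata/trial-schema.json`.
#'
#' @param trial a `trial_record`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "trial_record"))
  tr <- trial$trajectory
  L <- length(tr$timestamps)
  landmarks <- lapply(seq_len(L), function(i) {
    list(t = tr$timestamps[i],
         xyz = matrix(tr$positions[i, , ], ncol = 3))
  })
  events <- lapply(seq_len(nrow(trial$events)), function(i) {
    e <- list(kind = trial$events$kind[i], t = trial$events$t[i])
    pl <- trial$events$payload[[i]]
    if (!is.null(pl)) e$payload <- pl
    e
  })
  doc <- list(
    meta = list(
      subject_id = trial$subject_id,
      exergame = trial$exergame,
      level = trial$level,
      session_index = trial$session_index,
      mode = trial$mode,
      completed = trial$completed,
      nominal_fps = tr$nominal_fps,
      landmark_names = tr$landmark_names
    ),
    landmarks = landmarks,
    events = events
  )
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null"), con)
  invisible(path)
}

#' Read a trial record from JSON
#'
#' Parses and fully validates a trial file written in the package's JSON
#' schema. Schema violations raise an error naming the offending field;
#' non-monotone timestamps raise an error. Frames containing non-finite or
#' missing coordinates are retained and flagged in the trajectory's quality
#' report (see [trial_quality_report()]); they are never silently dropped.
#'
#' @param path path to a trial JSON file
#' @param theoretical_max per-game maximum levels used for validation
#' @return a validated `trial_record`
#' @export
read_trial <- function(path, theoretical_max = default_theoretical_max()) {
  if (!file.exists(path)) stop("trial file does not exist: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("meta", "landmarks", "events")) {
    if (is.null(doc[[key]])) stop("trial document missing field '", key, "'")
  }
  meta <- doc$meta
  for (key in c("subject_id", "exergame", "level", "session_index",
                "completed", "nominal_fps")) {
    if (is.null(meta[[key]])) stop("trial meta missing field 'meta.", key, "'")
  }
  L <- length(doc$landmarks)
  if (L < 1) stop("field 'landmarks' must contain at least one frame")
  ts <- numeric(L)
  pos <- array(NA_real_, dim = c(L, n_pose_landmarks(), 3))
  for (i in seq_len(L)) {
    fr <- doc$landmarks[[i]]
    if (is.null(fr$t)) stop("frame ", i, " missing field 'landmarks[].t'")
    ts[i] <- as.numeric(fr$t)
    xyz <- fr$xyz
    if (is.null(xyz) || length(xyz) != n_pose_landmarks()) {
      stop("frame ", i, " has ", length(xyz),
           " landmarks in field 'landmarks[].xyz'; expected 33")
    }
    for (j in seq_along(xyz)) {
      v <- xyz[[j]]
      if (length(v) != 3) {
        stop("frame ", i, " landmark ", j, " must have 3 coordinates")
      }
      pos[i, j, ] <- vapply(v, function(z) {
        if (is.null(z)) NA_real_ else as.numeric(z)
      }, numeric(1))
    }
  }
  if (L > 1 && any(diff(ts) <= 0)) {
    stop("field 'landmarks[].t': timestamps must be strictly increasing")
  }
  lm_names <- if (!is.null(meta$landmark_names)) {
    unlist(meta$landmark_names)
  } else {
    pose_landmark_names()
  }
  traj <- landmark_trajectory(ts, pos,
                              nominal_fps = as.numeric(meta$nominal_fps),
                              landmark_names = lm_names)
  events <- if (length(doc$events)) {
    game_events(
      kind = vapply(doc$events, function(e) as.character(e$kind), ""),
      t = vapply(doc$events, function(e) as.numeric(e$t), 0),
      payload = lapply(doc$events, function(e) e$payload)
    )
  } else {
    game_events()
  }
  trial_record(
    subject_id = meta$subject_id, exergame = meta$exergame,
    level = meta$level, session_index = meta$session_index,
    completed = isTRUE(meta$completed), trajectory = traj, events = events,
    mode = if (is.null(meta$mode)) NULL else meta$mode,
    theoretical_max = theoretical_max
  )
}

#' Read cohort clinical and questionnaire tables
#'
#' The clinical CSV carries one row per subject with columns `subject_id`,
#' `hy`, and one column per MDS-UPDRS Part III sub-item named
#' `item_<id>` with `.` replaced by `_` (e.g. `item_3_3_neck`, `item_3_10`);
#' see [updrs_item_ids()]. The questionnaire CSV carries one row per
#' subject x session with columns `subject_id`, `session_index`, `q1`..`q5`.
#'
#' @param clinical_csv,questionnaire_csv file paths
#' @return list with `clinical` (list of `clinical_assessment`, keyed by
#'   subject id) and `questionnaire` (tibble)
#' @export
read_cohort_tables <- function(clinical_csv, questionnaire_csv) {
  cl <- utils::read.csv(clinical_csv, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!all(c("subject_id", "hy") %in% names(cl))) {
    stop("clinical table must have columns subject_id and hy")
  }
  item_cols <- grep("^item_", names(cl), value = TRUE)
  ids <- sub("^item_", "", item_cols)
  ids <- sub("^3_", "3.", ids)
  assessments <- lapply(seq_len(nrow(cl)), function(i) {
    scores <- as.numeric(cl[i, item_cols])
    bad <- which(!is.finite(scores) | scores < 0 | scores > 4)
    if (length(bad)) {
      stop("clinical table row ", i, " (subject ", cl$subject_id[i],
           "): item ", ids[bad[1]], " score ", scores[bad[1]],
           " outside [0, 4]")
    }
    names(scores) <- ids
    clinical_assessment(cl$subject_id[i], cl$hy[i], scores)
  })
  names(assessments) <- as.character(cl$subject_id)

  qu <- utils::read.csv(questionnaire_csv, stringsAsFactors = FALSE)
  need <- c("subject_id", "session_index", paste0("q", 1:5))
  miss <- setdiff(need, names(qu))
  if (length(miss)) {
    stop("questionnaire table missing column(s): ", paste(miss, collapse = ", "))
  }
  ans <- as.matrix(qu[, paste0("q", 1:5)])
  bad <- which(!is.finite(ans) | ans < 1 | ans > 5, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("questionnaire table row ", bad[1, 1], ": answer q", bad[1, 2],
         " outside [1, 5]")
  }
  responses <- questionnaire_response(qu$subject_id, qu$session_index,
                                      qu$q1, qu$q2, qu$q3, qu$q4, qu$q5)
  list(clinical = assessments, questionnaire = responses)
}

#' Write cohort clinical and questionnaire tables
#'
#' Inverse of [read_cohort_tables()]; used by the simulator and the
#' pipeline to persist cohorts.
#'
#' @param clinical list of `clinical_assessment`
#' @param questionnaire tibble of questionnaire responses
#' @param clinical_csv,questionnaire_csv output paths
#' @return invisibly, the two paths
#' @export
write_cohort_tables <- function(clinical, questionnaire,
                                clinical_csv, questionnaire_csv) {
  ids <- updrs_item_ids()
  rows <- lapply(clinical, function(a) {
    scores <- a$items[ids]
    names(scores) <- paste0("item_", gsub("\\.", "_", ids))
    c(list(subject_id = a$subject_id, hy = a$hy), as.list(scores))
  })
  cl <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  utils::write.csv(cl, clinical_csv, row.names = FALSE)
  utils::write.csv(as.data.frame(questionnaire), questionnaire_csv,
                   row.names = FALSE)
  invisible(c(clinical_csv, questionnaire_csv))
}

#' Validate a directory of trial files
#'
#' Attempts to load every `*.json` file in `dir` and returns a per-file
#' quality report: load success, frame counts, flagged-frame counts, and the
#' load error message for files that fail validation.
#'
#' @param dir directory containing trial JSON files
#' @return tibble with columns `file`, `ok`, `frames`, `flagged`, `error`
#' @export
validate_trial_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  rows <- lapply(files, function(f) {
    res <- tryCatch(read_trial(f), error = function(e) e)
    if (inherits(res, "error")) {
      tibble(file = basename(f), ok = FALSE, frames = NA_integer_,
             flagged = NA_integer_, error = conditionMessage(res))
    } else {
      tibble(file = basename(f), ok = TRUE,
             frames = length(res$trajectory$timestamps),
             flagged = length(res$trajectory$flagged), error = NA_character_)
    }
  })
  dplyr::bind_rows(rows)
}
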