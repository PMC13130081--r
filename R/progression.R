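#' Default theoretical maximum levels per exergame
#'
#' The highest configured difficulty level of each exergame in the study
#' protocol: Airplane 8, Ski 11, Piano 2, Gym 3 (a single combined value for
#' the two Gym directions). The exergame platform is parametric, so these
#' are overridable throughout the package.
#'
#' @return named integer vector with elements AIRPLANE, SKI, PIANO, GYM
#' @export
default_theoretical_max <- function() {
  c(AIRPLANE = 8L, SKI = 11L, PIANO = 2L, GYM = 3L)
}

#' Percentage of completion
#'
#' The ratio of the highest achieved level to the theoretical maximum level
#' of the exergame, as a percentage. Balances the contribution of games with
#' different level counts to the progression metric.
#'
#' @param max_level highest achieved level (0 <= max_level <= theoretical_max)
#' @param theoretical_max the game's maximum level (>= 1)
#' @return percentage in \[0, 100\]
#' @export
completion_percentage <- function(max_level, theoretical_max) {
  if (any(theoretical_max < 1)) stop("theoretical_max must be >= 1")
  if (any(max_level < 0 | max_level > theoretical_max)) {
    stop("max_level must lie in [0, theoretical_max]")
  }
  100 * max_level / theoretical_max
}

#' Per-game Normalized Efficiency Index
#'
#' NEI = C_MAX^2 / (100 * S_TARGET), where C_MAX is the maximum percentage
#' of completion reached during the protocol and S_TARGET the session
#' (1-10) in which it was first achieved. The quadratic numerator
#' prioritizes full mastery over rapid but partial progression: NEI(100, 4)
#' equals NEI(50, 1) = 25. Values lie in \[0, 100\].
#'
#' @param c_max maximum completion percentage in \[0, 100\]
#' @param s_target session of first achievement, integer >= 1
#' @return NEI value (dimensionless)
#' @export
nei_game <- function(c_max, s_target) {
  if (any(s_target < 1)) stop("s_target must be >= 1")
  if (any(c_max < 0 | c_max > 100)) stop("c_max must lie in [0, 100]")
  c_max^2 / (100 * s_target)
}

#' Total Normalized Efficiency Index
#'
#' Sum of the four per-game NEI values (Airplane + Ski + Piano + Gym),
#' range \[0, 400\]. A game missing from `nei` is an error by default;
#' `missing_as_zero = TRUE` scores missing games as 0 for incomplete
#' cohorts.
#'
#' @param nei named numeric vector of per-game NEI values; names among
#'   AIRPLANE, SKI, PIANO, GYM
#' @param missing_as_zero treat absent games as NEI 0 instead of erroring
#' @return NEI_TOT
#' @export
nei_total <- function(nei, missing_as_zero = FALSE) {
  games <- c("AIRPLANE", "SKI", "PIANO", "GYM")
  if (is.null(names(nei)) && length(nei) == 4) names(nei) <- games
  missing <- setdiff(games, names(nei))
  if (length(missing) && !missing_as_zero) {
    stop("missing per-game NEI for: ", paste(missing, collapse = ", "),
         " (use missing_as_zero = TRUE to score them 0)")
  }
  full <- stats::setNames(numeric(4), games)
  full[names(nei)[names(nei) %in% games]] <- nei[names(nei) %in% games]
  if (any(!is.finite(full))) stop("per-game NEI values must be finite")
  sum(full)
}

#' Extract per-subject progression records from trials
#'
#' For each (subject, game): the maximum level over completed trials and the
#' earliest session in which that maximum was achieved. The two Gym
#' directions are combined into a single GYM game: the per-session combined
#' level is the minimum over the directions recorded in that session, and
#' max/first-session extraction runs on the combined series.
#'
#' @param trials tibble with columns `subject_id`, `exergame`, `level`,
#'   `session_index`, `completed` (a list of `trial_record`s is also
#'   accepted)
#' @param theoretical_max named per-game maxima, used to attach
#'   `theoretical_max` to each record
#' @return tibble with columns `subject_id`, `game`, `max_level`,
#'   `first_session`, `theoretical_max`; one row per (subject, game) with at
#'   least one completed trial. Invariant to trial ordering.
#' @export
extract_progression <- function(trials,
                                theoretical_max = default_theoretical_max()) {
  trials <- as_trial_table(trials)
  trials <- trials[trials$completed, , drop = FALSE]
  if (!nrow(trials)) {
    return(tibble(subject_id = character(), game = character(),
                  max_level = integer(), first_session = integer(),
                  theoretical_max = integer()))
  }
  trials$game <- progression_game(trials$exergame)

  # Per (subject, game, session): the session's achieved level. For GYM the
  # session level is the min over the directions recorded in that session.
  per_session <- trials |>
    dplyr::group_by(.data$subject_id, .data$game, .data$session_index,
                    .data$exergame) |>
    dplyr::summarise(level = max(.data$level), .groups = "drop") |>
    dplyr::group_by(.data$subject_id, .data$game, .data$session_index) |>
    dplyr::summarise(level = min(.data$level), .groups = "drop")

  per_session |>
    dplyr::group_by(.data$subject_id, .data$game) |>
    dplyr::summarise(
      max_level = max(.data$level),
      first_session = min(.data$session_index[.data$level == max(.data$level)]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      max_level = as.integer(.data$max_level),
      first_session = as.integer(.data$first_session),
      theoretical_max = as.integer(theoretical_max[.data$game])
    ) |>
    dplyr::arrange(.data$subject_id, .data$game)
}

# Accept either a metadata tibble or a list of trial_record objects.
as_trial_table <- function(trials) {
  if (is.data.frame(trials)) return(tibble::as_tibble(trials))
  if (is.list(trials) && all(vapply(trials, inherits, TRUE, "trial_record"))) {
    return(dplyr::bind_rows(lapply(trials, function(tr) {
      tibble(subject_id = tr$subject_id, exergame = tr$exergame,
             level = tr$level, session_index = tr$session_index,
             mode = if (is.null(tr$mode)) NA_character_ else tr$mode,
             completed = tr$completed)
    })))
  }
  stop("trials must be a data frame or a list of trial_record objects")
}

#' Per-subject NEI results from progression records
#'
#' Computes C_MAX, the per-game NEI and NEI_TOT for every subject in a
#' progression table. A subject at level 0 only has C_MAX = 0 and NEI = 0.
#'
#' @param progression tibble as returned by [extract_progression()] (or
#'   [study_progression_table()] joined with theoretical maxima)
#' @param theoretical_max named per-game maxima, used where the table lacks
#'   a `theoretical_max` column
#' @param missing_as_zero passed to [nei_total()]
#' @return tibble with one row per subject: `subject_id`,
#'   `nei_<game>` columns and `nei_tot`
#' @export
nei_results <- function(progression,
                        theoretical_max = default_theoretical_max(),
                        missing_as_zero = FALSE) {
  pr <- tibble::as_tibble(progression)
  if (!"theoretical_max" %in% names(pr)) {
    pr$theoretical_max <- as.integer(theoretical_max[pr$game])
  }
  pr$c_max <- completion_percentage(pr$max_level, pr$theoretical_max)
  pr$nei <- nei_game(pr$c_max, pr$first_session)
  wide <- pr |>
    dplyr::select("subject_id", "game", "nei") |>
    tidyr::pivot_wider(names_from = "game", values_from = "nei",
                       names_prefix = "nei_")
  wide$nei_tot <- vapply(seq_len(nrow(wide)), function(i) {
    v <- unlist(wide[i, setdiff(names(wide), c("subject_id", "nei_tot"))])
    names(v) <- sub("^nei_", "", names(v))
    nei_total(v[is.finite(v)], missing_as_zero = missing_as_zero)
  }, numeric(1))
  wide
}

#' Session-wise distribution of trials across difficulty levels
#'
#' For each (exergame, session), the percentage of that session's trials
#' performed at each level. Percentages within a (game, session) row sum
#' to 100.
#'
#' @param trials trial metadata (see [extract_progression()])
#' @return tibble with columns `exergame`, `session_index`, `level`,
#'   `n_trials`, `pct`
#' @export
level_distribution <- function(trials) {
  trials <- as_trial_table(trials)
  if (!nrow(trials)) stop("trial list is empty")
  trials |>
    dplyr::count(.data$exergame, .data$session_index, .data$level,
                 name = "n_trials") |>
    dplyr::group_by(.data$exergame, .data$session_index) |>
    dplyr::mutate(pct = 100 * .data$n_trials / sum(.data$n_trials)) |>
    dplyr::ungroup()
}

#' Cohort summary of maximum achieved levels
#'
#' Per game: mean and sample SD of the per-subject maximum levels and the
#' share of subjects reaching the theoretical maximum.
#'
#' @param records progression tibble (columns `game`, `max_level`, and
#'   `theoretical_max` or a `theoretical_max` argument)
#' @param theoretical_max named per-game maxima fallback
#' @return tibble with columns `game`, `n`, `mean_max_level`,
#'   `sd_max_level`, `pct_at_max`
#' @export
progression_summary <- function(records,
                                theoretical_max = default_theoretical_max()) {
  pr <- tibble::as_tibble(records)
  if (!"theoretical_max" %in% names(pr)) {
    pr$theoretical_max <- as.integer(theoretical_max[pr$game])
  }
  pr |>
    dplyr::group_by(.data$game) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_max_level = mean(.data$max_level),
      sd_max_level = stats::sd(.data$max_level),
      pct_at_max = 100 * mean(.data$max_level == .data$theoretical_max),
      .groups = "drop"
    )
}
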