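#' MDS-UPDRS Part III sub-scores
#'
#' Derives the motor sub-scores from an assessment's sub-item map:
#' * `UPDRSIII_SCORE`: sum of all Part III sub-items;
#' * `MOBILITY_SCORE`: items 3.4-3.7 (both sides);
#' * `GAITPOS_SCORE`: items 3.9-3.13;
#' * `BRADY_SCORE`: item 3.14;
#' * `TREMOR_SCORE`: items 3.15-3.18 (all sub-items);
#' * `RIGIDITY_SCORE`: item 3.3 over neck, arms, and legs.
#'
#' A sub-score whose required items are missing is reported `NA`; the
#' others are still computed. Sums are linear in the item scores.
#'
#' @param assessment a `clinical_assessment` (or its named item vector)
#' @return named numeric vector of the six sub-scores
#' @export
updrs_subscores <- function(assessment) {
  items <- if (inherits(assessment, "clinical_assessment")) {
    assessment$items
  } else {
    assessment
  }
  item_group <- function(prefixes) {
    ids <- updrs_item_ids()
    ids[vapply(ids, function(id) {
      any(vapply(prefixes, function(p) {
        id == p || startsWith(id, paste0(p, "_"))
      }, logical(1)))
    }, logical(1))]
  }
  sum_group <- function(prefixes) {
    need <- item_group(prefixes)
    if (!all(need %in% names(items))) return(NA_real_)
    sum(items[need])
  }
  c(
    UPDRSIII_SCORE = sum_group(sprintf("3.%d", 1:18)),
    MOBILITY_SCORE = sum_group(sprintf("3.%d", 4:7)),
    GAITPOS_SCORE = sum_group(sprintf("3.%d", 9:13)),
    BRADY_SCORE = sum_group("3.14"),
    TREMOR_SCORE = sum_group(sprintf("3.%d", 15:18)),
    RIGIDITY_SCORE = sum_group("3.3")
  )
}

#' Sub-score table for a cohort
#'
#' @param clinical list of `clinical_assessment` objects
#' @return tibble with `subject_id`, `hy`, and the six sub-score columns
#' @export
cohort_subscores <- function(clinical) {
  dplyr::bind_rows(lapply(clinical, function(a) {
    tibble::as_tibble(c(list(subject_id = a$subject_id, hy = a$hy),
                        as.list(updrs_subscores(a))))
  }))
}

#' Pearson correlation between difficulty level and mean game score
#'
#' Correlates level indices with the corresponding per-level mean game
#' scores (two-sided test). Used to quantify whether scoring performance
#' improves with task difficulty.
#'
#' @param levels numeric vector of level indices (>= 3 values)
#' @param scores per-level mean scores, same length
#' @return object of class `correlation_result`: list with `rho`, `p`,
#'   `n`, `method`, `excluded`
#' @export
pearson_level_score <- function(levels, scores) {
  if (length(levels) != length(scores)) {
    stop("levels and scores must have equal length")
  }
  if (length(levels) < 3) stop("need at least 3 (level, score) pairs")
  if (stats::sd(levels) == 0 || stats::sd(scores) == 0) {
    stop("correlation undefined: zero variance input")
  }
  ct <- stats::cor.test(levels, scores, method = "pearson",
                        alternative = "two.sided")
  correlation_result(unname(ct$estimate), ct$p.value, length(levels),
                     "pearson", character())
}

correlation_result <- function(rho, p, n, method, excluded) {
  structure(list(rho = rho, p = p, n = n, method = method,
                 excluded = excluded),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<%s correlation> rho = %.3f, p = %.4g, n = %d\n",
              x$method, x$rho, x$p, x$n))
  if (length(x$excluded)) {
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Spearman rank correlation with explicit subject exclusion
#'
#' Validity analysis of the progression index against clinical scores:
#' Spearman's rank correlation (average ranks for ties, computed as the
#' Pearson correlation of the rank transforms) with a two-sided p-value.
#' The default p-value uses the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of freedom;
#' `p_method = "permutation"` enumerates all permutations exactly (limited
#' to n <= 8). Subjects in `exclude` are removed before ranking and
#' recorded in the result; an empty exclusion list leaves the analysis
#' unchanged.
#'
#' @param x,y paired numeric vectors (e.g. per-subject NEI_TOT and a
#'   clinical score); must share `names()` or be positionally paired
#' @param exclude character vector of subject ids (matched against
#'   `names(x)`) or integer indices to drop
#' @param p_method "t" (default) or "permutation"
#' @return a `correlation_result`
#' @export
spearman_validity <- function(x, y, exclude = character(),
                              p_method = c("t", "permutation")) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- rep(TRUE, length(x))
  if (length(exclude)) {
    if (is.character(exclude)) {
      if (is.null(names(x))) stop("exclusion by id requires named input")
      keep <- !(names(x) %in% exclude)
    } else {
      keep[exclude] <- FALSE
    }
  }
  xs <- x[keep]
  ys <- y[keep]
  ok <- is.finite(xs) & is.finite(ys)
  xs <- xs[ok]
  ys <- ys[ok]
  n <- length(xs)
  if (n < 3) stop("need at least 3 paired observations after exclusion")
  rho <- spearman_rho(xs, ys)
  if (!is.finite(rho)) stop("correlation undefined: all-tied input")
  p <- switch(p_method,
    t = spearman_p_t(rho, n),
    permutation = spearman_p_perm(xs, ys)
  )
  excluded <- if (is.character(exclude)) exclude else as.character(exclude)
  correlation_result(rho, p, n, "spearman", excluded)
}

spearman_rho <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

spearman_p_t <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

spearman_p_perm <- function(x, y) {
  n <- length(x)
  if (n > 8) {
    stop("exact permutation p is limited to n <= 8; use p_method = 't'")
  }
  obs <- abs(spearman_rho(x, y))
  perms <- permutations_of(n)
  stat <- apply(perms, 1, function(p) abs(spearman_rho(x, y[p])))
  mean(stat >= obs - 1e-12)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(i, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

#' Independent-sample t-test
#'
#' Two-sided independent-sample t-test between two groups of aggregated
#' trial features (e.g. frontal vs lateral ROM). Welch's unequal-variance
#' form by default; `equal_variance = TRUE` gives the pooled form.
#'
#' @param sample_a,sample_b numeric vectors (each n >= 2)
#' @param equal_variance pooled-variance test instead of Welch
#' @return list with `t`, `p`, `df`, `mean_a`, `mean_b`
#' @export
independent_ttest <- function(sample_a, sample_b, equal_variance = FALSE) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("each sample must contain at least 2 observations")
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = equal_variance,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter),
       mean_a = mean(sample_a), mean_b = mean(sample_b))
}

#' Questionnaire domain and trend analysis
#'
#' Summarizes the five-item post-session questionnaire:
#' * per-item cohort mean and sample SD (over all responses);
#' * session-bucket trend means: each subject's attended sessions are
#'   partitioned positionally into initial / intermediate / final tertiles
#'   (the middle bucket absorbs the remainder, e.g. 10 sessions split
#'   3/4/3), and item means are reported per bucket;
#' * Spearman correlations between each item's per-subject mean score and
#'   the subject's NEI_TOT.
#'
#' Subjects without an NEI value are excluded from the correlations but
#' kept in the means.
#'
#' @param responses questionnaire tibble ([questionnaire_response()])
#' @param nei named numeric vector of per-subject NEI_TOT (names =
#'   subject ids), or a tibble with `subject_id` and `nei_tot`
#' @return list with `item_summary` (tibble), `trend` (tibble),
#'   `correlations` (tibble with `item`, `rho`, `p`, `n`)
#' @export
questionnaire_analysis <- function(responses, nei) {
  qs <- paste0("q", 1:5)
  if (is.data.frame(nei)) {
    nei <- stats::setNames(nei$nei_tot, nei$subject_id)
  }
  item_summary <- dplyr::bind_rows(lapply(qs, function(q) {
    tibble(item = toupper(q), mean = mean(responses[[q]]),
           sd = stats::sd(responses[[q]]))
  }))

  bucketed <- responses |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::arrange(.data$session_index, .by_group = TRUE) |>
    dplyr::mutate(bucket = session_bucket(dplyr::row_number(), dplyr::n())) |>
    dplyr::ungroup()
  trend <- bucketed |>
    tidyr::pivot_longer(dplyr::all_of(qs), names_to = "item",
                        values_to = "score") |>
    dplyr::group_by(.data$item, .data$bucket) |>
    dplyr::summarise(mean = mean(.data$score), sd = stats::sd(.data$score),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(item = toupper(.data$item))

  subj_means <- responses |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(qs), mean), .groups = "drop")
  subj_means <- subj_means[subj_means$subject_id %in% names(nei), ]
  correlations <- dplyr::bind_rows(lapply(qs, function(q) {
    x <- stats::setNames(subj_means[[q]], subj_means$subject_id)
    y <- nei[subj_means$subject_id]
    res <- tryCatch(spearman_validity(x, y), error = function(e) NULL)
    if (is.null(res)) {
      tibble(item = toupper(q), rho = NA_real_, p = NA_real_,
             n = length(x))
    } else {
      tibble(item = toupper(q), rho = res$rho, p = res$p, n = res$n)
    }
  }))
  list(item_summary = item_summary, trend = trend,
       correlations = correlations, buckets = bucketed)
}

# Positional tertile partition of a subject's attended sessions; the middle
# bucket takes the remainder (n = 10 -> 3/4/3).
session_bucket <- function(pos, n) {
  k1 <- round(n / 3)
  k2 <- n - round(n / 3)
  ifelse(pos <= k1, "initial", ifelse(pos <= k2, "intermediate", "final"))
}

#' NEI-vs-clinical validity report
#'
#' Runs the Spearman validity analysis of NEI_TOT against the UPDRS total
#' and every sub-score, with an optional subject exclusion list (the
#' re-analysis excluding an incongruent subject is the same operation with
#' a different list).
#'
#' @param nei tibble from [nei_results()]
#' @param subscores tibble from [cohort_subscores()]
#' @param exclude character vector of subject ids to exclude
#' @param p_method passed to [spearman_validity()]
#' @return tibble with `score`, `rho`, `p`, `n`, `excluded`
#' @export
nei_validity <- function(nei, subscores, exclude = character(),
                         p_method = "t") {
  merged <- dplyr::inner_join(nei[, c("subject_id", "nei_tot")], subscores,
                              by = "subject_id")
  score_cols <- c("UPDRSIII_SCORE", "MOBILITY_SCORE", "GAITPOS_SCORE",
                  "BRADY_SCORE", "TREMOR_SCORE", "RIGIDITY_SCORE")
  dplyr::bind_rows(lapply(score_cols, function(sc) {
    x <- stats::setNames(merged$nei_tot, merged$subject_id)
    y <- stats::setNames(merged[[sc]], merged$subject_id)
    res <- tryCatch(spearman_validity(x, y, exclude = exclude,
                                      p_method = p_method),
                    error = function(e) NULL)
    if (is.null(res)) {
      tibble(score = sc, rho = NA_real_, p = NA_real_, n = NA_integer_,
             excluded = paste(exclude, collapse = ";"))
    } else {
      tibble(score = sc, rho = res$rho, p = res$p, n = res$n,
             excluded = paste(exclude, collapse = ";"))
    }
  }))
}
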