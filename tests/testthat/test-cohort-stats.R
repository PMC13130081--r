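test_that("UPDRS sub-scores match hand-computed sums", {
  a0 <- make_assessment(score = 0)
  s0 <- updrs_subscores(a0)
  expect_true(all(s0 == 0))

  a1 <- make_assessment(score = 2)
  s1 <- updrs_subscores(a1)
  expect_equal(s1[["UPDRSIII_SCORE"]], 2 * 33)
  expect_equal(s1[["MOBILITY_SCORE"]], 2 * 8)   # 3.4-3.7, both sides
  expect_equal(s1[["GAITPOS_SCORE"]], 2 * 5)    # 3.9-3.13
  expect_equal(s1[["BRADY_SCORE"]], 2)          # 3.14
  expect_equal(s1[["TREMOR_SCORE"]], 2 * 10)    # 3.15-3.18 sub-items
  expect_equal(s1[["RIGIDITY_SCORE"]], 2 * 5)   # 3.3 body parts

  set.seed(14)
  items <- stats::setNames(sample(0:4, 33, replace = TRUE), updrs_item_ids())
  s <- updrs_subscores(clinical_assessment("X", 2, items))
  expect_equal(s[["UPDRSIII_SCORE"]], sum(items))
  expect_equal(s[["RIGIDITY_SCORE"]], sum(items[startsWith(names(items), "3.3_")]))
  expect_equal(s[["MOBILITY_SCORE"]],
               sum(items[grepl("^3\\.[4-7]_", names(items))]))
})

test_that("sub-score sums are linear and tolerate missing items", {
  items <- stats::setNames(rep(1, 33), updrs_item_ids())
  s1 <- updrs_subscores(items)
  s2 <- updrs_subscores(items * 3)
  expect_equal(unname(s2), unname(s1 * 3))
  partial <- items[!startsWith(names(items), "3.14")]
  sp <- updrs_subscores(partial)
  expect_true(is.na(sp[["BRADY_SCORE"]]))
  expect_true(is.na(sp[["UPDRSIII_SCORE"]]))
  expect_equal(sp[["RIGIDITY_SCORE"]], 5)
})

test_that("level-score Pearson reproduces the published correlations", {
  scores <- study_level_scores()
  air <- scores[scores$exergame == "AIRPLANE", ]
  res <- pearson_level_score(air$level, air$value)
  expect_equal(round(res$rho, 2), 0.91)
  ski <- scores[scores$exergame == "SKI", ]
  expect_equal(round(pearson_level_score(ski$level, ski$value)$rho, 2), 0.63)
  # exactly linear data
  expect_equal(pearson_level_score(1:5, 2 * (1:5) + 3)$rho, 1)
  expect_error(pearson_level_score(1:5, rep(2, 5)), "zero variance")
  expect_error(pearson_level_score(1:2, 1:2), "at least 3")
})

test_that("Spearman equals the rank-then-Pearson oracle, ties included", {
  set.seed(8)
  for (k in 1:20) {
    n <- sample(5:30, 1)
    x <- sample(1:6, n, replace = TRUE) + rnorm(n, 0, 0.01 * (k %% 2))
    y <- sample(1:6, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    got <- spearman_validity(x, y)
    oracle_rho <- stats::cor(rank(x), rank(y))
    expect_equal(got$rho, oracle_rho, tolerance = 1e-12)
    expect_equal(got$rho, stats::cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
})

test_that("perfectly monotone decreasing pairs give rho -1", {
  x <- c(10, 8, 5, 3, 1)
  y <- c(2, 4, 9, 12, 30)
  res <- spearman_validity(x, y)
  expect_equal(res$rho, -1)
  expect_equal(res$p, 0)
})

test_that("Spearman t-approximation p matches the base implementation", {
  set.seed(42)
  x <- rnorm(13)
  y <- 0.5 * x + rnorm(13)
  got <- spearman_validity(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                          exact = FALSE))
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-9)
})

test_that("exact permutation p agrees with enumeration at tiny n", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5)
  res <- spearman_validity(x, y, p_method = "permutation")
  # enumeration oracle, independent implementation
  perms <- gtools_like_perms(6)
  obs <- abs(cor(rank(x), rank(y)))
  stats_all <- apply(perms, 1, function(p) abs(cor(rank(x), rank(y[p]))))
  expect_equal(res$p, mean(stats_all >= obs - 1e-12))
  expect_error(spearman_validity(rnorm(9), rnorm(9),
                                 p_method = "permutation"), "n <= 8")
})

test_that("exclusion changes only the subjects used and empty exclusion is identity", {
  set.seed(1)
  x <- stats::setNames(rnorm(14), sprintf("S%02d", 1:14))
  y <- stats::setNames(-x + rnorm(14, 0, 0.5), names(x))
  full <- spearman_validity(x, y)
  same <- spearman_validity(x, y, exclude = character())
  expect_equal(full$rho, same$rho)
  expect_equal(full$n, 14)
  drop1 <- spearman_validity(x, y, exclude = "S14")
  ref <- spearman_validity(x[1:13], y[1:13])
  expect_equal(drop1$n, 13)
  expect_equal(drop1$rho, ref$rho)
  expect_equal(drop1$excluded, "S14")
})

test_that("planted impairment link is recovered at n = 200 (noiseless)", {
  co <- simulate_cohort(cohort_spec(n_subjects = 200, link_noise_sd = 0,
                                    seed = 2026))
  nei <- nei_results(extract_progression(co$trials))
  ss <- cohort_subscores(co$clinical)
  x <- stats::setNames(nei$nei_tot, nei$subject_id)
  y <- stats::setNames(ss$UPDRSIII_SCORE, ss$subject_id)[names(x)]
  res <- spearman_validity(x, y)
  expect_lte(res$rho, -0.95)
})

test_that("independent t-test matches the closed-form oracle", {
  same <- independent_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  a <- c(1, 2, 3)
  b <- c(4, 5, 6)
  # pooled closed form: t = (ma - mb) / sqrt(sp2 * (1/na + 1/nb))
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  pooled <- independent_ttest(a, b, equal_variance = TRUE)
  expect_equal(pooled$t, t_hand)
  expect_equal(pooled$df, 4)
  # Welch closed form
  se <- sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(independent_ttest(a, b)$t, (mean(a) - mean(b)) / se)
  expect_error(independent_ttest(1, c(1, 2)), "at least 2")
})

test_that("a planted frontal-vs-lateral ROM effect is detected", {
  set.seed(30)
  frontal <- rnorm(40, 100, 8)
  lateral <- rnorm(40, 80, 8)
  expect_lt(independent_ttest(frontal, lateral)$p, 0.001)
})

test_that("questionnaire analysis: constants, buckets, planted link", {
  resp <- questionnaire_response(rep(sprintf("S%02d", 1:4), each = 10),
                                 rep(1:10, 4),
                                 3, 3, 3, 3, 3)
  nei <- stats::setNames(c(10, 20, 30, 40), sprintf("S%02d", 1:4))
  qa <- questionnaire_analysis(resp, nei)
  expect_true(all(qa$item_summary$mean == 3))
  expect_true(all(qa$item_summary$sd == 0))
  expect_true(all(is.na(qa$correlations$rho)))
  # 10 sessions partition 3/4/3 and conserve counts
  b <- qa$buckets[qa$buckets$subject_id == "S01", ]
  expect_equal(as.vector(table(b$bucket)[c("initial", "intermediate", "final")]),
               c(3L, 4L, 3L))
  expect_equal(nrow(b), 10)

  # planted positive satisfaction link is recovered
  co <- simulate_cohort(cohort_spec(n_subjects = 40, seed = 9))
  nei2 <- nei_results(extract_progression(co$trials))
  qa2 <- questionnaire_analysis(co$questionnaire, nei2)
  expect_gt(qa2$correlations$rho[qa2$correlations$item == "Q2"], 0.3)
  expect_lt(qa2$correlations$rho[qa2$correlations$item == "Q4"], -0.3)
})

test_that("NEI validity report runs per score with an exclusion list", {
  co <- simulate_cohort(cohort_spec(n_subjects = 14, seed = 4))
  nei <- nei_results(extract_progression(co$trials))
  ss <- cohort_subscores(co$clinical)
  rep0 <- nei_validity(nei, ss)
  expect_equal(nrow(rep0), 6)
  expect_true(all(rep0$n == 14))
  rep1 <- nei_validity(nei, ss, exclude = "S03")
  expect_true(all(rep1$n == 13))
  expect_true(all(rep1$excluded == "S03"))
})
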