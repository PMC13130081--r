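#!/usr/bin/env Rscript
# Clinical validity layer on the simulated cohort: Spearman correlation of
# NEI_TOT against the UPDRS III total and sub-scores (with and without the
# most incongruent subject, mirroring the outlier re-analysis), the
# frontal-vs-lateral ROM t-test from the extracted features, and the
# questionnaire domain/trend analysis.

suppressPackageStartupMessages({
  library(exerkin)
  library(dplyr)
})

dir.create("results", showWarnings = FALSE)
tabs <- read_cohort_tables("results/cohort_clinical.csv",
                           "results/cohort_questionnaire.csv")
trials <- read.csv("results/cohort_trials.csv")
nei <- nei_results(extract_progression(trials))
subsc <- cohort_subscores(tabs$clinical)

val <- nei_validity(nei, subsc)
cat("NEI_TOT vs clinical scores (n = 14):\n")
for (i in seq_len(nrow(val))) {
  cat(sprintf("  %-16s rho = %+.2f  p = %.3f\n",
              val$score[i], val$rho[i], val$p[i]))
}

# rank-discrepancy outlier: the subject whose NEI rank disagrees most with
# the UPDRS rank (the study's wearing-off incongruence, as a data pattern)
merged <- inner_join(nei[, c("subject_id", "nei_tot")], subsc,
                     by = "subject_id")
disc <- abs(rank(merged$nei_tot) + rank(merged$UPDRSIII_SCORE) -
              (nrow(merged) + 1))
outlier <- merged$subject_id[which.max(disc)]
val_ex <- nei_validity(nei, subsc, exclude = outlier)
cat(sprintf("Re-analysis excluding %s (largest rank incongruence), n = %d:\n",
            outlier, val_ex$n[1]))
cat(sprintf("  UPDRSIII rho %+.2f -> %+.2f\n",
            val$rho[val$score == "UPDRSIII_SCORE"],
            val_ex$rho[val_ex$score == "UPDRSIII_SCORE"]))
write.csv(as.data.frame(bind_rows(val, val_ex)), "results/validity.csv",
          row.names = FALSE)

# frontal vs lateral ROM on the extracted features
if (file.exists("results/trial_features.csv")) {
  feats <- read.csv("results/trial_features.csv")
  tt <- independent_ttest(feats$ROM_ANG[feats$exergame == "GYM_FRONTAL"],
                          feats$ROM_ANG[feats$exergame == "GYM_LATERAL"])
  cat(sprintf("Frontal vs lateral ROM: %.1f vs %.1f deg, t = %.2f, p = %.3g\n",
              tt$mean_a, tt$mean_b, tt$t, tt$p))
}

qa <- questionnaire_analysis(tabs$questionnaire, nei)
write.csv(as.data.frame(qa$item_summary), "results/questionnaire_items.csv",
          row.names = FALSE)
write.csv(as.data.frame(qa$trend), "results/questionnaire_trend.csv",
          row.names = FALSE)
write.csv(as.data.frame(qa$correlations),
          "results/questionnaire_nei_correlations.csv", row.names = FALSE)
cat("Questionnaire item means:",
    paste(sprintf("%s %.2f", qa$item_summary$item, qa$item_summary$mean),
          collapse = ", "), "\n")
cat("Q2 (satisfaction) vs NEI_TOT Spearman rho:",
    sprintf("%+.2f", qa$correlations$rho[qa$correlations$item == "Q2"]), "\n")
cat("Wrote results/validity.csv and results/questionnaire_*.csv\n")
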