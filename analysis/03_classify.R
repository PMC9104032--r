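#!/usr/bin/env Rscript
# Step 3: per-subject classification. Calibration sessions are scored by
# stratified 5-fold cross-validation of the linear SVM (fold-mean accuracy
# is the headline, pooled accuracy reported alongside); online sessions are
# replayed against the classifier trained once on all of that subject's
# calibration epochs, mimicking the closed-loop feedback session.

suppressMessages(library(nirstate))

feats <- read.table("results/02_feature_manifest.tsv",
  sep = "\t", header = TRUE, stringsAsFactors = FALSE
)
cfg <- pipeline_config()

subjects <- unique(feats$subject)
rows <- list()
for (i in seq_along(subjects)) {
  sub <- subjects[i]
  cal <- read_features(feats$features_path[feats$subject == sub & feats$session == "calibration"])
  onl <- read_features(feats$features_path[feats$subject == sub & feats$session == "online"])
  cv <- crossvalidate(cal, k = cfg$k, C = cfg$C, seed = cfg$seed + i)
  rep <- replay_online(cal, onl, C = cfg$C)
  rows[[length(rows) + 1]] <- data.frame(
    subject = sub, session = "calibration",
    accuracy = round(cv$mean_accuracy, 2),
    pooled_accuracy = round(cv$pooled_accuracy, 2)
  )
  rows[[length(rows) + 1]] <- data.frame(
    subject = sub, session = "online",
    accuracy = round(rep$accuracy, 2),
    pooled_accuracy = round(rep$accuracy, 2)
  )
}
res <- do.call(rbind, rows)

n_trials <- feats$n_epochs[1]
bound <- chance_upper_bound(n_trials, 2, 0.05)
res <- flag_below_chance(res, bound)

write.table(res, "results/03_subject_accuracies.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
cat(sprintf(
  "chance upper bound for %d trials: %.2f%% (flagging below-chance results)\n",
  n_trials, bound$upper
))
for (ses in c("calibration", "online")) {
  acc <- res$accuracy[res$session == ses]
  cat(sprintf(
    "%-11s mean %.2f%%, sd %.2f%%, %d/%d below chance\n",
    ses, mean(acc), sd(acc), sum(res$below_chance[res$session == ses]), length(acc)
  ))
}
cat("per-subject table in results/03_subject_accuracies.tsv\n")
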