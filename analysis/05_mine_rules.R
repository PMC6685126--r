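#!/usr/bin/env Rscript
# Stage 5: association-rule mining. First the question-level analysis:
# Apriori over items "Qk>=3" (rating sometimes/always) plus the loneliness
# level, with the raise-support-until-empty search (confidence floor 90%).
# Then the behavior-level analysis: equal-frequency discretization of the
# classifier-selected features and Apriori against the post-semester level
# and the change category (support 10%, confidence 90%).

suppressMessages({library(lonelysense); library(data.table)})

surveys <- fread("results/cohort/surveys.csv")
outcomes <- fread("results/participant_outcomes.csv")
qcols <- paste0("q", 1:20)

for (wave_ in c("pre", "post")) {
  resp <- as.matrix(surveys[wave == wave_][order(participant_id), ..qcols])
  lv <- if (wave_ == "pre") outcomes[order(participant_id)]$pre_level
        else outcomes[order(participant_id)]$post_level
  out <- mine_question_associations(resp, lv, min_support = 0.10,
                                    min_confidence = 0.90,
                                    search_optimal_support = TRUE)
  cat(sprintf("%s-semester question rules: optimal support %.0f%%, %d rule(s)\n",
              wave_, 100 * out$optimal_support, nrow(out$rules)))
  if (nrow(out$rules)) print(format_rules(out$rules))
  fwrite(format_rules(out$rules),
         sprintf("results/question_rules_%s.csv", wave_))
}

# behavior-level rules from the features selected for the level task
sel <- fread("results/selected_features_level.csv")
sets <- c("bluetooth", "calls", "campus_map", "location", "screen",
          "sleep", "steps")
matrices <- lapply(sets, function(s) {
  dt <- fread(file.path("results/features", paste0(s, ".csv")))
  m <- as.matrix(dt[, -1]); rownames(m) <- dt$participant_id; m
})
names(matrices) <- sets
big <- do.call(cbind, unname(matrices))
big[big == -1] <- NA
keep <- intersect(sel[fold_share > 0.5]$feature, colnames(big))
cat("Features selected in more than half of the folds:", length(keep), "\n")
# keep the search tractable: strongest 25 features, itemsets of <= 4 items
keep <- head(sel[order(-fold_share)][feature %in% keep]$feature, 25)

for (task in c("post_level", "change")) {
  outc <- setNames(if (task == "post_level") outcomes$post_level else outcomes$change,
                   outcomes$participant_id)
  res <- mine_behavior_associations(big[, keep, drop = FALSE],
                                    outc[rownames(big)],
                                    outcome_prefix = task,
                                    min_support = 0.10, min_confidence = 0.90,
                                    max_itemset_size = 4)
  cat(sprintf("%s behavior rules: %d (from %d discretized features)\n",
              task, nrow(res$rules), length(keep) - length(res$excluded_features)))
  if (nrow(res$rules)) print(head(format_rules(res$rules), 10))
  fwrite(format_rules(res$rules), sprintf("results/behavior_rules_%s.csv", task))
}
cat("Rule tables written under results/\n")
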