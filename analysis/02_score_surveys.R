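#!/usr/bin/env Rscript
# Stage 2: score the UCLA-20 surveys written by 01_simulate.R, assign
# loneliness levels (cutoff: totals above 40 = high loneliness) and change
# categories, and write the descriptive summary.

suppressMessages({library(lonelysense); library(data.table)})

surveys <- fread("results/cohort/surveys.csv")
outcomes <- score_survey_table(surveys)
fwrite(outcomes, "results/participant_outcomes.csv")

s <- summarize_cohort(outcomes$pre_total, outcomes$post_total)
jsonlite::write_json(s, "results/survey_summary.json", auto_unbox = TRUE,
                     digits = NA)

cat(sprintf("Pre:  mean %.1f (SD %.1f), %d HL / %d LL\n",
            s$pre$mean, s$pre$sd, s$pre$n_hl, s$pre$n_ll))
cat(sprintf("Post: mean %.1f (SD %.1f), %d HL / %d LL\n",
            s$post$mean, s$post$sd, s$post$n_hl, s$post$n_ll))
cat("Change bands (partition of the cohort):\n")
print(s$change$bands)
cat("Wrote results/participant_outcomes.csv and results/survey_summary.json\n")
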