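#!/usr/bin/env Rscript
# Evaluate the 227-454-1 sigmoid perceptron by repeated random 5-fold
# cross-validation (20 repartitions = 100 experiments) on the extracted
# feature matrix, following the original protocol: the held-out fold serves
# both as the early-stopping set and as the reported test set.
#
# Input:  results/features.csv
# Output: results/cv_experiments.csv (one row per experiment),
#         results/cv_summary.json {accuracy, sensitivity, specificity, ...}

suppressPackageStartupMessages(library(enosepipe))

feats <- read_features("results/features.csv")
plan <- make_cv_plan(feats$record_id, n_folds = 5L, n_repeats = 20L,
                     seed = 20260102L)
profile <- train_config(max_epochs = 2000L, min_epochs = 500L,
                        patience = 200L, eval_every = 20L)

report <- run_cross_validation(feats, plan, profile,
                               master_seed = 20260103L)
print(report)
message(sprintf("early stopping spanned epochs %d..%d across experiments",
                min(report$experiments$stop_epoch),
                max(report$experiments$stop_epoch)))

write_eval_report(report, "results/cv_experiments.csv",
                  "results/cv_summary.json")
message("wrote results/cv_experiments.csv and results/cv_summary.json")
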