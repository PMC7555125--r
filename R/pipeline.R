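# End-to-end convenience driver: generate -> segment -> features -> CV.

#' Run the full pipeline on a synthetic cohort
#'
#' Generates a cohort, extracts the 227-dimensional feature matrix, and
#' evaluates the perceptron by repeated random cross-validation.
#'
#' @param scfg a [synth_config()].
#' @param tcfg a [train_config()].
#' @param n_folds,n_repeats cross-validation plan parameters.
#' @param master_seed master seed for the CV plan and per-experiment
#'   initialization seeds.
#' @param ... passed on to [run_cross_validation()].
#' @return list with `cohort`, `features`, `plan`, `report`.
#' @export
run_pipeline <- function(scfg = synth_config(), tcfg = train_config(),
                         n_folds = 5L, n_repeats = 20L, master_seed = 1L,
                         ...) {
  co <- generate_cohort(scfg)
  feats <- cohort_features(co)
  plan <- make_cv_plan(feats$record_id, n_folds = n_folds,
                       n_repeats = n_repeats, seed = master_seed)
  report <- run_cross_validation(feats, plan, tcfg,
                                 master_seed = master_seed, ...)
  list(cohort = co, features = feats, plan = plan, report = report)
}
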