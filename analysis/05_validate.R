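#!/usr/bin/env Rscript
# Stage 5: internal validation — landmark AUCs with bootstrap optimism
# correction, dynamic joint model vs static Cox comparator.
#
# For each landmark year the 3-year window risks of all at-risk patients
# are computed from (a) the refitted joint model and (b) the static Cox
# baseline-marker model; discrimination is the pairwise window AUC.
# Optimism is Harrell's bootstrap (patients resampled as clusters, the
# full pipeline refitted per replicate with shortened chains; the
# reduction is recorded in the output). Expect this stage to take on the
# order of an hour at the default settings; --fast cuts it to minutes.

suppressMessages(library(barrettjm))

fast <- "--fast" %in% commandArgs(trailingOnly = TRUE)

in_dir <- "results/data"
cohort <- read_cohort(file.path(in_dir, "baseline.csv"),
                      file.path(in_dir, "visits.csv"),
                      file.path(in_dir, "outcomes.csv"))
cohort <- standardize_age(cohort)

landmarks <- if (fast) 1:3 else 1:6
B <- if (fast) 2 else 20
# --fast scores all cases plus a control subsample per landmark (an
# unbiased, cheaper AUC); the full run scores everyone at risk
n_controls <- if (fast) 120 else Inf
refit_cfg <- if (fast) {
  joint_config(chains = 1, iter = 500, burnin = 200, n_knots = 2, b_store = 5)
} else {
  joint_config(chains = 1, iter = 1500, burnin = 600, n_knots = 3, b_store = 5)
}
score_cfg <- list(n_outer = if (fast) 15 else 40,
                  n_inner = if (fast) 60 else 120,
                  inner_burn = if (fast) 25 else 50, n_b = 2)

pick_subset <- function(cohort, landmark, seed) {
  if (!is.finite(n_controls)) return(NULL)
  oc <- cohort$outcomes
  cases <- oc$patient_id[oc$event == 1 & oc$event_time_years > landmark &
                           oc$event_time_years <= landmark + 3]
  ctrl <- setdiff(oc$patient_id[oc$event_time_years > landmark], cases)
  set.seed(seed)
  c(cases, sample(ctrl, min(n_controls, length(ctrl))))
}
dynamic_recipe <- function(train, seed) {
  cfg <- refit_cfg; cfg$seed <- seed
  fit <- suppressWarnings(fit_joint_model(train, cfg))
  function(eval_cohort, landmark, horizon)
    joint_risk_scores(fit, eval_cohort, landmark, horizon,
                      n_outer = score_cfg$n_outer,
                      n_inner = score_cfg$n_inner,
                      inner_burn = score_cfg$inner_burn,
                      n_b = score_cfg$n_b, seed = seed,
                      subset = pick_subset(eval_cohort, landmark,
                                           seed * 11 + landmark))
}
static_recipe <- function(train, seed) {
  fit <- suppressWarnings(fit_static_cox(train, on_monotone = "warn"))
  function(eval_cohort, landmark, horizon)
    static_cox_scores(fit, eval_cohort, landmark)
}

vc <- validation_config(landmarks = landmarks, horizon = 3,
                        n_bootstrap = B, seed = 99)
cat("dynamic model (", B, "bootstrap replicates )...\n")
dyn <- bootstrap_optimism(cohort, dynamic_recipe, vc)
cat("static Cox comparator...\n")
stat <- bootstrap_optimism(cohort, static_recipe, vc)

tab <- data.frame(year = landmarks,
                  auc_dynamic = round(dyn$apparent, 2),
                  auc_dynamic_corrected = round(dyn$corrected, 2),
                  auc_static = round(stat$apparent, 2))
print(tab, row.names = FALSE)
dir.create("results", showWarnings = FALSE)
utils::write.csv(tab, "results/validation_auc.csv", row.names = FALSE)
jsonlite::write_json(
  list(config = unclass(vc), fast = fast,
       refit_iterations = refit_cfg$iter,
       dynamic = dyn, static = stat),
  "results/validation_detail.json", auto_unbox = TRUE, digits = NA,
  dataframe = "rows")
cat("validation table written to results/validation_auc.csv\n")
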