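# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# Two-patient hand cohort with complete fields.
tiny_cohort <- function() {
  baselines <- data.frame(patient_id = c("A", "B"),
                          age_years = c(60, 50), female = c(0, 1))
  visits <- data.frame(
    patient_id = c("A", "A", "A", "B", "B"),
    time_years = c(0, 1.1, 2.4, 0, 0.9),
    lgd = c(0, 1, 0, 0, 0), p53 = c(0, 0, 1, 0, NA),
    sox2 = c(0, 0, 0, 1, 0),
    esophagitis = c(0, 0, 1, 0, 0), long_segment = c(1, 1, 1, 0, 0))
  outcomes <- data.frame(patient_id = c("A", "B"),
                         event_time_years = c(3.2, 5.5),
                         event = c(1, 0))
  new_cohort(baselines, visits, outcomes)
}

# Cohort whose person-time and event count reproduce a chosen summary:
# n_event events, total person-years py_total after 0.5-year entry.
incidence_cohort <- function(n_event, n_censor, py_total) {
  n <- n_event + n_censor
  py_each_event <- 2.5
  py_event <- n_event * py_each_event
  py_censor <- (py_total - py_event) / max(n_censor, 1)
  ids <- sprintf("I%03d", seq_len(n))
  T_i <- c(rep(0.5 + py_each_event, n_event),
           rep(0.5 + py_censor, n_censor))
  baselines <- data.frame(patient_id = ids, age_years = 60 +
                            seq_len(n) %% 7, female = seq_len(n) %% 2)
  visits <- data.frame(patient_id = ids, time_years = 0, lgd = 0, p53 = 0,
                       sox2 = 0, esophagitis = 0, long_segment = 1)
  outcomes <- data.frame(patient_id = ids, event_time_years = T_i,
                         event = rep(c(1, 0), c(n_event, n_censor)),
                         entry_time_years = 0.5)
  new_cohort(baselines, visits, outcomes)
}

# Truth with all covariate/association coefficients zero, constant
# baseline hazard exp(log_h), no dropout: pure exponential event times.
null_truth <- function(n, log_h, admin = 8) {
  beta <- matrix(0, 3, 6)
  beta[, 1] <- c(-1, -2, -2)   # marker intercepts only
  long <- longitudinal_params(beta, diag(c(1, 1, 1)))
  surv <- survival_params(baseline_hazard(numeric(0), log_h))
  simulation_truth(long, surv, n_patients = n, admin_censor_years = admin,
                   dropout_rate = 0, p_esophagitis = 0.1)
}

# Ordinary logistic regression by Newton-Raphson (independent oracle).
logistic_newton <- function(y, X, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (i in 1:100) {
    eta <- as.numeric(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    score <- t(X) %*% (y - p)
    info <- t(X) %*% (X * W)
    step <- solve(info, score)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# Brute-force window AUC: explicit double loop over case-control pairs.
auc_brute <- function(risks, outcomes, t, horizon) {
  oc <- outcomes[match(names(risks), outcomes$patient_id), ]
  keep <- oc$event_time_years > t
  oc <- oc[keep, ]; risks <- risks[keep]
  cases <- which(oc$event == 1 & oc$event_time_years <= t + horizon)
  controls <- which(oc$event_time_years > t + horizon)
  if (!length(cases) || !length(controls)) return(NA_real_)
  s <- 0
  for (i in cases) for (j in controls)
    s <- s + (risks[i] > risks[j]) + 0.5 * (risks[i] == risks[j])
  unname(s / (length(cases) * length(controls)))
}

# Small association-active simulated analysis cohort, filtered and
# age-standardized, with the study IHC design applied.
make_analysis_cohort <- function(n = 150, seed = 20, mode = "study") {
  tr <- default_truth(n_patients = n)
  sim <- simulate_cohort(tr, seed = seed)
  co <- apply_ihc_sampling_design(sim$cohort, mode = mode, seed = seed + 1)
  fl <- apply_eligibility_filters(co)
  list(cohort = standardize_age(fl$cohort), truth = tr, sim = sim,
       report = fl$report)
}
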