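## Internal validation: landmark window AUC, Harrell bootstrap optimism
## correction, and the static time-varying Cox comparator.

#' Landmark window AUC
#'
#' Discrimination between subjects who progress inside `(t, t + horizon]`
#' (cases) and subjects under observation and event-free at `t + horizon`
#' (controls), among subjects at risk at the landmark `t`. The AUC is
#' the proportion of case-control pairs ranked concordantly by the
#' predicted risk, ties counted half.
#'
#' Censoring policy: `"exclude"` drops subjects censored inside the
#' window from both groups; `"ipcw"` additionally weights each pair by
#' inverse Kaplan-Meier censoring-survival, evaluated at the case's
#' event time and at `t + horizon` for controls.
#'
#' @param risks named numeric vector of predicted window risks for
#'   subjects at risk at `t` (names = patient ids).
#' @param outcomes data.frame with `patient_id`, `event_time_years`,
#'   `event` covering at least the subjects in `risks`.
#' @param t landmark time (years).
#' @param horizon window length (years).
#' @param policy `"exclude"` or `"ipcw"`.
#' @return Scalar AUC in `[0, 1]`, or `NA` when there are no cases or no
#'   controls at this landmark.
#' @export
window_auc <- function(risks, outcomes, t, horizon,
                       policy = c("exclude", "ipcw")) {
  policy <- match.arg(policy)
  oc <- outcomes[match(names(risks), outcomes$patient_id), ]
  if (any(is.na(oc$patient_id)))
    stop("risks contain patient ids without outcome records", call. = FALSE)
  at_risk <- oc$event_time_years > t
  oc <- oc[at_risk, ]; risks <- risks[at_risk]
  Tt <- oc$event_time_years; ev <- oc$event
  is_case <- ev == 1 & Tt <= t + horizon
  is_control <- Tt > t + horizon
  if (sum(is_case) == 0 || sum(is_control) == 0) return(NA_real_)

  if (policy == "exclude") {
    rc <- risks[is_case]; rk <- risks[is_control]
    cmp <- outer(rc, rk, function(a, b) (a > b) + 0.5 * (a == b))
    return(sum(cmp) / length(cmp))
  }
  # IPCW: censoring-survival KM from the same outcome records
  cens_fit <- survival::survfit(
    survival::Surv(oc$event_time_years, 1 - oc$event) ~ 1)
  G <- function(times) {
    s <- summary(cens_fit, times = pmin(times, max(cens_fit$time)),
                 extend = TRUE)$surv
    pmax(s, 1e-6)
  }
  w_case <- 1 / G(Tt[is_case])
  w_ctrl <- rep(1 / G(t + horizon), sum(is_control))
  rc <- risks[is_case]; rk <- risks[is_control]
  cmp <- outer(rc, rk, function(a, b) (a > b) + 0.5 * (a == b))
  W <- outer(w_case, w_ctrl)
  sum(W * cmp) / sum(W)
}

#' Validation configuration
#'
#' @param landmarks landmark years (default 1..6).
#' @param horizon window (default 3 years).
#' @param n_bootstrap optimism-correction replicates (default 100).
#' @param censor_policy `"exclude"` or `"ipcw"`.
#' @param seed integer seed.
#' @return list of class `validation_config`.
#' @export
validation_config <- function(landmarks = 1:6, horizon = 3,
                              n_bootstrap = 100,
                              censor_policy = c("exclude", "ipcw"),
                              seed = 1) {
  stopifnot(all(landmarks > 0), !is.unsorted(landmarks, strictly = TRUE),
            n_bootstrap >= 0)
  structure(list(landmarks = landmarks, horizon = horizon,
                 n_bootstrap = as.integer(n_bootstrap),
                 censor_policy = match.arg(censor_policy),
                 seed = seed),
            class = "validation_config")
}

## Resample patients with replacement; clones get fresh unique ids.
resample_cohort <- function(cohort, ids) {
  new_ids <- sprintf("%s#%d", ids, seq_along(ids))
  pick <- function(df) {
    out <- do.call(rbind, lapply(seq_along(ids), function(j) {
      rows <- df[df$patient_id == ids[j], , drop = FALSE]
      rows$patient_id <- new_ids[j]
      rows
    }))
    rownames(out) <- NULL
    out
  }
  new_cohort(pick(cohort$baselines), pick(cohort$visits),
             pick(cohort$outcomes), age_scaler = cohort$age_scaler)
}

#' Bootstrap optimism-corrected landmark AUCs
#'
#' Harrell's procedure: the model recipe is refitted on each bootstrap
#' resample of patients (clusters, never visits); optimism is the mean
#' over replicates of (AUC on the bootstrap sample minus AUC of the same
#' refitted model on the original cohort), and the corrected AUC is the
#' apparent AUC minus the optimism, per landmark. Replicates whose refit
#' fails are dropped and counted.
#'
#' @param cohort the analysis `be_cohort`.
#' @param fit_recipe `function(cohort, seed)` returning a scoring
#'   function `function(cohort, landmark, horizon) -> named risk vector`
#'   for subjects at risk at the landmark. Must be deterministic given
#'   `seed`.
#' @param config A [validation_config()].
#' @return data.frame (one row per landmark): `landmark`, `apparent`,
#'   `optimism`, `corrected`, `n_replicates`, `n_failed`.
#' @export
bootstrap_optimism <- function(cohort, fit_recipe, config) {
  stopifnot(inherits(config, "validation_config"))
  L <- config$landmarks
  score_full <- fit_recipe(cohort, seed = config$seed)
  apparent <- vapply(L, function(t)
    window_auc(score_full(cohort, t, config$horizon), cohort$outcomes,
               t, config$horizon, config$censor_policy), numeric(1))

  B <- config$n_bootstrap
  opt <- matrix(NA_real_, B, length(L))
  n_failed <- 0
  if (B > 0) {
    set.seed(as.integer(config$seed))
    boot_seeds <- sample.int(1e6, B)
    ids <- cohort$baselines$patient_id
    for (bb in seq_len(B)) {
      set.seed(boot_seeds[bb])
      samp <- sample(ids, length(ids), replace = TRUE)
      res <- tryCatch({
        boot_cohort <- resample_cohort(cohort, samp)
        score_b <- fit_recipe(boot_cohort, seed = boot_seeds[bb])
        vapply(L, function(t) {
          a_boot <- window_auc(score_b(boot_cohort, t, config$horizon),
                               boot_cohort$outcomes, t, config$horizon,
                               config$censor_policy)
          a_orig <- window_auc(score_b(cohort, t, config$horizon),
                               cohort$outcomes, t, config$horizon,
                               config$censor_policy)
          a_boot - a_orig
        }, numeric(1))
      }, error = function(e) NULL)
      if (is.null(res)) n_failed <- n_failed + 1 else opt[bb, ] <- res
    }
  }
  optimism <- if (B > 0) colMeans(opt, na.rm = TRUE) else rep(0, length(L))
  optimism[is.nan(optimism)] <- 0
  data.frame(landmark = L, apparent = apparent, optimism = optimism,
             corrected = apparent - optimism,
             n_replicates = B - n_failed, n_failed = n_failed)
}

#' Static time-varying Cox comparator
#'
#' The sensitivity-analysis model: a Cox proportional hazards fit with
#' delayed entry at 0.5 years, baseline (index-endoscopy) marker values
#' as fixed covariates, standardized age and gender at baseline, and BE
#' length/esophagitis as time-varying step functions in
#' counting-process form. Efron tie handling; Wald 95% CIs. A missing
#' baseline marker is treated as normal (0) and counted — the study's
#' staining design guarantees sparse baseline p53/SOX2 in
#' non-progressors, so dropping those patients would bias the
#' comparator.
#'
#' @param cohort a filtered, age-standardized `be_cohort`.
#' @param on_monotone `"error"` (default) to fail on a monotone partial
#'   likelihood; `"warn"` to keep the fit — the linear predictor still
#'   ranks subjects, which is all the AUC comparator needs.
#' @return An object of class `static_cox_fit`: coefficient table with
#'   95% CIs and HRs, partial log-likelihood, ties method, count of
#'   imputed baseline markers, and the underlying `survival::coxph` fit.
#' @export
fit_static_cox <- function(cohort, on_monotone = c("error", "warn")) {
  on_monotone <- match.arg(on_monotone)
  stopifnot(inherits(cohort, "be_cohort"))
  if (is.null(cohort$age_scaler))
    stop("standardize_age() must be applied first", call. = FALSE)
  cp <- static_cox_frame(cohort)
  fit <- survival::coxph(
    survival::Surv(start, stop, event) ~ age_std + female + long_segment +
      esophagitis + lgd0 + p530 + sox20,
    data = cp$data, ties = "efron")
  cf <- stats::coef(fit)
  # constant covariates are aliased out (NA); a huge finite estimate
  # signals a monotone partial likelihood
  if (any(abs(cf[!is.na(cf)]) > 15)) {
    msg <- "static Cox fit: monotone partial likelihood for some covariate"
    if (on_monotone == "error") stop(msg, call. = FALSE) else warning(msg)
  }
  sm <- summary(fit)$coefficients
  est <- se <- stats::setNames(rep(NA_real_, length(cf)), names(cf))
  est[rownames(sm)] <- sm[, "coef"]
  se[rownames(sm)] <- sm[, "se(coef)"]
  tab <- data.frame(term = rownames(sm), coef = est, se = se,
                    hr = exp(est),
                    lower = exp(est - stats::qnorm(0.975) * se),
                    upper = exp(est + stats::qnorm(0.975) * se))
  rownames(tab) <- NULL
  structure(list(coefficients = tab,
                 loglik = fit$loglik[2], ties = "efron",
                 n_imputed_baseline = cp$n_imputed,
                 model = fit, age_scaler = cohort$age_scaler),
            class = "static_cox_fit")
}

## Counting-process frame: one row per patient per inter-visit interval
## after entry, with baseline markers fixed and step covariates updated.
static_cox_frame <- function(cohort, entry_default = 0.5) {
  bl <- cohort$baselines
  oc <- cohort$outcomes[match(bl$patient_id, cohort$outcomes$patient_id), ]
  vis <- cohort$visits
  age_std <- scaled_age(bl$age_years, cohort$age_scaler)
  n_imputed <- 0
  rows <- vector("list", nrow(bl))
  for (i in seq_len(nrow(bl))) {
    pid <- bl$patient_id[i]
    v <- vis[vis$patient_id == pid, , drop = FALSE]
    entry <- oc$entry_time_years[i]
    if (entry <= 0) entry <- entry_default
    Tt <- oc$event_time_years[i]
    if (Tt <= entry) next
    base <- v[1, ]
    m0 <- unname(vapply(MARKERS, function(m) {
      x <- base[[m]]
      if (is.na(x)) { n_imputed <<- n_imputed + 1; 0 } else x
    }, numeric(1)))
    cuts <- sort(unique(c(entry, v$time_years[v$time_years > entry &
                                                v$time_years < Tt], Tt)))
    idx <- findInterval(cuts[-length(cuts)], v$time_years)
    idx[idx == 0] <- 1L
    rows[[i]] <- data.frame(
      patient_id = pid,
      start = cuts[-length(cuts)], stop = cuts[-1],
      event = c(rep(0, length(cuts) - 2), oc$event[i]),
      age_std = age_std[i], female = bl$female[i],
      long_segment = v$long_segment[idx], esophagitis = v$esophagitis[idx],
      lgd0 = m0[1], p530 = m0[2], sox20 = m0[3])
  }
  list(data = do.call(rbind, rows), n_imputed = n_imputed)
}

#' @export
print.static_cox_fit <- function(x, ...) {
  cat(sprintf(
    "Static Cox comparator (Efron ties, delayed entry; %d baseline markers imputed as normal)\n",
    x$n_imputed_baseline))
  tab <- x$coefficients
  tab[, -1] <- round(tab[, -1], 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Risk scores from the static Cox comparator
#'
#' Baseline (index-endoscopy) linear predictor per patient at risk at
#' the landmark — the static comparator's risk ranking for
#' [window_auc()] (a rank, not a calibrated probability; all covariates
#' and markers are taken at baseline, so the score of a patient never
#' updates across landmarks).
#'
#' @param fit A `static_cox_fit`.
#' @param cohort cohort to score.
#' @param landmark landmark time (years).
#' @param horizon ignored (kept for recipe signature compatibility).
#' @return Named vector of scores for subjects with
#'   `event_time_years > landmark`.
#' @export
static_cox_scores <- function(fit, cohort, landmark, horizon = NULL) {
  stopifnot(inherits(fit, "static_cox_fit"))
  bl <- cohort$baselines
  oc <- cohort$outcomes[match(bl$patient_id, cohort$outcomes$patient_id), ]
  vis <- cohort$visits
  at_risk <- which(oc$event_time_years > landmark)
  cf <- stats::setNames(fit$coefficients$coef, fit$coefficients$term)
  cf[is.na(cf)] <- 0   # aliased (constant) covariates carry no signal
  age_std <- scaled_age(bl$age_years, fit$age_scaler)
  out <- vapply(at_risk, function(i) {
    v <- vis[vis$patient_id == bl$patient_id[i], , drop = FALSE][1, ]
    m0 <- vapply(MARKERS, function(m) {
      x <- v[[m]]
      if (is.na(x)) 0 else x
    }, numeric(1))
    sum(cf * c(age_std[i], bl$female[i], v$long_segment,
               v$esophagitis, m0))
  }, numeric(1))
  stats::setNames(out, bl$patient_id[at_risk])
}

#' Dynamic risk scores for every subject at risk at a landmark
#'
#' Builds each at-risk subject's history (visits at or before the
#' landmark, outcome withheld) and computes the [dynamic_risk()] point
#' risk. The workhorse behind the dynamic model's landmark AUCs.
#'
#' @param fit A `joint_fit`.
#' @param cohort cohort to score.
#' @param landmark landmark time (years).
#' @param horizon window (years).
#' @param n_outer,n_inner,inner_burn,n_b,seed passed to [dynamic_risk()]
#'   (reduced defaults: scoring a cohort runs one prediction per subject).
#' @param subset optional patient ids: score only these (e.g. all cases
#'   plus a random control subsample, an unbiased scaled-down AUC).
#' @return Named vector of window risks for subjects with
#'   `event_time_years > landmark`.
#' @export
joint_risk_scores <- function(fit, cohort, landmark, horizon = 3,
                              n_outer = 25, n_inner = 80, inner_burn = 30,
                              n_b = 2, seed = 1, subset = NULL) {
  bl <- cohort$baselines
  oc <- cohort$outcomes[match(bl$patient_id, cohort$outcomes$patient_id), ]
  vis <- cohort$visits
  at_risk <- which(oc$event_time_years > landmark)
  if (!is.null(subset))
    at_risk <- at_risk[bl$patient_id[at_risk] %in% subset]
  out <- vapply(seq_along(at_risk), function(jj) {
    i <- at_risk[jj]
    v <- vis[vis$patient_id == bl$patient_id[i], , drop = FALSE]
    v <- v[v$time_years <= landmark + 1e-9, , drop = FALSE]
    h <- patient_history(bl$age_years[i], bl$female[i], v)
    dynamic_risk(h, fit, landmark, horizon = horizon, n_outer = n_outer,
                 n_inner = n_inner, inner_burn = inner_burn, n_b = n_b,
                 seed = seed + i)$risk
  }, numeric(1))
  stats::setNames(out, bl$patient_id[at_risk])
}
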