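## Multivariate joint model: three random-intercept logistic marker
## processes linked to the HGD/EAC hazard through current-value and
## accumulated-effect associations, fitted by Metropolis-within-Gibbs.
##
## The likelihood engine works on a precomputed, stacked representation
## of the cohort (visit design rows; covariate/knot "pieces" per patient
## on which every marker linear predictor is affine in time; fixed
## Gauss-Legendre nodes per piece), so each evaluation is a handful of
## matrix operations.

#' Per-10% hazard ratio from an association coefficient
#'
#' Association coefficients are per unit probability of aberrant
#' expression; the reported hazard ratio is for a 10% change in that
#' probability, `HR = exp(0.1 * alpha)`.
#'
#' @param alpha association coefficient (value or accumulated scale).
#' @return Hazard ratio per 10% change.
#' @export
hazard_ratio_per_10pct <- function(alpha) exp(0.1 * alpha)

#' Illustrative per-marker risk contribution
#'
#' The back-of-envelope arithmetic used when explaining the model to
#' clinicians: the current estimated probability of aberrant expression
#' multiplied by the marker's value hazard ratio (e.g. 0.2 x 1.26 =
#' 0.25 for a p53 history of four normal and one aberrant measurement).
#' This illustrates how a marker's longitudinal evolution scales its
#' risk contribution; it is not the model-based window risk (for that,
#' see [dynamic_risk()]).
#'
#' @param prob_aberrant probability in `[0, 1]`.
#' @param hr_value the marker's value hazard ratio.
#' @return `prob_aberrant * hr_value`.
#' @export
illustrative_risk_contribution <- function(prob_aberrant, hr_value) {
  stopifnot(prob_aberrant >= 0, prob_aberrant <= 1)
  prob_aberrant * hr_value
}

## ---------------------------------------------------------------------
## Precomputed cohort representation

joint_precompute <- function(cohort, knots, nodes = 15) {
  stopifnot(inherits(cohort, "be_cohort"))
  bl <- cohort$baselines; vis <- cohort$visits
  oc <- cohort$outcomes[match(cohort$baselines$patient_id,
                              cohort$outcomes$patient_id), ]
  n <- nrow(bl)
  T_i <- oc$event_time_years
  entry <- oc$entry_time_years
  event <- oc$event
  age_std <- scaled_age(bl$age_years, cohort$age_scaler)
  female <- bl$female

  vm <- match(vis$patient_id, bl$patient_id)
  ordv <- order(vm, vis$time_years)
  vis <- vis[ordv, ]; vm <- vm[ordv]
  Xv <- cbind(1, vis$time_years, age_std[vm], female[vm],
              vis$long_segment, vis$esophagitis)
  Y <- as.matrix(vis[MARKERS])

  pieces <- do.call(rbind, lapply(seq_len(n), function(i) {
    idx <- which(vm == i)
    pcs <- build_pieces(vis$time_years[idx], vis$esophagitis[idx],
                        vis$long_segment[idx], knots, T_i[i])
    pcs$pat <- i
    pcs
  }))
  np <- nrow(pieces)
  Xp0 <- cbind(1, 0, age_std[pieces$pat], female[pieces$pat],
               pieces$long, pieces$eso)
  first_row <- which(!duplicated(pieces$pat))

  # outer quadrature nodes over [entry_i, T_i]
  gl <- gauss_legendre(nodes)
  qa <- pmax(pieces$start, entry[pieces$pat])
  qb <- pieces$end
  live <- which(qb > qa + 1e-12)
  q_piece <- rep(live, each = nodes)
  half <- (qb[live] - qa[live]) / 2
  mid <- (qb[live] + qa[live]) / 2
  q_s <- as.numeric(t(outer(mid, rep(1, nodes)) + outer(half, gl$nodes)))
  q_w <- as.numeric(t(outer(half, gl$weights)))
  q_pat <- pieces$pat[q_piece]
  Wq <- cbind(age_std[q_pat], female[q_pat],
              pieces$long[q_piece], pieces$eso[q_piece])

  # event rows: hazard evaluated at T_i (last piece of the patient)
  last_row <- c(first_row[-1] - 1L, np)
  e_pat <- which(event == 1)
  e_piece <- last_row[e_pat]
  e_t <- T_i[e_pat]
  We <- cbind(age_std[e_pat], female[e_pat],
              pieces$long[e_piece], pieces$eso[e_piece])

  list(n = n, patient_id = bl$patient_id, T_i = T_i, entry = entry,
       event = event, age_std = age_std, female = female,
       Xv = Xv, Y = Y, vm = vm,
       pieces = pieces, Xp0 = Xp0, first_row = first_row,
       q_piece = q_piece, q_s = q_s, q_w = q_w, q_pat = q_pat, Wq = Wq,
       e_pat = e_pat, e_piece = e_piece, e_t = e_t, We = We,
       lam_q = pieces$lam_idx[q_piece], lam_e = pieces$lam_idx[e_piece],
       knots = knots, nodes = nodes)
}

## Marker-dependent terms: visit-level linear predictors, piece-level
## affine coefficients, value and running-integral terms at quadrature
## and event nodes. `markers` allows recomputing a subset of columns
## against a previous result.
marker_terms <- function(pp, beta, b, prev = NULL, markers = 1:3) {
  mt <- prev %||% list(eta_v = matrix(0, nrow(pp$Xv), 3),
                       A = matrix(0, nrow(pp$pieces), 3),
                       cc = numeric(3),
                       Istart = matrix(0, nrow(pp$pieces), 3),
                       pis_q = matrix(0, length(pp$q_s), 3),
                       Iq = matrix(0, length(pp$q_s), 3),
                       pis_e = matrix(0, length(pp$e_t), 3),
                       Ie = matrix(0, length(pp$e_t), 3))
  pc <- pp$pieces
  for (k in markers) {
    bk <- beta[k, ]
    mt$eta_v[, k] <- pp$Xv %*% bk + b[pp$vm, k]
    A <- pp$Xp0 %*% bk + b[pc$pat, k]
    ck <- bk[[2]]
    dI <- integral_expit_affine(A, ck, pc$start, pc$end)
    cs <- cumsum(dI)
    Ist <- c(0, cs[-length(cs)])
    off <- Ist[pp$first_row]
    Ist <- Ist - off[pc$pat]
    mt$A[, k] <- A
    mt$cc[k] <- ck
    mt$Istart[, k] <- Ist
    Aq <- A[pp$q_piece]
    mt$pis_q[, k] <- expit(Aq + ck * pp$q_s)
    mt$Iq[, k] <- Ist[pp$q_piece] +
      integral_expit_affine(Aq, ck, pc$start[pp$q_piece], pp$q_s)
    if (length(pp$e_t)) {
      Ae <- A[pp$e_piece]
      mt$pis_e[, k] <- expit(Ae + ck * pp$e_t)
      mt$Ie[, k] <- Ist[pp$e_piece] +
        integral_expit_affine(Ae, ck, pc$start[pp$e_piece], pp$e_t)
    }
  }
  mt
}

## Per-patient survival log-likelihood: event * log h(T) - H(entry, T).
surv_ll_pat <- function(pp, mt, gamma, av, ac, log_rates) {
  loghaz_q <- log_rates[pp$lam_q] + pp$Wq %*% gamma +
    mt$pis_q %*% av + mt$Iq %*% ac
  Hq <- pp$q_w * exp(loghaz_q)
  H <- numeric(pp$n)
  sums <- rowsum(Hq, pp$q_pat)
  H[as.integer(rownames(sums))] <- sums
  ll <- -H
  if (length(pp$e_t)) {
    logh_e <- log_rates[pp$lam_e] + pp$We %*% gamma +
      mt$pis_e %*% av + mt$Ie %*% ac
    ll[pp$e_pat] <- ll[pp$e_pat] + logh_e
  }
  ll
}

## Per-patient Bernoulli log-likelihood over non-missing marker
## observations.
long_ll_pat <- function(pp, mt) {
  contrib <- pp$Y * mt$eta_v - softplus(mt$eta_v)
  contrib[is.na(pp$Y)] <- 0
  ll <- numeric(pp$n)
  sums <- rowsum(rowSums(contrib), pp$vm)
  ll[as.integer(rownames(sums))] <- sums
  ll
}

#' Joint log-likelihood at fixed parameters and random intercepts
#'
#' Sum over patients of the Bernoulli log-likelihood of the non-missing
#' marker observations plus the survival contribution
#' `event * log h(T) - H(entry, T)`, with the hazard of
#' [survival_params()] evaluated along each patient's covariate path and
#' marker probability trajectories implied by `(long, b)`. Visits whose
#' markers are all missing contribute nothing.
#'
#' @param cohort A `be_cohort` with `age_scaler` set; may be `NULL`/empty
#'   (log-likelihood 0).
#' @param long A [longitudinal_params()].
#' @param surv A [survival_params()].
#' @param b n x 3 matrix of per-patient random intercepts (rows in
#'   baseline-table order).
#' @param nodes Gauss-Legendre nodes per piece (default 15).
#' @return Scalar log-likelihood.
#' @export
joint_log_likelihood <- function(cohort, long, surv, b, nodes = 15) {
  if (is.null(cohort) || nrow(cohort$baselines) == 0L) return(0)
  pp <- joint_precompute(cohort, surv$baseline$knots, nodes = nodes)
  b <- matrix(b, pp$n, 3)
  mt <- marker_terms(pp, long$beta, b)
  ll <- sum(long_ll_pat(pp, mt)) +
    sum(surv_ll_pat(pp, mt, surv$gamma, surv$alpha_value,
                    surv$alpha_cumulative, surv$baseline$log_rates))
  if (!is.finite(ll)) {
    bad <- which(!is.finite(long_ll_pat(pp, mt) +
                              surv_ll_pat(pp, mt, surv$gamma,
                                          surv$alpha_value,
                                          surv$alpha_cumulative,
                                          surv$baseline$log_rates)))
    stop("non-finite joint log-likelihood for patient(s): ",
         paste(pp$patient_id[bad], collapse = ", "), call. = FALSE)
  }
  ll
}

## ---------------------------------------------------------------------
## Sampler configuration and priors

#' Sampler configuration for the joint model
#'
#' @param chains number of MCMC chains (chain c is seeded `seed + c`).
#' @param iter total iterations per chain (including burn-in).
#' @param burnin adaptation/burn-in iterations discarded from summaries.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer master seed.
#' @param n_knots baseline-hazard intervals (knots at event-time
#'   quantiles when `knots` is `NULL`).
#' @param knots explicit interior knots (overrides `n_knots`).
#' @param nodes Gauss-Legendre nodes per piece.
#' @param b_store number of (thinned) iterations for which per-patient
#'   random-intercept draws are kept.
#' @param prior_sd normal prior sd for fixed effects, gamma, alpha and
#'   log baseline rates.
#' @param sd_scale half-t(3, scale) prior scale for random-intercept sds.
#' @return A list of class `joint_config`.
#' @export
joint_config <- function(chains = 2, iter = 6000, burnin = 1000, thin = 1,
                         seed = 1, n_knots = 5, knots = NULL, nodes = 15,
                         b_store = 100, prior_sd = 10, sd_scale = 2.5) {
  stopifnot(iter > burnin, chains >= 1, thin >= 1)
  structure(list(chains = chains, iter = iter, burnin = burnin,
                 thin = thin, seed = seed, n_knots = n_knots,
                 knots = knots, nodes = nodes, b_store = b_store,
                 prior_sd = prior_sd, sd_scale = sd_scale),
            class = "joint_config")
}

log_half_t <- function(s, nu = 3, A = 2.5) {
  ifelse(s <= 0, -Inf, -(nu + 1) / 2 * log1p((s / A)^2 / nu))
}

## log MVN(b_i; 0, D) summed over patients, via Cholesky of D.
log_mvn_sum <- function(b, D) {
  ch <- tryCatch(chol(D), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  z <- backsolve(ch, t(b), transpose = TRUE)
  -0.5 * sum(z^2) - nrow(b) * (sum(log(diag(ch))) + 1.5 * log(2 * pi))
}

make_D <- function(sds, r) {
  R <- matrix(c(1, r[1], r[2],
                r[1], 1, r[3],
                r[2], r[3], 1), 3, 3)
  diag(sds) %*% R %*% diag(sds)
}

## ---------------------------------------------------------------------
## Metropolis-within-Gibbs sampler

#' Fit the multivariate joint model by MCMC
#'
#' Block Metropolis-within-Gibbs: random-walk updates for each marker's
#' fixed effects, the survival covariate coefficients, the value and
#' accumulated association coefficients, the log baseline rates, every
#' patient's random-intercept vector (proposed in parallel, accepted per
#' patient), and the random-intercept covariance (log-sd and correlation
#' blocks). Proposal scales adapt toward 20-40% acceptance during
#' burn-in only. Initialization comes from the separate marker fits
#' ([fit_mixed_logistic()]) and an events/person-years constant hazard.
#' Priors: normal(0, `prior_sd`^2) on fixed effects, gamma, alpha and log
#' rates; half-t(3, `sd_scale`) on random-intercept sds; uniform over
#' positive-definite correlation matrices.
#'
#' @param cohort A filtered, age-standardized `be_cohort` with >= 1 event.
#' @param config A [joint_config()].
#' @param init optional list with elements `beta`, `sd_b` to skip the
#'   marker-fit initialization (used by bootstrap refits).
#' @param prior_only ignore the data likelihood and sample from the
#'   prior (a sampler diagnostic: posterior moments must then match the
#'   prior's).
#' @param fix_alpha hold both association vectors at zero (the joint
#'   model then nests the covariate-only survival model).
#' @param verbose print progress.
#' @return A `joint_fit`: per-chain draw matrices, thinned random-intercept
#'   draws, split R-hat and effective sample size per scalar, acceptance
#'   rates, the frozen age scaler, knots, and the config. Flagged
#'   `converged = FALSE` when any scalar's split R-hat exceeds 1.1.
#' @export
fit_joint_model <- function(cohort, config = joint_config(), init = NULL,
                            prior_only = FALSE, fix_alpha = FALSE,
                            verbose = FALSE) {
  stopifnot(inherits(cohort, "be_cohort"))
  if (is.null(cohort$age_scaler))
    stop("standardize_age() must be applied before fitting", call. = FALSE)
  oc <- cohort$outcomes
  if (sum(oc$event) < 1) stop("need at least one event", call. = FALSE)

  knots <- config$knots
  if (is.null(knots)) {
    ev_t <- oc$event_time_years[oc$event == 1]
    K <- config$n_knots
    if (K > 1 && length(ev_t) >= K) {
      knots <- unname(stats::quantile(ev_t, probs = seq_len(K - 1) / K))
      knots <- unique(pmax(knots, min(oc$entry_time_years) + 0.25))
      knots <- knots[knots < max(oc$event_time_years)]
    } else knots <- numeric(0)
  }
  K <- length(knots) + 1L
  pp <- joint_precompute(cohort, knots, nodes = config$nodes)

  # initialization: separate marker fits + constant crude hazard
  # (skipped when sampling the prior; clamped against separation-inflated
  # estimates on sparse cohorts)
  if (is.null(init)) {
    init <- list(beta = matrix(0, 3, 6), sd_b = rep(1, 3))
    if (!prior_only) {
      for (k in 1:3) {
        fk <- tryCatch(
          suppressMessages(fit_mixed_logistic(cohort, MARKERS[k], nagq = 1)),
          error = function(e) NULL)
        if (!is.null(fk)) {
          est <- fk$estimates
          est[is.na(est)] <- 0
          init$beta[k, ] <- pmin(pmax(est, -8), 8)
          init$sd_b[k] <- min(max(fk$sd_b, 0.3), 5)
        }
      }
    }
  }
  py <- sum(pp$T_i - pp$entry)
  log_rate0 <- log(max(sum(pp$event), 0.5) / py)

  par_names <- c(
    paste0("beta.", rep(MARKERS, each = 6), ".", rep(FIXEF_NAMES, 3)),
    paste0("gamma.", GAMMA_NAMES),
    paste0("alpha_value.", MARKERS),
    paste0("alpha_cumulative.", MARKERS),
    paste0("log_rate.", seq_len(K)),
    paste0("sd_b.", MARKERS),
    c("cor.lgd.p53", "cor.lgd.sox2", "cor.p53.sox2"))

  run_chain <- function(chain) {
    set.seed(as.integer(config$seed) + chain)
    beta <- init$beta + matrix(stats::rnorm(18, 0, 0.02), 3, 6)
    dimnames(beta) <- list(MARKERS, FIXEF_NAMES)
    gamma <- stats::rnorm(4, 0, 0.02)
    av <- if (fix_alpha) rep(0, 3) else stats::rnorm(3, 0, 0.02)
    ac <- if (fix_alpha) rep(0, 3) else stats::rnorm(3, 0, 0.02)
    log_rates <- rep(log_rate0, K) + stats::rnorm(K, 0, 0.02)
    sds <- pmax(init$sd_b, 0.3) * exp(stats::rnorm(3, 0, 0.02))
    rr <- rep(0, 3)
    D <- make_D(sds, rr)
    b <- matrix(0, pp$n, 3)

    zero_ll <- numeric(pp$n)
    eval_mt <- function(beta, b, prev = NULL, markers = 1:3)
      if (prior_only) NULL else marker_terms(pp, beta, b, prev, markers)
    eval_long <- function(mt) if (prior_only) zero_ll else long_ll_pat(pp, mt)
    eval_surv <- function(mt, g, a1, a2, lr)
      if (prior_only) zero_ll else surv_ll_pat(pp, mt, g, a1, a2, lr)

    mt <- eval_mt(beta, b)
    ll_long <- eval_long(mt)
    ll_surv <- eval_surv(mt, gamma, av, ac, log_rates)

    prior_beta <- function(bt) sum(stats::dnorm(bt, 0, config$prior_sd,
                                                log = TRUE))
    # Adaptive-covariance Metropolis state. The survival parameters
    # (gamma, alpha_value, alpha_cumulative, log rates) are one joint
    # block: the value and accumulated associations of a marker are
    # strongly correlated a posteriori and componentwise walks stall.
    th_s <- c(gamma, av, ac, log_rates)
    d_s <- 10 + K
    s_active <- if (fix_alpha) c(1:4, 10 + seq_len(K)) else seq_len(d_s)
    chol_s <- diag(c(rep(0.1, 4), rep(0.3, 3), rep(0.12, 3),
                     rep(0.25, K))[s_active], length(s_active))
    chol_beta <- lapply(1:3, function(k) diag(0.08, 6))
    hist_s <- matrix(NA_real_, config$burnin, length(s_active))
    hist_beta <- lapply(1:3, function(k) matrix(NA_real_, config$burnin, 6))
    scales <- list(beta = rep(1, 3), surv = 1, b = 0.6,
                   sds = 0.15, cor = 0.1)
    acc <- list(beta = c(0, 0, 0), surv = 0, b = 0, sds = 0, cor = 0)
    cnt <- acc
    adapt_window <- 25

    n_keep <- floor((config$iter - config$burnin) / config$thin)
    draws <- matrix(NA_real_, n_keep, length(par_names),
                    dimnames = list(NULL, par_names))
    b_keep_at <- unique(round(seq(1, n_keep,
                                  length.out = min(config$b_store, n_keep))))
    b_draws <- array(NA_real_, c(length(b_keep_at), pp$n, 3))
    kept <- 0

    for (it in seq_len(config$iter)) {
      adapting <- it <= config$burnin
      # --- marker fixed-effect blocks (6-dim adaptive random walk each)
      for (k in 1:3) {
        prop <- beta
        prop[k, ] <- prop[k, ] +
          scales$beta[k] * drop(stats::rnorm(6) %*% chol_beta[[k]])
        mt2 <- eval_mt(prop, b, prev = mt, markers = k)
        ll_long2 <- eval_long(mt2)
        ll_surv2 <- eval_surv(mt2, gamma, av, ac, log_rates)
        lr <- sum(ll_long2 + ll_surv2) - sum(ll_long + ll_surv) +
          prior_beta(prop[k, ]) - prior_beta(beta[k, ])
        cnt$beta[k] <- cnt$beta[k] + 1
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          beta <- prop; mt <- mt2; ll_long <- ll_long2; ll_surv <- ll_surv2
          acc$beta[k] <- acc$beta[k] + 1
        }
        if (adapting) hist_beta[[k]][it, ] <- beta[k, ]
      }
      # --- joint survival block (adaptive covariance)
      prop_th <- th_s
      prop_th[s_active] <- th_s[s_active] +
        scales$surv * drop(stats::rnorm(length(s_active)) %*% chol_s)
      g2 <- prop_th[1:4]; av2 <- prop_th[5:7]; ac2 <- prop_th[8:10]
      lam2 <- prop_th[10 + seq_len(K)]
      ll_surv2 <- eval_surv(mt, g2, av2, ac2, lam2)
      lr <- sum(ll_surv2) - sum(ll_surv) +
        prior_beta(prop_th[s_active]) - prior_beta(th_s[s_active])
      cnt$surv <- cnt$surv + 1
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        th_s <- prop_th
        gamma <- g2; av <- av2; ac <- ac2; log_rates <- lam2
        ll_surv <- ll_surv2
        acc$surv <- acc$surv + 1
      }
      if (adapting) hist_s[it, ] <- th_s[s_active]
      # --- random intercepts: propose all patients, accept per patient
      ch_D <- chol(D)
      bprop <- b + matrix(stats::rnorm(pp$n * 3), pp$n, 3) %*%
        (scales$b * ch_D)
      mt2 <- eval_mt(beta, bprop)
      ll_long2 <- eval_long(mt2)
      ll_surv2 <- eval_surv(mt2, gamma, av, ac, log_rates)
      pr1 <- mvn_rows_logpdf(b, ch_D)
      pr2 <- mvn_rows_logpdf(bprop, ch_D)
      lr_pat <- (ll_long2 + ll_surv2 + pr2) - (ll_long + ll_surv + pr1)
      accept <- is.finite(lr_pat) & log(stats::runif(pp$n)) < lr_pat
      cnt$b <- cnt$b + 1
      acc$b <- acc$b + mean(accept)
      if (any(accept)) {
        b[accept, ] <- bprop[accept, ]
        ll_long[accept] <- ll_long2[accept]
        ll_surv[accept] <- ll_surv2[accept]
      }
      if (any(accept) && !prior_only) {
        sel <- function(old, new, rows) { old[rows, ] <- new[rows, ]; old }
        vrow <- accept[pp$vm]; prow <- accept[pp$pieces$pat]
        qrow <- accept[pp$q_pat]; erow <- accept[pp$e_pat]
        mt$eta_v <- sel(mt$eta_v, mt2$eta_v, vrow)
        mt$A <- sel(mt$A, mt2$A, prow)
        mt$Istart <- sel(mt$Istart, mt2$Istart, prow)
        mt$pis_q <- sel(mt$pis_q, mt2$pis_q, qrow)
        mt$Iq <- sel(mt$Iq, mt2$Iq, qrow)
        if (length(pp$e_t)) {
          mt$pis_e <- sel(mt$pis_e, mt2$pis_e, erow)
          mt$Ie <- sel(mt$Ie, mt2$Ie, erow)
        }
      }
      # --- covariance of the random intercepts
      for (blk in c("sds", "cor")) {
        if (blk == "sds") {
          prop_s <- sds * exp(stats::rnorm(3) * scales$sds)
          D2 <- make_D(prop_s, rr)
          lr <- log_mvn_sum(b, D2) - log_mvn_sum(b, D) +
            sum(log_half_t(prop_s, A = config$sd_scale)) -
            sum(log_half_t(sds, A = config$sd_scale)) +
            sum(log(prop_s)) - sum(log(sds))   # log-scale Jacobian
        } else {
          prop_r <- rr + stats::rnorm(3) * scales$cor
          D2 <- make_D(sds, prop_r)
          lr <- if (any(abs(prop_r) >= 1)) -Inf else
            log_mvn_sum(b, D2) - log_mvn_sum(b, D)
        }
        cnt[[blk]] <- cnt[[blk]] + 1
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          if (blk == "sds") sds <- prop_s else rr <- prop_r
          D <- D2
          acc[[blk]] <- acc[[blk]] + 1
        }
      }
      # --- adaptation (burn-in only)
      if (adapting && it %% adapt_window == 0) {
        tune <- function(s, a, n, target = 0.25)
          s * exp(0.6 * (a / n - target))
        scales$beta <- tune(scales$beta, acc$beta, cnt$beta)
        scales$surv <- tune(scales$surv, acc$surv, cnt$surv)
        for (blk in c("b", "sds", "cor"))
          scales[[blk]] <- tune(scales[[blk]], acc[[blk]], cnt[[blk]], 0.3)
        acc <- lapply(acc, function(x) x * 0)
        cnt <- lapply(cnt, function(x) x * 0)
      }
      if (adapting && it >= 200 && it %% 100 == 0) {
        win <- max(1, it - 600):it
        upd <- function(old, H, d) {
          S <- stats::cov(H[win, , drop = FALSE])
          tryCatch(chol(S * (2.38^2 / d) + diag(1e-9, d)),
                   error = function(e) old)
        }
        chol_s <- upd(chol_s, hist_s, length(s_active))
        for (k in 1:3) chol_beta[[k]] <- upd(chol_beta[[k]],
                                             hist_beta[[k]], 6)
      }
      # --- store
      if (it > config$burnin && (it - config$burnin) %% config$thin == 0) {
        kept <- kept + 1
        draws[kept, ] <- c(as.numeric(t(beta)), gamma, av, ac, log_rates,
                           sds, rr)
        pos <- match(kept, b_keep_at)
        if (!is.na(pos)) b_draws[pos, , ] <- b
      }
      if (verbose && it %% 500 == 0)
        message(sprintf("chain %d iter %d / %d", chain, it, config$iter))
    }
    list(draws = draws, b_draws = b_draws,
         accept = lapply(acc, function(x) x), final_scales = scales)
  }

  chains <- lapply(seq_len(config$chains), run_chain)
  draw_mats <- lapply(chains, `[[`, "draws")

  rhat <- vapply(par_names, function(pn) {
    split_rhat(sapply(draw_mats, function(d) d[, pn]))
  }, numeric(1))
  ess <- vapply(par_names, function(pn) {
    ess_basic(sapply(draw_mats, function(d) d[, pn]))
  }, numeric(1))
  converged <- all(is.finite(rhat)) && max(rhat, na.rm = TRUE) <= 1.1
  if (!converged)
    warning("joint model flagged non-converged: max split R-hat = ",
            round(max(rhat, na.rm = TRUE), 3))

  structure(list(draws = draw_mats,
                 b_draws = lapply(chains, `[[`, "b_draws"),
                 par_names = par_names, rhat = rhat, ess = ess,
                 converged = converged, knots = knots,
                 age_scaler = cohort$age_scaler, config = config,
                 n_patients = pp$n, n_events = sum(pp$event)),
            class = "joint_fit")
}

#' Build a degenerate joint fit at fixed parameters
#'
#' Wraps known `longitudinal_params`/`survival_params` as a `joint_fit`
#' whose posterior is a point mass (every draw identical). Useful for
#' profiling dynamic predictions at known parameter values and for
#' closed-form checks of the prediction machinery.
#'
#' @param long A [longitudinal_params()].
#' @param surv A [survival_params()].
#' @param age_scaler `c(mean, sd)` frozen age standardization.
#' @param n_draws number of (identical) draws to expose.
#' @return A `joint_fit`.
#' @export
as_joint_fit <- function(long, surv, age_scaler, n_draws = 200) {
  K <- length(surv$baseline$knots) + 1L
  sds <- sqrt(diag(long$D))
  R <- stats::cov2cor(long$D)
  row <- c(as.numeric(t(long$beta)), surv$gamma, surv$alpha_value,
           surv$alpha_cumulative, surv$baseline$log_rates,
           sds, R[1, 2], R[1, 3], R[2, 3])
  par_names <- c(
    paste0("beta.", rep(MARKERS, each = 6), ".", rep(FIXEF_NAMES, 3)),
    paste0("gamma.", GAMMA_NAMES),
    paste0("alpha_value.", MARKERS),
    paste0("alpha_cumulative.", MARKERS),
    paste0("log_rate.", seq_len(K)),
    paste0("sd_b.", MARKERS),
    c("cor.lgd.p53", "cor.lgd.sox2", "cor.p53.sox2"))
  draws <- matrix(row, n_draws, length(row), byrow = TRUE,
                  dimnames = list(NULL, par_names))
  structure(list(draws = list(draws), b_draws = list(),
                 par_names = par_names,
                 rhat = stats::setNames(rep(1, length(par_names)), par_names),
                 ess = stats::setNames(rep(n_draws, length(par_names)),
                                       par_names),
                 converged = TRUE, knots = surv$baseline$knots,
                 age_scaler = age_scaler,
                 config = joint_config(chains = 1, iter = n_draws + 1,
                                       burnin = 1),
                 n_patients = 0, n_events = 0),
            class = "joint_fit")
}

## Rowwise log MVN density given chol(D).
mvn_rows_logpdf <- function(b, ch_D) {
  z <- backsolve(ch_D, t(b), transpose = TRUE)
  -0.5 * colSums(z^2) - (sum(log(diag(ch_D))) + 1.5 * log(2 * pi))
}

## Pooled post-burn-in draws as one matrix.
pooled_draws <- function(fit) do.call(rbind, fit$draws)

## Extract longitudinal_params / survival_params for one pooled draw row.
params_from_draw <- function(fit, row) {
  d <- pooled_draws(fit)[row, ]
  beta <- matrix(d[1:18], 3, 6, byrow = TRUE,
                 dimnames = list(MARKERS, FIXEF_NAMES))
  gamma <- d[19:22]
  av <- d[23:25]
  ac <- d[26:28]
  K <- length(fit$knots) + 1L
  log_rates <- d[28 + seq_len(K)]
  sds <- d[28 + K + 1:3]
  rr <- d[28 + K + 4:6]
  list(long = longitudinal_params(beta, make_D(sds, rr)),
       surv = survival_params(baseline_hazard(fit$knots, log_rates),
                              gamma, av, ac))
}

#' Hazard-ratio table from a joint fit
#'
#' Covariate hazard ratios `exp(gamma)` and, per marker, the value and
#' accumulated-effect hazard ratios on the per-10% scale
#' (`exp(0.1 alpha)` applied draw by draw), summarized by the posterior
#' median, 2.5/97.5 percentiles and the two-sided posterior tail
#' probability of the coefficient crossing zero.
#'
#' @param fit A `joint_fit`.
#' @return data.frame with `term`, `hr`, `lower`, `upper`, `tail_prob`.
#' @export
hazard_ratio_table <- function(fit) {
  stopifnot(inherits(fit, "joint_fit"))
  dr <- pooled_draws(fit)
  rows <- list()
  tail_prob <- function(x) 2 * min(mean(x <= 0), mean(x >= 0))
  for (g in GAMMA_NAMES) {
    x <- dr[, paste0("gamma.", g)]
    rows[[g]] <- data.frame(term = g, hr = stats::median(exp(x)),
                            lower = unname(stats::quantile(exp(x), 0.025)),
                            upper = unname(stats::quantile(exp(x), 0.975)),
                            tail_prob = tail_prob(x))
  }
  for (m in MARKERS) for (assoc in c("value", "cumulative")) {
    col <- paste0(if (assoc == "value") "alpha_value." else
      "alpha_cumulative.", m)
    x <- dr[, col]
    hr <- hazard_ratio_per_10pct(x)
    rows[[col]] <- data.frame(
      term = paste0(m, "_", assoc), hr = stats::median(hr),
      lower = unname(stats::quantile(hr, 0.025)),
      upper = unname(stats::quantile(hr, 0.975)),
      tail_prob = tail_prob(x))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.joint_fit <- function(x, ...) {
  cat(sprintf(
    "Multivariate joint model fit: %d patients, %d events, %d chain(s) x %d kept draws\n",
    x$n_patients, x$n_events, length(x$draws), nrow(x$draws[[1]])))
  cat(sprintf("max split R-hat %.3f, min ESS %.0f%s\n",
              max(x$rhat, na.rm = TRUE), min(x$ess, na.rm = TRUE),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("\nHazard ratios (per 10% for marker associations):\n")
  tb <- hazard_ratio_table(x)
  tb[, 2:5] <- round(tb[, 2:5], 3)
  print(tb, row.names = FALSE)
  invisible(x)
}

#' Serialize a joint fit summary to JSON
#'
#' Posterior summaries (median and 95% credible interval per scalar),
#' the per-10% hazard-ratio table, convergence diagnostics, knots, the
#' age scaler and the sampler config.
#'
#' @param fit A `joint_fit`.
#' @param path optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
joint_fit_json <- function(fit, path = NULL) {
  dr <- pooled_draws(fit)
  summ <- lapply(colnames(dr), function(pn) {
    x <- dr[, pn]
    list(median = stats::median(x),
         lower = unname(stats::quantile(x, 0.025)),
         upper = unname(stats::quantile(x, 0.975)),
         rhat = unname(fit$rhat[pn]), ess = unname(fit$ess[pn]))
  })
  names(summ) <- colnames(dr)
  obj <- list(posterior = summ,
              hazard_ratios = hazard_ratio_table(fit),
              converged = fit$converged,
              knots = fit$knots,
              age_scaler = as.list(fit$age_scaler),
              config = unclass(fit$config))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
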