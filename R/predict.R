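## Individualized dynamic prediction: the posterior of a new patient's
## random intercepts given their marker history and survival so far, and
## the window risk P(T <= t + dt | T > t, history) averaged over the
## parameter posterior.

#' Assemble a patient history for prediction
#'
#' Baseline covariates plus the visits observed up to a landmark; no
#' outcome information. Visit fields and marker dialects are those of
#' the cohort tables (see [new_cohort()]); covariates missing at
#' follow-up visits are carried forward.
#'
#' @param age_years baseline age.
#' @param female 0/1.
#' @param visits data.frame with `time_years`, `lgd`, `p53`, `sox2`,
#'   `esophagitis`, `long_segment`; must start at t = 0 with
#'   non-missing covariates.
#' @return An object of class `patient_history`.
#' @export
patient_history <- function(age_years, female, visits) {
  stopifnot(age_years > 18, age_years < 110, female %in% c(0, 1))
  visits <- as.data.frame(visits)
  need <- c("time_years", MARKERS, "esophagitis", "long_segment")
  miss <- setdiff(need, names(visits))
  if (length(miss)) stop("history visits missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  visits <- visits[order(visits$time_years), , drop = FALSE]
  if (nrow(visits) == 0 || visits$time_years[1] != 0)
    stop("history must include the index visit at t = 0", call. = FALSE)
  if (any(duplicated(visits$time_years)))
    stop("duplicate visit times in history", call. = FALSE)
  for (m in MARKERS) visits[[m]] <- normalize_marker(visits[[m]], m)
  for (cv in c("esophagitis", "long_segment")) {
    v <- visits[[cv]]
    if (is.na(v[1])) stop(cv, " missing at index visit", call. = FALSE)
    for (j in seq_along(v)[-1]) if (is.na(v[j])) v[j] <- v[j - 1]
    visits[[cv]] <- v
  }
  structure(list(age_years = age_years, female = female, visits = visits),
            class = "patient_history")
}

## History pieces/design under one parameter draw's knots, spanning
## [0, t_max]; visits truncated to the landmark are the caller's job.
history_geometry <- function(history, knots, t_max) {
  v <- history$visits
  pieces <- build_pieces(v$time_years, v$esophagitis, v$long_segment,
                         knots, t_max)
  Xh <- cbind(1, v$time_years, NA, history$female,
              v$long_segment, v$esophagitis)  # age_std filled per fit
  list(pieces = pieces, Xh = Xh, Y = as.matrix(v[MARKERS]))
}

## Factory for the unnormalized log posterior of b under one draw's
## parameters: Bernoulli terms for the observed markers, the
## survival-to-landmark term (when the landmark exceeds the entry time),
## and the N(0, D) prior. Everything b-independent is precomputed.
make_b_logpost <- function(geom, long, surv, entry, survive_to,
                           age_std, female, ch_D) {
  eta0 <- geom$Xh %*% t(long$beta)
  obs <- !is.na(geom$Y)
  Yv <- geom$Y; Yv[!obs] <- 0
  Hf <- if (survive_to > entry)
    make_H_fun(geom$pieces, long$beta, surv, age_std, female,
               entry, survive_to) else function(b) 0
  nh <- nrow(eta0)
  function(b) {
    eta <- eta0 + matrix(b, nh, 3, byrow = TRUE)
    contrib <- (Yv * eta - softplus(eta)) * obs
    z <- backsolve(ch_D, b, transpose = TRUE)
    sum(contrib) - Hf(b) - 0.5 * sum(z^2) - sum(log(diag(ch_D)))
  }
}

#' Sample a new patient's random intercepts given their history
#'
#' For each (thinned) posterior parameter draw, runs a short Metropolis
#' chain targeting `p(b | history, T > t, theta)`: Bernoulli terms for
#' the observed markers, the survival-to-landmark term, and the
#' `N(0, D)` prior. With an empty history and `t = 0` this reduces to
#' the prior and draws are taken from it directly.
#'
#' @param history A [patient_history()] (visits at or before `landmark_t`).
#' @param fit A `joint_fit`.
#' @param landmark_t landmark time in years.
#' @param n_outer number of posterior parameter draws to use (thinned
#'   evenly from the pooled chains).
#' @param n_inner Metropolis iterations per outer draw (default 200,
#'   first `inner_burn` discarded).
#' @param inner_burn burn-in of the inner chain (default 50).
#' @param n_b retained b samples per outer draw (default 5, evenly
#'   spaced over the post-burn-in inner chain).
#' @param seed integer seed.
#' @param entry left-truncation time of the fitted model (default 0.5).
#' @return `list(b = (n_outer * n_b) x 3 matrix, draw_index, geometry)`.
#' @export
posterior_b_given_history <- function(history, fit, landmark_t,
                                      n_outer = 100, n_inner = 200,
                                      inner_burn = 50, n_b = 5,
                                      seed = 1, entry = 0.5) {
  stopifnot(inherits(history, "patient_history"),
            inherits(fit, "joint_fit"))
  v <- history$visits
  if (any(v$time_years > landmark_t + 1e-9))
    stop("history contains visits after the landmark", call. = FALSE)
  set.seed(as.integer(seed))
  dr <- pooled_draws(fit)
  rows <- unique(round(seq(1, nrow(dr), length.out = n_outer)))
  age_std <- scaled_age(history$age_years, fit$age_scaler)
  geom <- history_geometry(history, fit$knots,
                           t_max = max(landmark_t, 1e-6))
  geom$Xh[, 3] <- age_std
  obs_any <- any(!is.na(geom$Y))

  keep_at <- unique(round(seq(inner_burn + 1, n_inner, length.out = n_b)))
  out_b <- matrix(NA_real_, length(rows) * length(keep_at), 3)
  draw_index <- integer(nrow(out_b))
  bcur <- c(0, 0, 0)
  pos <- 0
  for (j in seq_along(rows)) {
    pars <- params_from_draw(fit, rows[j])
    D <- pars$long$D
    ch_D <- chol(D)
    if (!obs_any && landmark_t <= entry) {
      # prior draws
      z <- matrix(stats::rnorm(3 * length(keep_at)), length(keep_at), 3)
      bs <- z %*% ch_D
      idx <- pos + seq_len(length(keep_at))
      out_b[idx, ] <- bs
      draw_index[idx] <- rows[j]
      pos <- pos + length(keep_at)
      next
    }
    step <- 0.7 * sqrt(diag(D))
    logpost <- make_b_logpost(geom, pars$long, pars$surv, entry,
                              landmark_t, age_std, history$female, ch_D)
    lp <- logpost(bcur)
    for (it in seq_len(n_inner)) {
      bprop <- bcur + stats::rnorm(3) * step
      lp2 <- logpost(bprop)
      if (is.finite(lp2) && log(stats::runif(1)) < lp2 - lp) {
        bcur <- bprop; lp <- lp2
      }
      if (it %in% keep_at) {
        pos <- pos + 1
        out_b[pos, ] <- bcur
        draw_index[pos] <- rows[j]
      }
    }
  }
  list(b = out_b[seq_len(pos), , drop = FALSE],
       draw_index = draw_index[seq_len(pos)], geometry = geom)
}

#' Dynamic window risk for a patient history
#'
#' Posterior predictive probability of progression inside
#' `(t, t + horizon]` given survival to the landmark `t` and the marker
#' history observed so far: per (parameter draw, intercept sample) the
#' conditional risk is `1 - exp(-H(t, t + horizon))` with covariates
#' carried forward from the last visit; the point risk is the mean and
#' the interval the 2.5/97.5 percentiles over samples.
#'
#' @inheritParams posterior_b_given_history
#' @param horizon prediction window in years (default 3, must be > 0).
#' @return An object of class `dynamic_prediction`:
#'   `list(landmark_t, horizon, risk, ci95, n_draws)`.
#' @export
dynamic_risk <- function(history, fit, landmark_t, horizon = 3,
                         n_outer = 100, n_inner = 200, inner_burn = 50,
                         n_b = 5, seed = 1, entry = 0.5) {
  if (horizon <= 0) stop("horizon must be positive", call. = FALSE)
  bs <- posterior_b_given_history(history, fit, landmark_t,
                                  n_outer = n_outer, n_inner = n_inner,
                                  inner_burn = inner_burn, n_b = n_b,
                                  seed = seed, entry = entry)
  age_std <- scaled_age(history$age_years, fit$age_scaler)
  v <- history$visits
  geomF <- history_geometry(history, fit$knots, t_max = landmark_t + horizon)
  risks <- numeric(nrow(bs$b))
  Hf <- NULL; last_row <- -1L
  for (j in seq_len(nrow(bs$b))) {
    if (bs$draw_index[j] != last_row) {
      pars <- params_from_draw(fit, bs$draw_index[j])
      Hf <- make_H_fun(geomF$pieces, pars$long$beta, pars$surv,
                       age_std, history$female,
                       landmark_t, landmark_t + horizon, nodes = 15)
      last_row <- bs$draw_index[j]
    }
    risks[j] <- -expm1(-Hf(bs$b[j, ]))
  }
  ci <- unname(stats::quantile(risks, c(0.025, 0.975)))
  structure(list(landmark_t = landmark_t, horizon = horizon,
                 risk = mean(risks), ci95 = ci, n_draws = length(risks),
                 draws = risks),
            class = "dynamic_prediction")
}

#' @export
print.dynamic_prediction <- function(x, ...) {
  cat(sprintf(
    "window risk at landmark %.2f y (+%g y): %.4f (95%% CI %.4f-%.4f; %d samples)\n",
    x$landmark_t, x$horizon, x$risk, x$ci95[1], x$ci95[2], x$n_draws))
  invisible(x)
}

#' Risk trajectory over successive landmarks
#'
#' One [dynamic_risk()] per landmark, each conditioned only on the
#' history available at that landmark (visits after it are dropped), as
#' plotted in surveillance risk-trajectory figures.
#'
#' @inheritParams dynamic_risk
#' @param landmarks increasing landmark times (years).
#' @return data.frame with `landmark`, `horizon`, `risk`, `lower`,
#'   `upper`, `n_draws`.
#' @export
risk_trajectory <- function(history, fit, landmarks, horizon = 3,
                            n_outer = 100, n_inner = 200, inner_burn = 50,
                            n_b = 5, seed = 1, entry = 0.5) {
  if (any(diff(landmarks) <= 0))
    stop("landmarks must be increasing", call. = FALSE)
  rows <- lapply(seq_along(landmarks), function(i) {
    t_i <- landmarks[i]
    vis_i <- history$visits[history$visits$time_years <= t_i + 1e-9, ,
                            drop = FALSE]
    h_i <- patient_history(history$age_years, history$female, vis_i)
    p <- dynamic_risk(h_i, fit, t_i, horizon = horizon, n_outer = n_outer,
                      n_inner = n_inner, inner_burn = inner_burn,
                      n_b = n_b, seed = seed + i, entry = entry)
    data.frame(landmark = t_i, horizon = horizon, risk = p$risk,
               lower = p$ci95[1], upper = p$ci95[2], n_draws = p$n_draws)
  })
  do.call(rbind, rows)
}
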