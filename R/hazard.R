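## Hazard of neoplastic progression: generic functional interface
## (arbitrary per-marker probability trajectories, used in tests and for
## event-time sampling oracles) plus a fast path specialized to the
## model's piecewise-affine linear predictors, used by the MCMC sampler,
## the simulator and dynamic prediction.

#' Hazard at a single time point
#'
#' Evaluates
#' `h(t) = exp(log lambda(t) + gamma . w + sum_k [alpha_value_k pi_k(t)
#'  + alpha_cumulative_k * CumPi_k])` for one patient.
#'
#' @param t time in years (scalar, within baseline support).
#' @param params A [survival_params()].
#' @param pi list of 3 functions of time giving each marker's probability
#'   of aberrant expression (order lgd, p53, sox2).
#' @param running_integrals length-3 numeric: accumulated probability
#'   `int_0^t pi_k(s) ds` per marker (computed by the caller, e.g. via
#'   [cumulative_marker_probability()]).
#' @param w length-4 covariates at t `(age_std, female, long_segment,
#'   esophagitis)`.
#' @return Nonnegative scalar hazard.
#' @export
hazard_at <- function(t, params, pi, running_integrals, w) {
  stopifnot(inherits(params, "survival_params"), length(t) == 1L)
  pis <- vapply(pi, function(f) f(t), numeric(1))
  exp(log_rate_at(params$baseline, t) +
        sum(params$gamma * rep_len(w, 4)) +
        sum(params$alpha_value * pis) +
        sum(params$alpha_cumulative * rep_len(running_integrals, 3)))
}

#' Accumulated marker probability
#'
#' `int_0^t pi(s) ds` by Gauss-Legendre quadrature, split at the supplied
#' break times (covariate step changes), 30 nodes per piece.
#'
#' @param pi_fun function of time returning a probability.
#' @param t upper limit (years).
#' @param breaks optional interior break times where `pi_fun` may jump.
#' @return Nonnegative scalar.
#' @export
cumulative_marker_probability <- function(pi_fun, t, breaks = NULL) {
  if (t <= 0) return(0)
  bks <- sort(unique(c(0, breaks[breaks > 0 & breaks < t], t)))
  gl <- gauss_legendre(30)
  total <- 0
  for (j in seq_len(length(bks) - 1L)) {
    a <- bks[j]; b <- bks[j + 1L]
    s <- (a + b) / 2 + (b - a) / 2 * gl$nodes
    total <- total + (b - a) / 2 * sum(gl$weights * vapply(s, pi_fun, numeric(1)))
  }
  total
}

#' Cumulative hazard over an interval
#'
#' Integrates [hazard_at()] over `[t0, t1]` by Gauss-Legendre quadrature
#' with `nodes` nodes per baseline-hazard segment (further split at the
#' supplied covariate break times, where the integrand may jump).
#'
#' @param t0,t1 interval limits, `t0 < t1`, within baseline support.
#' @param params A [survival_params()].
#' @param pi list of 3 per-marker probability functions of time.
#' @param covariates function of time returning the length-4 covariate
#'   vector `(age_std, female, long_segment, esophagitis)`.
#' @param running_integral_funs optional list of 3 functions of time
#'   giving `int_0^t pi_k`; when `NULL` they are computed by nested
#'   quadrature via [cumulative_marker_probability()].
#' @param breaks optional interior times where covariates or `pi` jump.
#' @param nodes Gauss-Legendre nodes per segment (default 15).
#' @return Nonnegative scalar cumulative hazard.
#' @export
cumulative_hazard <- function(t0, t1, params, pi, covariates,
                              running_integral_funs = NULL,
                              breaks = NULL, nodes = 15) {
  stopifnot(inherits(params, "survival_params"))
  if (t0 >= t1) stop("need t0 < t1", call. = FALSE)
  if (t0 < 0) stop("time outside baseline-hazard support", call. = FALSE)
  kn <- params$baseline$knots
  bks <- sort(unique(c(t0, t1,
                       kn[kn > t0 & kn < t1],
                       breaks[breaks > t0 & breaks < t1])))
  gl <- gauss_legendre(nodes)
  if (is.null(running_integral_funs)) {
    running_integral_funs <- lapply(pi, function(f) {
      function(t) cumulative_marker_probability(f, t, breaks = breaks)
    })
  }
  H <- 0
  for (j in seq_len(length(bks) - 1L)) {
    a <- bks[j]; b <- bks[j + 1L]
    s <- (a + b) / 2 + (b - a) / 2 * gl$nodes
    hs <- vapply(s, function(tt) {
      ri <- vapply(running_integral_funs, function(f) f(tt), numeric(1))
      hazard_at(tt, params, pi, ri, covariates(tt))
    }, numeric(1))
    H <- H + (b - a) / 2 * sum(gl$weights * hs)
  }
  H
}

## ---------------------------------------------------------------------
## Fast path: piecewise-affine linear predictors.
##
## Within a piece (no covariate change, no baseline knot) each marker's
## linear predictor is eta_k(s) = a_k + c_k * s, so int expit is closed
## form (integral_expit_affine) and the hazard is smooth; 15-node
## Gauss-Legendre per piece then integrates it essentially exactly.

## Build the piece table for one patient: breaks at covariate-change
## times (visit times where esophagitis/long_segment can step) and
## baseline knots, covering [0, t_max].
build_pieces <- function(visit_times, eso, long, knots, t_max) {
  keep <- visit_times < t_max
  vt <- visit_times[keep]
  bks <- sort(unique(c(0, vt, knots[knots > 0 & knots < t_max], t_max)))
  starts <- bks[-length(bks)]
  ends <- bks[-1]
  idx <- findInterval(starts, vt)  # covariates carried forward
  idx[idx == 0] <- 1L
  data.frame(start = starts, end = ends,
             eso = eso[keep][idx], long = long[keep][idx],
             lam_idx = findInterval(starts, knots) + 1L)
}

## Per-marker affine coefficients on each piece for one patient.
## beta: 3x6; b: length 3. Returns list(a = n_piece x 3, c = length 3).
affine_eta <- function(pieces, beta, b, age_std, female) {
  Xp <- cbind(1, 0, age_std, female, pieces$long, pieces$eso)
  a <- Xp %*% t(beta) + matrix(b, nrow(pieces), 3, byrow = TRUE)
  list(a = a, c = beta[, 2])
}

## Cumulative int_0^t pi_k at the start of every piece (n_piece x 3).
cum_pi_starts <- function(pieces, eta) {
  dI <- vapply(1:3, function(k)
    integral_expit_affine(eta$a[, k], eta$c[k], pieces$start, pieces$end),
    numeric(nrow(pieces)))
  dI <- matrix(dI, nrow = nrow(pieces))
  apply(dI, 2, function(x) cumsum(c(0, x[-length(x)])))
}

## Cumulative hazard over [t0, t1] for one patient via the affine fast
## path. pieces must span [0, >= t1]. Returns scalar.
ch_affine <- function(t0, t1, surv, pieces, eta, age_std, female,
                      nodes = 15, Istart = NULL) {
  if (t1 <= t0) return(0)
  if (is.null(Istart)) Istart <- cum_pi_starts(pieces, eta)
  Istart <- matrix(Istart, nrow(pieces))
  gl <- gauss_legendre(nodes)
  sel <- which(pieces$end > t0 & pieces$start < t1)
  H <- 0
  for (p in sel) {
    a <- max(pieces$start[p], t0); b <- min(pieces$end[p], t1)
    s <- (a + b) / 2 + (b - a) / 2 * gl$nodes
    eta_s <- outer(s, eta$c) +
      matrix(eta$a[p, ], length(s), 3, byrow = TRUE)
    pis <- expit(eta_s)
    dim(pis) <- dim(eta_s)
    I_s <- matrix(Istart[p, ], length(s), 3, byrow = TRUE) +
      vapply(1:3, function(k)
        integral_expit_affine(eta$a[p, k], eta$c[k], pieces$start[p], s),
        numeric(length(s)))
    loghaz <- surv$baseline$log_rates[pieces$lam_idx[p]] +
      surv$gamma[[1]] * age_std + surv$gamma[[2]] * female +
      surv$gamma[[3]] * pieces$long[p] +
      surv$gamma[[4]] * pieces$eso[p] +
      pis %*% surv$alpha_value + I_s %*% surv$alpha_cumulative
    H <- H + (b - a) / 2 * sum(gl$weights * exp(loghaz))
  }
  H
}

## Build a fast evaluator of H(t0, t1) as a function of one patient's
## random-intercept vector b, with everything b-independent precomputed.
## Used by the inner Metropolis of dynamic prediction, where H must be
## re-evaluated thousands of times per patient. pieces span [0, >= t1];
## the accumulated-effect integral always runs from 0.
make_H_fun <- function(pieces, beta, surv, age_std, female,
                       t0, t1, nodes = 7) {
  if (t1 <= t0) return(function(b) 0)
  np <- nrow(pieces)
  A0 <- cbind(1, 0, age_std, female, pieces$long, pieces$eso) %*% t(beta)
  cc <- beta[, 2]
  s0 <- pieces$start; e0 <- pieces$end
  gl <- gauss_legendre(nodes)
  sel <- which(e0 > t0 & s0 < t1)
  a <- pmax(s0[sel], t0); bb <- pmin(e0[sel], t1)
  half <- (bb - a) / 2
  s_q <- as.numeric(t(outer((bb + a) / 2, rep(1, nodes)) +
                        outer(half, gl$nodes)))
  w_q <- as.numeric(t(outer(half, gl$weights)))
  qp <- rep(sel, each = nodes)
  g_q <- w_q * exp(surv$baseline$log_rates[pieces$lam_idx[qp]] +
                     surv$gamma[[1]] * age_std + surv$gamma[[2]] * female +
                     surv$gamma[[3]] * pieces$long[qp] +
                     surv$gamma[[4]] * pieces$eso[qp])
  A0q <- A0[qp, , drop = FALSE]
  Cs0 <- outer(s0, cc); Ce0 <- outer(e0, cc)
  Csq <- outer(s_q, cc); Cs0q <- Cs0[qp, , drop = FALSE]
  av <- surv$alpha_value; ac <- surv$alpha_cumulative
  use_cum <- any(ac != 0)
  small_c <- abs(cc) < 1e-10
  function(b) {
    bm <- matrix(b, np, 3, byrow = TRUE)
    Eq <- A0q + matrix(b, length(s_q), 3, byrow = TRUE) + Csq
    z <- expit(Eq) %*% av
    if (use_cum) {
      AB <- A0 + bm
      Fs <- softplus(AB + Cs0)
      dI <- (softplus(AB + Ce0) - Fs)
      for (k in which(!small_c)) dI[, k] <- dI[, k] / cc[k]
      for (k in which(small_c))
        dI[, k] <- expit(AB[, k] + (Cs0[, k] + Ce0[, k]) / 2) * (e0 - s0)
      Ist <- matrix(apply(dI, 2, function(x) cumsum(c(0, x[-np]))), np, 3)
      dIq <- softplus(Eq) - Fs[qp, , drop = FALSE]
      for (k in which(!small_c)) dIq[, k] <- dIq[, k] / cc[k]
      for (k in which(small_c))
        dIq[, k] <- expit((A0q[, k] + matrix(b[k], length(s_q), 1)) +
                            (Cs0q[, k] + Csq[, k]) / 2) * (s_q - s0[qp])
      z <- z + (Ist[qp, , drop = FALSE] + dIq) %*% ac
    }
    sum(g_q * exp(z))
  }
}

## log hazard at time t for one patient (affine path).
loghaz_affine <- function(t, surv, pieces, eta, age_std, female,
                          Istart = NULL) {
  if (is.null(Istart)) Istart <- cum_pi_starts(pieces, eta)
  Istart <- matrix(Istart, nrow(pieces))
  p <- findInterval(t, pieces$start, rightmost.closed = FALSE)
  p <- min(max(p, 1L), nrow(pieces))
  eta_t <- eta$a[p, ] + eta$c * t
  pis <- expit(eta_t)
  I_t <- Istart[p, ] + vapply(1:3, function(k)
    integral_expit_affine(eta$a[p, k], eta$c[k], pieces$start[p], t),
    numeric(1))
  surv$baseline$log_rates[pieces$lam_idx[p]] +
    surv$gamma[[1]] * age_std + surv$gamma[[2]] * female +
    surv$gamma[[3]] * pieces$long[p] +
    surv$gamma[[4]] * pieces$eso[p] +
    sum(surv$alpha_value * pis) + sum(surv$alpha_cumulative * I_t)
}
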