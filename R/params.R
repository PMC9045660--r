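## Parameter containers for the longitudinal submodels and the joint
## survival model.

## Fixed-effect design order shared by every marker submodel.
FIXEF_NAMES <- c("intercept", "time", "age_std", "female",
                 "long_segment", "esophagitis")
GAMMA_NAMES <- c("age_std", "female", "long_segment", "esophagitis")

#' Longitudinal submodel parameters
#'
#' Fixed effects for the three random-intercept logistic submodels
#' (one per marker: LGD, p53, SOX2) and the 3x3 covariance of the
#' random intercepts. Each marker's linear predictor is
#' `beta . (1, t, age_std, female, long_segment, esophagitis) + b_k`.
#'
#' @param beta 3x6 numeric matrix, rows `lgd`, `p53`, `sox2`, columns
#'   `intercept`, `time`, `age_std`, `female`, `long_segment`,
#'   `esophagitis`.
#' @param D 3x3 symmetric positive-definite covariance of the random
#'   intercepts `(b_lgd, b_p53, b_sox2)`.
#' @return An object of class `longitudinal_params`.
#' @export
longitudinal_params <- function(beta, D) {
  beta <- as.matrix(beta)
  if (!all(dim(beta) == c(3, 6)))
    stop("beta must be 3x6 (marker x fixed effect)", call. = FALSE)
  dimnames(beta) <- list(MARKERS, FIXEF_NAMES)
  D <- as.matrix(D)
  if (!all(dim(D) == c(3, 3)) || max(abs(D - t(D))) > 1e-8)
    stop("D must be symmetric 3x3", call. = FALSE)
  if (any(eigen(D, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("D must be positive definite", call. = FALSE)
  dimnames(D) <- list(MARKERS, MARKERS)
  structure(list(beta = beta, D = D), class = "longitudinal_params")
}

#' Piecewise-constant baseline hazard
#'
#' Interior knots partition follow-up time into `K = length(knots) + 1`
#' intervals with constant rate `exp(log_rates[k])` on each. The first
#' interval starts at time 0 (the index endoscopy); inference only ever
#' integrates the hazard from the 0.5-year entry time, while the
#' simulator uses the full support to draw event times before the
#' run-in exclusion is applied.
#'
#' @param knots strictly increasing positive interior knot times (years);
#'   may be empty for a constant hazard.
#' @param log_rates numeric, `length(knots) + 1` log hazard rates.
#' @return An object of class `baseline_hazard`.
#' @export
baseline_hazard <- function(knots, log_rates) {
  knots <- as.numeric(knots)
  if (length(knots) && (any(diff(knots) <= 0) || any(knots <= 0)))
    stop("knots must be strictly increasing and positive", call. = FALSE)
  if (length(log_rates) != length(knots) + 1L)
    stop("need length(knots) + 1 log rates", call. = FALSE)
  structure(list(knots = knots, log_rates = as.numeric(log_rates)),
            class = "baseline_hazard")
}

## log baseline rate at each time point (vectorized).
log_rate_at <- function(bh, t) {
  if (any(t < 0)) stop("time outside baseline-hazard support", call. = FALSE)
  bh$log_rates[findInterval(t, bh$knots) + 1L]
}

#' Joint survival submodel parameters
#'
#' The hazard for patient i is
#' `h_i(t) = exp(log lambda(t) + gamma . w_i(t)
#'              + sum_k alpha_value_k  * pi_ik(t)
#'              + sum_k alpha_cumulative_k * int_0^t pi_ik(s) ds)`,
#' where `pi_ik(t)` is the model probability of an aberrant marker k at
#' time t and `w_i(t) = (age_std, female, long_segment(t), esophagitis(t))`.
#' `alpha_value` is per unit probability (so `exp(0.1 * alpha)` is the
#' hazard ratio for a 10% change); `alpha_cumulative` is per
#' probability-year.
#'
#' @param baseline A [baseline_hazard()].
#' @param gamma length-4 covariate coefficients
#'   `(age_std, female, long_segment, esophagitis)`.
#' @param alpha_value,alpha_cumulative length-3 per-marker association
#'   coefficients (order lgd, p53, sox2).
#' @return An object of class `survival_params`.
#' @export
survival_params <- function(baseline, gamma = rep(0, 4),
                            alpha_value = rep(0, 3),
                            alpha_cumulative = rep(0, 3)) {
  stopifnot(inherits(baseline, "baseline_hazard"))
  gamma <- stats::setNames(rep_len(as.numeric(gamma), 4), GAMMA_NAMES)
  alpha_value <- stats::setNames(rep_len(as.numeric(alpha_value), 3), MARKERS)
  alpha_cumulative <- stats::setNames(rep_len(as.numeric(alpha_cumulative), 3),
                                      MARKERS)
  if (!all(is.finite(c(baseline$log_rates, gamma, alpha_value,
                       alpha_cumulative))))
    stop("survival parameters must be finite", call. = FALSE)
  structure(list(baseline = baseline, gamma = gamma,
                 alpha_value = alpha_value,
                 alpha_cumulative = alpha_cumulative),
            class = "survival_params")
}
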