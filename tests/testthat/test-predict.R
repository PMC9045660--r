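# Dynamic prediction: prior limits, posterior-b oracles, closed-form
# window risks, trajectories and leakage.

fixed_fit <- function(lam = 0.12, alpha_value = c(0, 0, 0),
                      alpha_cumulative = c(0, 0, 0), gamma = rep(0, 4),
                      beta = NULL, D = diag(3), n_draws = 150) {
  if (is.null(beta)) beta <- matrix(0, 3, 6)
  as_joint_fit(longitudinal_params(beta, D),
               survival_params(baseline_hazard(numeric(0), log(lam)),
                               gamma, alpha_value, alpha_cumulative),
               age_scaler = c(60, 10), n_draws = n_draws)
}

empty_history <- function(markers = c(NA, NA, NA)) {
  patient_history(60, 0, data.frame(
    time_years = 0, lgd = markers[1], p53 = markers[2], sox2 = markers[3],
    esophagitis = 0, long_segment = 0))
}

test_that("with no observations at t = 0 the intercepts come from the prior", {
  D <- diag(c(1.2, 0.8, 1.5)^2)
  D[1, 2] <- D[2, 1] <- 0.5 * 1.2 * 0.8
  fit <- fixed_fit(D = D, n_draws = 100)
  bs <- posterior_b_given_history(empty_history(), fit, landmark_t = 0,
                                  n_outer = 400, n_b = 10, seed = 2)
  n <- nrow(bs$b)
  se_mean <- sqrt(diag(D) / n)
  expect_true(all(abs(colMeans(bs$b)) < 3 * se_mean))
  # covariance recovered within ~3 MC SE (normal theory approximation)
  se_var <- sqrt(2 / (n - 1)) * diag(D)
  expect_true(all(abs(diag(cov(bs$b)) - diag(D)) < 3 * se_var))
  expect_equal(cov(bs$b)[1, 2], D[1, 2], tolerance = 0.15)
})

test_that("aberrant histories pull the marker intercept upward", {
  beta <- matrix(0, 3, 6); beta[, 1] <- -1
  fit <- fixed_fit(beta = beta, n_draws = 60)
  mk_hist <- function(val) patient_history(60, 0, data.frame(
    time_years = 0:4, lgd = NA, p53 = val, sox2 = NA,
    esophagitis = 0, long_segment = 0))
  b_ab <- posterior_b_given_history(mk_hist(1), fit, landmark_t = 4,
                                    n_outer = 60, n_b = 5, seed = 3)
  b_no <- posterior_b_given_history(mk_hist(0), fit, landmark_t = 4,
                                    n_outer = 60, n_b = 5, seed = 3)
  expect_gt(mean(b_ab$b[, 2]), mean(b_no$b[, 2]))
})

test_that("single-observation posterior mean matches grid integration", {
  beta <- matrix(0, 3, 6); beta[1, 1] <- -0.4
  sigma <- 1.3
  fit <- fixed_fit(beta = beta, D = diag(c(sigma^2, 1, 1)), lam = 1e-8)
  h <- empty_history(markers = c(1, NA, NA))  # one aberrant LGD at t = 0
  bs <- posterior_b_given_history(h, fit, landmark_t = 0.25,
                                  n_outer = 600, n_inner = 250,
                                  inner_burn = 50, n_b = 8, seed = 9)
  # oracle: 2001-point grid over b1; p(b1|y=1) prop plogis(-0.4+b1) phi(b1/sigma)
  g <- seq(-8 * sigma, 8 * sigma, length.out = 2001)
  w <- plogis(-0.4 + g) * dnorm(g, 0, sigma)
  mu_oracle <- sum(g * w) / sum(w)
  expect_equal(mean(bs$b[, 1]), mu_oracle, tolerance = 0.02)
})

test_that("window risk matches the exponential closed form and continuity at 0", {
  lam <- 0.2
  fit <- fixed_fit(lam = lam, n_draws = 80)
  h <- empty_history()
  p3 <- dynamic_risk(h, fit, landmark_t = 1, horizon = 3, n_outer = 40,
                     n_b = 2, seed = 4)
  expect_equal(p3$risk, 1 - exp(-lam * 3), tolerance = 1e-6)
  expect_true(p3$ci95[1] <= p3$risk && p3$risk <= p3$ci95[2])
  p0 <- dynamic_risk(h, fit, landmark_t = 1, horizon = 1e-6, n_outer = 20,
                     n_b = 2, seed = 4)
  expect_lt(p0$risk, 1e-4)
  expect_error(dynamic_risk(h, fit, landmark_t = 1, horizon = 0), "positive")
  # risk nondecreasing in the horizon
  rs <- sapply(c(0.5, 1, 2, 4), function(hh)
    dynamic_risk(h, fit, landmark_t = 1, horizon = hh, n_outer = 20,
                 n_b = 2, seed = 5)$risk)
  expect_true(all(diff(rs) > 0))
})

test_that("trajectories are deterministic and respond to new aberrant data", {
  lam <- 0.1
  fit <- fixed_fit(lam = lam, n_draws = 60)
  h <- patient_history(60, 0, data.frame(
    time_years = c(0, 1, 2), lgd = c(0, NA, NA), p53 = c(0, NA, NA),
    sox2 = c(0, NA, NA), esophagitis = 0, long_segment = 0))
  tr1 <- risk_trajectory(h, fit, landmarks = c(1, 2, 3), horizon = 3,
                         n_outer = 25, n_b = 2, seed = 11)
  tr2 <- risk_trajectory(h, fit, landmarks = c(1, 2, 3), horizon = 3,
                         n_outer = 25, n_b = 2, seed = 11)
  expect_identical(tr1, tr2)
  # alpha = 0 and constant hazard: no information accrual across landmarks
  expect_equal(tr1$risk, rep(1 - exp(-lam * 3), 3), tolerance = 1e-9)

  # a positive value association and a new aberrant p53 raises the risk
  beta <- matrix(0, 3, 6); beta[, 1] <- -1
  fit2 <- fixed_fit(beta = beta, alpha_value = c(0, 2.5, 0), n_draws = 60)
  h_ab <- patient_history(60, 0, data.frame(
    time_years = c(0, 2), lgd = c(0, NA), p53 = c(0, 1), sox2 = c(0, NA),
    esophagitis = 0, long_segment = 0))
  h_no <- patient_history(60, 0, data.frame(
    time_years = c(0, 2), lgd = c(0, NA), p53 = c(0, NA), sox2 = c(0, NA),
    esophagitis = 0, long_segment = 0))
  r_ab <- dynamic_risk(h_ab, fit2, landmark_t = 2, horizon = 3,
                       n_outer = 40, n_b = 4, seed = 6)
  r_no <- dynamic_risk(h_no, fit2, landmark_t = 2, horizon = 3,
                       n_outer = 40, n_b = 4, seed = 6)
  expect_gt(r_ab$risk, r_no$risk)
})

test_that("training patients score finite leakage-free risks in [0,1]", {
  res <- make_analysis_cohort(n = 40, seed = 23)
  co <- res$cohort
  fit <- as_joint_fit(res$truth$longitudinal, res$truth$survival,
                      age_scaler = co$age_scaler, n_draws = 40)
  scores <- joint_risk_scores(fit, co, landmark = 1, horizon = 3,
                              n_outer = 10, n_inner = 40, inner_burn = 20,
                              n_b = 2, seed = 3)
  expect_true(all(is.finite(scores)))
  expect_true(all(scores >= 0 & scores <= 1))
  expect_equal(sort(names(scores)),
               sort(co$outcomes$patient_id[co$outcomes$event_time_years > 1]))
})
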