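# Hazard and joint-likelihood machinery: closed forms, quadrature
# accuracy against dense oracles, and the missing-data contract.

pi_const <- function(p) function(t) p
covar0 <- function(t) c(0, 0, 0, 0)

test_that("hazard_at reduces to its closed forms", {
  lam <- 0.2
  sp0 <- survival_params(baseline_hazard(numeric(0), log(lam)))
  pis <- lapply(1:3, function(k) pi_const(0.5))
  expect_equal(hazard_at(1.7, sp0, pis, c(0, 0, 0), c(1, 0, 1, 0)), lam)
  # saturation: alpha_value with pi == 1
  a <- 0.8
  sp1 <- survival_params(baseline_hazard(numeric(0), log(lam)),
                         alpha_value = c(a, 0, 0))
  expect_equal(hazard_at(2.2, sp1, lapply(1:3, function(k) pi_const(1)),
                         c(0, 0, 0), rep(0, 4)),
               lam * exp(a))
  # accumulated effect with constant pi: hazard = lam * exp(c p t)
  cc <- 0.6; p <- 0.3; t <- 4
  sp2 <- survival_params(baseline_hazard(numeric(0), log(lam)),
                         alpha_cumulative = c(cc, 0, 0))
  expect_equal(hazard_at(t, sp2, lapply(1:3, function(k) pi_const(p)),
                         c(p * t, 0, 0), rep(0, 4)),
               lam * exp(cc * p * t))
  expect_error(hazard_at(-1, sp0, pis, c(0, 0, 0), rep(0, 4)), "support")
})

test_that("cumulative hazard matches closed forms and a dense trapezoid oracle", {
  lam <- 0.45
  sp0 <- survival_params(baseline_hazard(numeric(0), log(lam)))
  pis0 <- lapply(1:3, function(k) pi_const(0))
  H <- cumulative_hazard(0.5, 3.5, sp0, pis0, covar0)
  expect_equal(H, 3 * lam, tolerance = 1e-10)

  # Weibull-like: alpha_cumulative with constant pi
  cc <- 0.5; p <- 0.4
  sp2 <- survival_params(baseline_hazard(numeric(0), log(lam)),
                         alpha_cumulative = c(cc, 0, 0))
  pis_p <- lapply(1:3, function(k) pi_const(p))
  H2 <- cumulative_hazard(0.5, 4, sp2, pis_p, covar0,
                          running_integral_funs =
                            lapply(1:3, function(k) function(t)
                              if (k == 1) p * t else 0))
  H2_closed <- lam * (exp(cc * p * 4) - exp(cc * p * 0.5)) / (cc * p)
  expect_equal(H2, H2_closed, tolerance = 1e-8)

  # arbitrary smooth pi vs a 1e5-point trapezoid oracle
  pif <- function(t) 0.25 + 0.2 * sin(t) * exp(-0.1 * t)
  sp3 <- survival_params(baseline_hazard(c(1.5, 3), log(c(0.1, 0.25, 0.15))),
                         gamma = c(0.2, -0.1, 0.3, 0.1),
                         alpha_value = c(1.2, 0, 0),
                         alpha_cumulative = c(0.4, 0, 0))
  pis3 <- list(pif, pi_const(0), pi_const(0))
  w <- c(0.5, 1, 1, 0)
  H3 <- cumulative_hazard(0.5, 5, sp3, pis3, function(t) w)
  grid <- seq(0, 5, length.out = 100001)
  pig <- pif(grid)
  cumpi <- c(0, cumsum((pig[-1] + pig[-length(grid)]) / 2 * diff(grid)))
  cum_fun <- approxfun(grid, cumpi)
  # integrate segment by segment so the trapezoid never straddles a
  # baseline-rate jump
  segs <- cbind(c(0.5, 1.5, 3), c(1.5, 3, 5), exp(log(c(0.1, 0.25, 0.15))))
  Ho <- 0
  for (i in 1:3) {
    g <- seq(segs[i, 1], segs[i, 2], length.out = 40001)
    hg <- segs[i, 3] * exp(sum(sp3$gamma * w) + 1.2 * pif(g) +
                             0.4 * cum_fun(g))
    Ho <- Ho + sum((hg[-1] + hg[-length(g)]) / 2 * diff(g))
  }
  expect_equal(H3, Ho, tolerance = 1e-6)
})

test_that("the affine fast path agrees with the generic quadrature", {
  beta <- rbind(c(-1, 0.2, 0.3, -0.4, 0.5, -0.2),
                c(-2, 0.15, 0.6, -1.4, 1.0, -0.8),
                c(-1.5, 0.1, 0.25, -0.2, 0.1, -0.3))
  b <- c(0.5, -0.3, 0.2)
  sp <- survival_params(baseline_hazard(c(2, 4), log(c(0.05, 0.12, 0.9))),
                        gamma = c(0.1, -0.2, 0.3, 0.25),
                        alpha_value = c(0.5, 2, 3),
                        alpha_cumulative = c(0.2, 0, 0.15))
  vt <- c(0, 1.2, 2.7, 4.1); eso <- c(0, 1, 0, 1); lng <- rep(1, 4)
  age_std <- 0.7; female <- 1
  pieces <- barrettjm:::build_pieces(vt, eso, lng, sp$baseline$knots, 6)
  eta <- barrettjm:::affine_eta(pieces, beta, b, age_std, female)
  H_fast <- barrettjm:::ch_affine(0.5, 6, sp, pieces, eta, age_std, female)

  pi_funs <- lapply(1:3, function(k) function(t) {
    j <- findInterval(t, vt); j[j == 0] <- 1
    plogis(sum(beta[k, ] * c(1, t, age_std, female, lng[j], eso[j])) + b[k])
  })
  covf <- function(t) {
    j <- findInterval(t, vt); j[j == 0] <- 1
    c(age_std, female, lng[j], eso[j])
  }
  H_gen <- cumulative_hazard(0.5, 6, sp, pi_funs, covf, breaks = vt)
  expect_equal(H_fast, H_gen, tolerance = 1e-7)
  # cumulative hazard nondecreasing in the upper limit, hazard positive
  Hs <- sapply(seq(0.6, 6, by = 0.3), function(tt)
    barrettjm:::ch_affine(0.5, tt, sp, pieces, eta, age_std, female))
  expect_true(all(diff(Hs) > 0))
  # the precompiled per-patient evaluator agrees with both paths
  Hf <- barrettjm:::make_H_fun(pieces, beta, sp, age_std, female,
                               0.5, 6, nodes = 15)
  expect_equal(Hf(b), H_fast, tolerance = 1e-9)
  # and with a zero time coefficient (degenerate closed form)
  beta0 <- beta; beta0[, 2] <- 0
  eta0 <- barrettjm:::affine_eta(pieces, beta0, b, age_std, female)
  Hf0 <- barrettjm:::make_H_fun(pieces, beta0, sp, age_std, female,
                                0.5, 6, nodes = 15)
  expect_equal(Hf0(b),
               barrettjm:::ch_affine(0.5, 6, sp, pieces, eta0, age_std,
                                     female),
               tolerance = 1e-9)
})

test_that("joint log-likelihood matches a hand computation and the missing contract", {
  # empty cohort
  empty <- structure(list(baselines = data.frame(patient_id = character(0)),
                          visits = NULL, outcomes = NULL,
                          age_scaler = c(60, 10)), class = "be_cohort")
  long0 <- longitudinal_params(matrix(0, 3, 6), diag(3))
  h <- 0.15
  surv0 <- survival_params(baseline_hazard(numeric(0), log(h)))
  expect_equal(joint_log_likelihood(empty, long0, surv0,
                                    matrix(0, 0, 3)), 0)

  # one censored patient, one visit, one observed marker, flat hazard
  beta <- matrix(0, 3, 6); beta[1, 1] <- -0.7
  long1 <- longitudinal_params(beta, diag(3))
  co <- new_cohort(
    data.frame(patient_id = "X", age_years = 60, female = 0),
    data.frame(patient_id = "X", time_years = 0, lgd = 1, p53 = NA,
               sox2 = NA, esophagitis = 0, long_segment = 0),
    data.frame(patient_id = "X", event_time_years = 2.5, event = 0,
               entry_time_years = 0.5))
  co$age_scaler <- c(60, 10)
  bX <- matrix(c(0.4, 0, 0), 1, 3)
  ll <- joint_log_likelihood(co, long1, surv0, bX)
  ll_hand <- log(plogis(-0.7 + 0.4)) - h * (2.5 - 0.5)
  expect_equal(ll, ll_hand, tolerance = 1e-10)

  # appending a visit with all three markers missing changes nothing
  co2 <- co
  co2$visits <- rbind(co2$visits,
                      data.frame(patient_id = "X", time_years = 1.3,
                                 lgd = NA, p53 = NA, sox2 = NA,
                                 esophagitis = 0, long_segment = 0))
  expect_equal(joint_log_likelihood(co2, long1, surv0, bX), ll,
               tolerance = 1e-12)
})

test_that("joint log-likelihood is invariant to patient and visit order", {
  res <- make_analysis_cohort(n = 20, seed = 17)
  co <- res$cohort
  tr <- res$truth
  n <- nrow(co$baselines)
  set.seed(1); b <- matrix(rnorm(3 * n, 0, 0.8), n, 3)
  ll1 <- joint_log_likelihood(co, tr$longitudinal, tr$survival, b)
  perm <- sample(n)
  co2 <- co
  co2$baselines <- co$baselines[perm, ]
  co2$visits <- co$visits[rev(seq_len(nrow(co$visits))), ]
  co2$outcomes <- co$outcomes[rev(seq_len(n)), ]
  ll2 <- joint_log_likelihood(co2, tr$longitudinal, tr$survival,
                              b[perm, , drop = FALSE])
  expect_equal(ll2, ll1, tolerance = 1e-10)
})
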