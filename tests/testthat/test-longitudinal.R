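# Random-intercept logistic submodels: linear predictor arithmetic,
# marginal likelihood vs brute-force integration, ML fitting vs an
# ordinary-logistic oracle, and odds-ratio extraction.

test_that("linear predictor and marker probability follow the logistic form", {
  x <- c(1, 2, 0.5, 1, 0, 1)
  expect_equal(linear_predictor(rep(0, 6), x, 0), 0)
  expect_equal(marker_probability(0), 0.5)
  expect_equal(marker_probability(linear_predictor(rep(0, 6), x, log(4))),
               0.8)
  expect_error(linear_predictor(rep(0, 5), x), "dimension")
  # a time coefficient log(1.17) multiplies the odds by 1.17 per year
  beta <- c(0, log(1.17), 0, 0, 0, 0)
  t0 <- 2.3
  odds <- function(t) {
    p <- marker_probability(linear_predictor(beta, c(1, t, 0, 0, 0, 0)))
    p / (1 - p)
  }
  expect_equal(odds(t0 + 1) / odds(t0), 1.17, tolerance = 1e-12)
  # probability strictly increasing in the random intercept
  bgrid <- seq(-5, 5, length.out = 41)
  pvals <- marker_probability(linear_predictor(beta, c(1, 1, 0, 0, 0, 0), 0) +
                                bgrid)
  expect_true(all(diff(pvals) > 0))
  expect_true(all(pvals > 0 & pvals < 1))
})

test_that("adaptive quadrature matches brute-force integration on a toy set", {
  set.seed(42)
  n_pat <- 5
  X <- NULL; y <- NULL; pid <- NULL
  beta <- c(-0.5, 0.3, 0.4, -0.6, 0.2, 0.1)
  sigma <- 1.3
  for (i in 1:n_pat) {
    m <- sample(1:4, 1)
    Xi <- cbind(1, seq_len(m) - 1, rnorm(1), rbinom(1, 1, 0.5),
                rbinom(1, 1, 0.5), rbinom(m, 1, 0.2))
    X <- rbind(X, Xi)
    y <- c(y, rbinom(m, 1, 0.5))
    pid <- c(pid, rep(i, m))
  }
  ll_gh <- mixed_logistic_loglik(beta, sigma, y, X, pid)
  # oracle: adaptive numerical integration over b per patient
  ll_num <- 0
  for (i in 1:n_pat) {
    idx <- pid == i
    f <- function(b) {
      sapply(b, function(bb) {
        eta <- X[idx, , drop = FALSE] %*% beta + bb
        exp(sum(y[idx] * eta - log1p(exp(eta)))) * dnorm(bb, 0, sigma)
      })
    }
    ll_num <- ll_num + log(integrate(f, -10 * sigma, 10 * sigma,
                                     rel.tol = 1e-12)$value)
  }
  expect_equal(ll_gh, ll_num, tolerance = 1e-6)
})

test_that("visits with a missing marker leave the likelihood unchanged", {
  res <- make_analysis_cohort(n = 30, seed = 8)
  co <- res$cohort
  mf <- barrettjm:::marker_model_frame(co, "p53")
  beta <- c(-2, 0.1, 0.3, -0.5, 0.4, -0.2)
  ll1 <- mixed_logistic_loglik(beta, 1.1, mf$y, mf$X, mf$patient_id)
  # appending a visit with p53 missing does not alter the p53 frame
  co2 <- co
  extra <- co2$visits[1, ]
  extra$time_years <- max(co2$visits$time_years[
    co2$visits$patient_id == extra$patient_id]) + 0.01
  extra$p53 <- NA
  co2$visits <- rbind(co2$visits, extra)
  mf2 <- barrettjm:::marker_model_frame(co2, "p53")
  ll2 <- mixed_logistic_loglik(beta, 1.1, mf2$y, mf2$X, mf2$patient_id)
  expect_identical(ll1, ll2)
})

test_that("with one visit per patient and sigma fixed 0 the fit matches Newton-Raphson", {
  set.seed(7)
  n <- 400
  ids <- sprintf("N%03d", 1:n)
  age <- rnorm(n, 60, 10)
  fem <- rbinom(n, 1, 0.3); lng <- rbinom(n, 1, 0.6)
  eso <- rbinom(n, 1, 0.15)
  eta <- -1 + 0.4 * (age - 60) / 10 - 0.5 * fem + 0.3 * lng
  y <- rbinom(n, 1, plogis(eta))
  co <- new_cohort(
    data.frame(patient_id = ids, age_years = age, female = fem),
    data.frame(patient_id = ids, time_years = 0, lgd = y, p53 = 0, sox2 = 0,
               esophagitis = eso, long_segment = lng),
    data.frame(patient_id = ids, event_time_years = 5, event = 0))
  co <- standardize_age(co)
  fit <- fit_mixed_logistic(co, "lgd", random_intercept = FALSE)
  # every visit is the index visit, so the time column is aliased out
  expect_true(is.na(fit$estimates["time"]))
  mf <- barrettjm:::marker_model_frame(co, "lgd")
  oracle <- logistic_newton(mf$y, mf$X[, -2])
  est <- fit$estimates[!is.na(fit$estimates)]
  expect_equal(unname(est), oracle, tolerance = 1e-6)
  ok <- !is.na(fit$estimates)
  expect_true(all(fit$ci_lower[ok] <= fit$estimates[ok] &
                    fit$estimates[ok] <= fit$ci_upper[ok]))
})

test_that("constant markers raise a separation/degeneracy error", {
  res <- make_analysis_cohort(n = 25, seed = 14)
  co <- res$cohort
  co$visits$sox2[!is.na(co$visits$sox2)] <- 0
  expect_error(fit_mixed_logistic(co, "sox2"), "separation|constant")
})

test_that("odds ratios exponentiate estimates and CI bounds", {
  fit <- structure(list(
    marker = "lgd",
    estimates = setNames(c(-1, 0, log(1.58), log(0.55), 0.2, 0.1),
                         barrettjm:::FIXEF_NAMES),
    se = setNames(rep(0.1, 6), barrettjm:::FIXEF_NAMES),
    ci_lower = setNames(c(-1.2, -0.1, log(1.31), log(0.36), 0, 0),
                        barrettjm:::FIXEF_NAMES),
    ci_upper = setNames(c(-0.8, 0.1, log(1.91), log(0.82), 0.4, 0.2),
                        barrettjm:::FIXEF_NAMES),
    sd_b = 1, loglik = -10, converged = TRUE), class = "marker_fit")
  or <- odds_ratios(fit)
  expect_equal(or$or[or$covariate == "age_std"], 1.58)
  expect_equal(or$or[or$covariate == "female"], 0.55)
  expect_equal(or$or[or$covariate == "time"], 1.00)
  expect_equal(or$lower[or$covariate == "age_std"], 1.31)
  expect_equal(or$upper[or$covariate == "age_std"], 1.91)
})

test_that("the mixed fitter recovers generating parameters", {
  # replicate fits on freshly simulated cohorts; each coefficient's 95% CI
  # should cover its generating value at roughly nominal rate
  n_rep <- 6
  covered <- 0; total <- 0
  tr <- default_truth(n_patients = 250)
  for (r in seq_len(n_rep)) {
    sim <- simulate_cohort(tr, seed = 100 + r)
    co <- standardize_age(apply_eligibility_filters(sim$cohort)$cohort)
    fit <- fit_mixed_logistic(co, "lgd", nagq = 7)
    truth_beta <- tr$longitudinal$beta["lgd", ]
    # generator standardizes age against (age_mean, age_sd); re-express the
    # truth on the cohort's frozen scaler
    adj <- truth_beta
    adj["age_std"] <- truth_beta["age_std"] * co$age_scaler[2] / tr$age_sd
    adj["intercept"] <- truth_beta["intercept"] +
      truth_beta["age_std"] * (co$age_scaler[1] - tr$age_mean) / tr$age_sd
    cover <- fit$ci_lower <= adj & adj <= fit$ci_upper
    covered <- covered + sum(cover); total <- total + length(cover)
  }
  expect_gte(covered / total, 0.8)
})
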