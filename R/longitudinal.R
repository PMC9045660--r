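## Random-intercept logistic submodels for the three dichotomized
## biomarkers: linear predictors, the marginal log-likelihood with the
## intercept integrated out by adaptive Gauss-Hermite quadrature, a
## standalone maximum-likelihood fitter for odds-ratio reporting, and OR
## extraction.

#' Marker linear predictor
#'
#' `eta = beta . x + b` for one marker at one observation, with `x`
#' ordered `(1, t, age_std, female, long_segment, esophagitis)`.
#'
#' @param beta length-6 fixed effects.
#' @param x length-6 covariate vector.
#' @param b scalar random intercept.
#' @return Scalar logit-scale predictor.
#' @export
linear_predictor <- function(beta, x, b = 0) {
  if (length(beta) != length(x))
    stop("dimension mismatch: length(beta) = ", length(beta),
         ", length(x) = ", length(x), call. = FALSE)
  sum(beta * x) + b
}

#' Probability of aberrant expression from a linear predictor
#'
#' @param eta logit-scale linear predictor.
#' @return `expit(eta)`, strictly increasing in `eta` and in (0,1).
#' @export
marker_probability <- function(eta) expit(eta)

## Long-format model frame for one marker: response y, design X (6 cols),
## patient index. Rows with a missing marker are dropped (they contribute
## nothing to the likelihood).
marker_model_frame <- function(cohort, marker) {
  stopifnot(inherits(cohort, "be_cohort"), marker %in% MARKERS)
  vis <- cohort$visits
  bl <- cohort$baselines
  m <- match(vis$patient_id, bl$patient_id)
  age_std <- scaled_age(bl$age_years[m], cohort$age_scaler)
  keep <- !is.na(vis[[marker]])
  X <- cbind(intercept = 1, time = vis$time_years, age_std = age_std,
             female = bl$female[m], long_segment = vis$long_segment,
             esophagitis = vis$esophagitis)[keep, , drop = FALSE]
  list(y = vis[[marker]][keep], X = X,
       patient_id = vis$patient_id[keep])
}

#' Marginal log-likelihood of a random-intercept logistic model
#'
#' Integrates the random intercept out of the Bernoulli likelihood per
#' patient by adaptive Gauss-Hermite quadrature: nodes are centered at
#' each patient's posterior mode of `b` and scaled by the curvature
#' there. Patients with zero non-missing observations contribute a
#' factor of 1.
#'
#' @param beta length-6 fixed effects (order
#'   intercept, time, age_std, female, long_segment, esophagitis).
#' @param sigma_b random-intercept standard deviation (>= 0).
#' @param y 0/1 response vector.
#' @param X design matrix (rows matching `y`, 6 columns).
#' @param patient_id grouping vector matching `y`.
#' @param nodes Gauss-Hermite nodes (default 15).
#' @return Scalar marginal log-likelihood.
#' @export
mixed_logistic_loglik <- function(beta, sigma_b, y, X, patient_id,
                                  nodes = 15) {
  eta0 <- as.numeric(X %*% beta)
  if (sigma_b <= 0) {
    p <- expit(eta0)
    return(sum(y * log(p) + (1 - y) * log1p(-p)))
  }
  gh <- gauss_hermite(nodes)
  total <- 0
  for (idx in split(seq_along(y), patient_id)) {
    yi <- y[idx]; ei <- eta0[idx]
    logf <- function(b)
      sum(yi * (ei + b) - softplus(ei + b)) - b^2 / (2 * sigma_b^2)
    # Newton to the posterior mode of b
    bhat <- 0
    for (it in 1:50) {
      p <- expit(ei + bhat)
      g <- sum(yi - p) - bhat / sigma_b^2
      hss <- -sum(p * (1 - p)) - 1 / sigma_b^2
      step <- g / hss
      bhat <- bhat - step
      if (abs(step) < 1e-12) break
    }
    p <- expit(ei + bhat)
    s_hat <- 1 / sqrt(sum(p * (1 - p)) + 1 / sigma_b^2)
    bq <- bhat + sqrt(2) * s_hat * gh$nodes
    lf <- vapply(bq, logf, numeric(1))
    m0 <- max(lf)
    integral <- sqrt(2) * s_hat * sum(gh$weights * exp(lf - m0 + gh$nodes^2))
    total <- total + m0 + log(integral) - log(sqrt(2 * pi) * sigma_b)
  }
  total
}

#' Fit one marker's random-intercept logistic submodel
#'
#' Maximizes the marginal likelihood (random intercept integrated out by
#' adaptive Gauss-Hermite quadrature with 15 nodes, via `lme4::glmer`)
#' for the fixed effects `(intercept, time, age_std, female,
#' long_segment, esophagitis)` plus the intercept sd. Visits with a
#' missing marker value contribute nothing. Wald 95% CIs.
#'
#' @param cohort A `be_cohort` with `age_scaler` set
#'   (see [standardize_age()]).
#' @param marker `"lgd"`, `"p53"` or `"sox2"`.
#' @param random_intercept set `FALSE` to fix `sigma_b = 0` (ordinary
#'   logistic regression; useful with one observation per patient).
#' @param nagq adaptive quadrature nodes (default 15).
#' @return An object of class `marker_fit`: estimates, standard errors,
#'   95% CI bounds, `sd_b`, log-likelihood, convergence flag.
#' @export
fit_mixed_logistic <- function(cohort, marker, random_intercept = TRUE,
                               nagq = 15) {
  mf <- marker_model_frame(cohort, marker)
  if (length(unique(mf$patient_id[!is.na(mf$y)])) < 2)
    stop("need >= 2 patients with a non-missing ", marker, " observation",
         call. = FALSE)
  if (length(unique(mf$y)) < 2)
    stop("degenerate fit: ", marker, " is constant (all ",
         unique(mf$y), "); separation", call. = FALSE)
  for (cv in c("female", "long_segment", "esophagitis")) {
    x <- mf$X[, cv]
    if (length(unique(x)) == 2) {
      tab <- tapply(mf$y, x, mean)
      if (all(tab %in% c(0, 1)) && tab[1] != tab[2])
        stop("complete separation on covariate ", cv, " for marker ",
             marker, call. = FALSE)
    }
  }
  dat <- data.frame(y = mf$y, mf$X[, -1, drop = FALSE],
                    patient_id = mf$patient_id)
  if (random_intercept) {
    fit <- lme4::glmer(
      y ~ time + age_std + female + long_segment + esophagitis +
        (1 | patient_id),
      data = dat, family = stats::binomial(), nAGQ = nagq)
    sm <- summary(fit)$coefficients
    sd_b <- sqrt(unname(lme4::VarCorr(fit)$patient_id[1, 1]))
    conv <- length(fit@optinfo$conv$lme4$messages) == 0
    ll <- as.numeric(stats::logLik(fit))
  } else {
    fit <- stats::glm(y ~ time + age_std + female + long_segment +
                        esophagitis, data = dat, family = stats::binomial())
    sm <- summary(fit)$coefficients
    sd_b <- 0
    conv <- fit$converged
    ll <- as.numeric(stats::logLik(fit))
  }
  # aliased columns (e.g. a constant time with one visit per patient)
  # are reported as NA rather than silently dropped
  name_map <- c("(Intercept)" = "intercept", time = "time",
                age_std = "age_std", female = "female",
                long_segment = "long_segment", esophagitis = "esophagitis")
  est <- se <- stats::setNames(rep(NA_real_, 6), FIXEF_NAMES)
  est[name_map[rownames(sm)]] <- sm[, 1]
  se[name_map[rownames(sm)]] <- sm[, 2]
  if (!conv)
    warning("fit for marker ", marker,
            " flagged non-converged; returning partial results")
  structure(list(marker = marker, estimates = est, se = se,
                 ci_lower = est - stats::qnorm(0.975) * se,
                 ci_upper = est + stats::qnorm(0.975) * se,
                 sd_b = sd_b, loglik = ll, converged = conv,
                 n_obs = length(mf$y),
                 n_patients = length(unique(mf$patient_id))),
            class = "marker_fit")
}

#' Odds ratios from a marker submodel fit
#'
#' @param fit A `marker_fit`.
#' @return data.frame with `covariate`, `or`, `lower`, `upper`
#'   (exponentiated estimates and Wald CI bounds).
#' @export
odds_ratios <- function(fit) {
  stopifnot(inherits(fit, "marker_fit"))
  data.frame(covariate = names(fit$estimates),
             or = exp(unname(fit$estimates)),
             lower = exp(unname(fit$ci_lower)),
             upper = exp(unname(fit$ci_upper)))
}

#' @export
print.marker_fit <- function(x, ...) {
  cat(sprintf("Random-intercept logistic fit for %s (%d obs, %d patients)\n",
              x$marker, x$n_obs, x$n_patients))
  or <- odds_ratios(x)
  or[-1, c("or", "lower", "upper")] <- round(or[-1, c("or", "lower", "upper")], 2)
  print(or[-1, ], row.names = FALSE)
  cat(sprintf("random-intercept sd %.3f, logLik %.2f%s\n", x$sd_b, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Serialize a marker fit to JSON
#'
#' @param fit A `marker_fit`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
marker_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "marker_fit"))
  obj <- list(marker = fit$marker,
              estimates = as.list(fit$estimates),
              se = as.list(fit$se),
              ci_lower = as.list(fit$ci_lower),
              ci_upper = as.list(fit$ci_upper),
              sd_b = fit$sd_b, loglik = fit$loglik,
              converged = fit$converged)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
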