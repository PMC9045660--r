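## Small numeric helpers shared across modules.

#' Inverse logit
#'
#' @param x Numeric vector on the logit scale.
#' @return `1 / (1 + exp(-x))`, computed stably for large `|x|`.
#' @export
expit <- function(x) stats::plogis(x)

## log(1 + exp(x)) without overflow; antiderivative of expit up to scale.
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

## Exact integral of expit(a + c*s) over [s0, s1] (per element).
## Used for the accumulated-effect term: within a covariate piece the
## marker linear predictor is affine in time, so the integral is closed form.
integral_expit_affine <- function(a, c, s0, s1) {
  n <- max(length(a), length(c), length(s0), length(s1))
  a <- rep_len(a, n); c <- rep_len(c, n)
  s0 <- rep_len(s0, n); s1 <- rep_len(s1, n)
  small <- abs(c) < 1e-10
  if (!any(small))
    return((softplus(a + c * s1) - softplus(a + c * s0)) / c)
  out <- numeric(n)
  out[small] <- expit(a[small] + c[small] * (s0[small] + s1[small]) / 2) *
    (s1[small] - s0[small])
  if (any(!small)) {
    i <- !small
    out[i] <- (softplus(a[i] + c[i] * s1[i]) - softplus(a[i] + c[i] * s0[i])) / c[i]
  }
  out
}

## Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch (cached: the
## hazard quadrature requests the same rule millions of times).
.quad_cache <- new.env(parent = emptyenv())

gauss_legendre <- function(n) {
  key <- paste0("gl", n)
  hit <- .quad_cache[[key]]
  if (!is.null(hit)) return(hit)
  .quad_cache[[key]] <- gauss_legendre_raw(n)
  .quad_cache[[key]]
}

gauss_legendre_raw <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = 2 * (e$vectors[1, idx])^2)
}

## Gauss-Hermite nodes/weights (physicists' weight exp(-x^2)).
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = sqrt(pi) * (e$vectors[1, idx])^2)
}

## Split R-hat (Gelman et al.): draws is iterations x chains.
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  segs <- cbind(draws[seq_len(half), , drop = FALSE],
                draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(segs)
  means <- colMeans(segs)
  vars <- apply(segs, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W < 1e-300) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

## Effective sample size via initial positive sequence of autocorrelations.
ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws); m <- ncol(draws)
  if (n < 4) return(NA_real_)
  keep <- apply(draws, 2, stats::var) > 1e-300
  if (!any(keep)) return(n * m)   # constant scalar: no MC error
  draws <- draws[, keep, drop = FALSE]
  m <- ncol(draws)
  acf_mean <- rep(0, n - 1)
  for (j in seq_len(m)) {
    a <- stats::acf(draws[, j], lag.max = n - 2, plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
    acf_mean <- acf_mean + a / m
  }
  rho <- acf_mean[-1]
  rho[is.na(rho)] <- 0
  # sum paired autocorrelations while positive
  s <- 0
  k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  max(1, (n * m) / (1 + 2 * s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
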