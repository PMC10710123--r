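# Bayesian simple linear regression by Gibbs sampling.
#
# Model: y = a + b x + eps, eps ~ N(0, sigma^2)
# Priors: a, b ~ N(0, 10^2) independent; sigma ~ half-Cauchy(0, 1).
# (a, b) | sigma is conjugate normal; sigma | (a, b) is drawn by univariate
# slice sampling on log sigma. With standardized data and n in the hundreds
# the posterior mean slope is within MC error of the OLS slope (the priors
# are weak), which is the contract the index selection relies on.

#' @keywords internal
#' @noRd
slice_sample_1d <- function(x0, log_f, w = 1, max_step = 50) {
  ly <- log_f(x0) - stats::rexp(1)
  u <- stats::runif(1)
  L <- x0 - w * u
  R <- L + w
  k <- max_step
  while (k > 0 && log_f(L) > ly) { L <- L - w; k <- k - 1 }
  k <- max_step
  while (k > 0 && log_f(R) > ly) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (log_f(x1) > ly) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

#' Bayesian simple linear regression (posterior of the slope)
#'
#' @param x,y numeric vectors (typically standardized).
#' @param n_draws posterior draws kept after burn-in.
#' @param burn burn-in draws discarded.
#' @param prior_sd standard deviation of the normal prior on intercept and
#'   slope.
#' @return list with `slope_mean`, `intercept_mean`, `sigma_mean`, and the
#'   kept `draws` (matrix with columns `intercept,slope,sigma`).
#' @export
bayes_slr <- function(x, y, n_draws = 4000, burn = 500, prior_sd = 10) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  n <- length(x)
  X <- cbind(1, x)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  prior_prec <- diag(1 / prior_sd^2, 2)

  beta <- c(mean(y), 0)
  sigma <- stats::sd(y)
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  draws <- matrix(NA_real_, n_draws, 3,
                  dimnames = list(NULL, c("intercept", "slope", "sigma")))
  for (it in seq_len(n_draws + burn)) {
    V <- chol2inv(chol(XtX / sigma^2 + prior_prec))
    m <- V %*% (Xty / sigma^2)
    beta <- as.numeric(m + t(chol(V)) %*% stats::rnorm(2))
    ssr <- sum((y - X %*% beta)^2)
    log_post <- function(ls) {
      s2 <- exp(2 * ls)
      -n * ls - ssr / (2 * s2) - log1p(s2) + ls  # half-Cauchy + Jacobian
    }
    sigma <- exp(slice_sample_1d(log(sigma), log_post, w = 0.5))
    if (it > burn) draws[it - burn, ] <- c(beta, sigma)
  }
  list(slope_mean = mean(draws[, "slope"]),
       intercept_mean = mean(draws[, "intercept"]),
       sigma_mean = mean(draws[, "sigma"]),
       draws = draws)
}
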