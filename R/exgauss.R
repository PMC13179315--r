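#' The ex-Gaussian distribution
#'
#' Density, log-density and random generation for the exponentially
#' modified Gaussian distribution: the sum of a Gaussian with mean `mu` and
#' SD `sigma` and an independent exponential with mean `tau`. It is the
#' standard model for right-skewed timing data; its mean is `mu + tau` and
#' its variance `sigma^2 + tau^2`.
#'
#' The log-density
#' \deqn{\log f(x) = -\log\tau + \frac{\sigma^2}{2\tau^2} - \frac{x-\mu}{\tau}
#'   + \log\Phi\!\left(\frac{x-\mu}{\sigma} - \frac{\sigma}{\tau}\right)}
#' suffers catastrophic cancellation when `sigma/tau` is large (the
#' near-Gaussian limit), so it is evaluated through the scaled complementary
#' error function: with `z = (x - mu)/sigma` and `w = (sigma/tau - z)/sqrt(2)`,
#' `log f = -log(2 tau) - z^2/2 + log(erfcx(w))` whenever `w >= 0`, and
#' through the log-CDF form otherwise. Both branches are stable over the
#' full parameter range.
#'
#' @param x Numeric vector of quantiles (same unit as the parameters,
#'   milliseconds throughout this package).
#' @param mu Gaussian location.
#' @param sigma Gaussian SD, > 0.
#' @param tau Exponential mean, > 0.
#' @param n Number of draws.
#' @param log Return log-density?
#' @return `dexgauss` the (log-)density; `rexgauss` random draws.
#' @export
dexgauss <- function(x, mu, sigma, tau, log = FALSE) {
  if (any(sigma <= 0) || any(tau <= 0))
    stop("sigma and tau must be positive", call. = FALSE)
  z <- (x - mu) / sigma
  w <- (sigma / tau - z) / sqrt(2)
  lp <- numeric(length(z))
  pos <- w >= 0
  # near-Gaussian / left-tail branch: stable via erfcx
  lp[pos] <- -log(2 * tau) - z[pos]^2 / 2 + log_erfcx(w[pos])
  # right-tail branch: exponential decay dominates, log-CDF form is stable
  if (any(!pos)) {
    lp[!pos] <- -log(tau) + (sigma / tau)^2 / 2 - (x[!pos] - mu) / tau +
      stats::pnorm(z[!pos] - sigma / tau, log.p = TRUE)
  }
  if (log) lp else exp(lp)
}

# log of the scaled complementary error function for w >= 0.
# pracma::erfcx overflows to NaN near w = 27; beyond w = 20 the asymptotic
# expansion 1/(w sqrt(pi)) (1 - 1/(2w^2) + 3/(4w^4)) agrees to machine
# precision, so switch branches there.
log_erfcx <- function(w) {
  out <- numeric(length(w))
  small <- w < 20
  out[small] <- log(pracma::erfcx(w[small]))
  wl <- w[!small]
  out[!small] <- -log(wl * sqrt(pi)) + log1p(-1 / (2 * wl^2) + 3 / (4 * wl^4))
  out
}

#' @rdname dexgauss
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  if (any(sigma <= 0) || any(tau <= 0))
    stop("sigma and tau must be positive", call. = FALSE)
  stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau)
}

#' @rdname dexgauss
#' @param q Numeric vector of quantiles.
#' @export
pexgauss <- function(q, mu, sigma, tau) {
  # F(x) = Phi(z) - tau * f(x): the exponential-tilted term of the CDF is
  # exactly tau times the density, so stability follows from dexgauss
  z <- (q - mu) / sigma
  pmin(pmax(stats::pnorm(z) - tau * dexgauss(q, mu, sigma, tau), 0), 1)
}

#' Parameter container for an ex-Gaussian
#'
#' @param mu,sigma,tau See [dexgauss()].
#' @return A list of class `exgauss_params`.
#' @export
exgauss_params <- function(mu, sigma, tau) {
  stopifnot(is.finite(mu), sigma > 0, tau > 0)
  structure(list(mu = mu, sigma = sigma, tau = tau), class = "exgauss_params")
}

#' @export
print.exgauss_params <- function(x, ...) {
  cat(sprintf("<exgauss_params> mu = %.1f, sigma = %.1f, tau = %.1f (mean %.1f)\n",
              x$mu, x$sigma, x$tau, x$mu + x$tau))
  invisible(x)
}

#' Maximum-likelihood fit of an ex-Gaussian
#'
#' Fits (`mu`, `sigma`, `tau`) by numerical maximisation of the summed
#' log-density, starting from moment estimates: the skewness-based split
#' assigns `tau = sd * (skew/2)^(1/3)`, `mu = mean - tau`,
#' `sigma^2 = var - tau^2` (clamped to keep both scales positive).
#' Optimisation is on log-scale for `sigma` and `tau`.
#'
#' @param x Numeric vector of observations (>= 10 values).
#' @return An `exgauss_fit` list: `params` (an [exgauss_params()]),
#'   `loglik`, `n`, `convergence` (0 = converged) and the `optim` message
#'   if any.
#' @export
fit_exgauss_mle <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 10) stop("need at least 10 observations", call. = FALSE)
  m <- mean(x); s <- stats::sd(x)
  skew <- mean((x - m)^3) / s^3
  tau0 <- s * (max(skew, 0.01) / 2)^(1 / 3)
  tau0 <- min(max(tau0, s / 100), s * 2)
  sigma0 <- sqrt(max(s^2 - tau0^2, (s / 10)^2))
  start <- c(m - tau0, log(sigma0), log(tau0))
  nll <- function(p) {
    val <- -sum(dexgauss(x, p[1], exp(p[2]), exp(p[3]), log = TRUE))
    if (!is.finite(val)) 1e10 else val
  }
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  if (opt$convergence != 0)
    warning("ex-Gaussian MLE did not converge (code ", opt$convergence, "): ",
            opt$message %||% "")
  structure(list(params = exgauss_params(opt$par[1], exp(opt$par[2]),
                                         exp(opt$par[3])),
                 loglik = -opt$value, n = length(x),
                 convergence = opt$convergence,
                 message = opt$message),
            class = "exgauss_fit")
}

#' @export
print.exgauss_fit <- function(x, ...) {
  cat(sprintf("<exgauss_fit> n = %d, logLik = %.1f%s\n", x$n, x$loglik,
              if (x$convergence != 0) " [NOT CONVERGED]" else ""))
  print(x$params)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
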