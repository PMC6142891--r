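#' Gamma density of the reconstruction-error ratio
#'
#' Standard gamma density in shape/scale form,
#' `x^(alpha - 1) exp(-x / beta) / (Gamma(alpha) beta^alpha)`.
#' At `x = 0` the density is 0 for `alpha > 1`, `1 / beta` for `alpha = 1`,
#' and infinite for `alpha < 1`.
#'
#' @param x ratio value(s), >= 0.
#' @param alpha shape parameter, > 0.
#' @param beta scale parameter, > 0.
#' @return density values >= 0.
#' @export
gamma_pdf <- function(x, alpha, beta) {
  out <- gamma_logpdf(x, alpha, beta)
  exp(out)
}

#' @rdname gamma_pdf
#' @return `gamma_logpdf`: the log density (`-Inf` where the density is 0).
#' @export
gamma_logpdf <- function(x, alpha, beta) {
  if (alpha <= 0 || beta <= 0) stop_input("alpha and beta must be positive")
  if (any(x < 0)) stop_input("x must be >= 0")
  out <- (alpha - 1) * log(x) - x / beta - lgamma(alpha) - alpha * log(beta)
  at0 <- x == 0
  if (any(at0)) {
    out[at0] <- if (alpha > 1) -Inf else if (alpha == 1) -log(beta) else Inf
  }
  out
}

#' Maximum-likelihood gamma fit
#'
#' Method-of-moments start (`alpha = m^2 / v`, `beta = v / m`), then Newton
#' iterations on the profile shape equation
#' `log(alpha) - digamma(alpha) = log(mean) - mean(log x)`;
#' `beta = mean / alpha`. Deterministic.
#'
#' @param samples positive values; at least `min_n` of them.
#' @param min_n minimum sample count (default 50, matching the calibration
#'   requirement).
#' @param method `"mle"` (default) or `"moments"` to return the
#'   method-of-moments start itself.
#' @return list `(alpha, beta)`.
#' @export
fit_gamma <- function(samples, min_n = 50L, method = c("mle", "moments")) {
  method <- match.arg(method)
  samples <- as.numeric(samples)
  if (length(samples) < min_n)
    stop_calibration("need at least %d samples, got %d", min_n, length(samples))
  if (any(samples <= 0)) stop_input("gamma samples must be positive")
  m <- mean(samples); v <- stats::var(samples)
  if (v == 0) stop_degenerate("zero-variance samples: gamma fit undefined")
  a <- m^2 / v
  if (method == "moments") return(list(alpha = a, beta = v / m))
  s <- log(m) - mean(log(samples))
  if (s > 0) {
    for (i in 1:100) {
      f <- log(a) - digamma(a) - s
      fp <- 1 / a - trigamma(a)
      step <- f / fp
      a_new <- a - step
      if (a_new <= 0) a_new <- a / 2
      if (abs(a_new - a) < 1e-12 * a) { a <- a_new; break }
      a <- a_new
    }
  }
  list(alpha = a, beta = m / a)
}
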