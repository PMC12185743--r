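#' ARMA(1,1) parameter validation
#'
#' Checks stationarity (|phi| < 1) and invertibility (|theta| < 1).
#'
#' @param phi AR(1) coefficient.
#' @param theta MA(1) coefficient.
#' @return Invisibly `TRUE`; otherwise an error naming the offending bound.
#' @keywords internal
check_arma_params <- function(phi, theta) {
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) ||
      abs(phi) >= 1) {
    stop("`phi` must satisfy |phi| < 1 (stationarity); got ", phi,
         call. = FALSE)
  }
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      abs(theta) >= 1) {
    stop("`theta` must satisfy |theta| < 1 (invertibility); got ", theta,
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Theoretical autocorrelation function of an ARMA(1,1) process
#'
#' Closed form: rho(0) = 1,
#' rho(1) = (1 + phi*theta)(phi + theta) / (1 + 2*phi*theta + theta^2),
#' rho(k) = phi * rho(k - 1) for k >= 2.
#'
#' @param phi,theta ARMA(1,1) parameters, each in (-1, 1).
#' @param max_lag Largest lag to return.
#' @return Numeric vector of correlations at lags `0:max_lag`.
#' @examples
#' arma11_acf(0.5, 0, 3) # AR(1): 1, 0.5, 0.25, 0.125
#' @export
arma11_acf <- function(phi, theta, max_lag) {
  check_arma_params(phi, theta)
  stopifnot(is.numeric(max_lag), length(max_lag) == 1L, max_lag >= 0)
  out <- arma11_acf_cpp(phi, theta, as.integer(max_lag))
  names(out) <- 0:max_lag
  out
}

#' ARMA(1,1) correlation matrix over an ordered index
#'
#' Entry (i, j) equals the ARMA(1,1) autocorrelation at lag |i - j| of the
#' alongshore order index. Symmetric, unit-diagonal, positive definite for
#' stationary/invertible parameters.
#'
#' @inheritParams arma11_acf
#' @param n Matrix dimension (number of ordered sites).
#' @return `n` x `n` correlation matrix.
#' @export
arma11_cor_matrix <- function(phi, theta, n) {
  check_arma_params(phi, theta)
  stopifnot(n >= 1)
  rho <- arma11_acf(phi, theta, n - 1L)
  idx <- abs(outer(seq_len(n), seq_len(n), "-")) + 1L
  matrix(rho[idx], n, n)
}

#' Simulate a stationary ARMA(1,1) series
#'
#' Draws `z_t = phi z_(t-1) + e_t + theta e_(t-1)` with Gaussian innovations,
#' discarding a burn-in so the returned draw is (effectively) stationary.
#' The marginal variance is `sd^2 (1 + 2 phi theta + theta^2) / (1 - phi^2)`
#' where `sd` is the innovation standard deviation implied by the requested
#' marginal standard deviation — `sd` here is the *marginal* SD of the series.
#'
#' @inheritParams arma11_acf
#' @param n Length of the returned series.
#' @param sd Marginal standard deviation of the process (> 0).
#' @param seed Optional integer seed; if `NULL`, uses the current RNG stream.
#' @param burn Burn-in length discarded before the returned draw (>= 500).
#' @return Numeric vector of length `n`.
#' @export
simulate_arma11 <- function(n, phi, theta, sd = 1, seed = NULL, burn = 500L) {
  check_arma_params(phi, theta)
  stopifnot(n >= 1, sd > 0, burn >= 500L)
  innov_sd <- sd / sqrt((1 + 2 * phi * theta + theta^2) / (1 - phi^2))
  with_seed(seed, {
    m <- n + burn
    e <- rnorm(m, sd = innov_sd)
    u <- e + theta * c(0, e[-m])          # MA(1) part
    z <- stats::filter(u, phi, method = "recursive")
    as.numeric(z[(burn + 1L):m])
  })
}
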