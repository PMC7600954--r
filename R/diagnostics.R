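# Posterior trace diagnostics.

#' Effective sample size of an MCMC trace
#'
#' `N / (1 + 2 * sum(rho_k))` with the empirical autocorrelations summed up
#' to (but excluding) the first non-positive estimate (initial positive
#' sequence truncation). A zero-variance series has ESS = N by convention.
#'
#' @param samples numeric vector of at least 10 samples.
#' @param lag_max maximum lag considered.
#' @return the effective sample size.
#' @export
ess <- function(samples, lag_max = 2000L) {
  n <- length(samples)
  if (n < 10L) stop("need at least 10 samples")
  v <- var(samples)
  if (is.na(v) || v == 0) return(as.numeric(n))
  r <- as.numeric(acf(samples, lag.max = min(n - 2L, lag_max),
                      plot = FALSE, demean = TRUE)$acf)[-1]
  nonpos <- which(r <= 0)
  k <- if (length(nonpos)) nonpos[1L] - 1L else length(r)
  n / (1 + 2 * sum(r[seq_len(k)]))
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval over the sorted samples containing
#' `ceiling(prob * N)` of them.
#'
#' @param samples numeric vector.
#' @param prob probability mass in (0, 1); default 0.95.
#' @return numeric `c(low, high)`.
#' @examples
#' hpd_interval(rnorm(1e4))   # about (-1.96, 1.96)
#' @export
hpd_interval <- function(samples, prob = 0.95) {
  if (!(is.numeric(prob) && length(prob) == 1L && prob > 0 && prob < 1))
    stop("prob must lie strictly between 0 and 1")
  s <- sort(samples)
  n <- length(s)
  m <- ceiling(prob * n)
  if (m >= n) return(c(s[1L], s[n]))
  w <- s[m:n] - s[1:(n - m + 1L)]
  i <- which.min(w)
  c(s[i], s[i + m - 1L])
}
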