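#' General time reversible substitution model (GTR+Gamma+I)
#'
#' Container for a nucleotide substitution model: six GTR exchangeabilities
#' (order AC, AG, AT, CG, CT, GT; the GT entry is the reference and is fixed
#' to 1), stationary base frequencies, a gamma shape parameter for
#' among-site rate heterogeneity (four discrete categories, mean-per-category
#' discretisation) and a proportion of invariant sites. The rate matrix is
#' normalised so that one unit of branch length equals one expected
#' substitution per variable site.
#'
#' @param exch numeric(6), positive exchangeabilities in the order
#'   AC, AG, AT, CG, CT, GT. Rescaled internally so the GT entry is 1.
#' @param freqs numeric(4), stationary frequencies of A, C, G, T; must sum
#'   to 1 (renormalised if within 1e-8).
#' @param gamma_shape positive shape of the gamma rate distribution;
#'   `Inf` disables among-site heterogeneity.
#' @param ncat number of discrete gamma categories (default 4).
#' @param p_inv proportion of invariant sites in `[0, 1]`.
#' @return an object of class `substitution_model`.
#' @examples
#' jc <- substitution_model()            # Jukes-Cantor special case
#' m  <- substitution_model(exch = c(1, 4, 1, 1, 7, 1),
#'                          freqs = c(.30, .18, .15, .37),
#'                          gamma_shape = 0.5, p_inv = 0.2)
#' @export
substitution_model <- function(exch = rep(1, 6), freqs = rep(0.25, 4),
                               gamma_shape = Inf, ncat = 4L, p_inv = 0) {
  exch <- as.numeric(exch)
  freqs <- as.numeric(freqs)
  stopifnot(length(exch) == 6L, length(freqs) == 4L)
  if (any(exch <= 0)) stop("exchangeabilities must be strictly positive")
  if (any(freqs <= 0)) stop("base frequencies must be strictly positive")
  if (abs(sum(freqs) - 1) > 1e-8) stop("base frequencies must sum to 1")
  if (abs(sum(freqs) - 1) > 1e-12) freqs <- freqs / sum(freqs)
  if (!(is.numeric(gamma_shape) && length(gamma_shape) == 1L && gamma_shape > 0))
    stop("gamma_shape must be a single positive number (Inf to disable)")
  if (p_inv < 0 || p_inv > 1) stop("p_inv must lie in [0, 1]")
  exch <- exch / exch[6L]
  names(exch) <- c("AC", "AG", "AT", "CG", "CT", "GT")
  names(freqs) <- c("A", "C", "G", "T")
  structure(list(exch = exch, freqs = freqs, gamma_shape = gamma_shape,
                 ncat = as.integer(ncat), p_inv = p_inv),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("GTR substitution model\n")
  cat("  exchangeabilities:",
      paste(names(x$exch), round(x$exch, 4), sep = "=", collapse = " "), "\n")
  cat("  base frequencies: ",
      paste(names(x$freqs), round(x$freqs, 4), sep = "=", collapse = " "), "\n")
  if (is.finite(x$gamma_shape))
    cat("  gamma shape:       ", x$gamma_shape, " (", x$ncat, " categories)\n", sep = "")
  else cat("  gamma shape:       none (equal rates)\n")
  cat("  p(invariant):      ", x$p_inv, "\n", sep = "")
  invisible(x)
}

# GTR instantaneous rate matrix, normalised to mean rate 1 at stationarity.
gtr_rate_matrix <- function(exch, freqs) {
  R <- matrix(0, 4, 4)
  R[1, 2] <- exch[1]; R[1, 3] <- exch[2]; R[1, 4] <- exch[3]
  R[2, 3] <- exch[4]; R[2, 4] <- exch[5]; R[3, 4] <- exch[6]
  R <- R + t(R)
  Q <- R * rep(freqs, each = 4)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q / mu
}

# Eigendecomposition of the GTR generator via its symmetrised form,
# so that P(t) = A diag(exp(lambda t)) B.
gtr_eigen <- function(model) {
  Q <- gtr_rate_matrix(model$exch, model$freqs)
  d <- sqrt(model$freqs)
  S <- Q * outer(d, 1 / d)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  list(A = e$vectors / d, lambda = e$values, B = t(e$vectors) * rep(d, each = 4),
       Q = Q)
}

# Transition probability matrix for expected substitutions t (per variable site).
transition_probs <- function(eig, t) {
  P <- eig$A %*% (exp(eig$lambda * t) * eig$B)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Discrete gamma rate categories (mean-per-category)
#'
#' Standard discretisation of the mean-1 gamma distribution into `ncat`
#' equal-probability bins, each represented by its conditional mean.
#'
#' @param shape positive gamma shape (`Inf` gives a single category of rate 1).
#' @param ncat number of categories.
#' @return numeric vector of category rates with mean 1.
#' @export
gamma_categories <- function(shape, ncat = 4L) {
  if (!is.finite(shape)) return(1)
  if (ncat == 1L) return(1)
  q <- qgamma(seq_len(ncat - 1L) / ncat, shape = shape, rate = shape)
  p <- c(0, pgamma(q, shape = shape + 1, rate = shape), 1)
  r <- ncat * diff(p)
  r / mean(r)
}
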