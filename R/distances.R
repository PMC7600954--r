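# Pairwise genetic distances and the saturation regression.

#' Uncorrected p-distance between two sequences
#'
#' Proportion of differing sites among sites where both symbols are
#' unambiguous bases (pairwise deletion of gaps and ambiguity codes).
#'
#' @param a,b character vectors of equal length (IUPAC symbols).
#' @return a proportion in `[0, 1]`.
#' @examples
#' p_distance(strsplit("ACGT", "")[[1]], strsplit("ACGA", "")[[1]])  # 0.25
#' @export
p_distance <- function(a, b) {
  if (length(a) != length(b)) stop("sequences must have equal length")
  a <- toupper(a); b <- toupper(b)
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no comparable sites: p-distance undefined")
  mean(a[ok] != b[ok])
}

# Full p-distance matrix via indicator cross-products (fast for many taxa).
p_distance_matrix <- function(aln) {
  m <- encode_states(aln$matrix)
  ntaxa <- nrow(m)
  valid <- m < 4L
  comp <- tcrossprod(valid * 1)
  same <- matrix(0, ntaxa, ntaxa)
  for (s in 0:3) same <- same + tcrossprod((m == s & valid) * 1)
  if (any(comp[upper.tri(comp)] == 0))
    stop("some pairs share no comparable sites: p-distance undefined")
  d <- (comp - same) / comp
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Estimate a GTR model from an alignment
#'
#' Base frequencies are set to the empirical counts; the six
#' exchangeabilities (GT fixed to 1) are maximised by likelihood on a
#' neighbour-joining guide tree built from uncorrected p-distances
#' (the tree and its branch lengths are nuisance parameters). Returns a
#' model without gamma heterogeneity or invariant sites, as used for
#' model-corrected distances.
#'
#' @param aln a [codon_alignment] with at least 3 taxa.
#' @return a [substitution_model].
#' @export
estimate_gtr <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (nrow(aln$matrix) < 3L) stop("need at least 3 taxa to estimate a GTR model")
  if (all(apply(aln$matrix, 2, function(col) length(unique(col[col %in%
      c("A", "C", "G", "T")])) <= 1L)))
    stop("alignment has no variable sites: GTR model is degenerate")
  freqs <- empirical_freqs(aln)
  pd <- p_distance_matrix(aln)
  guide <- ape::nj(as.dist(pd))
  guide$edge.length[guide$edge.length < 1e-8] <- 1e-8
  dat <- phangorn::phyDat(aln$matrix, type = "DNA")
  fit <- phangorn::pml(guide, dat, bf = unname(freqs), k = 1)
  fit <- phangorn::optim.pml(fit, optQ = TRUE, optEdge = TRUE, optBf = FALSE,
                             control = phangorn::pml.control(trace = 0))
  exch <- fit$Q / fit$Q[6]
  substitution_model(exch = exch, freqs = freqs, gamma_shape = Inf, p_inv = 0)
}

#' Model-corrected pairwise distance
#'
#' The branch length maximising the two-sequence likelihood under a fixed
#' substitution model (one-dimensional bounded optimisation). With uniform
#' frequencies and equal exchangeabilities this reduces to the Jukes-Cantor
#' closed form `-(3/4) log(1 - 4p/3)`.
#'
#' @param a,b character vectors of equal length, or a precomputed 4x4
#'   count table passed as `a` with `b = NULL`.
#' @param model a [substitution_model].
#' @param max_distance upper bound; a saturated pair with no interior
#'   optimum returns this bound with a warning and attribute
#'   `saturated = TRUE`.
#' @return non-negative distance (expected substitutions per site).
#' @export
gtr_distance <- function(a, b = NULL, model, max_distance = 10) {
  counts <- if (is.null(b)) a else pair_count_table(a, b)
  if (sum(counts) == 0) stop("no comparable sites: distance undefined")
  if (sum(counts) == sum(diag(counts))) return(0)
  eig <- gtr_eigen(model)
  catrates <- gamma_categories(model$gamma_shape, model$ncat)
  pinv <- model$p_inv
  freqs <- model$freqs
  nll <- function(t) {
    L <- matrix(0, 4, 4)
    for (r in catrates) L <- L + transition_probs(eig, t * r) / length(catrates)
    L <- (1 - pinv) * freqs * L
    if (pinv > 0) diag(L) <- diag(L) + pinv * freqs
    -sum(counts * log(L))
  }
  opt <- optimize(nll, interval = c(0, max_distance), tol = 1e-9)
  d <- opt$minimum
  if (max_distance - d < 1e-4 && nll(max_distance) <= nll(d)) {
    warning("saturated pair: no finite distance optimum, returning max_distance")
    return(structure(max_distance, saturated = TRUE))
  }
  d
}

pair_count_table <- function(a, b) {
  if (length(a) != length(b)) stop("sequences must have equal length")
  bases <- c("A", "C", "G", "T")
  a <- toupper(a); b <- toupper(b)
  ok <- a %in% bases & b %in% bases
  table(factor(a[ok], bases), factor(b[ok], bases))
}

# All-pairs model-corrected distances; returns a symmetric matrix and
# tracks which pairs hit the saturation bound.
gtr_distance_matrix <- function(aln, model, max_distance = 10) {
  m <- aln$matrix
  ntaxa <- nrow(m)
  d <- matrix(0, ntaxa, ntaxa, dimnames = list(rownames(m), rownames(m)))
  sat <- matrix(FALSE, ntaxa, ntaxa)
  for (i in seq_len(ntaxa - 1L)) for (j in (i + 1L):ntaxa) {
    dij <- suppressWarnings(gtr_distance(m[i, ], m[j, ], model = model,
                                         max_distance = max_distance))
    d[i, j] <- d[j, i] <- as.numeric(dij)
    sat[i, j] <- sat[j, i] <- isTRUE(attr(dij, "saturated"))
  }
  attr(d, "saturated") <- sat
  d
}

#' Linear regression through the origin
#'
#' `slope = sum(xy)/sum(x^2)` and the uncentred coefficient of
#' determination `R2 = 1 - sum((y - slope*x)^2)/sum(y^2)` -- the standard
#' definitions for a no-intercept fit.
#'
#' @param x,y numeric vectors of equal length (>= 2); `x` must not be all
#'   zero.
#' @return list with `slope` and `r2`.
#' @export
regression_through_origin <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2")
  if (all(x == 0)) stop("x must not be all zero")
  slope <- sum(x * y) / sum(x * x)
  ssy <- sum(y * y)
  r2 <- if (ssy == 0) 1 else 1 - sum((y - slope * x)^2) / ssy
  list(slope = slope, r2 = r2)
}

#' Saturation regression across codon partitions
#'
#' For each codon partition ({1}, {2}, {3}, {1,2}, {1,2,3}) regresses
#' uncorrected p-distances (y) on model-corrected distances (x) over all
#' taxon pairs, through the origin. Under no saturation the relationship is
#' linear (R2 near 1); saturation makes the uncorrected distances plateau
#' and R2 drops. Emits a codon-3 inclusion recommendation: include codon 3
#' iff `R2({1,2,3}) >= R2({1,2}) - threshold`.
#'
#' @param aln a [codon_alignment] with a codon map.
#' @param model optional [substitution_model]; by default a single GTR model
#'   is estimated once on the full alignment and reused for every partition
#'   and pair.
#' @param threshold tolerated drop in R2 when adding codon 3 (default 0.01).
#' @param max_distance bound passed to [gtr_distance()].
#' @return a data.frame of class `saturation_regression` with one row per
#'   partition (`partition`, `slope`, `r2`, `n_pairs`, `saturated_pairs`,
#'   `low_information`) and attributes `include_codon3`, `threshold`.
#' @export
saturation_regression <- function(aln, model = NULL, threshold = 0.01,
                                  max_distance = 10) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (is.null(model)) model <- estimate_gtr(aln)
  partitions <- list("1" = 1L, "2" = 2L, "3" = 3L,
                     "1+2" = c(1L, 2L), "1+2+3" = 1:3)
  pair_data <- list()
  rows <- lapply(names(partitions), function(nm) {
    sub <- subset_positions(aln, partitions[[nm]])
    y <- tryCatch(p_distance_matrix(sub), error = function(e) NULL)
    if (is.null(y)) {
      warning("partition ", nm, " skipped: no comparable pairs")
      return(data.frame(partition = nm, slope = NA_real_, r2 = NA_real_,
                        n_pairs = 0L, saturated_pairs = 0L,
                        low_information = TRUE))
    }
    x <- gtr_distance_matrix(sub, model, max_distance = max_distance)
    ut <- upper.tri(y)
    xs <- x[ut]; ys <- y[ut]
    if (all(xs == 0)) {
      warning("partition ", nm, " skipped: no variation")
      return(data.frame(partition = nm, slope = NA_real_, r2 = NA_real_,
                        n_pairs = sum(ut), saturated_pairs = 0L,
                        low_information = TRUE))
    }
    labs <- which(ut, arr.ind = TRUE)
    pair_data[[nm]] <<- data.frame(
      partition = nm,
      taxon_a = rownames(y)[labs[, 1]], taxon_b = rownames(y)[labs[, 2]],
      corrected = xs, uncorrected = ys)
    reg <- if (length(xs) == 1L)  # single pair: fits exactly by construction
      list(slope = ys / xs, r2 = 1)
    else regression_through_origin(xs, ys)
    data.frame(partition = nm, slope = reg$slope, r2 = reg$r2,
               n_pairs = sum(ut),
               saturated_pairs = sum(attr(x, "saturated")[ut]),
               low_information = sum(xs > 0) < 2L)
  })
  out <- do.call(rbind, rows)
  r2 <- setNames(out$r2, out$partition)
  include3 <- isTRUE(r2[["1+2+3"]] >= r2[["1+2"]] - threshold)
  attr(out, "include_codon3") <- include3
  attr(out, "threshold") <- threshold
  attr(out, "pairs") <- do.call(rbind, pair_data)   # scatter-plot data
  class(out) <- c("saturation_regression", "data.frame")
  out
}

#' @export
print.saturation_regression <- function(x, ...) {
  cat("Saturation regression (uncorrected vs model-corrected distances)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(if (attr(x, "include_codon3"))
        "Recommendation: include codon position 3"
      else "Recommendation: exclude codon position 3 (saturated)", "\n")
  invisible(x)
}
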