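# Entropy-based index of substitution saturation (Iss) with
# simulation-derived critical values.

#' Shannon entropy of an alignment column
#'
#' `H = -sum f_i log2 f_i` over the unambiguous bases in the column;
#' gaps and ambiguity codes are ignored.
#'
#' @param column character vector of symbols, or a named count vector /
#'   table over A, C, G, T.
#' @return entropy in bits, or `NA` for a column with no unambiguous base.
#' @examples
#' site_entropy(c("A", "A", "C", "G"))   # counts (2,1,1,0) -> 1.5 bits
#' @export
site_entropy <- function(column) {
  bases <- c("A", "C", "G", "T")
  counts <- if (is.character(column))
    table(factor(toupper(column), bases))
  else column[bases]
  counts <- as.numeric(counts)
  counts[is.na(counts)] <- 0
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  f <- counts[counts > 0] / n
  -sum(f * log2(f))
}

# Expected entropy of a fully saturated column: n i.i.d. draws from the
# base frequencies. By linearity over the four bases this only needs
# binomial marginals.
full_saturation_entropy <- function(n, freqs) {
  k <- seq_len(n)
  h <- 0
  for (f in freqs) {
    if (f <= 0) next
    h <- h - sum(dbinom(k, n, f) * (k / n) * log2(k / n))
  }
  h
}

#' Index of substitution saturation (Iss)
#'
#' Mean per-site entropy over the variable fraction of sites, divided by the
#' expected entropy of a fully saturated column (`H_FSS`, computed from the
#' subset's empirical base frequencies for the subset's number of
#' sequences). The invariant fraction contributes zero entropy, so the index
#' is the total column entropy divided by `sites_used x H_FSS` with
#' `sites_used = round((1 - p_inv) * n_sites)`. Iss is 0 for an invariant
#' alignment and close to 1 for fully randomised columns.
#'
#' @param aln a [codon_alignment] with at least 4 taxa.
#' @param p_inv assumed proportion of invariant sites in `[0, 1)`.
#' @return the index (non-negative real).
#' @export
iss <- function(aln, p_inv = 0) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (nrow(aln$matrix) < 4L) stop("Iss needs at least 4 sequences")
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must lie in [0, 1)")
  hs <- apply(aln$matrix, 2, site_entropy)
  if (sum(hs, na.rm = TRUE) == 0) return(0)   # invariant alignment
  freqs <- empirical_freqs(aln)
  h_fss <- full_saturation_entropy(nrow(aln$matrix), freqs)
  if (h_fss <= 0) stop("degenerate base frequencies: H_FSS is zero")
  sites_used <- iss_sites_used(ncol(aln$matrix), p_inv)
  sum(hs, na.rm = TRUE) / (sites_used * h_fss)
}

iss_sites_used <- function(n_sites, p_inv) {
  s <- as.integer(round((1 - p_inv) * n_sites))
  if (s < 1L) stop("p_inv leaves no sites for the Iss test")
  s
}

#' Jackknifed Iss over random taxon subsets
#'
#' Mean and standard error of [iss()] over `replicates` seeded random
#' subsets of `num_otu` taxa drawn without replacement, as in the standard
#' saturation-test battery.
#'
#' @param aln a [codon_alignment].
#' @param num_otu subset size (<= number of taxa).
#' @param replicates number of jackknife replicates (>= 2).
#' @param p_inv assumed proportion of invariant sites.
#' @param seed integer seed; results are reproducible bit-for-bit.
#' @return list with `mean`, `se` and the per-replicate `values`.
#' @export
iss_jackknife <- function(aln, num_otu, replicates = 100L, p_inv = 0,
                          seed = 1L) {
  ntaxa <- nrow(aln$matrix)
  if (num_otu > ntaxa) stop("num_otu exceeds the number of taxa")
  if (num_otu < 4L) stop("num_otu must be at least 4")
  if (replicates < 2L) stop("need at least 2 replicates")
  vals <- with_seed(seed, vapply(seq_len(replicates), function(i) {
    rows <- sample.int(ntaxa, num_otu)
    iss(codon_alignment(aln$matrix[rows, , drop = FALSE], aln$codon_map),
        p_inv = p_inv)
  }, 0))
  list(mean = mean(vals), se = sd(vals) / sqrt(replicates), values = vals)
}

# Ultrametric test topologies for the critical-value simulation:
# "sym" = balanced binary tree, "asym" = caterpillar. Root-to-tip expected
# substitutions equal `depth`.
shaped_tree <- function(num_otu, shape = c("sym", "asym"), depth) {
  shape <- match.arg(shape)
  phy <- ape::stree(num_otu, type = if (shape == "sym") "balanced" else "left")
  phy$edge.length <- rep(1, nrow(phy$edge))
  ntip <- num_otu
  # height of a node = max edge-steps down to a tip, scaled to `depth`
  post <- ape::reorder.phylo(phy, "postorder")
  steps <- numeric(ntip + phy$Nnode)
  for (e in seq_len(nrow(post$edge)))
    steps[post$edge[e, 1]] <- max(steps[post$edge[e, 1]],
                                  steps[post$edge[e, 2]] + 1)
  h <- steps / steps[ntip + 1L] * depth
  h[seq_len(ntip)] <- 0
  tt <- timetree(phy, heights = h)
  tt$rates <- rep(1, nrow(phy$edge))
  tt
}

jc_corrected_dist <- function(pd, cap = 5) {
  x <- 1 - 4 * pd / 3
  d <- ifelse(x > 0, -0.75 * log(pmax(x, 1e-12)), cap)
  pmin(d, cap)
}

#' Simulation-derived critical Iss value
#'
#' Estimates the Iss value at which neighbour-joining recovery of the true
#' topology drops to `reliability` (default 0.95). Alignments are simulated
#' on a balanced ("sym") or caterpillar ("asym") ultrametric topology under
#' an equal-exchangeability model with the supplied base frequencies, over a
#' grid of increasing tree depths; the recovery frequency and mean observed
#' Iss are interpolated at the crossing point. If the grid never crosses the
#' threshold the boundary Iss is returned with a warning.
#'
#' @param num_otu one of 4, 8, 16, 32.
#' @param n_sites alignment length (>= 100).
#' @param freqs base frequencies used in the simulation.
#' @param topology_shape `"sym"` or `"asym"`.
#' @param seed integer seed.
#' @param reliability recovery threshold defining the critical value.
#' @param replicates simulated alignments per depth.
#' @param depths grid of root-to-tip expected substitutions.
#' @return the critical Iss value (attributes carry the grid summaries).
#' @export
iss_critical <- function(num_otu, n_sites, freqs = rep(0.25, 4),
                         topology_shape = c("sym", "asym"), seed = 1L,
                         reliability = 0.95, replicates = 40L,
                         depths = exp(seq(log(0.03), log(3), length.out = 8))) {
  topology_shape <- match.arg(topology_shape)
  if (!num_otu %in% c(4L, 8L, 16L, 32L)) stop("num_otu must be 4, 8, 16 or 32")
  if (n_sites < 100) stop("n_sites must be at least 100")
  model <- substitution_model(freqs = freqs, gamma_shape = Inf, p_inv = 0)
  n_sim <- 3L * ceiling(n_sites / 3)
  rec <- iss_mean <- numeric(length(depths))
  for (k in seq_along(depths)) {
    tt <- shaped_tree(num_otu, topology_shape, depths[k])
    true_unrooted <- ape::unroot(tt$phylo)
    res <- vapply(seq_len(replicates), function(r) {
      aln <- simulate_alignment(tt, model, n_sim,
                                seed = seed + 7919L * k + r)
      pd <- p_distance_matrix(aln)
      est <- ape::nj(as.dist(jc_corrected_dist(pd)))
      ok <- tryCatch(ape::dist.topo(true_unrooted, est) == 0,
                     error = function(e) FALSE)
      c(ok, iss(aln, p_inv = 0))
    }, c(0, 0))
    rec[k] <- mean(res[1, ])
    iss_mean[k] <- mean(res[2, ])
  }
  # recovery decays with depth but is noisy near the shallow end; take the
  # deepest grid point still meeting the reliability threshold and
  # interpolate towards the next (failing) one
  above <- which(rec >= reliability)
  if (!length(above)) {
    warning("recovery below threshold over the whole grid; ",
            "returning the boundary Iss")
    val <- iss_mean[1L]
  } else if (max(above) == length(depths)) {
    warning("recovery never fell below the reliability threshold; ",
            "returning Iss at the deepest grid point")
    val <- iss_mean[length(depths)]
  } else {
    i <- max(above)
    f <- (rec[i] - reliability) / (rec[i] - rec[i + 1L])
    val <- iss_mean[i] + f * (iss_mean[i + 1L] - iss_mean[i])
  }
  structure(val, recovery = rec, iss_grid = iss_mean, depths = depths)
}

#' Substitution saturation test battery
#'
#' For each OTU subset size, jackknifes the observed Iss and compares it to
#' the critical value under symmetrical and asymmetrical topologies with a
#' two-sided one-sample t statistic `t = |Iss.c - mean(Iss)| / SE` on
#' `sites_used - 1` degrees of freedom. Saturation is rejected for a subset
#' when the observed Iss is significantly below Iss.c.
#'
#' @param aln a [codon_alignment] (>= 32 taxa for the full battery; smaller
#'   batteries use the subset sizes that fit).
#' @param p_inv assumed proportion of invariant sites.
#' @param seed integer seed.
#' @param num_otus OTU subset sizes to test.
#' @param replicates jackknife replicates per subset size.
#' @param iss_c optional precomputed critical values: a data.frame with
#'   columns `num_otu`, `sym`, `asym` (skips the critical-value simulation).
#' @param crit_replicates,crit_sites,depths passed to [iss_critical()].
#' @return data.frame of class `iss_test` with one row per subset size:
#'   `num_otu`, `iss_mean`, `iss_se`, `iss_c_sym`, `t_sym`, `df`, `p_sym`,
#'   `iss_c_asym`, `t_asym`, `p_asym`, `verdict_sym`, `verdict_asym`.
#' @export
iss_test <- function(aln, p_inv = 0, seed = 1L,
                     num_otus = c(4L, 8L, 16L, 32L), replicates = 100L,
                     iss_c = NULL, crit_replicates = 30L,
                     crit_sites = NULL,
                     depths = exp(seq(log(0.03), log(3), length.out = 8))) {
  stopifnot(inherits(aln, "codon_alignment"))
  ntaxa <- nrow(aln$matrix)
  num_otus <- num_otus[num_otus <= ntaxa]
  if (!length(num_otus)) stop("alignment too small for any OTU subset")
  n_sites <- ncol(aln$matrix)
  sites_used <- iss_sites_used(n_sites, p_inv)
  df <- sites_used - 1L
  freqs <- empirical_freqs(aln)
  if (is.null(crit_sites)) crit_sites <- max(100L, min(n_sites, 600L))
  rows <- lapply(seq_along(num_otus), function(i) {
    no <- num_otus[i]
    jk <- iss_jackknife(aln, no, replicates = replicates, p_inv = p_inv,
                        seed = seed + i)
    if (is.null(iss_c)) {
      c_sym <- as.numeric(iss_critical(no, crit_sites, freqs, "sym",
                                       seed = seed + 100L + i,
                                       replicates = crit_replicates,
                                       depths = depths))
      c_asym <- as.numeric(iss_critical(no, crit_sites, freqs, "asym",
                                        seed = seed + 200L + i,
                                        replicates = crit_replicates,
                                        depths = depths))
    } else {
      j <- match(no, iss_c$num_otu)
      if (is.na(j)) stop("iss_c table is missing num_otu = ", no)
      c_sym <- iss_c$sym[j]; c_asym <- iss_c$asym[j]
    }
    tstat <- function(crit) {
      if (jk$se == 0) {
        if (jk$mean == crit) 0 else Inf
      } else abs(crit - jk$mean) / jk$se
    }
    t_sym <- tstat(c_sym); t_asym <- tstat(c_asym)
    p_sym <- if (is.infinite(t_sym)) 0 else 2 * pt(-t_sym, df)
    p_asym <- if (is.infinite(t_asym)) 0 else 2 * pt(-t_asym, df)
    verdict <- function(crit, t, p) {
      if (jk$mean < crit && p < 0.05) "saturation rejected"
      else if (p >= 0.05) "inconclusive"
      else "significant saturation"
    }
    data.frame(num_otu = no, iss_mean = jk$mean, iss_se = jk$se,
               iss_c_sym = c_sym, t_sym = t_sym, df = df, p_sym = p_sym,
               iss_c_asym = c_asym, t_asym = t_asym, p_asym = p_asym,
               verdict_sym = verdict(c_sym, t_sym, p_sym),
               verdict_asym = verdict(c_asym, t_asym, p_asym))
  })
  out <- do.call(rbind, rows)
  attr(out, "p_inv") <- p_inv
  attr(out, "sites_used") <- sites_used
  class(out) <- c("iss_test", "data.frame")
  out
}

#' @export
print.iss_test <- function(x, ...) {
  cat("Substitution saturation test (Iss vs critical Iss)\n")
  cat("p_inv =", attr(x, "p_inv"), "| sites used =", attr(x, "sites_used"), "\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
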