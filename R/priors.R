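# Tree and clock priors.

# Number of internal nodes in the subtree rooted at each internal node.
# The product of these counts is the normalising constant linking the
# i.i.d.-exponential construction to the per-topology height density
# (hook-length formula for linear extensions of the height ordering).
internal_subtree_sizes <- function(phy) {
  ntip <- length(phy$tip.label)
  post <- ape::reorder.phylo(phy, "postorder")
  s <- integer(ntip + phy$Nnode)
  s[(ntip + 1L):(ntip + phy$Nnode)] <- 1L
  for (e in seq_len(nrow(post$edge))) {
    ch <- post$edge[e, 2L]
    if (ch > ntip) s[post$edge[e, 1L]] <- s[post$edge[e, 1L]] + s[ch]
  }
  s[(ntip + 1L):(ntip + phy$Nnode)]
}

#' Yule (pure-birth) log prior on node heights
#'
#' Log density of the internal node heights of an ultrametric tree under the
#' ranked pure-birth prior used throughout the package: the n-1 node heights
#' are the descending order statistics of i.i.d. Exponential(birth_rate)
#' draws, assigned to internal nodes by a uniformly chosen ranking compatible
#' with the topology. For a fixed topology the density is
#' `prod_v s_v * prod_i lambda exp(-lambda h_i)` on the region where every
#' parent is above its children, with `s_v` the number of internal nodes in
#' the subtree of `v`; it integrates to 1 over that region. For two tips the
#' root height is Exponential(lambda). [simulate_yule_tree()] samples from
#' exactly this distribution.
#'
#' @param tree an ultrametric [timetree] (tips at height 0).
#' @param birth_rate positive birth rate.
#' @return the log prior density.
#' @export
yule_log_prior <- function(tree, birth_rate) {
  stopifnot(inherits(tree, "timetree"))
  if (birth_rate <= 0) stop("birth_rate must be positive")
  ntip <- length(tree$phylo$tip.label)
  h <- tree$heights[(ntip + 1L):length(tree$heights)]
  sum(log(internal_subtree_sizes(tree$phylo))) +
    sum(log(birth_rate) - birth_rate * h)
}

# Same density from raw pieces (used inside the MCMC loop).
yule_log_prior_heights <- function(h_internal, birth_rate, log_const) {
  log_const + length(h_internal) * log(birth_rate) - birth_rate * sum(h_internal)
}

#' Log density of branch rates under the mean-1 lognormal clock prior
#'
#' Sum of lognormal log densities with `meanlog = -ucld_stdev^2/2` and
#' `sdlog = ucld_stdev`, so the real-space mean is exactly 1 for every
#' spread. At `ucld_stdev = 0` the prior degenerates to a point mass at 1:
#' the log density is 0 if all rates equal 1 and `-Inf` otherwise.
#'
#' @param rates positive branch rates.
#' @param ucld_stdev non-negative lognormal spread.
#' @return the log density.
#' @export
rate_prior_logdensity <- function(rates, ucld_stdev) {
  if (ucld_stdev < 0) stop("ucld_stdev must be non-negative")
  if (any(rates <= 0)) stop("rates must be strictly positive")
  if (ucld_stdev == 0) return(if (all(rates == 1)) 0 else -Inf)
  sum(dlnorm(rates, meanlog = -ucld_stdev^2 / 2, sdlog = ucld_stdev, log = TRUE))
}
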