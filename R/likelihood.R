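# Felsenstein pruning likelihood (R surface over the C++ kernel).

# Precompute the immutable structures the kernel needs: site patterns in the
# tree's tip order and the postorder edge traversal. `edge_order` maps
# postorder edge rows back to rows of tt$phylo$edge so per-branch rates can
# be realigned cheaply inside the MCMC.
likelihood_structure <- function(tree, aln) {
  phy <- tree$phylo
  pat <- alignment_patterns(aln, taxa = phy$tip.label)
  ntip <- length(phy$tip.label)
  edge <- phy$edge
  erow <- integer(ntip + phy$Nnode)
  erow[edge[, 2]] <- seq_len(nrow(edge))
  # internal nodes ordered children-before-parents (ascending subtree size)
  int_ids <- (ntip + 1L):(ntip + phy$Nnode)
  sizes <- vapply(phangorn::Descendants(phy, int_ids, type = "tips"),
                  length, 1L)
  node_order <- int_ids[order(sizes)]
  nodes <- t(vapply(node_order, function(v) {
    ch <- edge[edge[, 1] == v, 2]
    c(v, ch[1], ch[2], erow[ch[1]], erow[ch[2]])
  }, integer(5)))
  list(states = pat$states, weights = pat$weights, compat = pat$compat,
       nodes = nodes, ntip = ntip)
}

loglik_kernel <- function(struct, elen, eig, catrates, p_inv, freqs) {
  pruning_loglik_cpp(struct$states, struct$weights, struct$nodes, elen,
                     eig$A, eig$lambda, eig$B, freqs, catrates, p_inv,
                     struct$compat)
}

#' Phylogenetic log-likelihood by the pruning algorithm
#'
#' Log-likelihood of an alignment on a rate-annotated time tree under
#' GTR+Gamma+I, computed by postorder partial likelihoods with per-node
#' rescaling. The expected number of substitutions on a branch is
#' branch rate x time span (x gamma category rate for variable sites).
#' Symbols other than A/C/G/T are treated as missing data.
#'
#' @param tree a [timetree] with branch rates.
#' @param model a [substitution_model].
#' @param aln a [codon_alignment] whose taxa include the tree's tips.
#' @return the log-likelihood (a single number).
#' @examples
#' d <- simulate_dataset(n_tips = 6, n_sites = 300, seed = 1)
#' pruning_loglik(d$truth$tree, d$truth$model, d$aln)
#' @export
pruning_loglik <- function(tree, model, aln) {
  stopifnot(inherits(tree, "timetree"), inherits(model, "substitution_model"),
            inherits(aln, "codon_alignment"))
  if (is.null(tree$rates)) stop("branch rates have not been assigned")
  missing <- setdiff(tree$phylo$tip.label, taxa_labels(aln))
  if (length(missing))
    stop("alignment is missing taxa: ", paste(missing, collapse = ", "))
  struct <- likelihood_structure(tree, aln)
  eig <- gtr_eigen(model)
  elen <- tree$rates * edge_timespans(tree)
  loglik_kernel(struct, elen, eig, gamma_categories(model$gamma_shape, model$ncat),
                model$p_inv, model$freqs)
}
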