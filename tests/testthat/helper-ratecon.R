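# Shared fixtures, all generated in code.

# tiny hand-made alignment
toy_alignment <- function() {
  m <- rbind(t1 = c("A", "C", "G", "T", "A", "C"),
             t2 = c("A", "C", "G", "T", "A", "T"),
             t3 = c("A", "C", "G", "A", "C", "T"),
             t4 = c("A", "C", "T", "A", "C", "T"))
  codon_alignment(m)
}

# a small rate-annotated time tree built by hand:
# ((t1,t2),t3); cherry at height 1, root at height 3
toy_timetree <- function(rates = c(1, 1, 1, 1)) {
  phy <- ape::read.tree(text = "((t1:1,t2:1):2,t3:3);")
  timetree(phy, rates = rates)
}

# brute-force pruning likelihood by exhaustive enumeration of internal
# states, including gamma categories and the invariant-site class
brute_force_loglik <- function(tree, model, aln) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  eig <- ratecon:::gtr_eigen(model)
  cr <- gamma_categories(model$gamma_shape, model$ncat)
  spans <- ratecon:::edge_timespans(tree)
  m <- ratecon:::encode_states(aln$matrix)[phy$tip.label, , drop = FALSE] + 1L
  nnode <- phy$Nnode
  total <- 0
  for (s in seq_len(ncol(m))) {
    sitelik <- 0
    for (ci in seq_along(cr)) {
      P <- lapply(seq_len(nrow(phy$edge)), function(e)
        ratecon:::transition_probs(eig, tree$rates[e] * spans[e] * cr[ci]))
      grid <- do.call(expand.grid, rep(list(1:4), nnode))
      lik <- 0
      for (g in seq_len(nrow(grid))) {
        st <- c(m[, s], as.integer(grid[g, ]))
        pr <- model$freqs[st[ntip + 1]]
        for (e in seq_len(nrow(phy$edge))) {
          b <- st[phy$edge[e, 2]]
          if (b == 5) next
          pr <- pr * P[[e]][st[phy$edge[e, 1]], b]
        }
        lik <- lik + pr
      }
      sitelik <- sitelik + lik / length(cr)
    }
    obs <- m[, s]; obs <- obs[obs < 5]
    inv <- if (length(unique(obs)) <= 1) {
      if (length(obs)) model$freqs[obs[1]] else 1
    } else 0
    total <- total + log((1 - model$p_inv) * sitelik + model$p_inv * inv)
  }
  as.numeric(total)
}

# exhaustive shortest-window HPD (oracle for hpd_interval)
brute_force_hpd <- function(x, prob = 0.95) {
  s <- sort(x)
  n <- length(s)
  m <- ceiling(prob * n)
  if (m >= n) return(c(s[1], s[n]))
  best <- c(s[1], s[m]); bw <- s[m] - s[1]
  for (i in seq_len(n - m + 1)) {
    w <- s[i + m - 1] - s[i]
    if (w < bw) { bw <- w; best <- c(s[i], s[i + m - 1]) }
  }
  best
}

# study dataset on the packaged deep-crown topology
deep_crown_dataset <- function(seed, n_sites = 900, multiplier = NULL,
                               ucld_stdev = 0) {
  tt <- deep_crown_tree()
  clades <- attr(tt, "clades")
  tt <- assign_branch_rates(tt, ucld_stdev, multiplier, clades, seed = seed)
  aln <- simulate_alignment(tt, coi_like_model(), n_sites,
                            partition_multipliers = c(0.45, 0.15, 2.40),
                            seed = seed + 1000L)
  list(tree = tt, aln = aln, clades = clades)
}
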