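test_that("two-sequence JC log-likelihood matches the closed form", {
  phy <- ape::read.tree(text = "(t1:1,t2:1);")
  tt <- timetree(phy, heights = c(0, 0, 0.21), rates = c(1, 1))
  jc <- substitution_model()
  aln <- simulate_alignment(tt, jc, 999, seed = 71)
  d <- 0.42                               # total path length between the tips
  n_same <- sum(aln$matrix[1, ] == aln$matrix[2, ])
  n_diff <- 999 - n_same
  closed <- n_same * log(0.25 * (0.25 + 0.75 * exp(-4 * d / 3))) +
    n_diff * log(0.25 * (0.25 - 0.25 * exp(-4 * d / 3)))
  expect_equal(pruning_loglik(tt, jc, aln), closed, tolerance = 1e-8)
})

test_that("pruning equals exhaustive ancestral-state enumeration (GTR+G+I)", {
  for (n in 4:5) {
    d <- simulate_dataset(n_tips = n, n_sites = 45, ucld_stdev = 0.4,
                          seed = 70 + n)
    ll <- pruning_loglik(d$truth$tree, d$truth$model, d$aln)
    oracle <- brute_force_loglik(d$truth$tree, d$truth$model, d$aln)
    expect_equal(ll, oracle, tolerance = 1e-8)
  }
})

test_that("enumeration oracle also covers missing data", {
  d <- simulate_dataset(n_tips = 4, n_sites = 30, seed = 77)
  d$aln$matrix[1, 1:5] <- "-"
  d$aln$matrix[2, 3:8] <- "N"
  expect_equal(pruning_loglik(d$truth$tree, d$truth$model, d$aln),
               brute_force_loglik(d$truth$tree, d$truth$model, d$aln),
               tolerance = 1e-8)
})

test_that("the pulley principle holds at the root", {
  # with a reversible model the likelihood depends on the two root-adjacent
  # branches only through the sum of their expected substitutions
  d <- simulate_dataset(n_tips = 6, n_sites = 201, seed = 79)
  tt <- d$truth$tree
  root_edges <- which(tt$phylo$edge[, 1] == 7L)
  spans <- ratecon:::edge_timespans(tt)
  total <- sum(tt$rates[root_edges] * spans[root_edges])
  ll0 <- pruning_loglik(tt, d$truth$model, d$aln)
  for (f in c(0.25, 0.6, 0.9)) {
    tt2 <- tt
    tt2$rates[root_edges[1]] <- f * total / spans[root_edges[1]]
    tt2$rates[root_edges[2]] <- (1 - f) * total / spans[root_edges[2]]
    expect_equal(pruning_loglik(tt2, d$truth$model, d$aln), ll0,
                 tolerance = 1e-8)
  }
})

test_that("pruning agrees with an independent likelihood implementation", {
  m <- substitution_model(exch = c(2, 5, 1, 1.5, 6, 1),
                          freqs = c(.3, .2, .2, .3), gamma_shape = .7,
                          p_inv = 0)
  d <- simulate_dataset(n_tips = 8, n_sites = 600, model = m, seed = 80)
  tt <- d$truth$tree
  phy <- tt$phylo
  phy$edge.length <- tt$rates * ratecon:::edge_timespans(tt)
  fit <- phangorn::pml(ape::unroot(phy),
                       phangorn::phyDat(d$aln$matrix, type = "DNA"),
                       bf = unname(m$freqs), Q = unname(m$exch),
                       k = 4, shape = 0.7)
  expect_equal(pruning_loglik(tt, m, d$aln), fit$logLik, tolerance = 1e-6)
})

test_that("a taxon mismatch is reported with the offending names", {
  d <- simulate_dataset(n_tips = 5, n_sites = 30, seed = 81)
  rownames(d$aln$matrix)[2] <- "other"
  expect_error(pruning_loglik(d$truth$tree, d$truth$model, d$aln), "t2")
})
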