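test_that("Yule tree simulation matches the pure-birth root-height law", {
  # n = 2: root height is Exponential(birth_rate) with mean 1/birth_rate
  lambda <- 2
  h <- vapply(1:3000, function(i)
    simulate_yule_tree(2, lambda, seed = i)$heights[3], 0)
  expect_equal(mean(h), 1 / lambda, tolerance = 4 / sqrt(3000) / lambda)
})

test_that("Yule trees are binary, ultrametric and reproducible", {
  tt <- simulate_yule_tree(8, 1, seed = 42)
  expect_equal(tt$phylo$Nnode, 7)          # n - 1 internal nodes
  expect_equal(nrow(tt$phylo$edge), 14)    # 2n - 2 branches
  expect_true(all(tt$heights[1:8] == 0))
  expect_identical(write_timetree(simulate_yule_tree(8, 1, seed = 7)),
                   write_timetree(simulate_yule_tree(8, 1, seed = 7)))
  expect_false(identical(write_timetree(simulate_yule_tree(8, 1, seed = 7)),
                         write_timetree(simulate_yule_tree(8, 1, seed = 8))))
  expect_error(simulate_yule_tree(1, 1, 1), "at least 2")
})

test_that("branch rates follow the mean-1 lognormal with crown-only multipliers", {
  tt <- toy_timetree()
  # degenerate spread: every rate exactly 1
  r0 <- assign_branch_rates(tt, 0, seed = 1)$rates
  expect_identical(r0, rep(1, 4))
  # multiplier applies to crown branches of the clade only, not its stem
  clades <- list(AB = c("t1", "t2"))
  r3 <- assign_branch_rates(tt, 0, c(AB = 3), clades, seed = 1)$rates
  crown <- clade_edges(tt, c("t1", "t2"))
  expect_equal(unname(r3[crown]), rep(3, 2))
  expect_equal(unname(r3[-crown]), rep(1, 2))
  expect_error(assign_branch_rates(tt, 0, c(XX = 2), clades, seed = 1),
               "not defined")
  # lognormal real-space mean is 1: Monte-Carlo over ~10^4 branches
  big <- simulate_yule_tree(5001, 1, seed = 3)
  rb <- assign_branch_rates(big, 0.5, seed = 4)$rates
  expect_equal(mean(rb), 1, tolerance = 4 * sd(rb) / sqrt(length(rb)))
})

test_that("simulated divergence matches the Jukes-Cantor expectation", {
  # two taxa, rate x time = 0.3043 -> expected p-distance 0.25
  phy <- ape::read.tree(text = "(t1:1,t2:1);")
  tt <- timetree(phy, heights = c(0, 0, 0.30435), rates = c(0.5, 0.5))
  aln <- simulate_alignment(tt, substitution_model(), 99999, seed = 9)
  expect_equal(p_distance(aln$matrix[1, ], aln$matrix[2, ]), 0.25,
               tolerance = 0.006)
})

test_that("degenerate simulations behave as expected", {
  tt <- toy_timetree()
  m <- coi_like_model()
  # all sites invariant
  inv <- simulate_alignment(tt, substitution_model(p_inv = 1), 300, seed = 2)
  expect_true(all(apply(inv$matrix, 2, function(col) length(unique(col)) == 1)))
  # (near-)zero total tree length: sequences identical to the root draw
  tt0 <- tt; tt0$rates <- rep(1e-12, 4)
  a0 <- simulate_alignment(tt0, m, 300, seed = 3)
  expect_true(all(a0$matrix[1, ] == a0$matrix[2, ]) &&
                all(a0$matrix[1, ] == a0$matrix[3, ]))
  expect_error(simulate_alignment(tt, m, 100, seed = 1), "divisible by 3")
  tt_bare <- toy_timetree(); tt_bare$rates <- NULL
  expect_error(simulate_alignment(tt_bare, m, 300, seed = 1), "rates")
})

test_that("empirical base frequencies converge to the stationary distribution", {
  m <- substitution_model(exch = c(1, 4, 1, 1, 7, 1),
                          freqs = c(.30, .18, .15, .37), gamma_shape = 0.5)
  tt <- assign_branch_rates(simulate_yule_tree(8, 1, seed = 5), 0.2, seed = 6)
  aln <- simulate_alignment(tt, m, 30000, seed = 7)
  counts <- table(factor(aln$matrix, c("A", "C", "G", "T")))
  expect_lt(max(abs(counts / sum(counts) - m$freqs)), 0.01)
})

test_that("pairwise model-corrected distances recover patristic path lengths", {
  m <- coi_like_model()
  tt <- assign_branch_rates(simulate_yule_tree(6, 1, seed = 11), 0, seed = 11)
  aln <- simulate_alignment(tt, m, 30000, seed = 12)
  phy <- tt$phylo
  patristic <- ape::cophenetic.phylo(phy)
  for (pair in list(c("t1", "t2"), c("t2", "t5"))) {
    d <- gtr_distance(aln$matrix[pair[1], ], aln$matrix[pair[2], ], model = m)
    truth <- patristic[pair[1], pair[2]]
    expect_equal(as.numeric(d), truth, tolerance = 0.05 * truth)
  }
})

test_that("the truth record round-trips through its file serialisation", {
  d <- simulate_dataset(n_tips = 10, n_sites = 30, ucld_stdev = 0.3,
                        clade_multipliers = c(A = 2.5), seed = 21)
  f1 <- tempfile(); f2 <- tempfile()
  write_truth(d$truth, f1)
  tr2 <- read_truth(f1)
  write_truth(tr2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(tr2$tree$rates, d$truth$tree$rates)
  expect_identical(tr2$clades, d$truth$clades)
})
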