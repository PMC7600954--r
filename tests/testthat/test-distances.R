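test_that("p-distance uses pairwise deletion and is a proper dissimilarity", {
  expect_equal(p_distance(strsplit("ACGT", "")[[1]], strsplit("ACGT", "")[[1]]), 0)
  expect_equal(p_distance(strsplit("ACGT", "")[[1]], strsplit("ACGA", "")[[1]]), 0.25)
  expect_equal(p_distance(strsplit("AC-T", "")[[1]], strsplit("ACGA", "")[[1]]), 1 / 3)
  # ambiguity codes are treated as missing
  expect_equal(p_distance(c("A", "N", "G"), c("A", "C", "G")), 0)
  expect_error(p_distance(c("-", "N"), c("A", "C")), "comparable")
  # symmetry on random pairs
  set.seed(1)
  for (i in 1:10) {
    a <- sample(c("A", "C", "G", "T", "-"), 60, TRUE)
    b <- sample(c("A", "C", "G", "T", "-"), 60, TRUE)
    expect_identical(p_distance(a, b), p_distance(b, a))
  }
})

test_that("model-corrected distance reduces to the Jukes-Cantor closed form", {
  jc <- substitution_model()
  for (p in seq(0.05, 0.70, by = 0.05)) {
    # build a pair count table realising exactly proportion p of differences
    n <- 10000
    counts <- matrix(p * n / 12, 4, 4)
    diag(counts) <- (1 - p) * n / 4
    d <- gtr_distance(counts, model = jc)
    expect_equal(as.numeric(d), -0.75 * log(1 - 4 * p / 3), tolerance = 1e-6)
  }
  expect_equal(gtr_distance(c("A", "C", "G"), c("A", "C", "G"), model = jc), 0)
})

test_that("model-corrected distance is monotone in the p-distance and flags saturation", {
  jc <- substitution_model()
  ps <- seq(0.05, 0.7, by = 0.05)
  ds <- vapply(ps, function(p) {
    counts <- matrix(p * 1200 / 12, 4, 4); diag(counts) <- (1 - p) * 1200 / 4
    as.numeric(gtr_distance(counts, model = jc))
  }, 0)
  expect_true(all(diff(ds) > 0))
  # brute-force grid optimisation agrees
  eig <- ratecon:::gtr_eigen(jc)
  counts <- matrix(0.4 * 1200 / 12, 4, 4); diag(counts) <- 0.6 * 1200 / 4
  grid <- seq(0.001, 5, by = 0.0005)
  ll <- vapply(grid, function(t)
    sum(counts * log(0.25 * ratecon:::transition_probs(eig, t))), 0)
  expect_equal(as.numeric(gtr_distance(counts, model = jc)),
               grid[which.max(ll)], tolerance = 1e-3)
  # a saturated pair hits the configured maximum with a warning
  counts <- matrix(100, 4, 4); diag(counts) <- 5
  expect_warning(d <- gtr_distance(counts, model = jc, max_distance = 8),
                 "saturated")
  expect_equal(as.numeric(d), 8)
})

test_that("GTR estimation recovers simulated exchangeabilities", {
  m <- substitution_model(exch = c(1, 4, 1, 1, 7, 1),
                          freqs = c(.30, .18, .15, .37))
  tt <- assign_branch_rates(simulate_yule_tree(8, 1, seed = 31), 0, seed = 31)
  tt$heights <- tt$heights * 0.5
  tt <- timetree(tt$phylo, tt$heights, tt$rates)
  aln <- simulate_alignment(tt, m, 30000, seed = 32)
  est <- estimate_gtr(aln)
  expect_equal(unname(est$exch), unname(m$exch), tolerance = 0.10)
  expect_equal(unname(est$freqs), unname(m$freqs), tolerance = 0.02)
})

test_that("JC-simulated data give approximately equal exchangeabilities", {
  tt <- assign_branch_rates(simulate_yule_tree(8, 1, seed = 33), 0, seed = 33)
  tt$heights <- tt$heights * 0.5
  tt <- timetree(tt$phylo, tt$heights, tt$rates)
  aln <- simulate_alignment(tt, substitution_model(), 21000, seed = 34)
  est <- estimate_gtr(aln)
  expect_lt(max(est$exch) / min(est$exch), 1.35)
})

test_that("an invariant alignment is rejected as a degenerate model", {
  m <- matrix("A", 4, 60, dimnames = list(paste0("t", 1:4), NULL))
  m[, 1:30] <- "C"
  expect_error(estimate_gtr(codon_alignment(m)), "degenerate|variable")
})

test_that("regression through the origin follows the stated formulas", {
  r <- regression_through_origin(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$slope, 2); expect_equal(r$r2, 1)
  r <- regression_through_origin(c(1, 2, 3), c(1, 2, 4))
  expect_equal(r$slope, 17 / 14, tolerance = 1e-12)
  expect_equal(r$r2, 1 - (70 / 196) / 21, tolerance = 1e-12)
  expect_error(regression_through_origin(c(0, 0), c(1, 2)), "zero")
  # invariance under common positive rescaling of x and y
  set.seed(4)
  x <- runif(20); y <- 2 * x + rnorm(20, 0, .1)
  r1 <- regression_through_origin(x, y)
  r2 <- regression_through_origin(3.7 * x, 3.7 * y)
  expect_equal(r1$r2, r2$r2, tolerance = 1e-12)
})

test_that("saturation regression distinguishes clean from saturated codon positions", {
  # near-linear regime: short tree, mild heterogeneity
  m <- substitution_model(exch = c(1, 3, 1, 1, 5, 1), freqs = c(.3, .2, .2, .3))
  tt <- assign_branch_rates(simulate_yule_tree(10, 1, seed = 41), 0, seed = 41)
  tt <- timetree(tt$phylo, tt$heights * 0.1 / tt$heights[11], rep(1, 18))
  aln <- simulate_alignment(tt, m, 1200, seed = 42)
  reg <- saturation_regression(aln, model = m)
  expect_true(all(reg$r2 > 0.99))
  expect_true(attr(reg, "include_codon3"))
})

test_that("a two-taxon alignment is flagged as low-information", {
  phy <- ape::read.tree(text = "(t1:1,t2:1);")
  tt <- timetree(phy, heights = c(0, 0, 0.2), rates = c(1, 1))
  aln <- simulate_alignment(tt, substitution_model(), 300, seed = 43)
  reg <- saturation_regression(aln, model = substitution_model())
  expect_true(all(reg$low_information))
  expect_true(all(abs(reg$r2 - 1) < 1e-9))  # single point: R2 = 1 by construction
})
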