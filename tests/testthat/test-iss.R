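test_that("site entropy follows the Shannon formula over unambiguous bases", {
  expect_equal(site_entropy(rep("A", 8)), 0)
  expect_equal(site_entropy(c("A", "C", "G", "T")), 2)
  expect_equal(site_entropy(c("A", "A", "C", "G")), 1.5)   # counts (2,1,1,0)
  expect_equal(site_entropy(c(A = 2, C = 1, G = 1, T = 0)), 1.5)
  expect_equal(site_entropy(c("A", "N", "-", "A")), 0)     # ambiguity ignored
  expect_true(is.na(site_entropy(c("-", "N"))))
})

test_that("Iss is 0 on invariant data and about 1 on fully randomised columns", {
  inv <- codon_alignment(matrix("A", 4, 300,
                                dimnames = list(paste0("t", 1:4), NULL)))
  expect_equal(iss(inv), 0)
  set.seed(5)
  rnd <- codon_alignment(matrix(sample(c("A", "C", "G", "T"), 4 * 9999, TRUE),
                                4, 9999, dimnames = list(paste0("t", 1:4), NULL)))
  expect_equal(iss(rnd), 1, tolerance = 0.02)
  expect_error(iss(inv, p_inv = 1), "p_inv")
})

test_that("the invariant-site adjustment reproduces the stated df arithmetic", {
  # 1491 sites with p_inv = 0.21 must give df = 1177
  expect_equal(ratecon:::iss_sites_used(1491, 0.21) - 1L, 1177)
  set.seed(6)
  m <- matrix(sample(c("A", "C", "G", "T"), 8 * 1491, TRUE), 8, 1491,
              dimnames = list(paste0("t", 1:8), NULL))
  crit <- data.frame(num_otu = c(4, 8), sym = c(0.83, 0.81),
                     asym = c(0.80, 0.71))
  res <- iss_test(codon_alignment(m), p_inv = 0.21, seed = 1,
                  num_otus = c(4, 8), replicates = 30, iss_c = crit)
  expect_true(all(res$df == 1177))
  expect_true(all(res$p_sym >= 0 & res$p_sym <= 1))
})

test_that("jackknifed Iss is deterministic and matches the exhaustive subset mean", {
  d <- simulate_dataset(n_tips = 10, n_sites = 300, ucld_stdev = 0.3, seed = 51)
  aln <- d$aln
  j1 <- iss_jackknife(aln, 4, replicates = 100, seed = 9)
  j2 <- iss_jackknife(aln, 4, replicates = 100, seed = 9)
  expect_identical(j1, j2)
  # exhaustive mean over all choose(10, 4) subsets
  subsets <- combn(10, 4)
  all_iss <- apply(subsets, 2, function(rows)
    iss(codon_alignment(aln$matrix[rows, , drop = FALSE], aln$codon_map)))
  expect_lt(abs(j1$mean - mean(all_iss)), 3 * j1$se)
  expect_error(iss_jackknife(aln, 40, seed = 1), "exceeds")
})

test_that("identical sequences give a zero jackknife with a degenerate t test", {
  m <- matrix(rep(c("A", "C", "G", "T"), each = 6, times = 25), nrow = 6,
              dimnames = list(paste0("t", 1:6), NULL))
  aln <- codon_alignment(m[, 1:99])
  jk <- iss_jackknife(aln, 4, replicates = 20, seed = 2)
  expect_equal(jk$mean, 0); expect_equal(jk$se, 0)
  crit <- data.frame(num_otu = 4, sym = 0.8, asym = 0.7)
  res <- iss_test(aln, seed = 1, num_otus = 4, replicates = 20, iss_c = crit)
  expect_true(is.infinite(res$t_sym))
  expect_equal(res$p_sym, 0)
  expect_equal(res$verdict_sym, "saturation rejected")
})

test_that("critical Iss values reproduce the qualitative battery patterns", {
  freqs <- rep(0.25, 4)
  depths <- exp(seq(log(0.05), log(2.5), length.out = 6))
  cs4 <- iss_critical(4, 600, freqs, "sym", seed = 61, replicates = 14,
                      depths = depths)
  # 32-taxon trees can fail recovery even at the shallowest grid depth;
  cs32 <- suppressWarnings(iss_critical(32, 600, freqs, "sym", seed = 62,
                                        replicates = 14, depths = depths))
  # a 32-taxon caterpillar can fail recovery even at the shallowest depth;
  # the documented behaviour is to return the boundary value with a warning
  ca32 <- suppressWarnings(iss_critical(32, 600, freqs, "asym", seed = 63,
                                        replicates = 14, depths = depths))
  # more OTUs make topology recovery harder: critical value decreases
  expect_lt(as.numeric(cs32), as.numeric(cs4))
  # asymmetric (caterpillar) topologies are harder than symmetric ones
  expect_lt(as.numeric(ca32), as.numeric(cs32))
  # at shallow depths recovery is essentially perfect
  expect_gt(attr(cs4, "recovery")[1], 0.95)
})
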