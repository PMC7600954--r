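fit_small <- function(gens = 3000, seed = 5, ...) {
  d <- deep_crown_dataset(seed = 141, n_sites = 300)
  relaxed_clock(d$aln, d$tree, clades = d$clades, generations = gens,
                sample_every = 20, seed = seed, ...)
}

test_that("the trace has the documented shape and sample count", {
  fit <- fit_small()
  expect_equal(nrow(fit$trace), floor(3000 / 20) + 1)   # incl. initial state
  expect_true(all(c("state", "posterior", "likelihood", "prior", "ucld_stdev",
                    "gamma_shape", "p_inv", "birth_rate", "exch_AC", "freq_A")
                  %in% names(fit$trace)))
  expect_equal(ncol(fit$rates), nrow(fit$phy$edge))
  expect_equal(ncol(fit$heights), fit$phy$Nnode)
  # realised branch rates are always strictly positive
  expect_true(all(fit$rates > 0))
})

test_that("chains are bit-reproducible under a fixed seed", {
  f1 <- fit_small(seed = 9)
  f2 <- fit_small(seed = 9)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$rates, f2$rates)
  f3 <- fit_small(seed = 10)
  expect_false(identical(f1$trace$posterior, f3$trace$posterior))
})

test_that("recorded posterior equals likelihood plus prior at sampled states", {
  d <- deep_crown_dataset(seed = 142, n_sites = 300)
  fit <- relaxed_clock(d$aln, d$tree, clades = d$clades, generations = 2000,
                       sample_every = 100, seed = 6)
  expect_equal(fit$trace$posterior,
               fit$trace$likelihood + fit$trace$prior, tolerance = 1e-10)
  # recompute the likelihood column independently from the recorded state
  pr <- fit$config$priors
  ntip <- length(fit$phy$tip.label)
  for (i in c(3, 11, 21)) {
    h <- c(rep(0, ntip), fit$heights[i, ])
    tt <- timetree(fit$phy, heights = h, rates = fit$rates[i, ])
    m <- substitution_model(
      unlist(fit$trace[i, paste0("exch_", c("AC","AG","AT","CG","CT","GT"))]),
      unlist(fit$trace[i, paste0("freq_", c("A","C","G","T"))]),
      gamma_shape = fit$trace$gamma_shape[i], p_inv = fit$trace$p_inv[i])
    expect_equal(pruning_loglik(tt, m, d$aln), fit$trace$likelihood[i],
                 tolerance = 1e-6)
    lp <- yule_log_prior(tt, fit$trace$birth_rate[i]) +
      dexp(fit$trace$ucld_stdev[i], pr$ucld_rate, log = TRUE) +
      sum(dlnorm(unlist(fit$trace[i, paste0("exch_", c("AC","AG","AT","CG","CT"))]),
                 0, pr$exch_sdlog, log = TRUE)) +
      dexp(fit$trace$gamma_shape[i], pr$gamma_rate, log = TRUE) + lgamma(4) -
      log(fit$trace$birth_rate[i]) -
      log(log(pr$birth_bounds[2] / pr$birth_bounds[1]))
    expect_equal(lp, fit$trace$prior[i], tolerance = 1e-8)
  }
})

test_that("a prior-only chain keeps the mean branch rate anchored near 1", {
  d <- deep_crown_dataset(seed = 143, n_sites = 30)
  fit <- relaxed_clock(d$aln, d$tree, clades = d$clades, generations = 15000,
                       sample_every = 10, seed = 8, likelihood = FALSE)
  idx <- ratecon:::post_burnin_idx(fit)
  expect_equal(mean(fit$rates[idx, ]), 1, tolerance = 0.1)
  expect_equal(mean(fit$trace$likelihood[idx]), 0)
})

test_that("configuration errors are caught before sampling", {
  d <- deep_crown_dataset(seed = 144, n_sites = 30)
  expect_error(relaxed_clock(d$aln, d$tree, burnin_fraction = 1.2,
                             generations = 100), "burnin")
  poly <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_error(relaxed_clock(d$aln, poly, generations = 100), "polytomies|rooted")
})

test_that("summary and coef expose posterior summaries", {
  fit <- fit_small()
  s <- suppressWarnings(summary(fit))
  expect_s3_class(s, "summary.ratecon_fit")
  expect_true(all(c("mean", "hpd_low", "hpd_high", "ess") %in%
                    colnames(s$parameters)))
  cf <- coef(fit)
  expect_true(all(c("ucld_stdev", "gamma_shape", "p_inv") %in% names(cf)))
  expect_output(print(fit), "Relaxed-clock")
})
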