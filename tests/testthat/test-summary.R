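# a minimal hand-built fit object for testing the report machinery without
# running a chain
mock_fit <- function(clade_samples, phy_text = "((t1:1,t2:1):2,(t3:1,t4:1):2);") {
  phy <- ape::read.tree(text = phy_text)
  tt <- timetree(phy)
  ntip <- length(phy$tip.label)
  nsamp <- nrow(clade_samples$rates)
  structure(list(trace = data.frame(state = seq_len(nsamp)),
                 heights = matrix(rep(tt$heights[(ntip + 1):(ntip + phy$Nnode)],
                                      each = nsamp), nsamp),
                 rates = clade_samples$rates, phy = phy, clades = NULL,
                 config = list(burnin_fraction = 0, likelihood = TRUE)),
            class = "ratecon_fit")
}

test_that("clade mean rate is the time-weighted crown average", {
  tt <- toy_timetree(rates = c(2.5, 2.5, 2.5, 2.5))
  expect_equal(clade_mean_rate(tt, c("t1", "t2")), 2.5)
  # hand computation with unequal spans: heights give crown spans (1, 1) for
  # the cherry and (2, 1, 1) once t3's stem is excluded from clade {t1,t2,t3}
  tt2 <- toy_timetree(rates = c(1, 3, 2, 5))
  e <- clade_edges(tt2, c("t1", "t2"))
  spans <- ratecon:::edge_timespans(tt2)[e]
  expect_equal(clade_mean_rate(tt2, c("t1", "t2")),
               sum(tt2$rates[e] * spans) / sum(spans))
  # invariance under a common rescaling of all time spans
  tt3 <- timetree(tt2$phylo, heights = tt2$heights * 7, rates = tt2$rates)
  expect_equal(clade_mean_rate(tt3, c("t1", "t2")),
               clade_mean_rate(tt2, c("t1", "t2")), tolerance = 1e-12)
})

test_that("non-monophyletic clades yield NA rather than a number", {
  phy <- ape::read.tree(text = "(((t1:1,t2:1):1,t3:2):1,t4:3);")
  tt <- timetree(phy, rates = rep(1, 6))
  expect_true(is.na(clade_mean_rate(tt, c("t1", "t3"))))
})

test_that("the rate-constancy report flags deviating and differing clades", {
  # 4 taxa, 6 edges; build samples where clade {t1,t2} is fast
  set.seed(111)
  nsamp <- 400
  rates <- cbind(matrix(rlnorm(nsamp * 2, log(3), 0.05), nsamp),   # crown t1,t2
                 matrix(rlnorm(nsamp * 4, 0, 0.05), nsamp))
  phy <- ape::read.tree(text = "((t1:1,t2:1):2,(t3:1,t4:1):2);")
  # identify crown edges of {t1,t2} and order columns accordingly
  tt <- timetree(phy)
  e <- clade_edges(tt, c("t1", "t2"))
  R <- matrix(rlnorm(nsamp * 6, 0, 0.05), nsamp)
  R[, e] <- rlnorm(nsamp * 2, log(3), 0.05)
  fit <- mock_fit(list(rates = R))
  clades <- list(fast = c("t1", "t2"), slow = c("t3", "t4"))
  expect_error(rate_constancy_report(fit, clades, focal = "nope"), "focal")
  rep_ <- suppressWarnings(rate_constancy_report(fit, clades, focal = "slow"))
  expect_true(rep_$deviates_from_mean[rep_$clade == "fast"])
  expect_true(rep_$differs_from_focal[rep_$clade == "fast"])
  expect_false(rep_$deviates_from_mean[rep_$clade == "slow"])
  expect_false(rep_$differs_from_focal[rep_$clade == "slow"])  # focal vs itself
  expect_match(attr(rep_, "calibration_advice"), "appropriate")

  # widening the HPD can only turn flags off, never on
  rep99 <- suppressWarnings(rate_constancy_report(fit, clades, focal = "slow",
                                                  prob = 0.999))
  expect_true(all(rep_$deviates_from_mean | !rep99$deviates_from_mean))
  expect_true(all(rep_$differs_from_focal | !rep99$differs_from_focal))
})

test_that("MCC tree keeps the fixed topology and uses per-clade medians", {
  d <- deep_crown_dataset(seed = 121, n_sites = 300)
  fit <- relaxed_clock(d$aln, d$tree, clades = d$clades, generations = 2000,
                       sample_every = 20, seed = 3)
  mcc <- mcc_tree(fit)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(mcc$phylo),
                                         ape::unroot(fit$phy))), 0)
  expect_true(all(attr(mcc, "support") == 1))   # fixed topology throughout
  # median node heights equal per-node sample medians (direct oracle)
  idx <- ratecon:::post_burnin_idx(fit)
  ntip <- 16
  med <- apply(fit$heights[idx, , drop = FALSE], 2, median)
  expect_equal(unname(mcc$heights[as.integer(colnames(fit$heights))]),
               unname(med), tolerance = 1e-6)
  expect_error(mcc_tree(list()), "at least 2")
})
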