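# Bayesian relative-rate estimation on a fixed topology: GTR+Gamma(4)+I
# likelihood, ranked pure-birth prior on node heights, and an uncorrelated
# lognormal clock whose branch-rate prior has real-space mean fixed to 1
# (meanlog = -ucld_stdev^2/2), so estimated rates are relative to 1
# substitution/site/time.
#
# The clock is quantile-discretised: with E branches, branch e carries rate
# q_{LN(-s^2/2, s)}((c_e - 0.5)/E) where (c_1..c_E) is a permutation of
# 1..E sampled by category swaps and s is the (sampled) ucld_stdev. The
# realised rates are therefore always a stratified lognormal sample of
# spread s; the chain cannot shrink every rate towards 1 while keeping s
# small, which is what makes clade-specific accelerations identifiable
# against compensatory node-height stretching (see the methods vignette).

default_rate_priors <- function() {
  list(ucld_rate = 3,                 # ucld_stdev ~ Exponential(mean 1/3)
       birth_bounds = c(1e-6, 1e3),   # birth rate ~ uniform on the log scale
       exch_sdlog = 1.25,             # free exchangeabilities ~ iid Lognormal(0, sd)
       gamma_rate = 1)                # gamma shape ~ Exponential(1)
}

default_move_weights <- function() {
  c(swap = 0.30, height = 0.14, subtree = 0.08, root = 0.04,
    tree_scale = 0.05, sigma = 0.10, shape = 0.05, pinv = 0.05, exch = 0.09,
    freqs = 0.05, birth = 0.03)
}

# rates implied by the quantile clock: permutation `cats`, spread `sigma`
quantile_rates <- function(zq, cats, sigma)
  exp(sigma * zq[cats] - sigma^2 / 2)

#' Fit a relaxed molecular clock with relative rates anchored to 1
#'
#' Metropolis-Hastings sampling of node heights, per-branch substitution
#' rates, GTR exchangeabilities, base frequencies, gamma shape, proportion of
#' invariant sites, lognormal clock spread (`ucld_stdev`) and Yule birth rate,
#' on a fixed rooted binary topology. The clock prior anchors the real-space
#' mean branch rate to exactly 1, so sampled rates are relative rates
#' (substitutions/site/time) and a clade whose 95% HPD excludes 1 deviates
#' from the tree-wide average rate.
#'
#' @param aln a [codon_alignment] containing all tree tips.
#' @param tree the constraint topology: a [timetree] or rooted binary
#'   `phylo`. Topology is fixed throughout; node heights are estimated.
#' @param clades optional named list of tip-label vectors used by
#'   [rate_constancy_report()] and `summary()`.
#' @param generations number of MCMC proposals.
#' @param sample_every thinning interval; `floor(generations/sample_every)+1`
#'   states are recorded (including the initial state).
#' @param burnin_fraction fraction of samples discarded by the summary
#'   methods (default 0.10).
#' @param seed integer seed; chains are bit-reproducible.
#' @param likelihood set `FALSE` to sample from the prior alone
#'   (prior-recovery checks).
#' @param priors,move_weights optional overrides of the defaults (see
#'   `ratecon:::default_rate_priors()`).
#' @param tune adapt proposal scales towards ~30% acceptance during burn-in.
#' @param verbose print progress every 10% of the run.
#' @return an object of class `ratecon_fit` with the scalar `trace`
#'   (state, posterior, likelihood, prior, ucld_stdev, gamma_shape, p_inv,
#'   birth_rate, exchangeabilities, frequencies), per-sample node `heights`
#'   and branch `rates`, the fixed topology, clade definitions, acceptance
#'   statistics and the run configuration.
#' @seealso [rate_constancy_report()], [mcc_tree()], [hpd_interval()], [ess()]
#' @export
relaxed_clock <- function(aln, tree, clades = NULL,
                          generations = 5e5, sample_every = 100L,
                          burnin_fraction = 0.10, seed = 1L,
                          likelihood = TRUE, priors = list(),
                          move_weights = NULL, tune = TRUE, verbose = FALSE) {
  if (inherits(tree, "phylo"))
    tree <- timetree(init_heights_phylo(tree))
  stopifnot(inherits(tree, "timetree"), inherits(aln, "codon_alignment"))
  if (burnin_fraction < 0 || burnin_fraction >= 1)
    stop("burnin_fraction must lie in [0, 1)")
  pr <- utils::modifyList(default_rate_priors(), priors)
  w <- default_move_weights()
  if (!is.null(move_weights)) w[names(move_weights)] <- move_weights
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  root <- ntip + 1L
  int_ids <- (ntip + 1L):(ntip + nnode)
  nonroot_int <- setdiff(int_ids, root)
  if (!length(nonroot_int)) w["height"] <- 0
  edge <- phy$edge
  nedge <- nrow(edge)
  parent_e <- edge[, 1L]; child_e <- edge[, 2L]
  kids <- lapply(seq_len(ntip + nnode), function(v) child_e[parent_e == v])
  parent_of <- integer(ntip + nnode)
  parent_of[child_e] <- parent_e
  # internal descendants (incl. self) of every internal node, for the
  # subtree-scale move
  int_desc <- lapply(seq_len(ntip + nnode), function(v) {
    if (v <= ntip) return(integer(0))
    d <- c(v, unlist(phangorn::Descendants(phy, v, type = "all")))
    d[d > ntip]
  })
  log_const <- sum(log(internal_subtree_sizes(phy)))

  struct <- NULL
  if (likelihood) {
    missing <- setdiff(phy$tip.label, taxa_labels(aln))
    if (length(missing))
      stop("alignment is missing taxa: ", paste(missing, collapse = ", "))
    struct <- likelihood_structure(tree, aln)
  }

  # ---- initial state -------------------------------------------------------
  # Parsimony-informed start: branch substitution counts give approximate
  # expected substitutions per branch; heights are rescaled so the mean rate
  # starts near 1 (the prior anchor) and rate categories are assigned by the
  # rank of the crude per-branch rate estimates.
  zq <- qnorm((seq_len(nedge) - 0.5) / nedge)
  h <- tree$heights
  cats <- seq_len(nedge)
  sigma0 <- 0.3
  if (likelihood) {
    elen0 <- tryCatch({
      dat <- phangorn::phyDat(aln$matrix[phy$tip.label, , drop = FALSE],
                              type = "DNA")
      pt <- phangorn::acctran(phy, dat)
      pmax(pt$edge.length[match(child_e, pt$edge[, 2])], 0.5) /
        ncol(aln$matrix)
    }, error = function(e) NULL)
    if (!is.null(elen0)) {
      span0 <- h[parent_e] - h[child_e]
      scale0 <- sum(elen0) / sum(span0)
      h <- h * scale0
      r0 <- elen0 / (span0 * scale0)
      cats <- rank(r0, ties.method = "first")
      sigma0 <- min(max(sd(log(r0)), 0.1), 2)
    }
  }
  freqs0 <- if (likelihood) pmax(empirical_freqs(aln), 1e-3) else rep(0.25, 4)
  state <- list(h = h, cats = cats, exch = rep(1, 6),
                freqs = freqs0 / sum(freqs0),
                shape = 1, pinv = 0.1, sigma = sigma0,
                birth = min(max((nnode) / sum(h[int_ids]), pr$birth_bounds[1]),
                            pr$birth_bounds[2]))

  log_prior <- function(s) {
    # the rate-category permutation is uniform, so it contributes a constant
    lp <- yule_log_prior_heights(s$h[int_ids], s$birth, log_const) +
      dexp(s$sigma, pr$ucld_rate, log = TRUE) +
      sum(dlnorm(s$exch[1:5], 0, pr$exch_sdlog, log = TRUE)) +
      dexp(s$shape, pr$gamma_rate, log = TRUE) + lgamma(4)
    if (s$birth < pr$birth_bounds[1] || s$birth > pr$birth_bounds[2])
      return(-Inf)
    lp - log(s$birth) - log(log(pr$birth_bounds[2] / pr$birth_bounds[1]))
  }
  log_lik <- function(s, eig, catrates) {
    if (!likelihood) return(0)
    elen <- quantile_rates(zq, s$cats, s$sigma) *
      (s$h[parent_e] - s$h[child_e])
    loglik_kernel(struct, elen, eig, catrates, s$pinv, s$freqs)
  }

  eig <- gtr_eigen(substitution_model(state$exch, state$freqs))
  catrates <- gamma_categories(state$shape, 4L)
  cur_lp <- log_prior(state)
  cur_ll <- log_lik(state, eig, catrates)

  # ---- bookkeeping ---------------------------------------------------------
  nsamp <- floor(generations / sample_every) + 1L
  scal_names <- c("state", "posterior", "likelihood", "prior", "ucld_stdev",
                  "gamma_shape", "p_inv", "birth_rate",
                  paste0("exch_", c("AC", "AG", "AT", "CG", "CT", "GT")),
                  paste0("freq_", c("A", "C", "G", "T")))
  trace <- matrix(NA_real_, nsamp, length(scal_names),
                  dimnames = list(NULL, scal_names))
  H <- matrix(NA_real_, nsamp, nnode, dimnames = list(NULL, int_ids))
  R <- matrix(NA_real_, nsamp, nedge)
  record <- function(k, it) {
    trace[k, ] <<- c(it, cur_ll + cur_lp, cur_ll, cur_lp, state$sigma,
                     state$shape, state$pinv, state$birth, state$exch,
                     state$freqs)
    H[k, ] <<- state$h[int_ids]
    R[k, ] <<- quantile_rates(zq, state$cats, state$sigma)
  }

  tun <- c(root = 0.6, subtree = 0.5, tree_scale = 0.3, sigma = 0.4,
           shape = 0.8, exch = 0.6, birth = 1.0, pinv = 0.15, freqs = 0.08)
  prop_n <- acc_n <- setNames(numeric(length(w)), names(w))
  win_n <- win_a <- setNames(numeric(length(tun)), names(tun))
  burn_gen <- max(1, floor(burnin_fraction * generations))
  move_names <- names(w)
  move_p <- w / sum(w)

  with_seed(seed, {
    record(1L, 0L)
    k <- 1L
    for (it in seq_len(generations)) {
      mv <- sample(move_names, 1L, prob = move_p)
      prop_n[mv] <- prop_n[mv] + 1
      cand <- state
      logH <- 0
      new_eig <- eig; new_cat <- catrates
      need_ll <- TRUE
      ok <- TRUE
      if (mv == "swap") {
        # swap the rate categories of two branches; mostly local swaps
        # (nearby quantiles) with occasional global ones
        i <- sample.int(nedge, 1L)
        j <- if (runif(1) < 0.8) {
          step <- sample(c(-2L, -1L, 1L, 2L), 1L)
          which(state$cats == (((state$cats[i] - 1L + step) %% nedge) + 1L))
        } else sample.int(nedge, 1L)
        ij <- c(i, j)
        cand$cats[ij] <- state$cats[rev(ij)]
      } else if (mv == "height") {
        v <- if (length(nonroot_int) == 1L) nonroot_int else
          nonroot_int[sample.int(length(nonroot_int), 1L)]
        lower <- max(state$h[kids[[v]]])
        upper <- state$h[parent_of[v]]
        cand$h[v] <- runif(1, lower, upper)
      } else if (mv == "root") {
        s <- exp(tun["root"] * (runif(1) - 0.5))
        cand$h[root] <- state$h[root] * s
        logH <- log(s)
        ok <- cand$h[root] > max(state$h[kids[[root]]])
      } else if (mv == "subtree") {
        # scale all node heights inside one subtree: lets a clade's crown
        # stretch or shrink coherently against its rates
        v <- if (length(nonroot_int) == 1L) nonroot_int else
          nonroot_int[sample.int(length(nonroot_int), 1L)]
        sc <- exp(tun["subtree"] * (runif(1) - 0.5))
        dd <- int_desc[[v]]
        cand$h[dd] <- state$h[dd] * sc
        logH <- length(dd) * log(sc)
        ok <- cand$h[v] < state$h[parent_of[v]]
      } else if (mv == "tree_scale") {
        s <- exp(tun["tree_scale"] * (runif(1) - 0.5))
        cand$h[int_ids] <- state$h[int_ids] * s
        logH <- nnode * log(s)
      } else if (mv == "sigma") {
        # changes every branch rate through the quantile map
        s <- exp(tun["sigma"] * (runif(1) - 0.5))
        cand$sigma <- state$sigma * s
        logH <- log(s)
      } else if (mv == "shape") {
        s <- exp(tun["shape"] * (runif(1) - 0.5))
        cand$shape <- state$shape * s
        logH <- log(s)
        ok <- cand$shape > 0.02 && cand$shape < 50
        if (ok) new_cat <- gamma_categories(cand$shape, 4L)
      } else if (mv == "pinv") {
        p <- state$pinv + tun["pinv"] * (runif(1) - 0.5)
        if (p < 0) p <- -p
        if (p > 0.99) p <- 1.98 - p
        ok <- p >= 0 && p <= 0.99
        cand$pinv <- p
      } else if (mv == "exch") {
        i <- sample.int(5L, 1L)
        s <- exp(tun["exch"] * (runif(1) - 0.5))
        cand$exch[i] <- state$exch[i] * s
        logH <- log(s)
        new_eig <- gtr_eigen(substitution_model(cand$exch, cand$freqs))
      } else if (mv == "freqs") {
        ij <- sample.int(4L, 2L)
        d <- runif(1, 0, tun["freqs"])
        f <- state$freqs
        f[ij[1]] <- f[ij[1]] - d; f[ij[2]] <- f[ij[2]] + d
        ok <- all(f > 1e-4)
        cand$freqs <- f
        if (ok) new_eig <- gtr_eigen(substitution_model(cand$exch, f))
      } else if (mv == "birth") {
        s <- exp(tun["birth"] * (runif(1) - 0.5))
        cand$birth <- state$birth * s
        logH <- log(s)
        need_ll <- FALSE
      }
      if (ok) {
        new_lp <- log_prior(cand)
        if (is.finite(new_lp)) {
          new_ll <- if (need_ll) log_lik(cand, new_eig, new_cat) else cur_ll
          if (log(runif(1)) < (new_lp + new_ll) - (cur_lp + cur_ll) + logH) {
            state <- cand; cur_lp <- new_lp; cur_ll <- new_ll
            eig <- new_eig; catrates <- new_cat
            acc_n[mv] <- acc_n[mv] + 1
            if (mv %in% names(tun)) win_a[mv] <- win_a[mv] + 1
          }
        }
      }
      if (mv %in% names(tun)) {
        win_n[mv] <- win_n[mv] + 1
        if (tune && it <= burn_gen && win_n[mv] >= 50) {
          rate_acc <- win_a[mv] / win_n[mv]
          tun[mv] <- tun[mv] * exp(rate_acc - 0.3)
          if (mv %in% c("pinv", "freqs")) {
            tun[mv] <- min(max(tun[mv], 1e-4), 0.5)
          } else tun[mv] <- min(max(tun[mv], 0.01), 10)
          win_n[mv] <- win_a[mv] <- 0
        }
      }
      if (it %% sample_every == 0L) {
        k <- k + 1L
        record(k, it)
      }
      if (verbose && it %% max(1, generations %/% 10L) == 0L)
        message(sprintf("generation %d/%d  posterior %.2f", it, generations,
                        cur_ll + cur_lp))
    }
  })

  acc <- data.frame(move = names(w), proposed = as.numeric(prop_n),
                    accepted = as.numeric(acc_n))
  structure(list(trace = as.data.frame(trace), heights = H, rates = R,
                 phy = phy, clades = clades,
                 acceptance = acc, tuning = tun,
                 config = list(generations = generations,
                               sample_every = sample_every,
                               burnin_fraction = burnin_fraction,
                               seed = seed, likelihood = likelihood,
                               priors = pr),
                 n_sites = if (likelihood) ncol(aln$matrix) else NA_integer_),
            class = "ratecon_fit")
}

# Grafen-style ultrametric initial heights for a topology-only tree.
init_heights_phylo <- function(phy) {
  if (!ape::is.binary(phy)) stop("constraint tree must be fully resolved (no polytomies)")
  if (!ape::is.rooted(phy)) stop("constraint tree must be rooted")
  ape::compute.brlen(phy, method = "Grafen")
}

post_burnin_idx <- function(fit, burnin = NULL) {
  if (is.null(burnin)) burnin <- fit$config$burnin_fraction
  n <- nrow(fit$trace)
  start <- floor(burnin * n) + 1L
  start:n
}

#' Posterior tree samples from a fit
#'
#' Reconstructs the post-burn-in posterior sample of rate-annotated time
#' trees (shared fixed topology, per-sample heights and branch rates).
#'
#' @param fit a `ratecon_fit`.
#' @param burnin burn-in fraction (default: the fit's configuration).
#' @param thin keep every `thin`-th retained sample.
#' @return list of [timetree] objects.
#' @export
tree_samples <- function(fit, burnin = NULL, thin = 1L) {
  idx <- post_burnin_idx(fit, burnin)
  idx <- idx[seq(1L, length(idx), by = thin)]
  ntip <- length(fit$phy$tip.label)
  lapply(idx, function(i) {
    h <- c(rep(0, ntip), fit$heights[i, ])
    timetree(fit$phy, heights = h, rates = fit$rates[i, ])
  })
}

#' @export
print.ratecon_fit <- function(x, ...) {
  cat("Relaxed-clock relative-rate fit (fixed topology)\n")
  cat("  tips:", length(x$phy$tip.label),
      "| generations:", x$config$generations,
      "| samples:", nrow(x$trace),
      if (!x$config$likelihood) "| PRIOR-ONLY RUN" else "", "\n")
  idx <- post_burnin_idx(x)
  cat("  post burn-in mean posterior:",
      format(mean(x$trace$posterior[idx]), digits = 6), "\n")
  acc <- x$acceptance
  cat("  overall acceptance:",
      sprintf("%.1f%%", 100 * sum(acc$accepted) / max(1, sum(acc$proposed))),
      "\n")
  invisible(x)
}

#' @export
summary.ratecon_fit <- function(object, burnin = NULL, prob = 0.95, ...) {
  idx <- post_burnin_idx(object, burnin)
  pars <- c("posterior", "likelihood", "prior", "ucld_stdev", "gamma_shape",
            "p_inv", "birth_rate",
            grep("^exch_|^freq_", names(object$trace), value = TRUE))
  tab <- t(vapply(pars, function(p) {
    s <- object$trace[[p]][idx]
    hp <- hpd_interval(s, prob)
    c(mean = mean(s), hpd_low = hp[1], hpd_high = hp[2], ess = ess(s))
  }, numeric(4)))
  out <- list(parameters = as.data.frame(tab),
              clades = if (!is.null(object$clades))
                rate_constancy_report(object, object$clades,
                                      focal = names(object$clades)[1],
                                      burnin = burnin, prob = prob)
              else NULL,
              config = object$config)
  class(out) <- "summary.ratecon_fit"
  out
}

#' @export
print.summary.ratecon_fit <- function(x, ...) {
  cat("Posterior summaries (post burn-in)\n")
  print(round(x$parameters, 4))
  if (!is.null(x$clades)) {
    cat("\nClade relative rates\n")
    print(x$clades)
  }
  invisible(x)
}

#' @export
coef.ratecon_fit <- function(object, burnin = NULL, ...) {
  idx <- post_burnin_idx(object, burnin)
  pars <- c("ucld_stdev", "gamma_shape", "p_inv", "birth_rate",
            grep("^exch_|^freq_", names(object$trace), value = TRUE))
  vapply(pars, function(p) mean(object$trace[[p]][idx]), 0)
}

#' @export
plot.ratecon_fit <- function(x, type = c("rates", "trace"), focal = NULL, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    idx <- seq_len(nrow(x$trace))
    plot.default(x$trace$state, x$trace$posterior, type = "l",
                 xlab = "generation", ylab = "log posterior", ...)
    abline(v = x$trace$state[max(post_burnin_idx(x)[1] - 1, 1)], lty = 2)
    return(invisible(x))
  }
  if (is.null(x$clades)) stop("no clades defined; use type = 'trace'")
  rep_ <- rate_constancy_report(x, x$clades,
                                focal = if (is.null(focal))
                                  names(x$clades)[1] else focal)
  mids <- barplot(rep_$mean_rate, names.arg = rep_$clade,
                  ylim = c(0, max(rep_$hpd_high) * 1.1),
                  ylab = "relative rate (substitutions/site/time)", ...)
  segments(mids, rep_$hpd_low, mids, rep_$hpd_high)
  abline(h = 1, lty = 2)
  invisible(x)
}
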