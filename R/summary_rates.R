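# Per-clade relative-rate summaries and rate-constancy calls.

#' Time-weighted mean relative rate of a clade
#'
#' `sum(rate_i * timespan_i) / sum(timespan_i)` over the crown branches
#' strictly inside the clade (the stem branch is excluded): only the
#' within-clade, more recent and less saturated branches enter the summary.
#'
#' @param tree a rate-annotated [timetree].
#' @param taxa tip labels of the clade.
#' @return the weighted mean rate, or `NA` if the clade is not monophyletic
#'   on this tree.
#' @export
clade_mean_rate <- function(tree, taxa) {
  stopifnot(inherits(tree, "timetree"))
  if (is.null(tree$rates)) stop("branch rates have not been assigned")
  if (!clade_is_monophyletic(tree$phylo, taxa)) return(NA_real_)
  e <- clade_edges(tree, taxa)
  if (!length(e)) stop("clade has no crown branches (fewer than 2 tips)")
  tspan <- edge_timespans(tree)[e]
  sum(tree$rates[e] * tspan) / sum(tspan)
}

# Per-sample clade mean rates for every clade, computed directly from the
# fit's height and rate matrices (the topology is fixed, so crown edge sets
# are constant across samples).
clade_rate_samples <- function(fit, clades, burnin = NULL) {
  idx <- post_burnin_idx(fit, burnin)
  phy <- fit$phy
  ntip <- length(phy$tip.label)
  parent_e <- phy$edge[, 1L]; child_e <- phy$edge[, 2L]
  Hp <- fit$heights[idx, match(parent_e, (ntip + 1L):(ntip + phy$Nnode)),
                    drop = FALSE]
  Hc <- matrix(0, length(idx), length(child_e))
  int_child <- child_e > ntip
  Hc[, int_child] <- fit$heights[idx, match(child_e[int_child],
                                            (ntip + 1L):(ntip + phy$Nnode)),
                                 drop = FALSE]
  spans <- Hp - Hc
  Rt <- fit$rates[idx, , drop = FALSE]
  vapply(clades, function(taxa) {
    e <- clade_edges(phy, taxa)
    rowSums(Rt[, e, drop = FALSE] * spans[, e, drop = FALSE]) /
      rowSums(spans[, e, drop = FALSE])
  }, numeric(length(idx)))
}

#' Rate-constancy report per clade
#'
#' For every named clade: posterior mean of the clade's time-weighted mean
#' relative rate, its 95% HPD interval and effective sample size, whether it
#' deviates from the tree-wide mean rate (HPD excludes 1), and whether it
#' differs from the focal clade (the two HPD intervals are disjoint). Also
#' attaches a calibration-advice line: a secondary ("universal") rate is
#' deemed appropriate for the focal group iff the focal HPD includes 1.
#'
#' @param fit a `ratecon_fit` (burn-in is removed here).
#' @param clades named list of tip-label vectors; each clade must be
#'   monophyletic on the fixed topology and have at least 2 tips.
#' @param focal name of the focal clade (must appear in `clades`).
#' @param prob HPD mass (default 0.95).
#' @param burnin burn-in fraction override.
#' @param ess_threshold warn when any clade-rate ESS falls below this.
#' @return data.frame of class `rate_constancy_report` with columns `clade`,
#'   `mean_rate`, `hpd_low`, `hpd_high`, `ess`, `deviates_from_mean`,
#'   `differs_from_focal`; attributes `focal`, `calibration_advice`,
#'   `skipped_samples`.
#' @export
rate_constancy_report <- function(fit, clades = fit$clades, focal,
                                  prob = 0.95, burnin = NULL,
                                  ess_threshold = 200) {
  stopifnot(inherits(fit, "ratecon_fit"))
  if (is.null(clades) || is.null(names(clades)))
    stop("clades must be a named list of tip labels")
  if (!focal %in% names(clades))
    stop("focal clade '", focal, "' is not among the clade definitions")
  samples <- clade_rate_samples(fit, clades, burnin)
  skipped <- colSums(is.na(samples))
  rows <- lapply(names(clades), function(nm) {
    s <- samples[, nm]
    s <- s[!is.na(s)]
    hp <- hpd_interval(s, prob)
    data.frame(clade = nm, mean_rate = mean(s), hpd_low = hp[1],
               hpd_high = hp[2], ess = ess(s))
  })
  out <- do.call(rbind, rows)
  out$deviates_from_mean <- out$hpd_low > 1 | out$hpd_high < 1
  f <- match(focal, out$clade)
  out$differs_from_focal <- out$hpd_low > out$hpd_high[f] |
    out$hpd_high < out$hpd_low[f]
  out$differs_from_focal[f] <- FALSE
  if (any(out$ess < ess_threshold))
    warning("clade-rate ESS below ", ess_threshold, " for: ",
            paste(out$clade[out$ess < ess_threshold], collapse = ", "))
  attr(out, "focal") <- focal
  attr(out, "skipped_samples") <- skipped
  attr(out, "calibration_advice") <- if (!out$deviates_from_mean[f])
    paste0("Focal clade '", focal, "' HPD includes 1: a secondary rate ",
           "calibration at the tree-wide mean rate is appropriate.")
  else
    paste0("Focal clade '", focal, "' HPD excludes 1: a secondary rate ",
           "calibration at the tree-wide mean rate is NOT appropriate.")
  class(out) <- c("rate_constancy_report", "data.frame")
  out
}

#' @export
print.rate_constancy_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(attr(x, "calibration_advice"), "\n")
  invisible(x)
}

clade_key <- function(labels) paste(sort(labels), collapse = "|")

#' Maximum clade credibility tree
#'
#' Picks the sampled tree maximising the product of clade posterior
#' frequencies and annotates it with median node heights and median branch
#' rates taken across the samples containing each clade. When medians of
#' adjacent nodes would invert (possible for independently computed
#' medians), the parent is nudged just above its children.
#'
#' @param samples list of [timetree] objects sharing a taxon set, or a
#'   `ratecon_fit` (post burn-in samples are used).
#' @param burnin burn-in override when `samples` is a fit.
#' @return a [timetree] with attributes `support` (per internal node, in the
#'   order of node ids) and `score`.
#' @export
mcc_tree <- function(samples, burnin = NULL) {
  if (inherits(samples, "ratecon_fit"))
    samples <- tree_samples(samples, burnin)
  if (!length(samples) || length(samples) < 2L)
    stop("need at least 2 tree samples")
  n <- length(samples)
  info <- lapply(samples, function(tt) {
    phy <- tt$phylo
    ntip <- length(phy$tip.label)
    desc <- phangorn::Descendants(phy, seq_len(ntip + phy$Nnode), type = "tips")
    keys <- vapply(desc, function(t) clade_key(phy$tip.label[t]), "")
    stem <- match(seq_len(ntip + phy$Nnode), phy$edge[, 2L])
    list(keys = keys, heights = tt$heights,
         stem_rate = ifelse(is.na(stem), NA_real_, tt$rates[stem]),
         ntip = ntip)
  })
  # posterior frequency of every internal clade
  all_int <- unlist(lapply(info, function(z)
    z$keys[(z$ntip + 1L):length(z$keys)]))
  freq <- table(all_int) / n
  heights_by <- new.env(parent = emptyenv())
  rates_by <- new.env(parent = emptyenv())
  for (z in info) for (i in seq_along(z$keys)) {
    k <- z$keys[i]
    assign(k, c(if (exists(k, heights_by)) get(k, heights_by), z$heights[i]),
           heights_by)
    if (!is.na(z$stem_rate[i]))
      assign(k, c(if (exists(k, rates_by)) get(k, rates_by), z$stem_rate[i]),
             rates_by)
  }
  scores <- vapply(info, function(z)
    sum(log(freq[z$keys[(z$ntip + 1L):length(z$keys)]])), 0)
  best <- which.max(scores)
  tt <- samples[[best]]
  z <- info[[best]]
  h <- vapply(z$keys, function(k) median(get(k, heights_by)), 0)
  h[seq_len(z$ntip)] <- 0
  # enforce parent-above-child after independent medians
  post <- ape::reorder.phylo(tt$phylo, "postorder")
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1L]; ch <- post$edge[e, 2L]
    if (h[p] <= h[ch]) h[p] <- h[ch] + 1e-9 + abs(h[ch]) * 1e-9
  }
  r <- vapply(seq_len(nrow(tt$phylo$edge)), function(e)
    median(get(z$keys[tt$phylo$edge[e, 2L]], rates_by)), 0)
  out <- timetree(tt$phylo, heights = unname(h), rates = r)
  attr(out, "support") <- as.numeric(
    freq[z$keys[(z$ntip + 1L):length(z$keys)]])
  attr(out, "score") <- scores[best]
  out
}
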