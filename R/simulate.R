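# Synthetic-data generator: Yule time-trees, lognormal branch rates with
# clade multipliers, and GTR+Gamma+I site evolution with codon-position
# rate heterogeneity. These are the generative counterparts of the
# inference model, so every stage can be tested by parameter recovery.

# Evaluate `code` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a Yule (pure-birth) time tree
#'
#' Draws a ranked topology by the forward pure-birth splitting process (each
#' extant lineage equally likely to split next) and node heights as the
#' descending order statistics of `n_tips - 1` i.i.d. Exponential(birth_rate)
#' draws, matched to the split ranking. This is exactly the tree prior used
#' by [relaxed_clock()] (see [yule_log_prior()]), so prior-sampling and
#' MCMC prior recovery are mutually consistent. For two tips the root height
#' is Exponential(birth_rate) with mean `1/birth_rate`.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate positive birth rate (per unit relative time).
#' @param seed integer seed; the same seed always yields the same tree.
#' @return a [timetree] with tips `t1..tn` at height 0.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = 1L) {
  n_tips <- as.integer(n_tips)
  if (is.na(n_tips) || n_tips < 2L) stop("n_tips must be at least 2")
  if (birth_rate <= 0) stop("birth_rate must be positive")
  with_seed(seed, {
    parent_rank <- rep(NA_integer_, max(n_tips - 1L, 1L))
    active <- c(1L, 1L)                       # lineages hanging off the root (rank 1)
    if (n_tips > 2L) {
      for (j in 2L:(n_tips - 1L)) {
        i <- sample.int(length(active), 1L)
        parent_rank[j] <- active[i]
        active <- c(active[-i], j, j)
      }
    }
    h_int <- sort(rexp(n_tips - 1L, rate = birth_rate), decreasing = TRUE)
    node_id <- function(rank) n_tips + rank
    tip_edges <- cbind(node_id(active), seq_len(n_tips))
    int_edges <- if (n_tips > 2L)
      cbind(node_id(parent_rank[2:(n_tips - 1L)]), node_id(2:(n_tips - 1L)))
    else NULL
    edge <- rbind(int_edges, tip_edges)
    phy <- structure(list(edge = edge, tip.label = sprintf("t%d", seq_len(n_tips)),
                          Nnode = n_tips - 1L,
                          edge.length = rep(1, nrow(edge))),
                     class = "phylo")
    phy <- ape::reorder.phylo(phy, "cladewise")
    timetree(phy, heights = c(rep(0, n_tips), h_int))
  })
}

#' Assign branch rates under an uncorrelated lognormal clock
#'
#' Each branch receives rate `m * exp(X)` with
#' `X ~ Normal(-ucld_stdev^2/2, ucld_stdev^2)`, so the base lognormal has
#' real-space mean exactly 1 (the mean-rate anchoring used at inference
#' time). `m` is the multiplier of the most nested named clade whose crown
#' contains the branch (stem branches excluded; default 1), emulating
#' taxonomic groups with accelerated or decelerated substitution rates.
#'
#' @param tree a [timetree].
#' @param ucld_stdev standard deviation (log space) of the lognormal; 0 gives
#'   a strict clock with every rate exactly 1 before multipliers.
#' @param clade_multipliers named numeric vector or list, clade name ->
#'   positive multiplier.
#' @param clades named list, clade name -> character vector of tip labels;
#'   every name in `clade_multipliers` must resolve to a monophyletic group.
#' @param seed integer seed.
#' @return the tree with `rates` filled in.
#' @export
assign_branch_rates <- function(tree, ucld_stdev = 0, clade_multipliers = NULL,
                                clades = list(), seed = 1L) {
  stopifnot(inherits(tree, "timetree"))
  if (ucld_stdev < 0) stop("ucld_stdev must be non-negative")
  nedge <- nrow(tree$phylo$edge)
  mult <- rep(1, nedge)
  if (length(clade_multipliers)) {
    cm <- unlist(clade_multipliers)
    if (is.null(names(cm)) || any(!nzchar(names(cm))))
      stop("clade_multipliers must be named")
    missing_cl <- setdiff(names(cm), names(clades))
    if (length(missing_cl))
      stop("clade not defined: ", paste(missing_cl, collapse = ", "))
    if (any(cm <= 0)) stop("clade multipliers must be positive")
    sizes <- lengths(clades[names(cm)])
    for (nm in names(cm)[order(sizes, decreasing = TRUE)])
      mult[clade_edges(tree, clades[[nm]])] <- cm[[nm]]
  }
  with_seed(seed, {
    x <- rnorm(nedge, mean = -ucld_stdev^2 / 2, sd = ucld_stdev)
    tree$rates <- mult * exp(x)
  })
  tree
}

#' Simulate a codon alignment down a rate-annotated time tree
#'
#' Sites evolve independently under GTR+Gamma+I. A site is invariant with
#' probability `model$p_inv`; otherwise it draws one of the discrete gamma
#' categories, and the expected number of substitutions on a branch is
#' `branch rate x time span x codon-position multiplier x category rate`.
#' Codon positions cycle 1,2,3 along the alignment.
#'
#' @param tree a [timetree] with branch rates assigned.
#' @param model a [substitution_model].
#' @param n_sites number of sites, divisible by 3.
#' @param partition_multipliers length-3 positive relative rates of codon
#'   positions 1-3; normalised internally to mean 1.
#' @param seed integer seed.
#' @return a [codon_alignment].
#' @export
simulate_alignment <- function(tree, model, n_sites,
                               partition_multipliers = c(1, 1, 1), seed = 1L) {
  stopifnot(inherits(tree, "timetree"), inherits(model, "substitution_model"))
  if (is.null(tree$rates)) stop("branch rates have not been assigned")
  n_sites <- as.integer(n_sites)
  if (n_sites %% 3L != 0L) stop("n_sites must be divisible by 3")
  pm <- as.numeric(partition_multipliers)
  if (length(pm) != 3L || any(pm <= 0)) stop("need 3 positive partition multipliers")
  pm <- pm / mean(pm)
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  eig <- gtr_eigen(model)
  catrates <- gamma_categories(model$gamma_shape, model$ncat)
  spans <- edge_timespans(tree)
  codon_map <- rep_len(1:3, n_sites)
  with_seed(seed, {
    invariant <- runif(n_sites) < model$p_inv
    cat_of <- sample.int(length(catrates), n_sites, replace = TRUE)
    factor_site <- ifelse(invariant, 0, pm[codon_map] * catrates[cat_of])
    states <- matrix(0L, ntip + phy$Nnode, n_sites)
    states[ntip + 1L, ] <- sample.int(4L, n_sites, replace = TRUE,
                                      prob = model$freqs)
    groups <- split(seq_len(n_sites), factor_site)
    # cladewise order guarantees parents are simulated before children
    for (e in seq_len(nrow(phy$edge))) {
      par <- phy$edge[e, 1L]; child <- phy$edge[e, 2L]
      out <- states[par, ]
      base <- tree$rates[e] * spans[e]
      for (g in names(groups)) {
        f <- as.numeric(g)
        if (f == 0) next
        idx <- groups[[g]]
        P <- transition_probs(eig, base * f)
        ps <- states[par, idx]
        for (s in 1:4) {
          ii <- idx[ps == s]
          if (length(ii))
            out[ii] <- sample.int(4L, length(ii), replace = TRUE, prob = P[s, ])
        }
      }
      states[child, ] <- out
    }
    m <- matrix(c("A", "C", "G", "T")[states[seq_len(ntip), ]], ntip, n_sites)
    rownames(m) <- phy$tip.label
    codon_alignment(m, codon_map)
  })
}

#' Default COI-like substitution model for simulations
#'
#' An AT-rich, transition-biased GTR+Gamma+I parameterisation resembling
#' estimates for arthropod mitochondrial COI: elevated AG/CT
#' exchangeabilities, strong gamma heterogeneity, and a fifth of sites
#' invariant.
#'
#' @return a [substitution_model].
#' @export
coi_like_model <- function() {
  substitution_model(exch = c(1, 4, 1, 1, 7, 1),
                     freqs = c(0.30, 0.18, 0.15, 0.37),
                     gamma_shape = 0.5, p_inv = 0.2)
}

#' Simulate a complete synthetic dataset with known truth
#'
#' One-call generator for recovery experiments: Yule tree, lognormal branch
#' rates with optional clade multipliers, and a codon alignment. Defaults
#' emulate a small COI-like study: 16 taxa, four named clades of four taxa
#' each, strict clock, and codon-position multipliers that concentrate
#' substitutions on position 3.
#'
#' @param n_tips,birth_rate passed to [simulate_yule_tree()].
#' @param ucld_stdev,clade_multipliers passed to [assign_branch_rates()].
#' @param clades named list of tip-label vectors; `NULL` auto-defines
#'   clades `A`, `B`, ... as disjoint monophyletic groups whose sizes fall
#'   in `clade_size` (a `c(min, max)` range).
#' @param clade_size size range of auto-defined clades.
#' @param model a [substitution_model]; default [coi_like_model()].
#' @param n_sites,partition_multipliers passed to [simulate_alignment()].
#' @param seed integer seed driving all three stages.
#' @return list with `aln` (a [codon_alignment]) and `truth` (a `sim_truth`).
#' @export
simulate_dataset <- function(n_tips = 16L, birth_rate = 1,
                             ucld_stdev = 0, clade_multipliers = NULL,
                             clades = NULL, clade_size = c(3L, 5L),
                             model = coi_like_model(), n_sites = 900L,
                             partition_multipliers = c(0.45, 0.15, 2.40),
                             seed = 1L) {
  tree <- simulate_yule_tree(n_tips, birth_rate, seed = seed)
  if (is.null(clades)) clades <- auto_clades(tree, clade_size)
  tree <- assign_branch_rates(tree, ucld_stdev, clade_multipliers, clades,
                              seed = seed + 1L)
  aln <- simulate_alignment(tree, model, n_sites, partition_multipliers,
                            seed = seed + 2L)
  truth <- sim_truth(tree = tree, model = model,
                     clade_multipliers = clade_multipliers, clades = clades,
                     partition_multipliers = partition_multipliers,
                     ucld_stdev = ucld_stdev, seed = seed)
  list(aln = aln, truth = truth)
}

# Disjoint monophyletic clades of `min_size` to `max_size` tips (greedy,
# smallest first), named A, B, C, ...
auto_clades <- function(tree, min_size = 3L, max_size = 5L) {
  if (length(min_size) == 2L) { max_size <- min_size[2]; min_size <- min_size[1] }
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  desc <- phangorn::Descendants(phy, (ntip + 1L):(ntip + phy$Nnode),
                                type = "tips")
  counts <- lengths(desc)
  used <- logical(ntip)
  clades <- list()
  for (i in order(counts)) {
    if (counts[i] < min_size || counts[i] > max_size) next
    tips <- desc[[i]]
    if (any(used[tips])) next
    used[tips] <- TRUE
    clades[[LETTERS[length(clades) + 1L]]] <- phy$tip.label[tips]
  }
  clades
}

#' Packaged 16-taxon rate-study topology
#'
#' A fixed ultrametric topology emulating the geometry that makes
#' clade-specific rate deviations identifiable in relative-rate analyses:
#' densely sampled named groups whose crown ages are a large fraction of the
#' root age, packed under a shallow backbone (as hexapod orders are under
#' the arthropod root). On such a tree a rate multiplier on a clade cannot
#' be absorbed by stretching the clade's crown node heights, because the
#' crown is boxed in by its stem parent and the backbone is pinned by the
#' other groups' crowns; the signal is forced into the branch rates (see the
#' methods vignette). Root height 1.5, four named clades: A (5 tips, crown
#' 1.0), B (4 tips, crown 0.9), C (4 tips, crown 0.85), D (2 tips, crown
#' 0.4), plus a free tip.
#'
#' @return a [timetree] with attribute `clades` (named list of tip labels).
#' @export
deep_crown_tree <- function() {
  nw <- paste0(
    "((((a1:0.3,a2:0.3):0.7,(a3:0.55,(a4:0.25,a5:0.25):0.3):0.45):0.2,",
    "(b1:0.9,(b2:0.6,(b3:0.3,b4:0.3):0.3):0.3):0.3):0.3,",
    "((c1:0.85,(c2:0.55,(c3:0.25,c4:0.25):0.3):0.3):0.3,",
    "((d1:0.4,d2:0.4):0.4,f1:0.8):0.35):0.35);")
  tt <- read_timetree(nw, text = TRUE)
  attr(tt, "clades") <- list(A = paste0("a", 1:5), B = paste0("b", 1:4),
                             C = paste0("c", 1:4), D = c("d1", "d2"))
  tt
}

#' Truth record for a synthetic dataset
#'
#' Bundles everything the generator drew - tree with branch rates, clade
#' definitions and multipliers, substitution model, partition multipliers,
#' lognormal spread and seed - so inference output can be scored against it.
#' Serialises to a plain-text key-value file that round-trips bit-exactly
#' through [write_truth()] / [read_truth()].
#'
#' @param tree rate-annotated [timetree].
#' @param model a [substitution_model].
#' @param clade_multipliers named multipliers (may be `NULL`).
#' @param clades named list of tip labels.
#' @param partition_multipliers length-3 numeric.
#' @param ucld_stdev lognormal spread used.
#' @param seed integer seed used.
#' @return an object of class `sim_truth`.
#' @export
sim_truth <- function(tree, model, clade_multipliers, clades,
                      partition_multipliers, ucld_stdev, seed) {
  structure(list(tree = tree, model = model,
                 clade_multipliers = clade_multipliers, clades = clades,
                 partition_multipliers = as.numeric(partition_multipliers),
                 ucld_stdev = ucld_stdev, seed = as.integer(seed)),
            class = "sim_truth")
}

#' @rdname sim_truth
#' @param truth a `sim_truth`.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  m <- truth$model
  kv <- c(
    paste0("seed\t", truth$seed),
    paste0("ucld_stdev\t", fmt_num(truth$ucld_stdev)),
    paste0("partition_multipliers\t",
           paste(fmt_num(truth$partition_multipliers), collapse = ",")),
    paste0("exch\t", paste(fmt_num(unname(m$exch)), collapse = ",")),
    paste0("freqs\t", paste(fmt_num(unname(m$freqs)), collapse = ",")),
    paste0("gamma_shape\t", fmt_num(m$gamma_shape)),
    paste0("ncat\t", m$ncat),
    paste0("p_inv\t", fmt_num(m$p_inv)),
    paste0("clade_multipliers\t",
           if (length(truth$clade_multipliers))
             paste(names(truth$clade_multipliers),
                   vapply(truth$clade_multipliers, fmt_num, ""),
                   sep = "=", collapse = ",") else ""),
    vapply(names(truth$clades), function(nm)
      paste0("clade\t", nm, ":", paste(truth$clades[[nm]], collapse = ",")), ""),
    paste0("tree\t", write_timetree(truth$tree))
  )
  writeLines(kv, path)
  invisible(path)
}

#' @rdname sim_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(parts, `[`, "", 1L)
  val <- function(k) {
    v <- parts[[match(k, keys)]]
    if (length(v) < 2L) "" else v[2L]
  }
  nums <- function(k) as.numeric(strsplit(val(k), ",", fixed = TRUE)[[1]])
  cm_raw <- val("clade_multipliers")
  cm <- NULL
  if (nzchar(cm_raw)) {
    pieces <- strsplit(strsplit(cm_raw, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
    cm <- setNames(as.numeric(vapply(pieces, `[`, "", 2L)),
                   vapply(pieces, `[`, "", 1L))
  }
  clades <- list()
  for (p in parts[keys == "clade"]) {
    cc <- strsplit(p[2L], ":", fixed = TRUE)[[1]]
    clades[[cc[1L]]] <- strsplit(cc[2L], ",", fixed = TRUE)[[1]]
  }
  model <- substitution_model(exch = nums("exch"), freqs = nums("freqs"),
                              gamma_shape = as.numeric(val("gamma_shape")),
                              ncat = as.integer(val("ncat")),
                              p_inv = as.numeric(val("p_inv")))
  sim_truth(tree = read_timetree(val("tree"), text = TRUE), model = model,
            clade_multipliers = cm, clades = clades,
            partition_multipliers = nums("partition_multipliers"),
            ucld_stdev = as.numeric(val("ucld_stdev")),
            seed = as.integer(val("seed")))
}
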