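#' Time tree with node heights and branch rates
#'
#' A `timetree` wraps an [ape::phylo] topology together with node heights in
#' relative time (tips at height 0, every parent strictly above its children)
#' and, optionally, one substitution rate per branch
#' (substitutions/site/time). Branch lengths of the underlying `phylo` are
#' kept in time units; the expected number of substitutions on a branch is
#' rate x time span.
#'
#' @param phylo a rooted, strictly binary `phylo` object.
#' @param heights numeric vector of node heights indexed by ape node id
#'   (tips `1..n`, then internal nodes). If `NULL`, heights are derived from
#'   `phylo$edge.length`, which must then describe an ultrametric tree.
#' @param rates numeric vector of per-branch rates aligned with the rows of
#'   `phylo$edge`, or `NULL` if rates have not been assigned.
#' @return an object of class `timetree` with elements `phylo`, `heights`,
#'   `rates`.
#' @seealso [simulate_yule_tree()], [assign_branch_rates()]
#' @export
timetree <- function(phylo, heights = NULL, rates = NULL) {
  if (!inherits(phylo, "phylo")) stop("phylo must be an ape 'phylo' object")
  if (!ape::is.rooted(phylo)) stop("tree must be rooted")
  if (!ape::is.binary(phylo)) stop("tree must be strictly binary (no polytomies)")
  if (anyDuplicated(phylo$tip.label)) stop("duplicate tip labels")
  n <- length(phylo$tip.label)
  ntot <- n + phylo$Nnode
  if (is.null(heights)) {
    if (is.null(phylo$edge.length))
      stop("heights are required when the tree has no branch lengths")
    depth <- ape::node.depth.edgelength(phylo)
    h <- max(depth) - depth
    if (any(abs(h[seq_len(n)]) > 1e-8 * max(depth)))
      stop("tree is not ultrametric; supply node heights explicitly")
    h[seq_len(n)] <- 0
    heights <- h
  }
  heights <- as.numeric(heights)
  if (length(heights) != ntot) stop("heights must have one entry per node")
  span <- heights[phylo$edge[, 1]] - heights[phylo$edge[, 2]]
  if (any(span <= 0)) stop("every parent must be strictly higher than its children")
  keep_lengths <- !is.null(phylo$edge.length) &&
    max(abs(phylo$edge.length - span)) <= 1e-9 * max(span)
  if (!is.null(rates)) {
    rates <- as.numeric(rates)
    if (length(rates) != nrow(phylo$edge)) stop("one rate per branch required")
    if (any(rates <= 0)) stop("branch rates must be strictly positive")
  }
  if (!keep_lengths) phylo$edge.length <- span
  structure(list(phylo = phylo, heights = heights, rates = rates),
            class = "timetree")
}

#' @export
print.timetree <- function(x, ...) {
  n <- length(x$phylo$tip.label)
  cat("timetree:", n, "tips, root height",
      format(x$heights[n + 1L], digits = 5),
      if (is.null(x$rates)) "(no branch rates)" else "(branch rates assigned)",
      "\n")
  invisible(x)
}

#' @export
as.phylo.timetree <- function(x, ...) x$phylo

# Time span of each branch, aligned with rows of phylo$edge.
edge_timespans <- function(tt) {
  tt$heights[tt$phylo$edge[, 1]] - tt$heights[tt$phylo$edge[, 2]]
}

# Node ids of the tips named in `taxa`; errors name the offenders.
tip_ids <- function(phy, taxa) {
  idx <- match(taxa, phy$tip.label)
  if (anyNA(idx))
    stop("unknown taxa: ", paste(taxa[is.na(idx)], collapse = ", "))
  idx
}

# TRUE if `taxa` form a monophyletic group on the (rooted) tree.
clade_is_monophyletic <- function(phy, taxa) {
  idx <- tip_ids(phy, taxa)
  if (length(idx) == length(phy$tip.label)) return(TRUE)
  if (length(idx) == 1L) return(TRUE)
  mrca <- ape::getMRCA(phy, idx)
  tips <- unlist(phangorn::Descendants(phy, mrca, type = "tips"))
  length(tips) == length(idx)
}

#' Crown branches of a clade
#'
#' Indices (rows of `phylo$edge`) of the branches strictly inside a clade:
#' every branch whose parent node lies at or below the clade's most recent
#' common ancestor. The stem branch leading into the MRCA is excluded, so
#' these are the "within-clade" branches used for rate summaries.
#'
#' @param tt a [timetree] (or bare `phylo`).
#' @param taxa character vector of tip labels defining the clade (must be
#'   monophyletic).
#' @return integer vector of edge indices.
#' @export
clade_edges <- function(tt, taxa) {
  phy <- if (inherits(tt, "timetree")) tt$phylo else tt
  idx <- tip_ids(phy, taxa)
  if (length(idx) < 2L) return(integer(0))
  if (!clade_is_monophyletic(phy, taxa))
    stop("clade is not monophyletic on this tree: ",
         paste(taxa, collapse = ", "), call. = FALSE)
  mrca <- ape::getMRCA(phy, idx)
  inside <- c(mrca, unlist(phangorn::Descendants(phy, mrca, type = "all")))
  which(phy$edge[, 1] %in% inside)
}

# --- Newick serialisation with branch-rate annotations -----------------------

fmt_num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)

#' Write a time tree as annotated Newick
#'
#' Serialises a [timetree] to Newick with branch lengths in time units and,
#' when rates are present, per-branch annotations in BEAST-style comment
#' blocks (`taxon[&rate=r]:length`). The format round-trips exactly through
#' [read_timetree()].
#'
#' @param tt a [timetree].
#' @param path output file; if `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_timetree <- function(tt, path = NULL) {
  phy <- tt$phylo
  n <- length(phy$tip.label)
  children <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  edge_of <- integer(n + phy$Nnode)
  edge_of[phy$edge[, 2]] <- seq_len(nrow(phy$edge))
  rec <- function(node) {
    lab <- if (node <= n) phy$tip.label[node] else ""
    kids <- children[[as.character(node)]]
    body <- if (is.null(kids)) lab else
      paste0("(", paste(vapply(phy$edge[kids, 2], rec, ""), collapse = ","), ")", lab)
    e <- edge_of[node]
    if (e == 0L) return(body)  # root
    ann <- if (!is.null(tt$rates)) paste0("[&rate=", fmt_num(tt$rates[e]), "]") else ""
    paste0(body, ann, ":", fmt_num(phy$edge.length[e]))
  }
  s <- paste0(rec(n + 1L), ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Read an annotated Newick time tree
#'
#' Parses Newick as written by [write_timetree()], including optional
#' `[&rate=...]` branch annotations, into a [timetree]. Branch lengths are
#' interpreted as time spans and must describe an ultrametric tree.
#'
#' @param path file path, or a Newick string when `text = TRUE`.
#' @param text logical; treat `path` as the Newick text itself.
#' @return a [timetree].
#' @export
read_timetree <- function(path, text = FALSE) {
  s <- if (text) path else paste(readLines(path, warn = FALSE), collapse = "")
  s <- gsub("[[:space:]]", "", s)
  pos <- 1L
  nchar_s <- nchar(s)
  peek <- function() substr(s, pos, pos)
  take_while <- function(stop_chars) {
    start <- pos
    while (pos <= nchar_s && !(substr(s, pos, pos) %in% stop_chars))
      pos <<- pos + 1L
    substr(s, start, pos - 1L)
  }
  tips <- character(0)
  edges <- list()   # list of c(parent, child) using temporary negative ids for internals
  lens <- numeric(0); rates <- numeric(0)
  n_int <- 0L
  parse_node <- function() {
    if (peek() == "(") {
      pos <<- pos + 1L
      n_int <<- n_int + 1L
      me <- -n_int
      repeat {
        child <- parse_node()
        edges[[length(edges) + 1L]] <<- c(me, child$id, child$len, child$rate)
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("malformed Newick near position ", pos)
      }
      take_while(c("[", ":", ",", ")", ";"))  # internal label ignored
      id <- me
    } else {
      lab <- take_while(c("[", ":", ",", ")", ";"))
      if (!nzchar(lab)) stop("empty tip label near position ", pos)
      tips <<- c(tips, lab)
      id <- length(tips)
    }
    rate <- NA_real_
    if (peek() == "[") {
      pos <<- pos + 1L
      ann <- take_while("]")
      pos <<- pos + 1L
      m <- regmatches(ann, regexec("&rate=([-0-9.eE+]+)", ann))[[1]]
      if (length(m) == 2L) rate <- as.numeric(m[2])
    }
    len <- NA_real_
    if (peek() == ":") {
      pos <<- pos + 1L
      len <- as.numeric(take_while(c("[", ",", ")", ";")))
      if (peek() == "[") {  # tolerate annotation after the length as well
        pos <<- pos + 1L
        ann <- take_while("]")
        pos <<- pos + 1L
        m <- regmatches(ann, regexec("&rate=([-0-9.eE+]+)", ann))[[1]]
        if (length(m) == 2L) rate <- as.numeric(m[2])
      }
    }
    list(id = id, len = len, rate = rate)
  }
  root <- parse_node()
  if (peek() != ";") stop("expected ';' at end of Newick")
  ntip <- length(tips)
  emat <- do.call(rbind, edges)
  renum <- function(id) as.integer(ifelse(id > 0, id, ntip + (-id)))
  edge <- cbind(renum(emat[, 1]), renum(emat[, 2]))
  if (anyNA(emat[, 3])) stop("every non-root branch needs a length")
  phy <- structure(list(edge = edge, tip.label = tips, Nnode = n_int,
                        edge.length = emat[, 3]), class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  o <- match(paste(phy$edge[, 1], phy$edge[, 2]), paste(edge[, 1], edge[, 2]))
  r <- emat[o, 4]
  timetree(phy, rates = if (anyNA(r)) NULL else r)
}
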