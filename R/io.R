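# Readers and writers for the pipeline's file formats.

#' Read a codon alignment
#'
#' Reads FASTA or NEXUS (sequential or interleaved) into a
#' [codon_alignment], deriving the codon-position map from a reading-frame
#' offset: with `frame_offset = 1` the first alignment column is codon
#' position 2.
#'
#' @param path input file.
#' @param format `"fasta"` or `"nexus"`.
#' @param frame_offset 0, 1 or 2.
#' @return a [codon_alignment].
#' @export
read_alignment <- function(path, format = c("fasta", "nexus"),
                           frame_offset = 0L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  seqs <- if (format == "fasta") {
    lapply(as.character(ape::read.FASTA(path)), toupper)
  } else {
    lapply(ape::read.nexus.data(path), toupper)
  }
  if (!length(seqs)) stop("no sequences in ", path)
  if (anyDuplicated(names(seqs)))
    stop("duplicate taxon labels in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment in ", path, ": lengths ",
         paste(unique(lens), collapse = ", "))
  m <- do.call(rbind, seqs)
  codon_map <- ((seq_len(ncol(m)) - 1L + frame_offset) %% 3L) + 1L
  codon_alignment(m, codon_map)
}

#' Write a codon alignment as FASTA
#'
#' @param aln a [codon_alignment].
#' @param path output file.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "codon_alignment"))
  lines <- as.vector(rbind(paste0(">", rownames(aln$matrix)),
                           apply(aln$matrix, 1, paste, collapse = "")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a constraint tree
#'
#' Reads a rooted, fully resolved (binary) tree in Newick or NEXUS format.
#' If branch lengths describe an ultrametric tree they become the node
#' heights; otherwise heights are initialised by Grafen's method and only
#' the topology is meaningful (the relaxed-clock fit estimates heights).
#'
#' @param path input file.
#' @param format `"newick"` or `"nexus"`.
#' @return a [timetree].
#' @export
read_tree <- function(path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  phy <- if (format == "newick") ape::read.tree(path) else ape::read.nexus(path)
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  if (is.null(phy)) stop("could not parse a tree from ", path)
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels in ", path)
  if (!ape::is.rooted(phy)) stop("tree in ", path, " is unrooted; the fixed-",
                                 "topology engine needs a rooted tree")
  if (!ape::is.binary(phy))
    stop("tree in ", path, " contains polytomies; resolve it fully ",
         "before running the fixed-topology engine")
  if (!is.null(phy$edge.length)) {
    depth <- ape::node.depth.edgelength(phy)
    ntip <- length(phy$tip.label)
    if (max(depth) > 0 &&
        all(abs(max(depth) - depth[seq_len(ntip)]) < 1e-6 * max(depth)))
      return(timetree(phy))
  }
  timetree(init_heights_phylo(phy))
}

#' Read clade definitions
#'
#' Plain-text clade file: one clade per line, `name: taxon1 taxon2 ...`
#' (commas also accepted as separators). Lines starting with `#` and blank
#' lines are ignored.
#'
#' @param path input file.
#' @return named list of character vectors.
#' @export
read_clades <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    i <- regexpr(":", ln, fixed = TRUE)
    if (i < 1) stop("malformed clade line (missing ':'): ", ln)
    nm <- trimws(substr(ln, 1, i - 1))
    taxa <- strsplit(trimws(substr(ln, i + 1, nchar(ln))), "[,[:space:]]+")[[1]]
    taxa <- taxa[nzchar(taxa)]
    if (!nzchar(nm) || !length(taxa)) stop("malformed clade line: ", ln)
    out[[nm]] <- taxa
  }
  out
}

#' Write clade definitions
#' @param clades named list of tip labels.
#' @param path output file.
#' @export
write_clades <- function(clades, path) {
  writeLines(vapply(names(clades), function(nm)
    paste0(nm, ": ", paste(clades[[nm]], collapse = " ")), ""), path)
  invisible(path)
}

#' Read a key-value run configuration
#'
#' Plain-text `key = value` lines (comments with `#`). Values that parse as
#' numbers become numeric; `true`/`false` become logical.
#'
#' @param path input file.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    i <- regexpr("=", ln, fixed = TRUE)
    if (i < 1) stop("malformed config line (missing '='): ", ln)
    key <- trimws(substr(ln, 1, i - 1))
    val <- trimws(substr(ln, i + 1, nchar(ln)))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
      else val
  }
  out
}

# Provenance header written at the top of every pipeline output.
provenance_header <- function(seed, config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  config <- config[setdiff(names(config), "outdir")]
  writeLines(deparse(config[order(names(config))]), tmp)
  hash <- unname(tools::md5sum(tmp))
  c(paste0("# ratecon ", as.character(packageVersion("ratecon"))),
    paste0("# seed=", seed, " config_md5=", hash))
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}
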