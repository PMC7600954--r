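#' Codon alignment container
#'
#' A nucleotide alignment with taxon labels and a codon-position map.
#' Symbols are IUPAC nucleotide codes (upper case) including gaps; anything
#' other than A, C, G, T is treated as missing by the distance, entropy and
#' likelihood machinery.
#'
#' @param matrix character matrix, one row per taxon (rownames are the taxon
#'   labels), one column per site.
#' @param codon_map integer vector in `{1,2,3}`, one entry per site.
#' @return an object of class `codon_alignment`.
#' @export
codon_alignment <- function(matrix, codon_map = NULL) {
  if (!is.matrix(matrix) || !is.character(matrix))
    stop("matrix must be a character matrix")
  if (is.null(rownames(matrix))) stop("matrix must have taxon rownames")
  if (anyDuplicated(rownames(matrix))) stop("duplicate taxon labels")
  if (nrow(matrix) < 2L) stop("an alignment needs at least 2 taxa")
  matrix[] <- toupper(matrix)
  if (is.null(codon_map)) codon_map <- rep_len(1:3, ncol(matrix))
  codon_map <- as.integer(codon_map)
  if (length(codon_map) != ncol(matrix) || !all(codon_map %in% 1:3))
    stop("codon_map must assign every site a position in {1,2,3}")
  structure(list(matrix = matrix, codon_map = codon_map),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", nrow(x$matrix), "taxa x", ncol(x$matrix), "sites\n")
  invisible(x)
}

#' @export
dim.codon_alignment <- function(x) dim(x$matrix)

taxa_labels <- function(aln) rownames(aln$matrix)

# Subset an alignment to the given codon positions (keeps the map).
subset_positions <- function(aln, positions) {
  keep <- aln$codon_map %in% positions
  codon_alignment(aln$matrix[, keep, drop = FALSE], aln$codon_map[keep])
}

# Integer encoding A=0 C=1 G=2 T=3, everything else (gap/ambiguity) 4.
encode_states <- function(m) {
  codes <- matrix(4L, nrow(m), ncol(m), dimnames = dimnames(m))
  codes[m == "A"] <- 0L; codes[m == "C"] <- 1L
  codes[m == "G"] <- 2L; codes[m == "T"] <- 3L
  codes
}

# Collapse an encoded alignment into unique site patterns.
# Returns states (ntaxa x npat), weights, and per-pattern bitmask of states
# an invariant site could have (bit s set iff all non-missing symbols == s).
alignment_patterns <- function(aln, taxa = NULL) {
  m <- encode_states(aln$matrix)
  if (!is.null(taxa)) {
    idx <- match(taxa, rownames(m))
    if (anyNA(idx))
      stop("alignment is missing taxa: ", paste(taxa[is.na(idx)], collapse = ", "))
    m <- m[idx, , drop = FALSE]
  }
  key <- apply(m, 2, paste, collapse = ".")
  first <- !duplicated(key)
  states <- m[, first, drop = FALSE]
  weights <- as.numeric(table(key)[key[first]])
  compat <- apply(states, 2, function(col) {
    obs <- unique(col[col < 4L])
    if (length(obs) == 0L) return(15L)
    if (length(obs) > 1L) return(0L)
    bitwShiftL(1L, obs)
  })
  list(states = states, weights = weights, compat = as.integer(compat))
}

# Empirical base frequencies over unambiguous symbols.
empirical_freqs <- function(aln) {
  m <- aln$matrix
  counts <- c(A = sum(m == "A"), C = sum(m == "C"),
              G = sum(m == "G"), T = sum(m == "T"))
  if (sum(counts) == 0) stop("alignment contains no unambiguous bases")
  counts / sum(counts)
}
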