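# Shared conventions
#
# * Genomic coordinates are 1-based inclusive throughout the tabular API;
#   BED exports are 0-based half-open.
# * A poly(A) site is the coordinate of the LAST genome-templated nucleotide
#   before the tail, in transcript sense ("-1 position" of the flank).
# * Flank sequences are 150 nt in transcript sense with position labels
#   -100..-1 (site at -1) then +1..+50; there is no position 0.

#' Coerce a genome to a named DNAStringSet
#'
#' Accepts a `Biostrings::DNAStringSet`, a named character vector of
#' chromosome sequences, or a path to a FASTA file.
#'
#' @param genome Genome in any of the accepted forms.
#' @return A named [Biostrings::DNAStringSet].
#' @export
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    if (is.null(names(genome))) stop("genome sequences must be named")
    return(genome)
  }
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    return(Biostrings::readDNAStringSet(genome))
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome sequences must be named")
    return(Biostrings::DNAStringSet(genome))
  }
  stop("cannot interpret 'genome' as a genome sequence set")
}

# plain character version for fast substr work
genome_chars <- function(genome) {
  g <- as_genome(genome)
  setNames(as.character(g), names(g))
}

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper over [Biostrings::reverseComplement()] that takes
#' and returns plain character vectors (N is preserved).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Position labels for a flank of `upstream` + `downstream` bases (site at -1).
position_labels <- function(upstream = 100, downstream = 50) {
  c(seq(-upstream, -1L), seq_len(downstream))
}

# label -> 1-based string index within a standard flank
label_to_index <- function(label, upstream = 100) {
  ifelse(label < 0, label + upstream + 1L, label + upstream)
}

# longest run of a given letter in a string (0 if absent)
max_char_run <- function(x, char = "A") {
  vapply(x, function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]] == char)
    m <- r$lengths[r$values]
    if (length(m)) max(m) else 0L
  }, integer(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
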