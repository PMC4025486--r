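# Poly(A)/(T) tail detection and read orientation.
#
# A tail is the LONGEST terminal window of the (sense-oriented) read whose
# adenosine fraction is >= min_purity and whose length is >= min_tail_length
# ("maximal by left extension"): among all suffixes that satisfy both
# thresholds the one with the smallest start index wins.

# core scalar scan: returns 1-based tail start index, or NA if no window
# qualifies. O(length) using suffix A-counts.
find_tail_start <- function(seq, min_len, min_purity) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (L < min_len) return(NA_integer_)
  a_suffix <- rev(cumsum(rev(chars == "A")))   # a_suffix[i] = #A in seq[i..L]
  len <- L - seq_len(L) + 1L
  ok <- len >= min_len & a_suffix / len >= min_purity
  if (!any(ok)) return(NA_integer_) else which(ok)[1]
}

#' Orient reads so any poly(A) evidence is a 3' tail
#'
#' cDNA reads may carry the poly(A) tail either as a trailing A-run (sense)
#' or as a leading T-run (the reverse-complemented strand). If a qualifying
#' trailing A-tail exists the read is kept as-is; otherwise, if the reverse
#' complement would carry a qualifying tail (i.e. the read starts with a
#' qualifying T-head), the reverse complement is returned and flagged. When
#' both a qualifying A-tail and T-head are present the A-tail wins, which
#' avoids double-counting chimeric reads.
#'
#' @param reads Tibble with columns `read_id` and `seq` (A/C/G/T/N), or a
#'   character vector of sequences.
#' @param params A [polya_params()] rule set.
#' @return The input tibble with `seq` replaced by the oriented sequence and
#'   a logical column `was_polyt_head` added.
#' @examples
#' r <- tibble::tibble(read_id = "r1",
#'                     seq = paste0(strrep("T", 16), "GCGCGTACGTTGCAGT"))
#' orient_reads(r, polya_params("est"))
#' @export
orient_reads <- function(reads, params = polya_params("est")) {
  reads <- normalise_reads(reads)
  if (any(!nzchar(reads$seq))) stop("empty read sequence")
  a_start <- vapply(reads$seq, find_tail_start, integer(1),
                    min_len = params$min_tail_length,
                    min_purity = params$min_purity, USE.NAMES = FALSE)
  need_rc <- is.na(a_start)
  if (any(need_rc)) {
    rc <- revcomp(reads$seq[need_rc])
    t_start <- vapply(rc, find_tail_start, integer(1),
                      min_len = params$min_tail_length,
                      min_purity = params$min_purity, USE.NAMES = FALSE)
    flip <- !is.na(t_start)
    reads$seq[need_rc][flip] <- rc[flip]
    was_t <- logical(nrow(reads))
    was_t[need_rc] <- flip
  } else {
    was_t <- logical(nrow(reads))
  }
  reads$was_polyt_head <- was_t
  reads
}

#' Detect and trim poly(A) tails from oriented reads
#'
#' Applies the terminal-window tail definition to each (sense-oriented) read.
#' Reads without a qualifying tail get `NA` in the tail columns; callers
#' typically `dplyr::filter(!is.na(tail_length))` before mapping.
#'
#' @inheritParams orient_reads
#' @return Input tibble with columns `body` (read prefix before the tail),
#'   `tail_length`, and `tail_purity` appended.
#' @examples
#' r <- tibble::tibble(read_id = "r1", seq = paste0("CCGT", strrep("A", 12)))
#' find_tails(r, polya_params("est"))
#' @export
find_tails <- function(reads, params = polya_params("est")) {
  reads <- normalise_reads(reads)
  start <- vapply(reads$seq, find_tail_start, integer(1),
                  min_len = params$min_tail_length,
                  min_purity = params$min_purity, USE.NAMES = FALSE)
  L <- nchar(reads$seq)
  reads$body <- ifelse(is.na(start), NA_character_,
                       substr(reads$seq, 1L, start - 1L))
  reads$tail_length <- ifelse(is.na(start), NA_integer_, L - start + 1L)
  tailseq <- ifelse(is.na(start), NA_character_, substr(reads$seq, start, L))
  reads$tail_purity <- ifelse(
    is.na(start), NA_real_,
    stringr::str_count(tailseq, "A") / reads$tail_length)
  reads
}

normalise_reads <- function(reads) {
  if (is.character(reads)) {
    reads <- tibble(read_id = paste0("read", seq_along(reads)), seq = reads)
  }
  stopifnot(is.data.frame(reads), all(c("read_id", "seq") %in% names(reads)))
  as_tibble(reads)
}
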