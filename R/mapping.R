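# Exact-match placement of trimmed read bodies on the genome.
#
# The mapper is deliberately simple: the body's 3'-terminal seed (default
# 20-mer) is matched exactly against both strands, then extended maximally
# to the 5' side. Unmappable bases between the aligned end and the tail
# prevent the terminal seed from matching, so the seed is retried after
# clipping 1, 2, ... terminal bases. Clipped adenosines are tail material
# (a tail trimmed at its last impurity leaves a partial A-run plus the
# impurity on the body), so only clipped non-A bases count as nontemplated
# additions, and clipping stops once they would exceed the nontemplated
# cap. Reads whose best-scoring placement is not unique are discarded (no
# multi-mapping resolution); spliced alignment is out of scope because
# 3'-terminal fragments are modelled as unspliced.

# longest common suffix length of two strings
lcs_len <- function(a, b) {
  ca <- rev(strsplit(a, "", fixed = TRUE)[[1]])
  cb <- rev(strsplit(b, "", fixed = TRUE)[[1]])
  n <- min(length(ca), length(cb))
  if (n == 0L) return(0L)
  neq <- which(ca[seq_len(n)] != cb[seq_len(n)])
  if (length(neq)) neq[1] - 1L else n
}

map_one_body <- function(body, genome_set, genome_chr, seed_length,
                         max_clip, max_nontemplated, min_body) {
  Lb <- nchar(body)
  none <- list(ok = FALSE)
  # cumulative non-A count of the clipped terminal segment, from the 3' end
  rev_chars <- rev(strsplit(body, "", fixed = TRUE)[[1]])
  non_a <- cumsum(rev_chars != "A")
  for (drop in 0:max_clip) {
    nt_eff <- if (drop == 0L) 0L else non_a[drop]
    if (nt_eff > max_nontemplated) break
    bl <- Lb - drop
    if (bl < max(seed_length, min_body)) break
    b <- substr(body, 1L, bl)
    seed <- substr(b, bl - seed_length + 1L, bl)
    if (grepl("N", seed, fixed = TRUE)) next
    prefix <- substr(b, 1L, bl - seed_length)
    hits <- list()
    plus <- Biostrings::vmatchPattern(seed, genome_set)
    for (ci in seq_along(plus)) {
      for (j in seq_along(plus[[ci]])) {
        s <- BiocGenerics::start(plus[[ci]])[j]
        e <- BiocGenerics::end(plus[[ci]])[j]
        avail <- min(nchar(prefix), s - 1L)
        up <- if (avail > 0) substr(genome_chr[[ci]], s - avail, s - 1L) else ""
        ext <- lcs_len(prefix, up)
        hits[[length(hits) + 1L]] <- list(
          chrom = names(genome_chr)[ci], strand = "+",
          start = s - ext, end = e, score = seed_length + ext)
      }
    }
    minus <- Biostrings::vmatchPattern(revcomp(seed), genome_set)
    for (ci in seq_along(minus)) {
      clen <- nchar(genome_chr[[ci]])
      for (j in seq_along(minus[[ci]])) {
        s <- BiocGenerics::start(minus[[ci]])[j]
        e <- BiocGenerics::end(minus[[ci]])[j]
        avail <- min(nchar(prefix), clen - e)
        dn <- if (avail > 0) substr(genome_chr[[ci]], e + 1L, e + avail) else ""
        ext <- lcs_len(prefix, revcomp(dn))
        hits[[length(hits) + 1L]] <- list(
          chrom = names(genome_chr)[ci], strand = "-",
          start = s, end = e + ext, score = seed_length + ext)
      }
    }
    if (!length(hits)) next
    scores <- vapply(hits, `[[`, numeric(1), "score")
    best <- which(scores == max(scores))
    if (length(best) != 1L) return(none)  # ambiguous placement
    h <- hits[[best]]
    h$ok <- TRUE
    h$clipped <- drop
    h$nontemplated <- nt_eff
    return(h)
  }
  none
}

#' Map trimmed read bodies to a reference genome
#'
#' @param tailed Tibble from [find_tails()] (rows with `NA` tails are
#'   dropped with a message).
#' @param genome Genome accepted by [as_genome()].
#' @param seed_length Length of the 3'-terminal exact seed.
#' @param min_body Minimum aligned body length.
#' @param max_clip Maximum terminal bases clipped while retrying the seed
#'   (residual tail adenosines plus nontemplated additions).
#' @param params [polya_params()] providing the nontemplated cap: clipping
#'   stops once the clipped segment holds more than `max_nontemplated`
#'   non-A bases.
#' @return Tibble of uniquely placed reads: `read_id`, `chrom`, `strand`,
#'   `start`, `end` (1-based aligned span on the plus strand), `clipped`
#'   (total bases between aligned end and detected tail), `nontemplated`
#'   (the non-A ones), and the tail columns carried through. Unmapped or
#'   ambiguous reads are absent.
#' @export
map_reads <- function(tailed, genome, seed_length = 20L, min_body = 20L,
                      max_clip = 100L, params = polya_params("est")) {
  genome_set <- as_genome(genome)
  genome_chr <- genome_chars(genome_set)
  tailed <- dplyr::filter(tailed, !is.na(.data$body))
  res <- purrr::map(tailed$body, map_one_body,
                    genome_set = genome_set, genome_chr = genome_chr,
                    seed_length = as.integer(seed_length),
                    max_clip = as.integer(max_clip),
                    max_nontemplated = params$max_nontemplated,
                    min_body = as.integer(min_body))
  ok <- map_lgl(res, "ok")
  out <- tailed[ok, , drop = FALSE]
  out$chrom <- map_chr(res[ok], "chrom")
  out$strand <- map_chr(res[ok], "strand")
  out$start <- map_int(res[ok], ~ as.integer(.x$start))
  out$end <- map_int(res[ok], ~ as.integer(.x$end))
  out$clipped <- map_int(res[ok], ~ as.integer(.x$clipped))
  out$nontemplated <- map_int(res[ok], ~ as.integer(.x$nontemplated))
  as_tibble(out)
}
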