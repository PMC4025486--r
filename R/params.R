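#' Tail-calling rule sets
#'
#' Bundles the thresholds that define a valid poly(A) tail and a valid
#' cleavage-site call. Two presets mirror the two families of input data:
#'
#' * `"est"` — Sanger EST-style reads: minimum tail length 10 nt and a strict
#'   all-A tail (purity 1.0).
#' * `"ngs"` — 454/Illumina-style reads: minimum tail length 15 nt and 95%
#'   adenosine purity over the terminal tail window.
#'
#' Both presets allow at most 4 genome-templated adenosines to be reassigned
#' from the aligned read end into the tail, and at most 3 nontemplated
#' nucleotides between the aligned end and the tail start.
#'
#' @param mode `"est"` or `"ngs"`.
#' @param min_tail_length Minimum valid tail length in nt.
#' @param min_purity Minimum fraction of A in the terminal tail window.
#' @param max_genomic_a Maximum aligned genomic adenosines absorbed into the
#'   tail before a call is rejected.
#' @param max_nontemplated Maximum nontemplated nucleotides between the
#'   aligned 3' end and the tail start.
#' @return A list of class `polya_params`.
#' @examples
#' polya_params("est")
#' polya_params("ngs", min_tail_length = 12)
#' @export
polya_params <- function(mode = c("est", "ngs"),
                         min_tail_length = NULL,
                         min_purity = NULL,
                         max_genomic_a = 4L,
                         max_nontemplated = 3L) {
  mode <- match.arg(mode)
  defaults <- switch(mode,
    est = list(min_tail_length = 10L, min_purity = 1.0),
    ngs = list(min_tail_length = 15L, min_purity = 0.95)
  )
  p <- list(
    mode = mode,
    min_tail_length = as.integer(min_tail_length %||% defaults$min_tail_length),
    min_purity = min_purity %||% defaults$min_purity,
    max_genomic_a = as.integer(max_genomic_a),
    max_nontemplated = as.integer(max_nontemplated)
  )
  stopifnot(p$min_tail_length >= 1L, p$min_purity > 0, p$min_purity <= 1,
            p$max_genomic_a >= 0L, p$max_nontemplated >= 0L)
  structure(p, class = "polya_params")
}

#' @export
print.polya_params <- function(x, ...) {
  cat(sprintf(
    "<polya_params> mode=%s min_tail=%d min_purity=%.2f max_genomic_A=%d max_nontemplated=%d\n",
    x$mode, x$min_tail_length, x$min_purity, x$max_genomic_a, x$max_nontemplated))
  invisible(x)
}
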