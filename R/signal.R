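# Exhaustive k-mer signal scanning in windows around poly(A) sites, with
# three counting modes, and Z-scores against Markov-chain backgrounds.
#
# Modes:
#  * overlapping  — every match start is counted (gap ignored);
#  * distribution — greedy left-to-right; a match at start s counts only if
#                   s >= previous counted start + k + gap, so gap = 0 means
#                   adjacent non-overlapping occurrences;
#  * frequency    — at most one count per sequence, the occurrence closest
#                   to the poly(A) site (position -1); ties go to the more
#                   3' occurrence.
#
# With gap = 2 the 8-mer ATATATAT scores a single count for each of ATATAT
# and TATATA in distribution mode (the second overlapping start is closer
# than k + gap), while overlapping mode counts both starts.
#
# Motifs are reported in the RNA alphabet (U for T). Windows containing N
# are skipped both in counting and in the scanned-position total.

to_rna <- function(x) chartr("T", "U", toupper(x))
to_dna <- function(x) chartr("U", "T", toupper(x))

# greedy spaced selection of sorted match starts
greedy_starts <- function(starts, k, gap) {
  sel <- integer(0)
  last <- -Inf
  for (s in starts) {
    if (s >= last + k + gap) { sel <- c(sel, s); last <- s }
  }
  sel
}

# labelled axis: collapse the missing 0 so adjacent labels differ by 1
label_axis <- function(label) ifelse(label < 0, label, label - 1L)

# per-sequence k-mer windows; list(starts, kmers) with non-ACGT dropped
seq_windows <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(list(starts = integer(0), kmers = character(0)))
  starts <- seq_len(L - k + 1L)
  kms <- substring(seq, starts, starts + k - 1L)
  ok <- !grepl("[^ACGT]", kms)
  list(starts = starts[ok], kmers = kms[ok])
}

# selected occurrence starts per sequence under a mode;
# start_labels: label of window position 1 .. (needed for frequency mode)
select_starts <- function(win, k, mode, gap, labels) {
  if (!length(win$starts)) return(list(starts = integer(0), kmers = character(0)))
  if (mode == "overlapping") return(win)
  groups <- split(win$starts, win$kmers)
  if (mode == "distribution") {
    sel <- lapply(groups, greedy_starts, k = k, gap = gap)
  } else {  # frequency: closest to -1, tie -> more 3'
    ax <- label_axis(labels)
    sel <- lapply(groups, function(st) {
      a <- ax[st]
      d <- abs(a + 1L)
      cand <- st[d == min(d)]
      cand[which.max(ax[cand])]
    })
  }
  starts <- unlist(sel, use.names = FALSE)
  kmers <- rep(names(sel), lengths(sel))
  list(starts = starts, kmers = kmers)
}

all_kmers <- function(k) {
  if (k > 6L) return(NULL)
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "U")), k),
                              stringsAsFactors = FALSE)[, k:1, drop = FALSE])
}

#' Count k-mers in a set of sequences
#'
#' Low-level counting engine behind [scan_kmers()]; operates on plain
#' character sequences (already windowed). See the mode semantics in
#' [scan_kmers()].
#'
#' @param seqs Character vector of DNA/RNA sequences.
#' @param k Motif length.
#' @param mode One of `"overlapping"`, `"distribution"`, `"frequency"`.
#' @param gap Minimum free nt between counted occurrences
#'   (distribution mode).
#' @param labels Optional integer position labels of each sequence position
#'   (needed for frequency mode; defaults to `-L..-1` ending at the site).
#' @return A `motif_table` tibble: `kmer` (RNA alphabet), `count`, `freq`
#'   (= count / number of sequences), `rank` (by decreasing frequency, ties
#'   lexicographic). Attributes: `n_sequences`, `n_positions` (total
#'   N-free windows), `k`, `mode`, `gap`.
#' @examples
#' count_kmers("ATATATAT", k = 6, mode = "distribution", gap = 2)
#' @export
count_kmers <- function(seqs, k = 5L,
                        mode = c("overlapping", "distribution", "frequency"),
                        gap = 0L, labels = NULL) {
  mode <- match.arg(mode)
  seqs <- to_dna(seqs)
  lens <- nchar(seqs)
  if (any(lens < k) && all(lens < k)) stop("k exceeds the sequence length")
  if (is.null(labels)) labels <- seq(-max(lens), -1L)
  wins <- lapply(seqs, seq_windows, k = k)
  n_positions <- sum(lengths(lapply(wins, `[[`, "starts")))
  selected <- lapply(wins, select_starts, k = k, mode = mode, gap = gap,
                     labels = labels)
  kmers_all <- to_rna(unlist(lapply(selected, `[[`, "kmers"),
                             use.names = FALSE))
  counts <- table(kmers_all)
  universe <- all_kmers(k) %||% sort(unique(names(counts)))
  out <- tibble(kmer = universe,
                count = as.integer(counts[universe]))
  out$count[is.na(out$count)] <- 0L
  out$freq <- out$count / length(seqs)
  out <- arrange(out, desc(.data$freq), .data$kmer)
  out$rank <- seq_len(nrow(out))
  structure(out, n_sequences = length(seqs), n_positions = n_positions,
            k = as.integer(k), mode = mode, gap = as.integer(gap),
            class = c("motif_table", class(out)))
}

#' Extract a labelled window from flank sequences
#'
#' @param flanks Flank tibble from [pac_flanks()] (attribute `positions`),
#'   or a character vector of equal-length sequences plus `positions`.
#' @param window Length-2 inclusive label range, e.g. `c(-28, -5)` for the
#'   near-upstream element (NUE) or `c(-100, -28)` for the far-upstream
#'   element (FUE).
#' @param positions Integer labels of the sequence positions (defaults to
#'   the flank attribute).
#' @return Character vector of window subsequences with attribute
#'   `positions` (labels of the window).
#' @export
window_sequences <- function(flanks, window = c(-28, -5), positions = NULL) {
  if (is.data.frame(flanks)) {
    positions <- positions %||% attr(flanks, "positions")
    seqs <- flanks$seq
  } else {
    seqs <- flanks
    positions <- positions %||% position_labels(
      upstream = nchar(seqs[1]), downstream = 0L)[seq_len(nchar(seqs[1]))]
  }
  idx <- which(positions >= window[1] & positions <= window[2])
  if (!length(idx)) stop("window outside the labelled positions")
  out <- substr(seqs, min(idx), max(idx))
  attr(out, "positions") <- positions[idx]
  out
}

#' Scan flanks for k-mer poly(A) signals in a position window
#'
#' Exhaustive fixed-length motif search within a labelled window relative
#' to the poly(A) site, under one of three counting modes (see Details of
#' the package vignette). The default window `c(-28, -5)` is the
#' near-upstream element where the canonical Chlamydomonas signal UGUAA
#' resides.
#'
#' @inheritParams window_sequences
#' @inheritParams count_kmers
#' @return A `motif_table` tibble (see [count_kmers()]) with attribute
#'   `window`.
#' @export
scan_kmers <- function(flanks, k = 5L, window = c(-28, -5),
                       mode = c("overlapping", "distribution", "frequency"),
                       gap = 0L, positions = NULL) {
  mode <- match.arg(mode)
  ws <- window_sequences(flanks, window, positions)
  if (k > nchar(ws[1])) stop("k exceeds the window length")
  out <- count_kmers(ws, k = k, mode = mode, gap = gap,
                     labels = attr(ws, "positions"))
  attr(out, "window") <- window
  out
}

#' Single-nucleotide profile around poly(A) sites
#'
#' Per-position base frequencies (T reported as U) over a set of
#' equal-length labelled sequences; N-padded positions are ignored in the
#' denominator.
#'
#' @inheritParams window_sequences
#' @return A `nucleotide_profile` tibble: `position`, `A`, `C`, `G`, `U`
#'   (each row sums to 1 wherever any non-N base is present).
#' @export
nucleotide_profile <- function(flanks, positions = NULL) {
  if (is.data.frame(flanks)) {
    positions <- positions %||% attr(flanks, "positions")
    seqs <- flanks$seq
  } else seqs <- flanks
  if (!length(seqs)) stop("no sequences")
  lens <- unique(nchar(seqs))
  if (length(lens) != 1L) stop("sequences must have equal length")
  positions <- positions %||% position_labels(100, 50)[seq_len(lens)]
  mat <- matrix(unlist(strsplit(to_dna(seqs), "", fixed = TRUE)),
                nrow = lens)
  freq_one <- function(row) {
    tt <- tabulate(factor(row, levels = c("A", "C", "G", "T")), nbins = 4L)
    tot <- sum(tt)
    if (tot == 0) rep(NA_real_, 4) else tt / tot
  }
  fr <- t(apply(mat, 1, freq_one))
  out <- tibble(position = positions,
                A = fr[, 1], C = fr[, 2], G = fr[, 3], U = fr[, 4])
  structure(out, class = c("nucleotide_profile", class(out)))
}

#' Positional matrix of counted motif occurrences
#'
#' Where, within the window, does a given motif occur under a counting
#' mode? Returns the distribution of counted occurrence start positions and
#' the base composition contributed by those occurrences at each window
#' position.
#'
#' @inheritParams scan_kmers
#' @param motif Motif string (RNA or DNA alphabet).
#' @return A `motif_pssm` tibble: `position` (window start labels),
#'   `count`, `freq` (start distribution over counted occurrences), and
#'   `A`, `C`, `G`, `U` giving, per window position, the fraction of
#'   counted occurrences placing that base there (0 where uncovered).
#' @export
motif_pssm <- function(flanks, motif, window = c(-28, -5),
                       mode = c("overlapping", "distribution", "frequency"),
                       gap = 0L, positions = NULL) {
  mode <- match.arg(mode)
  motif <- to_dna(motif)
  k <- nchar(motif)
  ws <- window_sequences(flanks, window, positions)
  labels <- attr(ws, "positions")
  W <- nchar(ws[1])
  wins <- lapply(ws, seq_windows, k = k)
  sel <- lapply(wins, select_starts, k = k, mode = mode, gap = gap,
                labels = labels)
  starts <- unlist(lapply(sel, function(s) s$starts[s$kmers == motif]),
                   use.names = FALSE)
  start_labels <- labels[seq_len(W - k + 1L)]
  cnt <- tabulate(starts, nbins = W - k + 1L)
  n_occ <- sum(cnt)
  base_mat <- matrix(0, nrow = W, ncol = 4,
                     dimnames = list(NULL, c("A", "C", "G", "U")))
  if (n_occ > 0) {
    mchars <- strsplit(to_rna(motif), "", fixed = TRUE)[[1]]
    for (s in which(cnt > 0)) {
      for (j in seq_len(k)) {
        base_mat[s + j - 1L, mchars[j]] <-
          base_mat[s + j - 1L, mchars[j]] + cnt[s]
      }
    }
    base_mat <- base_mat / n_occ
  }
  out <- tibble(position = start_labels,
                count = cnt,
                freq = if (n_occ > 0) cnt / n_occ else rep(0, length(cnt)),
                A = base_mat[seq_along(start_labels), "A"],
                C = base_mat[seq_along(start_labels), "C"],
                G = base_mat[seq_along(start_labels), "G"],
                U = base_mat[seq_along(start_labels), "U"])
  structure(out, motif = to_rna(motif), mode = mode,
            class = c("motif_pssm", class(out)))
}

#' Train a Markov-chain background model
#'
#' Maximum-likelihood transition frequencies of order `order` with add-one
#' smoothing, estimated from the scanned sequence set itself (the usual
#' background choice when no external model is supplied). The probability
#' of a motif is the smoothed probability of its length-`order` prefix
#' times the product of the smoothed transition probabilities.
#'
#' @param seqs Character vector of sequences (DNA or RNA; N splits counting
#'   stretches).
#' @param order Markov order (default 3).
#' @return A `markov_bg` object.
#' @export
train_markov <- function(seqs, order = 3L) {
  stopifnot(order >= 0L)
  seqs <- to_dna(seqs)
  grams <- function(m) {
    if (m == 0L) return(character(0))
    unlist(lapply(seqs, function(s) {
      w <- seq_windows(s, m)
      w$kmers
    }), use.names = FALSE)
  }
  g1 <- grams(order + 1L)
  if (length(g1) < 4^(order + 1L)) {
    warning("fewer (order+1)-grams than alphabet combinations; ",
            "background estimates may be unstable")
  }
  trans_counts <- table(g1)
  ctx_counts <- if (order > 0L) table(grams(order)) else table(character(0))
  structure(list(order = as.integer(order),
                 trans_counts = trans_counts,
                 ctx_counts = ctx_counts,
                 n_trans = length(g1),
                 n_ctx = if (order > 0L) sum(ctx_counts) else 0L),
            class = "markov_bg")
}

lookup_count <- function(tab, key) {
  v <- tab[key]
  ifelse(is.na(v), 0, as.numeric(v))
}

#' Motif probability under a Markov background
#'
#' @param motif Motif string (RNA or DNA).
#' @param background A `markov_bg` from [train_markov()].
#' @return Smoothed probability of observing the motif at a fixed position.
#' @export
motif_prob <- function(motif, background) {
  m <- background$order
  motif <- to_dna(motif)
  k <- nchar(motif)
  if (m >= k) stop("Markov order must be smaller than the motif length")
  if (m == 0L) {
    bases <- strsplit(motif, "", fixed = TRUE)[[1]]
    tot <- background$n_trans
    p <- (lookup_count(background$trans_counts, bases) + 1) / (tot + 4)
    return(prod(p))
  }
  prefix <- substr(motif, 1L, m)
  p <- (lookup_count(background$ctx_counts, prefix) + 1) /
    (background$n_ctx + 4^m)
  for (i in (m + 1L):k) {
    gram <- substr(motif, i - m, i)
    ctx <- substr(motif, i - m, i - 1L)
    # context total restricted to continuations (sum over 4 extensions)
    ctx_tot <- sum(lookup_count(background$trans_counts,
                                paste0(ctx, c("A", "C", "G", "T"))))
    p <- p * (lookup_count(background$trans_counts, gram) + 1) / (ctx_tot + 4)
  }
  unname(p)
}

#' Z-score of a motif count against a Markov background
#'
#' The expected count is `n_positions * p(motif)`; the variance uses the
#' binomial approximation `n * p * (1 - p)`. Add-one smoothing guarantees
#' `0 < p < 1`.
#'
#' @param observed Observed motif count.
#' @param motif Motif string.
#' @param background A `markov_bg`.
#' @param n_positions Total number of scanned N-free windows (attribute
#'   `n_positions` of a `motif_table`).
#' @return One-row tibble: `motif`, `observed`, `expected`, `p_motif`, `zscore`.
#' @export
motif_zscore <- function(observed, motif, background, n_positions) {
  p <- motif_prob(motif, background)
  e <- n_positions * p
  z <- (observed - e) / sqrt(n_positions * p * (1 - p))
  tibble(motif = to_rna(motif), observed = observed, expected = e,
         p_motif = p, zscore = z)
}

#' Add expected counts and Z-scores to a motif table
#'
#' @param motif_table A `motif_table` from [scan_kmers()]/[count_kmers()].
#' @param background A `markov_bg`; defaults to an order-3 model trained on
#'   `sequences`.
#' @param sequences Sequences to train the default background on (usually
#'   the scanned window sequences).
#' @param order Markov order for the default background.
#' @return The motif table with `expected`, `p_motif` and `zscore` columns.
#' @export
add_zscores <- function(motif_table, background = NULL, sequences = NULL,
                        order = 3L) {
  if (is.null(background)) {
    if (is.null(sequences)) stop("supply either a background or sequences")
    background <- train_markov(sequences, order = order)
  }
  n_pos <- attr(motif_table, "n_positions")
  if (is.null(n_pos)) stop("motif_table lacks an n_positions attribute")
  ps <- vapply(motif_table$kmer, motif_prob, numeric(1),
               background = background)
  motif_table$p_motif <- unname(ps)
  motif_table$expected <- n_pos * motif_table$p_motif
  motif_table$zscore <- (motif_table$count - motif_table$expected) /
    sqrt(n_pos * motif_table$p_motif * (1 - motif_table$p_motif))
  motif_table
}
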