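# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use different algorithms/idioms from the package code.

# random DNA of given length and base probabilities
rand_dna <- function(n, p = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# exhaustive suffix scan: longest terminal window meeting the thresholds
oracle_find_tail <- function(seq, min_len, min_purity) {
  L <- nchar(seq)
  for (start in seq_len(L)) {
    win <- substring(seq, start, L)
    len <- L - start + 1L
    if (len < min_len) break
    n_a <- lengths(regmatches(win, gregexpr("A", win, fixed = TRUE)))
    if (n_a / len >= min_purity) {
      return(list(start = start, length = len, purity = n_a / len))
    }
  }
  NULL
}

# sliding-window internal-priming decision on a window string
oracle_ip <- function(window, run_t = 6L, count_t = 7L) {
  chars <- strsplit(window, "")[[1]]
  L <- length(chars)
  # A-run check
  best <- 0L; cur <- 0L
  for (ch in chars) {
    cur <- if (ch == "A") cur + 1L else 0L
    best <- max(best, cur)
  }
  if (best >= run_t) return(TRUE)
  if (L >= 10L) {
    for (s in seq_len(L - 9L)) {
      if (sum(chars[s:(s + 9L)] == "A") >= count_t) return(TRUE)
    }
  }
  FALSE
}

# all contiguous partitions of n ordered items (list of integer id vectors)
contiguous_partitions <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (mask in 0:(2^(n - 1L) - 1L)) {
    cuts <- as.integer(intToBits(mask))[seq_len(n - 1L)]
    out[[length(out) + 1L]] <- cumsum(c(1L, cuts))
  }
  out
}

# best (fewest clusters, then min weighted WSS) contiguous partition under a
# span cap; returns list(k, wss) or NULL if infeasible
oracle_best_partition <- function(x, w, max_span) {
  best <- NULL
  for (ids in contiguous_partitions(length(x))) {
    ok <- TRUE; tot <- 0
    for (cl in unique(ids)) {
      xi <- x[ids == cl]; wi <- w[ids == cl]
      if (max(xi) - min(xi) + 1L > max_span) { ok <- FALSE; break }
      m <- stats::weighted.mean(xi, wi)
      tot <- tot + sum(wi * (xi - m)^2)
    }
    if (!ok) next
    k <- max(ids)
    if (is.null(best) || k < best$k ||
        (k == best$k && tot < best$wss - 1e-9)) {
      best <- list(k = k, wss = tot, ids = ids)
    }
  }
  best
}

# regex-lookahead overlapping match starts of a fixed motif
oracle_match_starts <- function(seq, motif) {
  m <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# recursive greedy spaced counting
oracle_greedy <- function(starts, k, gap) {
  if (!length(starts)) return(0L)
  rest <- starts[starts >= starts[1] + k + gap]
  1L + oracle_greedy(rest, k, gap)
}

# full mode-aware count of one motif in one sequence (positions with N are
# excluded by masking the sequence first)
oracle_motif_count <- function(seq, motif, mode, gap = 0L) {
  starts <- oracle_match_starts(seq, motif)
  if (mode == "overlapping") return(length(starts))
  if (mode == "distribution") return(oracle_greedy(starts, nchar(motif), gap))
  as.integer(length(starts) > 0)  # frequency: at most one per sequence
}

# permutation-based two-sided rank-sum p via the Mann-Whitney U statistic
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_stat <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_stat(seq_len(n1))
  mu <- n1 * n2 / 2
  sets <- utils::combn(n1 + n2, n1)
  us <- apply(sets, 2, u_stat)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# small deterministic gene-model fixture: two genes on opposite strands
toy_models <- function() {
  f <- tibble::tribble(
    ~gene_id, ~transcript_id, ~type, ~chrom, ~strand, ~start, ~end,
    "gA", NA, "gene", "chr1", "+", 1001L, 3000L,
    "gA", "gA.t1", "mRNA", "chr1", "+", 1001L, 3000L,
    "gA", "gA.t1", "exon", "chr1", "+", 1001L, 1800L,
    "gA", "gA.t1", "exon", "chr1", "+", 2101L, 3000L,
    "gA", "gA.t1", "five_prime_UTR", "chr1", "+", 1001L, 1200L,
    "gA", "gA.t1", "CDS", "chr1", "+", 1201L, 1800L,
    "gA", "gA.t1", "CDS", "chr1", "+", 2101L, 2700L,
    "gA", "gA.t1", "three_prime_UTR", "chr1", "+", 2701L, 3000L,
    "gB", NA, "gene", "chr1", "-", 5001L, 7000L,
    "gB", "gB.t1", "mRNA", "chr1", "-", 5001L, 7000L,
    "gB", "gB.t1", "exon", "chr1", "-", 5001L, 7000L,
    "gB", "gB.t1", "five_prime_UTR", "chr1", "-", 6801L, 7000L,
    "gB", "gB.t1", "CDS", "chr1", "-", 5401L, 6800L,
    "gB", "gB.t1", "three_prime_UTR", "chr1", "-", 5001L, 5400L)
  as_gene_models(f)
}
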