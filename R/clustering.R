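# Clustering unique poly(A) sites into PACs.
#
# Cleavage is "sloppy": reads from one biological poly(A) site scatter over
# a few nucleotides (microheterogeneity). Adjacent unique sites on the same
# chromosome and strand are therefore merged into poly(A) site clusters
# (PACs) under Ward's minimum-variance objective, with each site weighted
# by its read support. Because positions are one-dimensional, the optimal
# contiguous partition can be computed exactly: the clustering returns the
# partition with the fewest clusters subject to a maximum genomic span per
# cluster, and among those the minimum support-weighted within-cluster sum
# of squares. The span cap (default 24 nt) is a package parameter chosen on
# the scale of reported microheterogeneity, not a literature constant.

#' Keep unique sites with sufficient read support
#'
#' @param sites Unique-site tibble from [aggregate_sites()].
#' @param min_support Minimum reads per unique site (default 3).
#' @return Filtered tibble.
#' @export
filter_min_support <- function(sites, min_support = 3L) {
  dplyr::filter(as_tibble(sites), .data$support >= min_support)
}

# weighted within-cluster sum of squares for positions x, weights w
wss <- function(x, w) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  sum(w * (x - m)^2)
}

# exact DP over contiguous partitions of sorted positions:
# lexicographic objective (number of clusters, total WSS), span <= max_span.
# returns integer cluster ids in input order.
ward_partition <- function(x, w, max_span) {
  n <- length(x)
  if (n == 1L) return(1L)
  # best[i] = list(k, ss, cut) for prefix 1..i
  bestk <- rep(Inf, n); bests <- rep(Inf, n); cut <- integer(n)
  for (i in seq_len(n)) {
    for (j in i:1) {
      if (x[i] - x[j] + 1L > max_span) break
      prevk <- if (j == 1L) 0 else bestk[j - 1L]
      prevs <- if (j == 1L) 0 else bests[j - 1L]
      if (!is.finite(prevk)) next
      k <- prevk + 1
      ss <- prevs + wss(x[j:i], w[j:i])
      if (k < bestk[i] || (k == bestk[i] && ss < bests[i] - 1e-12)) {
        bestk[i] <- k; bests[i] <- ss; cut[i] <- j
      }
    }
  }
  ids <- integer(n)
  i <- n; cl <- bestk[n]
  while (i >= 1L) {
    j <- cut[i]
    ids[j:i] <- cl
    cl <- cl - 1
    i <- j - 1L
  }
  as.integer(ids)
}

# fallback: split only where adjacent sites are farther than max_gap apart
gap_partition <- function(x, max_gap) {
  if (length(x) == 1L) return(1L)
  cumsum(c(TRUE, diff(x) > max_gap))
}

#' Pick the representative site of a PAC
#'
#' The member with maximal read support; ties are broken toward the most
#' 3' position in transcript sense (largest coordinate on the plus strand,
#' smallest on the minus strand).
#'
#' @param members Tibble of member sites with `position`, `support`, `strand`.
#' @return One-row tibble (the representative member).
#' @export
pac_representative <- function(members) {
  stopifnot(nrow(members) > 0)
  m <- dplyr::filter(members, .data$support == max(.data$support))
  if (nrow(m) > 1L) {
    m <- if (m$strand[1] == "+") slice_max(m, .data$position, n = 1L)
         else dplyr::slice_min(m, .data$position, n = 1L)
  }
  m[1, , drop = FALSE]
}

#' Cluster unique poly(A) sites into PACs
#'
#' @param sites Support-filtered unique-site tibble ([filter_min_support()]).
#' @param max_span Maximum genomic span (nt, inclusive) of one PAC.
#' @param method `"ward"` (exact span-capped minimum-variance contiguous
#'   partition, the default) or `"gap"` (split at inter-site gaps larger
#'   than `max_span`; single-linkage-style comparison baseline).
#' @return Tibble of PACs: `pac_id`, `chrom`, `strand`, `start`, `end`,
#'   `n_sites`, `total_support`, `rep_position`, `rep_support`, and a
#'   list-column `members` holding each PAC's member site rows.
#' @examples
#' sites <- tibble::tibble(chrom = "chr1", strand = "+",
#'                         position = c(1000L, 1003L, 1010L),
#'                         support = c(4L, 3L, 3L))
#' cluster_pacs(sites)
#' @export
cluster_pacs <- function(sites, max_span = 24L, method = c("ward", "gap")) {
  method <- match.arg(method)
  sites <- as_tibble(sites)
  if (!nrow(sites)) {
    return(tibble(pac_id = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  n_sites = integer(), total_support = integer(),
                  rep_position = integer(), rep_support = integer(),
                  members = list()))
  }
  pacs <- sites %>%
    arrange(.data$chrom, .data$strand, .data$position) %>%
    group_by(.data$chrom, .data$strand) %>%
    mutate(.cluster = {
      # pre-split stretches separated by gaps no cluster could bridge,
      # then solve each stretch exactly
      seg <- cumsum(c(TRUE, diff(.data$position) + 1L > max_span))
      ids <- integer(length(seg))
      off <- 0L
      for (s in unique(seg)) {
        idx <- which(seg == s)
        part <- if (method == "ward") {
          ward_partition(.data$position[idx], .data$support[idx], max_span)
        } else {
          gap_partition(.data$position[idx], max_span)
        }
        ids[idx] <- part + off
        off <- off + max(part)
      }
      ids
    }) %>%
    group_by(.data$chrom, .data$strand, .data$.cluster) %>%
    summarise(
      start = min(.data$position), end = max(.data$position),
      n_sites = dplyr::n(), total_support = sum(.data$support),
      members = list(tibble(position = position, support = support,
                            strand = dplyr::cur_group()$strand)),
      .groups = "drop")
  rep <- map(pacs$members, pac_representative)
  pacs$rep_position <- map_int(rep, ~ as.integer(.x$position))
  pacs$rep_support <- map_int(rep, ~ as.integer(.x$support))
  pacs <- pacs %>%
    arrange(.data$chrom, .data$start, .data$strand) %>%
    mutate(pac_id = sprintf("PAC%05d", row_number())) %>%
    select("pac_id", "chrom", "strand", "start", "end", "n_sites",
           "total_support", "rep_position", "rep_support", "members")
  pacs
}

#' Extract flanking sequences around PAC representative sites
#'
#' Returns, for each PAC, the transcript-sense sequence from `upstream` nt
#' before to `downstream` nt after the representative site, with the site
#' base at position label -1 (labels run -upstream..-1, +1..+downstream; no
#' zero). Minus-strand flanks are reverse-complemented. Positions beyond the
#' contig are padded with `N` and flagged.
#'
#' @param pacs PAC tibble from [cluster_pacs()].
#' @param genome Genome accepted by [as_genome()].
#' @param upstream,downstream Flank widths in nt (defaults 100 and 50).
#' @return Tibble `pac_id`, `seq`, `padded` with attribute
#'   `positions` giving the label vector.
#' @export
pac_flanks <- function(pacs, genome, upstream = 100L, downstream = 50L) {
  genome_chr <- genome_chars(genome)
  missing <- setdiff(unique(pacs$chrom), names(genome_chr))
  if (length(missing)) {
    stop("chromosome(s) absent from genome: ", paste(missing, collapse = ", "))
  }
  res <- pmap(list(pacs$chrom, pacs$strand, pacs$rep_position),
              function(chrom, strand, pos) {
    clen <- nchar(genome_chr[[chrom]])
    if (strand == "+") { lo <- pos - upstream + 1L; hi <- pos + downstream }
    else               { lo <- pos - downstream;    hi <- pos + upstream - 1L }
    clo <- max(1L, lo); chi <- min(clen, hi)
    core <- substr(genome_chr[[chrom]], clo, chi)
    left <- strrep("N", clo - lo); right <- strrep("N", hi - chi)
    s <- paste0(left, core, right)
    if (strand == "-") s <- revcomp(s)
    list(seq = s, padded = nchar(left) + nchar(right) > 0L)
  })
  out <- tibble(pac_id = pacs$pac_id,
                seq = map_chr(res, "seq"),
                padded = map_lgl(res, "padded"))
  attr(out, "positions") <- position_labels(upstream, downstream)
  out
}
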