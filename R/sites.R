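# Cleavage-site calling from placed reads, internal-priming filtering, and
# aggregation into a unique-site table.

sense_base <- function(genome_chr, chrom, pos, strand) {
  b <- substr(genome_chr[[chrom]], pos, pos)
  if (strand == "+") b else chartr("ACGTN", "TGCAN", b)
}

#' Call cleavage-site candidates from mapped reads
#'
#' The site is the last genome-templated base of the alignment, after
#' reassigning up to `max_genomic_a` trailing aligned adenosines (sense
#' strand) into the tail: a templated A immediately upstream of a poly(A)
#' tail cannot be distinguished from the tail itself, so the convention is
#' to push the called site upstream past such A's. Reads with more trailing
#' aligned A's than the cap, with too many nontemplated bases, or whose
#' aligned 3' end sits at the contig edge (the tail would run off the
#' contig) are rejected with a reason code.
#'
#' @param mapped Tibble from [map_reads()].
#' @param genome Genome accepted by [as_genome()].
#' @param params A [polya_params()] rule set.
#' @param label Optional dataset label recorded per candidate (recycled).
#' @return Tibble with `read_id`, `chrom`, `strand`, `position`, `label`,
#'   `accepted`, `reason` (`NA` when accepted).
#' @export
call_sites <- function(mapped, genome, params = polya_params("est"),
                       label = "reads") {
  genome_chr <- genome_chars(genome)
  n <- nrow(mapped)
  position <- integer(n); accepted <- logical(n); reason <- rep(NA_character_, n)
  label <- rep_len(label, n)
  nt_count <- if ("nontemplated" %in% names(mapped)) mapped$nontemplated
              else mapped$clipped
  for (i in seq_len(n)) {
    chrom <- mapped$chrom[i]; strand <- mapped$strand[i]
    s <- mapped$start[i]; e <- mapped$end[i]
    clen <- nchar(genome_chr[[chrom]])
    if (nt_count[i] > params$max_nontemplated) {
      accepted[i] <- FALSE; reason[i] <- "nontemplated_overflow"; next
    }
    end3 <- if (strand == "+") e else s          # aligned 3' end, sense
    at_edge <- if (strand == "+") end3 >= clen else end3 <= 1L
    if (at_edge) {
      accepted[i] <- FALSE; reason[i] <- "contig_edge"; next
    }
    # trailing aligned A's in transcript sense
    run <- 0L
    pos <- end3
    step <- if (strand == "+") -1L else 1L
    while (pos >= s && pos <= e &&
           sense_base(genome_chr, chrom, pos, strand) == "A") {
      run <- run + 1L
      pos <- pos + step
      if (run > params$max_genomic_a) break
    }
    if (run > params$max_genomic_a) {
      accepted[i] <- FALSE; reason[i] <- "genomic_a_overflow"; next
    }
    if (run >= (e - s + 1L)) {
      accepted[i] <- FALSE; reason[i] <- "alignment_all_a"; next
    }
    accepted[i] <- TRUE
    position[i] <- if (strand == "+") e - run else s + run
  }
  out <- tibble(
    read_id = mapped$read_id, chrom = mapped$chrom, strand = mapped$strand,
    position = ifelse(accepted, position, NA_integer_),
    label = label, accepted = accepted, reason = reason)
  out
}

# sense-strand window of `flank` bases either side of the site (clamped)
ip_window <- function(genome_chr, chrom, strand, position, flank = 10L) {
  clen <- nchar(genome_chr[[chrom]])
  lo <- max(1L, position - flank)
  hi <- min(clen, position + flank)
  w <- substr(genome_chr[[chrom]], lo, hi)
  if (strand == "-") w <- revcomp(w)
  list(seq = w, clamped = (position - flank < 1L) || (position + flank > clen))
}

# dual internal-priming rule on one window
ip_hit <- function(window, run_threshold, count_threshold, subwindow = 10L) {
  if (max_char_run(window, "A") >= run_threshold) return(TRUE)
  L <- nchar(window)
  if (L >= subwindow) {
    chars <- strsplit(window, "", fixed = TRUE)[[1]] == "A"
    cs <- c(0L, cumsum(chars))
    counts <- cs[(subwindow + 1L):(L + 1L)] - cs[seq_len(L - subwindow + 1L)]
    if (any(counts >= count_threshold)) return(TRUE)
  }
  FALSE
}

#' Filter internal-priming candidate sites
#'
#' Oligo(dT) primers can anneal to genomically encoded A-rich stretches,
#' producing artifactual "sites" with no real tail. A site is dropped when
#' the sense-strand genomic window from -10 to +10 around it contains a run
#' of at least `run_threshold` consecutive adenosines, or any fully
#' contained 10-nt subwindow with at least `count_threshold` adenosines.
#' Windows are clamped at contig edges and evaluated on the available bases
#' (`edge` flags such sites).
#'
#' @param sites Tibble with `chrom`, `strand`, `position`.
#' @param genome Genome accepted by [as_genome()].
#' @param run_threshold Minimum A-run length that triggers a drop.
#' @param count_threshold Minimum A count in a 10-nt subwindow that triggers
#'   a drop.
#' @param flank Half-width of the window around the site.
#' @return Input tibble with logical columns `internal_priming` and `edge`.
#'   Use `dplyr::filter(!internal_priming)` to keep clean sites.
#' @export
flag_internal_priming <- function(sites, genome, run_threshold = 6L,
                                  count_threshold = 7L, flank = 10L) {
  genome_chr <- genome_chars(genome)
  key <- distinct(sites, .data$chrom, .data$strand, .data$position)
  ws <- pmap(key, function(chrom, strand, position) {
    ip_window(genome_chr, chrom, strand, position, flank)
  })
  key$internal_priming <- map_lgl(ws, ~ ip_hit(.x$seq, run_threshold,
                                               count_threshold))
  key$edge <- map_lgl(ws, "clamped")
  left_join(as_tibble(sites), key, by = c("chrom", "strand", "position"))
}

#' Aggregate site candidates into a unique-site table
#'
#' Collapses accepted candidates to one row per (chromosome, strand,
#' position) with total read support and per-dataset-label counts, sorted
#' by genomic coordinate.
#'
#' @param candidates Tibble from [call_sites()] (rejected rows are ignored)
#'   or any tibble with `chrom`, `strand`, `position` and optional `label`.
#' @return Tibble with one row per unique site: `chrom`, `strand`,
#'   `position`, `support`, and one `n_<label>` column per dataset label.
#' @export
aggregate_sites <- function(candidates) {
  cand <- as_tibble(candidates)
  if ("accepted" %in% names(cand)) cand <- dplyr::filter(cand, .data$accepted)
  if (!nrow(cand)) {
    return(tibble(chrom = character(), strand = character(),
                  position = integer(), support = integer()))
  }
  if (!"label" %in% names(cand)) cand$label <- "reads"
  out <- cand %>%
    count(.data$chrom, .data$strand, .data$position, .data$label) %>%
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       names_prefix = "n_", values_fill = 0L)
  out$support <- as.integer(rowSums(out[grep("^n_", names(out))]))
  out %>%
    select("chrom", "strand", "position", "support", dplyr::starts_with("n_")) %>%
    arrange(.data$chrom, .data$position, .data$strand)
}
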