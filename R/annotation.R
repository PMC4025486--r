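# Genic region assignment for PACs.
#
# Region labels: UTR5, UTR3, CDS, INTRON, INTERGENIC. The annotated 3'-UTR
# is extended downstream (default 50 nt) before assignment: incompletely
# annotated 3' ends otherwise push genuine 3'-UTR sites into the intergenic
# class. Precedence when a coordinate falls in several features (including
# across overlapping genes): UTR3 (extended) > CDS > UTR5 > INTRON; among
# genes tied at the same precedence the gene whose annotated 3' end is
# closest wins. Strand-mismatched (antisense) containment does not count;
# such sites fall through to INTERGENIC.

#' Read gene models from a GFF3 file
#'
#' Imports gene/mRNA/exon/CDS/UTR features, resolves the gene each feature
#' belongs to, and derives introns as the gaps between consecutive exons of
#' a transcript.
#'
#' @param gff Path to a GFF3 file, or a `GRanges` as returned by
#'   [rtracklayer::import()].
#' @return A `gene_models` tibble with columns `gene_id`, `transcript_id`,
#'   `type`, `chrom`, `strand`, `start`, `end`.
#' @export
read_gene_models <- function(gff) {
  gr <- if (methods::is(gff, "GRanges")) gff else rtracklayer::import(gff)
  tb <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = as.character(gr$type),
    ID = as.character(gr$ID %||% rep(NA_character_, length(gr))),
    Parent = vapply(as.list(gr$Parent %||% vector("list", length(gr))),
                    function(p) if (length(p)) p[[1]] else NA_character_,
                    character(1))
  )
  keep <- c("gene", "mRNA", "exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  tb <- dplyr::filter(tb, .data$type %in% keep)
  tx2gene <- tb %>% dplyr::filter(.data$type == "mRNA") %>%
    select(transcript_id = "ID", gene_id = "Parent")
  tb <- tb %>%
    mutate(
      transcript_id = dplyr::case_when(
        type == "mRNA" ~ .data$ID,
        type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR") ~
          .data$Parent,
        TRUE ~ NA_character_),
      gene_id = dplyr::case_when(
        type == "gene" ~ .data$ID,
        type == "mRNA" ~ .data$Parent,
        TRUE ~ NA_character_)) %>%
    left_join(tx2gene, by = "transcript_id", suffix = c("", ".tx")) %>%
    mutate(gene_id = dplyr::coalesce(.data$gene_id, .data$gene_id.tx)) %>%
    select("gene_id", "transcript_id", "type", "chrom", "strand",
           "start", "end")
  as_gene_models(tb)
}

#' Coerce a feature table to gene models (deriving introns)
#'
#' @param features Tibble with `gene_id`, `transcript_id`, `type`, `chrom`,
#'   `strand`, `start`, `end` (1-based inclusive). Intron rows are derived
#'   from exon gaps if absent.
#' @return A `gene_models` tibble.
#' @export
as_gene_models <- function(features) {
  tb <- as_tibble(features)
  if (!"intron" %in% tb$type) {
    introns <- tb %>%
      dplyr::filter(.data$type == "exon", !is.na(.data$transcript_id)) %>%
      group_by(.data$gene_id, .data$transcript_id, .data$chrom, .data$strand) %>%
      arrange(.data$start, .by_group = TRUE) %>%
      dplyr::reframe(
        istart = if (dplyr::n() > 1) utils::head(.data$end, -1) + 1L else integer(0),
        iend = if (dplyr::n() > 1) utils::tail(.data$start, -1) - 1L else integer(0)) %>%
      rename(start = "istart", end = "iend") %>%
      mutate(type = "intron")
    tb <- bind_rows(tb, introns)
  }
  structure(arrange(tb, .data$chrom, .data$start),
            class = c("gene_models", class(tb)))
}

# one row per gene with its annotated 3' end (pre-extension)
gene_ends <- function(models) {
  models %>%
    dplyr::filter(.data$type == "gene") %>%
    mutate(end3 = if_else(.data$strand == "+", .data$end, .data$start)) %>%
    select("gene_id", "chrom", "strand", gene_start = "start",
           gene_end = "end", "end3")
}

#' Extend annotated 3'-UTRs downstream
#'
#' Grows each transcript's 3'-UTR by `extension` nt downstream in transcript
#' sense, truncated at the next same-strand gene start (so an extension
#' never reaches past a downstream neighbour's first base) and at the contig
#' edge when `seq_lengths` is supplied. Transcripts without an annotated
#' 3'-UTR gain one spanning only the extension.
#'
#' @param models A `gene_models` tibble.
#' @param extension Extension length in nt (default 50).
#' @param seq_lengths Optional named vector of contig lengths for clamping.
#' @return `gene_models` tibble with adjusted 3'-UTR intervals; the applied
#'   extension is recorded in attribute `utr3_extension`.
#' @export
extend_utr3 <- function(models, extension = 50L, seq_lengths = NULL) {
  stopifnot(extension >= 0)
  ge <- gene_ends(models)
  if (!nrow(ge)) {
    attr(models, "utr3_extension") <- extension
    return(models)
  }
  # allowed downstream room per gene before hitting next same-strand gene
  room <- ge %>%
    group_by(.data$chrom, .data$strand) %>%
    arrange(.data$gene_start, .by_group = TRUE) %>%
    mutate(allowed = if (.data$strand[1] == "+") {
      nxt <- dplyr::lead(.data$gene_start)
      if_else(is.na(nxt), Inf, as.numeric(nxt - .data$end3))
    } else {
      prv <- dplyr::lag(.data$gene_end)
      if_else(is.na(prv), Inf, as.numeric(.data$end3 - prv))
    }) %>%
    ungroup() %>%
    select("gene_id", "allowed", "end3")
  ext_tbl <- room %>%
    mutate(ext = pmin(extension, pmax(0, .data$allowed)))
  models2 <- left_join(as_tibble(models), select(ext_tbl, "gene_id", "ext"),
                       by = "gene_id")
  # grow existing UTR3 rows
  is_u3 <- models2$type == "three_prime_UTR"
  plus <- is_u3 & models2$strand == "+"
  minus <- is_u3 & models2$strand == "-"
  models2$end[plus] <- models2$end[plus] + as.integer(models2$ext[plus])
  models2$start[minus] <- models2$start[minus] - as.integer(models2$ext[minus])
  # transcripts with no UTR3 at all: append one covering the extension
  have_u3 <- unique(models2$gene_id[is_u3])
  need <- ext_tbl %>%
    dplyr::filter(!.data$gene_id %in% have_u3, .data$ext > 0) %>%
    inner_join(gene_ends(models), by = c("gene_id", "end3"))
  if (nrow(need)) {
    extra <- need %>%
      mutate(type = "three_prime_UTR",
             transcript_id = NA_character_,
             start = if_else(.data$strand == "+", .data$end3 + 1L,
                             .data$end3 - as.integer(.data$ext)),
             end = if_else(.data$strand == "+",
                           .data$end3 + as.integer(.data$ext),
                           .data$end3 - 1L)) %>%
      select("gene_id", "transcript_id", "type", "chrom", "strand",
             "start", "end")
    models2 <- bind_rows(models2, extra)
  }
  models2$ext <- NULL
  if (!is.null(seq_lengths)) {
    models2 <- models2 %>%
      mutate(start = pmax(.data$start, 1L),
             end = pmin(.data$end,
                        unname(seq_lengths[.data$chrom])))
  }
  models2$start <- pmax(models2$start, 1L)
  out <- structure(arrange(models2, .data$chrom, .data$start),
                   class = c("gene_models", class(as_tibble(models2))))
  attr(out, "utr3_extension") <- extension
  out
}

region_levels <- c("UTR5", "UTR3", "CDS", "INTRON", "INTERGENIC")

#' Assign PACs to genic regions
#'
#' @param pacs PAC tibble from [cluster_pacs()] (uses `rep_position`), or
#'   any tibble with `chrom`, `strand` and a `position` column.
#' @param models `gene_models` tibble, typically after [extend_utr3()].
#' @return Tibble with `pac_id` (if present), `chrom`, `strand`, `position`,
#'   `region`, `gene_id` (`NA` for INTERGENIC), and `dist_to_3p`, the signed
#'   transcript-sense distance from the assigned (or nearest same-strand)
#'   gene's annotated 3' end: positive downstream of it.
#' @export
assign_regions <- function(pacs, models) {
  pacs <- as_tibble(pacs)
  pos_col <- if ("rep_position" %in% names(pacs)) "rep_position" else "position"
  q <- tibble(.row = seq_len(nrow(pacs)),
              pac_id = pacs$pac_id %||% sprintf("site%05d", seq_len(nrow(pacs))),
              chrom = pacs$chrom, strand = pacs$strand,
              position = pacs[[pos_col]])
  feats <- as_tibble(models) %>%
    mutate(region = dplyr::recode(.data$type,
      three_prime_UTR = "UTR3", CDS = "CDS",
      five_prime_UTR = "UTR5", intron = "INTRON", .default = NA_character_)) %>%
    dplyr::filter(!is.na(.data$region)) %>%
    mutate(prio = match(.data$region, c("UTR3", "CDS", "UTR5", "INTRON")))
  ge <- gene_ends(models)
  feats <- left_join(feats, select(ge, "gene_id", "end3"), by = "gene_id")
  hits <- inner_join(
    q, select(feats, "chrom", "strand", "start", "end", "region",
              "prio", "gene_id", "end3"),
    by = dplyr::join_by(chrom, strand, between(position, start, end))) %>%
    mutate(d3 = if_else(.data$strand == "+",
                        .data$position - .data$end3,
                        .data$end3 - .data$position)) %>%
    group_by(.data$.row) %>%
    arrange(.data$prio, abs(.data$d3), .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup() %>%
    select(".row", "region", "gene_id", dist_to_3p = "d3")
  out <- left_join(q, hits, by = ".row")
  # intergenic: nearest same-strand annotated 3' end
  inter <- which(is.na(out$region))
  if (length(inter) && nrow(ge)) {
    for (i in inter) {
      cand <- ge[ge$chrom == out$chrom[i] & ge$strand == out$strand[i], ]
      if (!nrow(cand)) next
      d <- if (out$strand[i] == "+") out$position[i] - cand$end3
           else cand$end3 - out$position[i]
      j <- which.min(abs(d))
      out$dist_to_3p[i] <- d[j]
    }
  }
  out$region <- factor(if_else(is.na(out$region), "INTERGENIC", out$region),
                       levels = region_levels)
  out$gene_id[out$region == "INTERGENIC"] <- NA_character_
  select(out, -".row")
}

#' Regional distribution of PACs
#'
#' @param assignments Tibble from [assign_regions()].
#' @return Tibble with one row per region label: `region`, `n`, `pct`
#'   (percentages sum to 100).
#' @export
region_distribution <- function(assignments) {
  if (!nrow(assignments)) stop("no assignments to summarise")
  assignments %>%
    count(region = factor(.data$region, levels = region_levels),
          .drop = FALSE) %>%
    mutate(pct = 100 * .data$n / sum(.data$n))
}

#' Distance profile of intergenic PACs to annotated 3' ends
#'
#' @param assignments Tibble from [assign_regions()].
#' @param max_distance Consider intergenic sites within this absolute
#'   distance of a same-strand annotated 3' end (nt).
#' @param binwidth Histogram bin width in nt.
#' @param cutoffs Distances at which to report cumulative fractions.
#' @return List with `histogram` (tibble `bin_start`, `bin_end`, `n`) and
#'   `cumulative` (tibble `cutoff`, `fraction` of in-range intergenic sites
#'   within the cutoff).
#' @export
distance_profile <- function(assignments, max_distance = 1000L,
                             binwidth = 50L, cutoffs = 50L) {
  d <- assignments %>%
    dplyr::filter(.data$region == "INTERGENIC", !is.na(.data$dist_to_3p)) %>%
    pull(.data$dist_to_3p) %>%
    abs()
  d <- d[d <= max_distance]
  breaks <- seq(0L, max_distance + binwidth - 1e-9, by = binwidth)
  bin <- findInterval(d, breaks, left.open = TRUE, rightmost.closed = FALSE)
  hist <- tibble(bin_start = breaks[-length(breaks)],
                 bin_end = breaks[-1]) %>%
    mutate(n = vapply(seq_len(dplyr::n()),
                      function(i) sum(bin == i), integer(1)))
  cum <- tibble(cutoff = cutoffs,
                fraction = vapply(cutoffs,
                                  function(cc) if (length(d)) mean(d <= cc)
                                               else NA_real_,
                                  numeric(1)))
  list(histogram = hist, cumulative = cum)
}
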