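# End-to-end convenience wrappers.

#' Call poly(A) site clusters from raw reads
#'
#' Chains orientation, tail detection, mapping, site calling,
#' internal-priming filtering, support filtering and clustering.
#'
#' @param reads Tibble `read_id`, `seq` (or character vector).
#' @param genome Genome accepted by [as_genome()].
#' @param params A [polya_params()] rule set.
#' @param label Dataset label carried into the unique-site table.
#' @param min_support Minimum reads per unique site before clustering.
#' @param max_span Maximum PAC span (nt).
#' @param ip_run,ip_count Internal-priming thresholds (A-run length /
#'   A count in a 10-nt subwindow) applied to the -10..+10 window.
#' @param seed_length,min_body Mapper settings (see [map_reads()]).
#' @return Object of class `pac_pipeline`: list with `tailed`, `mapped`,
#'   `called`, `unique_sites` (all, with internal-priming flags), `sites`
#'   (clean, support-filtered), `pacs`, and `stats`.
#' @export
call_pac_pipeline <- function(reads, genome, params = polya_params("est"),
                              label = "reads", min_support = 3L,
                              max_span = 24L, ip_run = 6L, ip_count = 7L,
                              seed_length = 20L, min_body = 20L) {
  genome <- as_genome(genome)
  oriented <- orient_reads(reads, params)
  tailed <- find_tails(oriented, params) %>%
    dplyr::filter(!is.na(.data$body))
  mapped <- map_reads(tailed, genome, seed_length = seed_length,
                      min_body = min_body, params = params)
  called <- call_sites(mapped, genome, params, label = label)
  unique_sites <- aggregate_sites(called) %>%
    flag_internal_priming(genome, run_threshold = ip_run,
                          count_threshold = ip_count)
  clean <- dplyr::filter(unique_sites, !.data$internal_priming)
  sites <- filter_min_support(clean, min_support)
  pacs <- cluster_pacs(sites, max_span = max_span)
  stats <- tibble(
    n_reads = nrow(normalise_reads(reads)),
    n_tailed = nrow(tailed),
    n_mapped = nrow(mapped),
    n_accepted = sum(called$accepted),
    n_unique_sites = nrow(unique_sites),
    n_internal_priming = sum(unique_sites$internal_priming),
    n_supported_sites = nrow(sites),
    n_pacs = nrow(pacs))
  structure(list(params = params, tailed = tailed, mapped = mapped,
                 called = called, unique_sites = unique_sites,
                 sites = sites, pacs = pacs, stats = stats),
            class = "pac_pipeline")
}

#' @export
print.pac_pipeline <- function(x, ...) {
  s <- x$stats
  cat(sprintf(paste0(
    "<pac_pipeline> %d reads -> %d tailed -> %d mapped -> %d accepted\n",
    "  %d unique sites (%d internal-priming) -> %d supported -> %d PACs\n"),
    s$n_reads, s$n_tailed, s$n_mapped, s$n_accepted, s$n_unique_sites,
    s$n_internal_priming, s$n_supported_sites, s$n_pacs))
  invisible(x)
}

#' @method tidy pac_pipeline
#' @export
tidy.pac_pipeline <- function(x, ...) select(x$pacs, -"members")

#' @method glance pac_pipeline
#' @export
glance.pac_pipeline <- function(x, ...) x$stats

#' Full APA analysis from reads, genome and annotation
#'
#' Runs [call_pac_pipeline()], assigns PACs to genic regions (with the
#' 3'-UTR extension), extracts flanks, scans the near-upstream element for
#' pentamer signals in frequency mode with order-3 Markov Z-scores, and
#' summarises APA per gene.
#'
#' @inheritParams call_pac_pipeline
#' @param models A `gene_models` tibble (see [read_gene_models()] /
#'   [as_gene_models()]).
#' @param utr3_extension 3'-UTR extension in nt (default 50).
#' @param nue_window NUE window labels (default `c(-28, -5)`).
#' @param markov_order Background Markov order for signal Z-scores.
#' @param ... Passed to [call_pac_pipeline()].
#' @return Object of class `apa_result`: the `pac_pipeline` plus
#'   `assignments`, `region_summary`, `flanks`, `nue_scan` (motif table
#'   with Z-scores), `gene_pacs`, `classified`, `apa_extent`.
#' @export
run_apa_pipeline <- function(reads, genome, models,
                             params = polya_params("est"),
                             utr3_extension = 50L,
                             nue_window = c(-28, -5),
                             markov_order = 3L, ...) {
  pipe <- call_pac_pipeline(reads, genome, params = params, ...)
  ext <- extend_utr3(models, utr3_extension)
  assignments <- assign_regions(pipe$pacs, ext)
  region_summary <- if (nrow(assignments)) region_distribution(assignments)
                    else NULL
  flanks <- pac_flanks(pipe$pacs, genome)
  nue_scan <- NULL
  if (nrow(flanks)) {
    ws <- window_sequences(flanks, nue_window)
    nue_scan <- scan_kmers(flanks, k = 5L, window = nue_window,
                           mode = "frequency") %>%
      add_zscores(sequences = ws, order = markov_order)
  }
  gene_pacs <- gene_pac_table(assignments, pipe$pacs)
  classified <- if (nrow(gene_pacs)) classify_pac_sites(gene_pacs) else NULL
  extent <- if (nrow(gene_pacs)) apa_extent(gene_pacs) else NA_real_
  structure(c(unclass(pipe),
              list(assignments = assignments,
                   region_summary = region_summary, flanks = flanks,
                   nue_scan = nue_scan, gene_pacs = gene_pacs,
                   classified = classified, apa_extent = extent)),
            class = c("apa_result", "pac_pipeline"))
}

#' @export
print.apa_result <- function(x, ...) {
  NextMethod()
  cat(sprintf("  APA extent among PAC-bearing genes: %.1f%%\n",
              x$apa_extent))
  if (!is.null(x$nue_scan)) {
    top <- x$nue_scan[1, ]
    cat(sprintf("  top NUE pentamer: %s (freq %.3f, Z = %.1f)\n",
                top$kmer, top$freq, top$zscore))
  }
  invisible(x)
}

#' @method glance apa_result
#' @export
glance.apa_result <- function(x, ...) {
  mutate(x$stats, apa_extent = x$apa_extent)
}
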