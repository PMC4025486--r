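# Gene-level APA summaries and poly(A) site categories.
#
# Site categories follow the read-share rule: a gene with a single PAC has
# a constitutive site; in a gene with several PACs, a PAC holding at least
# `strong_fraction` (default 75%) of the gene's supporting reads is strong
# and its siblings weak; APA genes without a strong site have all-median
# sites.

#' Summarise PACs per gene
#'
#' Joins region assignments with PAC supports and keeps genic PACs (any
#' label other than INTERGENIC maps a PAC to its gene; intergenic PACs are
#' excluded from gene summaries).
#'
#' @param assignments Tibble from [assign_regions()].
#' @param pacs PAC tibble from [cluster_pacs()].
#' @return Tibble with one row per genic PAC: `gene_id`, `pac_id`,
#'   `total_support`, `region`.
#' @export
gene_pac_table <- function(assignments, pacs) {
  assignments %>%
    dplyr::filter(.data$region != "INTERGENIC") %>%
    inner_join(select(pacs, "pac_id", "total_support"), by = "pac_id") %>%
    select("gene_id", "pac_id", "total_support", "region")
}

#' Classify poly(A) sites into constitutive/strong/weak/median
#'
#' @param gene_pacs Tibble with `gene_id`, `pac_id`, `total_support`
#'   (one row per genic PAC), e.g. from [gene_pac_table()].
#' @param strong_fraction Read share at or above which a PAC in a
#'   multi-PAC gene is strong (inclusive; default 0.75).
#' @return Input tibble with `share` and `category` columns
#'   (`constitutive`, `strong`, `weak`, `median`).
#' @examples
#' g <- tibble::tibble(gene_id = c("g1", "g1"), pac_id = c("p1", "p2"),
#'                     total_support = c(80L, 20L))
#' classify_pac_sites(g)
#' @export
classify_pac_sites <- function(gene_pacs, strong_fraction = 0.75) {
  if (!nrow(gene_pacs)) stop("no genic PACs to classify")
  gene_pacs %>%
    group_by(.data$gene_id) %>%
    mutate(share = .data$total_support / sum(.data$total_support),
           category = if (dplyr::n() == 1L) "constitutive"
                      else if (max(.data$share) >= strong_fraction)
                        if_else(.data$share >= strong_fraction &
                                  .data$share == max(.data$share),
                                "strong", "weak")
                      else "median") %>%
    ungroup()
}

#' APA extent of a set of PAC-bearing genes
#'
#' Percentage of genes with at least one PAC that have two or more PACs
#' (the operational definition of an APA gene).
#'
#' @param gene_pacs Tibble with `gene_id` and one row per PAC (e.g. from
#'   [gene_pac_table()] or [classify_pac_sites()]).
#' @return Percentage in `[0, 100]`.
#' @export
apa_extent <- function(gene_pacs) {
  if (!nrow(gene_pacs)) stop("no PAC-bearing genes")
  per_gene <- count(gene_pacs, .data$gene_id)
  100 * mean(per_gene$n >= 2L)
}

#' Category table of PACs and genes
#'
#' PAC counts and percentages per category, plus per-category gene counts
#' (a gene counts under `strong` if it has a strong site, under `weak` if
#' it has weak sites — by construction the same genes — under `median` if
#' its sites are all median, and under `constitutive` if it has a single
#' PAC). Gene percentages are emitted only when the annotated-gene
#' denominator is supplied.
#'
#' @param classified Tibble from [classify_pac_sites()].
#' @param n_genes Optional total number of annotated genes (denominator of
#'   the gene percentage).
#' @return Tibble: `category`, `n_pacs`, `pac_pct`, `n_genes`, `gene_pct`.
#' @export
pac_category_table <- function(classified, n_genes = NULL) {
  lv <- c("constitutive", "strong", "weak", "median")
  pac_counts <- classified %>%
    count(category = factor(.data$category, levels = lv), .drop = FALSE,
          name = "n_pacs")
  gene_counts <- classified %>%
    distinct(.data$gene_id, .data$category) %>%
    count(category = factor(.data$category, levels = lv), .drop = FALSE,
          name = "n_genes")
  out <- left_join(pac_counts, gene_counts, by = "category") %>%
    mutate(pac_pct = 100 * .data$n_pacs / sum(.data$n_pacs),
           gene_pct = if (is.null(n_genes)) NA_real_
                      else 100 * .data$n_genes / n_genes) %>%
    select("category", "n_pacs", "pac_pct", "n_genes", "gene_pct")
  out
}

#' Correlation between APA extent and dataset size
#'
#' Pearson product-moment correlation (with the usual t-based two-sided
#' p-value) between the number of PACs in a dataset and its APA extent.
#'
#' @param records Tibble with columns `n_pacs` and `apa_extent` (one row
#'   per dataset).
#' @return One-row tibble: `estimate` (r), `statistic` (t), `p_value`,
#'   `df`, `n`.
#' @examples
#' extent_size_correlation(tibble::tibble(
#'   n_pacs = c(11035, 30086, 88304, 97479),
#'   apa_extent = c(7.87, 27.49, 63.46, 67.78)))
#' @export
extent_size_correlation <- function(records) {
  stopifnot(all(c("n_pacs", "apa_extent") %in% names(records)))
  if (nrow(records) < 3L) {
    if (nrow(records) == 2L) {
      r <- sign(diff(records$apa_extent) * diff(records$n_pacs))
      return(tibble(estimate = as.numeric(r), statistic = NA_real_,
                    p_value = NA_real_, df = 0L, n = 2L))
    }
    stop("need at least two records")
  }
  if (stats::sd(records$n_pacs) == 0 || stats::sd(records$apa_extent) == 0) {
    stop("correlation undefined: a coordinate is constant")
  }
  ct <- cor.test(records$n_pacs, records$apa_extent, method = "pearson")
  tibble(estimate = unname(ct$estimate), statistic = unname(ct$statistic),
         p_value = ct$p.value, df = unname(ct$parameter), n = nrow(records))
}
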