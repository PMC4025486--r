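# Interplay of intronic polyadenylation with splicing.
#
# Intron splice classes (constitutive = spliced in all isoforms, retained =
# retained in some) and gene coding classes are INPUTS (a classification
# table or simulator ground truth); the package never infers them from
# alignments.

splice_levels <- c("constitutive", "retained")
coding_levels <- c("coding", "noncoding")

#' Cross intronic PACs with intron classes
#'
#' Counts, for each splice class x gene class cell, how many introns
#' contain at least one PAC (an intron with several PACs counts once), and
#' the percentage over all introns of the cell.
#'
#' @param introns Tibble with `chrom`, `strand`, `start`, `end` (1-based
#'   inclusive), `splice_class` (`constitutive`/`retained`) and
#'   `gene_class` (`coding`/`noncoding`).
#' @param pacs PAC tibble from [cluster_pacs()] (uses `rep_position`), or
#'   a tibble with `chrom`, `strand`, `position`.
#' @param by `"representative"` (default) tests whether the representative
#'   site lies inside the intron; `"span"` tests overlap of the whole PAC
#'   span.
#' @return Tibble with one row per class cell: `splice_class`,
#'   `gene_class`, `n_introns`, `n_with_pac`, `pct`, plus `n_pac_hits`
#'   (PAC-level count, multi-PAC introns counted per PAC).
#' @export
intron_pac_table <- function(introns, pacs, by = c("representative", "span")) {
  by <- match.arg(by)
  introns <- as_tibble(introns) %>%
    mutate(.intron = dplyr::row_number(),
           length = .data$end - .data$start + 1L)
  pacs <- as_tibble(pacs)
  if (by == "representative") {
    pos_col <- if ("rep_position" %in% names(pacs)) "rep_position" else "position"
    p <- tibble(chrom = pacs$chrom, strand = pacs$strand,
                pstart = pacs[[pos_col]], pend = pacs[[pos_col]])
  } else {
    p <- tibble(chrom = pacs$chrom, strand = pacs$strand,
                pstart = pacs$start, pend = pacs$end)
  }
  hits <- inner_join(
    introns, p,
    by = dplyr::join_by(chrom, strand, overlaps(start, end, pstart, pend)))
  per_intron <- hits %>% count(.data$.intron, name = "n_pacs_in")
  introns <- left_join(introns, per_intron, by = ".intron") %>%
    mutate(n_pacs_in = dplyr::coalesce(.data$n_pacs_in, 0L),
           contains_pac = .data$n_pacs_in > 0L)
  introns %>%
    group_by(splice_class = factor(.data$splice_class, levels = splice_levels),
             gene_class = factor(.data$gene_class, levels = coding_levels),
             .drop = FALSE) %>%
    summarise(n_introns = dplyr::n(),
              n_with_pac = sum(.data$contains_pac),
              n_pac_hits = sum(.data$n_pacs_in),
              .groups = "drop") %>%
    mutate(pct = if_else(.data$n_introns > 0,
                         100 * .data$n_with_pac / .data$n_introns, 0)) %>%
    select("splice_class", "gene_class", "n_introns", "n_with_pac",
           "pct", "n_pac_hits")
}

#' Class means of intron-PAC percentages
#'
#' Averages the cell percentages of [intron_pac_table()] across the other
#' classification: the constitutive mean is the mean of the
#' constitutive-coding and constitutive-noncoding percentages, the coding
#' mean averages over splice classes, and so on.
#'
#' @param cells Tibble from [intron_pac_table()] (or any tibble with
#'   `splice_class`, `gene_class`, `pct`).
#' @return Tibble: `class_type` (`splice`/`gene`), `class`, `mean_pct`.
#' @export
intron_class_means <- function(cells) {
  bind_rows(
    cells %>% group_by(class = as.character(.data$splice_class)) %>%
      summarise(mean_pct = mean(.data$pct), .groups = "drop") %>%
      mutate(class_type = "splice"),
    cells %>% group_by(class = as.character(.data$gene_class)) %>%
      summarise(mean_pct = mean(.data$pct), .groups = "drop") %>%
      mutate(class_type = "gene")
  ) %>% select("class_type", "class", "mean_pct")
}

#' Draw control groups of PAC-free features
#'
#' Simple random samples without replacement, independent across groups,
#' used as length-matched control sets (NPA1..NPAk) for features that
#' contain a PAC.
#'
#' @param pool Tibble of PAC-free features (any columns), or a numeric
#'   vector of lengths.
#' @param n Sample size per group (must not exceed the pool size).
#' @param n_groups Number of control groups (default 3).
#' @param seed Optional integer seed for reproducible sampling.
#' @return Tibble of sampled rows with a `group` column (`NPA1`, ...).
#' @export
sample_controls <- function(pool, n, n_groups = 3L, seed = NULL) {
  if (is.atomic(pool)) pool <- tibble(length = pool)
  if (nrow(pool) < n) stop("pool smaller than the requested sample size")
  draw <- function() {
    bind_rows(lapply(seq_len(n_groups), function(g) {
      idx <- sample.int(nrow(pool), n)
      mutate(pool[idx, , drop = FALSE], group = paste0("NPA", g))
    }))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# exact two-sided rank-sum p by enumeration of the rank multiset
rank_sum_exact_p <- function(ranks, n1, w_obs) {
  N <- length(ranks)
  mu <- n1 * mean(ranks) # = n1 (N+1)/2, also correct under midranks
  sets <- combn(N, n1)
  ws <- colSums(matrix(ranks[sets], nrow = n1))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration of the rank-sum distribution (midranks, so ties are
#' handled) when both groups have at most `exact_limit` observations;
#' otherwise the normal approximation with tie and continuity corrections.
#' The two-sided exact p-value is the probability, over all equally likely
#' assignments of the pooled ranks, of a rank sum at least as far from its
#' mean as observed.
#'
#' @param x,y Numeric vectors.
#' @param exact_limit Largest group size for which enumeration is used.
#' @return Object of class `rank_sum`: list with `statistic` (rank sum of
#'   `x`), `p_value`, `method`, `n1`, `n2`.
#' @export
rank_sum_test <- function(x, y, exact_limit = 8L) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  stopifnot(n1 > 0, n2 > 0)
  ranks <- rank(c(x, y))
  w <- sum(ranks[seq_len(n1)])
  if (n1 <= exact_limit && n2 <= exact_limit) {
    p <- rank_sum_exact_p(ranks, n1, w)
    method <- "exact enumeration"
  } else {
    mu <- n1 * (N + 1) / 2
    ties <- table(ranks)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation with tie/continuity correction"
  }
  structure(list(statistic = w, p_value = p, method = method,
                 n1 = n1, n2 = n2), class = "rank_sum")
}

#' @export
print.rank_sum <- function(x, ...) {
  cat(sprintf("Rank-sum test (%s): W = %g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$method, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' @method tidy rank_sum
#' @export
tidy.rank_sum <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, method = x$method,
         n1 = x$n1, n2 = x$n2)
}

#' Compare lengths of features with PACs against control groups
#'
#' @param with_pac Numeric vector of lengths of features containing a PAC,
#'   or a tibble with a `length` column.
#' @param controls Tibble from [sample_controls()] (columns `length`,
#'   `group`).
#' @param exact_limit Passed to [rank_sum_test()].
#' @return A `length_comparison` tibble: `set`, `n`, `mean`, `median`,
#'   `p_value` (two-sided rank-sum against the with-PAC set; `NA` for the
#'   with-PAC row itself).
#' @export
compare_lengths <- function(with_pac, controls, exact_limit = 8L) {
  if (is.data.frame(with_pac)) with_pac <- with_pac$length
  stopifnot(length(with_pac) > 0, nrow(controls) > 0)
  groups <- split(controls$length, controls$group)
  rows <- c(list(PA = with_pac), groups)
  out <- tibble(
    set = names(rows),
    n = unname(lengths(rows)),
    mean = unname(vapply(rows, mean, numeric(1))),
    median = unname(vapply(rows, median, numeric(1))),
    p_value = c(NA_real_,
                unname(vapply(groups, function(g)
                  rank_sum_test(with_pac, g, exact_limit)$p_value,
                  numeric(1)))))
  structure(out, class = c("length_comparison", class(out)))
}
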