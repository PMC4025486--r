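# Intron-PAC crossing, control sampling and the rank-sum machinery.

toy_introns <- function() {
  tibble::tibble(
    intron_id = sprintf("i%02d", 1:8),
    gene_id = rep(c("g1", "g2", "g3", "g4"), each = 2),
    chrom = "chr1", strand = rep(c("+", "-"), 4),
    start = seq(100L, 800L, by = 100L),
    end = seq(100L, 800L, by = 100L) + 49L,
    splice_class = rep(c("constitutive", "retained"), each = 4),
    gene_class = rep(c("coding", "coding", "noncoding", "noncoding"), 2))
}

test_that("intron_pac_table counts containing introns once and is order-invariant", {
  introns <- toy_introns()
  pacs <- tibble::tibble(chrom = "chr1",
                         strand = c("+", "+", "-"),
                         position = c(120L, 130L, 220L))
  tab <- intron_pac_table(introns, pacs)
  cc <- dplyr::filter(tab, splice_class == "constitutive",
                      gene_class == "coding")
  expect_equal(cc$n_with_pac, 2L)   # intron i01 (two PACs, counted once) + i02
  expect_equal(cc$n_pac_hits, 3L)
  expect_equal(cc$pct, 100)
  expect_equal(sum(tab$n_introns), 8L)
  # conservation: containing + non-containing = total
  expect_true(all(tab$n_with_pac <= tab$n_introns))
  # order invariance
  tab2 <- intron_pac_table(introns[sample(8), ], pacs[c(3, 1, 2), ])
  expect_equal(dplyr::arrange(tab, splice_class, gene_class)$n_with_pac,
               dplyr::arrange(tab2, splice_class, gene_class)$n_with_pac)
  # zero PACs: all percentages zero
  tab0 <- intron_pac_table(introns, pacs[0, ])
  expect_true(all(tab0$pct == 0))
})

test_that("published cell percentages and class means are reproduced", {
  # intron universe with the published counts per cell; one PAC planted in
  # each "containing" intron
  cells <- tibble::tribble(
    ~splice_class, ~gene_class, ~total, ~with,
    "constitutive", "coding", 134708L, 12031L,
    "constitutive", "noncoding", 2550L, 153L,
    "retained", "coding", 5151L, 120L,
    "retained", "noncoding", 116L, 5L)
  introns <- cells %>%
    dplyr::rowwise() %>%
    dplyr::do(tibble::tibble(
      splice_class = .$splice_class, gene_class = .$gene_class,
      idx = seq_len(.$total), with = seq_len(.$total) <= .$with)) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(intron_id = sprintf("i%06d", dplyr::row_number()),
                  chrom = "chr1", strand = "+",
                  start = 100L * dplyr::row_number(),
                  end = 100L * dplyr::row_number() + 50L)
  pacs <- introns %>% dplyr::filter(with) %>%
    dplyr::transmute(chrom, strand, position = start + 10L)
  tab <- intron_pac_table(introns, pacs)
  cc <- dplyr::filter(tab, splice_class == "constitutive",
                      gene_class == "coding")
  expect_equal(round(cc$pct, 2), 8.93)
  means <- intron_class_means(tab)
  expect_equal(round(means$mean_pct[means$class == "constitutive"], 2), 7.47)
  expect_equal(round(means$mean_pct[means$class == "retained"], 2), 3.32)
  expect_equal(round(means$mean_pct[means$class == "coding"], 2), 5.63)
  expect_equal(round(means$mean_pct[means$class == "noncoding"], 2), 5.16)
})

test_that("sample_controls is seeded, exhaustive at pool size, and errors when short", {
  pool <- tibble::tibble(length = 1:100)
  a <- sample_controls(pool, 10, seed = 42)
  b <- sample_controls(pool, 10, seed = 42)
  expect_identical(a, b)
  c <- sample_controls(pool, 10, seed = 43)
  expect_false(identical(a, c))
  expect_equal(dplyr::count(a, group)$n, rep(10L, 3))

  full <- sample_controls(pool, 100, n_groups = 2, seed = 1)
  expect_equal(sort(full$length[full$group == "NPA1"]), 1:100)
  expect_error(sample_controls(pool, 101), "pool smaller")
})

test_that("rank_sum_test agrees with the permutation oracle for small n", {
  withr::local_seed(71)
  for (trial in 1:25) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- sample(1:12, n1, replace = TRUE)  # replace=TRUE forces ties too
    y <- sample(1:12, n2, replace = TRUE)
    got <- rank_sum_test(x, y)
    expect_equal(got$p_value, oracle_ranksum_p(x, y), tolerance = 1e-12,
                 info = paste(c(x, "|", y), collapse = " "))
  }
  # identical multisets: no shift, p = 1
  expect_equal(rank_sum_test(c(3, 5, 5, 9), c(9, 5, 3, 5))$p_value, 1)
})

test_that("the large-sample approximation matches wilcox.test", {
  withr::local_seed(83)
  x <- rnorm(30); y <- rnorm(35, 0.4)
  got <- rank_sum_test(x, y)
  want <- stats::wilcox.test(x, y, correct = TRUE, exact = FALSE)$p.value
  expect_equal(got$p_value, want, tolerance = 1e-6)
  # strong shift is detected at moderate n
  shifted <- rank_sum_test(rexp(50, 0.1), rexp(50, 1))
  expect_lt(shifted$p_value, 0.01)
})

test_that("compare_lengths summarises sets and flags shifts", {
  withr::local_seed(29)
  with_pac <- c(100, 200, 300, 400, 500)
  controls <- sample_controls(rep(c(10, 20, 30, 40, 50), 20), 5,
                              n_groups = 3, seed = 2)
  cmp <- compare_lengths(with_pac, controls)
  expect_equal(cmp$set[1], "PA")
  expect_equal(cmp$n, rep(5L, 4))
  expect_equal(cmp$mean[1], 300)
  expect_equal(cmp$median[1], 300)
  expect_true(is.na(cmp$p_value[1]))
  expect_true(all(cmp$p_value[-1] < 0.05))
})
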