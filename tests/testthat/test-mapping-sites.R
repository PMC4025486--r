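# Read placement, cleavage-site calling, internal-priming filtering and
# unique-site aggregation.

make_toy_genome <- function(seed = 5, len = 600) {
  withr::with_seed(seed, setNames(rand_dna(len, c(A = .18, C = .32,
                                                  G = .32, T = .18)), "chr1"))
}

tailed_row <- function(body) {
  tibble::tibble(read_id = "r1", seq = paste0(body, strrep("A", 12)),
                 was_polyt_head = FALSE, body = body, tail_length = 12L,
                 tail_purity = 1)
}

test_that("map_reads places planted bodies on the correct locus and strand", {
  g <- make_toy_genome()
  body <- substr(g[["chr1"]], 101, 160)
  m <- map_reads(tailed_row(body), g)
  expect_equal(nrow(m), 1L)
  expect_equal(m$strand, "+")
  expect_equal(m$start, 101L)
  expect_equal(m$end, 160L)
  expect_equal(m$clipped, 0L)

  m <- map_reads(tailed_row(revcomp(body)), g)
  expect_equal(m$strand, "-")
  expect_equal(m$start, 101L)
  expect_equal(m$end, 160L)

  # nontemplated bases: clipped before the seed matches
  m <- map_reads(tailed_row(paste0(body, "CG")), g)
  expect_equal(m$clipped, 2L)
  expect_equal(m$nontemplated, 2L)
  expect_equal(m$end, 160L)

  # residual tail after an impurity: clipped adenosines are tail, only the
  # impurity counts as nontemplated
  m <- map_reads(tailed_row(paste0(body, "GAAAAA")), g)
  expect_equal(m$clipped, 6L)
  expect_equal(m$nontemplated, 1L)
  expect_equal(m$end, 160L)

  # more non-A additions than the cap: unmapped
  m <- map_reads(tailed_row(paste0(body, "GCGC")), g)
  expect_equal(nrow(m), 0L)
})

test_that("map_reads drops ambiguous placements", {
  seg <- withr::with_seed(9, rand_dna(60))
  g <- setNames(paste0(seg, strrep("C", 50), seg, strrep("G", 50)), "chr1")
  m <- map_reads(tailed_row(seg), g)
  expect_equal(nrow(m), 0L)
})

test_that("call_sites reassigns trailing genomic adenosines up to the cap", {
  base <- strrep("C", 40)
  p <- polya_params("est")
  mk_mapped <- function(genome, end) {
    tibble::tibble(read_id = "r1", chrom = "chr1", strand = "+",
                   start = 1L, end = end, clipped = 0L)
  }
  # aligned end on non-A: site = aligned end
  g1 <- setNames(paste0(base, "G", strrep("C", 20)), "chr1")
  cs <- call_sites(mk_mapped(g1, 41L), g1, p)
  expect_true(cs$accepted)
  expect_equal(cs$position, 41L)

  # three trailing aligned A's: the site moves to the C just upstream
  g2 <- setNames(paste0(strrep("C", 38), "AAA", strrep("G", 20)), "chr1")
  cs <- call_sites(mk_mapped(g2, 41L), g2, p)
  expect_true(cs$accepted)
  expect_equal(cs$position, 38L)

  # five trailing aligned A's exceed the 4-nt cap: rejected
  g3 <- setNames(paste0(strrep("C", 36), "AAAAA", strrep("G", 20)), "chr1")
  cs <- call_sites(mk_mapped(g3, 41L), g3, p)
  expect_false(cs$accepted)
  expect_equal(cs$reason, "genomic_a_overflow")

  # alignment ending at the contig edge (tail would run off): rejected
  g4 <- setNames(strrep("C", 41), "chr1")
  cs <- call_sites(mk_mapped(g4, 41L), g4, p)
  expect_false(cs$accepted)
  expect_equal(cs$reason, "contig_edge")

  # minus-strand reassignment is strand-symmetric (sense A = plus-strand T)
  g5 <- setNames(paste0(strrep("C", 20), "G", "TTT", strrep("C", 20)), "chr1")
  m5 <- tibble::tibble(read_id = "r1", chrom = "chr1", strand = "-",
                       start = 22L, end = 44L, clipped = 0L)
  cs <- call_sites(m5, g5, p)
  expect_true(cs$accepted)
  expect_equal(cs$position, 25L)
})

test_that("internal-priming flag implements the dual run/count rule", {
  # helper genome builder: 21-nt window content around position 50
  with_window <- function(window) {
    stopifnot(nchar(window) == 21)
    g <- paste0(strrep("C", 39), window, strrep("C", 40))
    setNames(g, "chr1")
  }
  site <- tibble::tibble(chrom = "chr1", strand = "+", position = 50L)

  f <- flag_internal_priming(site, with_window(strrep("A", 21)))
  expect_true(f$internal_priming)
  f <- flag_internal_priming(site, with_window(strrep("G", 21)))
  expect_false(f$internal_priming)
  # exactly AAAAAA at +1..+6 and no other A: run rule fires
  w <- paste0(strrep("C", 11), "AAAAAA", strrep("C", 4))
  f <- flag_internal_priming(site, with_window(w))
  expect_true(f$internal_priming)
  # 7 A's spread over a 10-nt subwindow without a 6-run: count rule fires
  w <- paste0(strrep("C", 11), "AAAGAAAA", strrep("C", 2))
  f <- flag_internal_priming(site, with_window(w))
  expect_true(f$internal_priming)
})

test_that("internal-priming flag agrees with a sliding-window oracle", {
  withr::local_seed(13)
  for (i in 1:200) {
    win <- rand_dna(21, c(A = .45, C = .2, G = .2, T = .15))
    g <- setNames(paste0(strrep("C", 39), win, strrep("C", 40)), "chr1")
    site <- tibble::tibble(chrom = "chr1", strand = "+", position = 50L)
    got <- flag_internal_priming(site, g)$internal_priming
    expect_equal(got, oracle_ip(win), info = win)
  }
})

test_that("surviving sites never contain a disqualifying A-run in -10..+10", {
  withr::local_seed(21)
  g <- setNames(rand_dna(2000, c(A = .4, C = .2, G = .2, T = .2)), "chr1")
  sites <- tibble::tibble(chrom = "chr1", strand = "+",
                          position = seq(20L, 1980L, by = 7L))
  kept <- dplyr::filter(flag_internal_priming(sites, g), !internal_priming)
  gs <- g[["chr1"]]
  runs <- vapply(kept$position, function(p) {
    pacfinder:::max_char_run(substr(gs, p - 10, p + 10), "A")
  }, integer(1))
  expect_true(all(runs < 6))
})

test_that("aggregate_sites collapses identical coordinates and keeps strands apart", {
  cand <- tibble::tibble(
    read_id = paste0("r", 1:5), chrom = "chr1",
    strand = c("+", "+", "-", "+", "+"),
    position = c(100L, 100L, 100L, 200L, 100L),
    label = c("est", "ngs", "est", "est", "est"),
    accepted = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    reason = NA_character_)
  out <- aggregate_sites(cand)
  expect_equal(nrow(out), 3L)
  plus100 <- dplyr::filter(out, position == 100, strand == "+")
  expect_equal(plus100$support, 2L)
  expect_equal(plus100$n_est, 1L)
  expect_equal(plus100$n_ngs, 1L)
  expect_equal(nrow(aggregate_sites(cand[0, ])), 0L)
})
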