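# Region assignment with the 3'-UTR extension rule.

test_that("extend_utr3 grows 3'-UTRs downstream with truncation", {
  m <- toy_models()
  ext <- extend_utr3(m, 50)
  u3a <- dplyr::filter(ext, gene_id == "gA", type == "three_prime_UTR")
  expect_equal(u3a$end, 3050L)      # plus strand: 3000 -> 3050
  u3b <- dplyr::filter(ext, gene_id == "gB", type == "three_prime_UTR")
  expect_equal(u3b$start, 4951L)    # minus strand: 5001 -> 4951

  # a same-strand neighbour 20 nt downstream truncates the extension
  m2 <- dplyr::mutate(as_tibble(toy_models()),
                      strand = "+",
                      gene_id = .data$gene_id)
  m2 <- as_gene_models(m2)
  # gB (now +) starts at 5001; push gA's end next to it: distance 2001
  ext2 <- extend_utr3(m2, 50)
  u3 <- dplyr::filter(ext2, gene_id == "gA", type == "three_prime_UTR")
  expect_equal(u3$end, 3050L)       # room (2001 nt) does not bind
  m3 <- as_tibble(toy_models())
  m3[m3$gene_id == "gB", "strand"] <- "+"
  m3[m3$gene_id == "gB", c("start", "end")] <-
    m3[m3$gene_id == "gB", c("start", "end")] - 1981L
  ext3 <- extend_utr3(as_gene_models(m3), 50)
  u3 <- dplyr::filter(ext3, gene_id == "gA", type == "three_prime_UTR")
  expect_equal(u3$end, 3020L)       # gB starts 20 nt downstream: ext = 20
})

test_that("assign_regions applies containment, extension and precedence", {
  ext <- extend_utr3(toy_models(), 50)
  q <- tibble::tibble(
    pac_id = paste0("P", 1:5), chrom = "chr1",
    strand = c("+", "+", "+", "-", "+"),
    position = c(1500L,   # inside gA CDS
                 3030L,   # 30 nt downstream of gA end: UTR3 via extension
                 4000L,   # 200 nt beyond gA's extended end: intergenic
                 6900L,   # inside gB 5'UTR (minus strand)
                 1900L))  # inside gA intron
  a <- assign_regions(q, ext)
  expect_equal(as.character(a$region),
               c("CDS", "UTR3", "INTERGENIC", "UTR5", "INTRON"))
  expect_equal(a$gene_id[1:2], c("gA", "gA"))
  expect_true(is.na(a$gene_id[3]))
  expect_equal(a$dist_to_3p[3], 1000L)  # distance to gA's annotated end
  expect_equal(a$dist_to_3p[2], 30L)

  # antisense containment does not count: minus-strand site inside gA
  anti <- assign_regions(tibble::tibble(
    pac_id = "P9", chrom = "chr1", strand = "-", position = 1500L), ext)
  expect_equal(as.character(anti$region), "INTERGENIC")
})

test_that("UTR3 assignments are monotone in the extension", {
  withr::local_seed(77)
  q <- tibble::tibble(pac_id = sprintf("P%02d", 1:40), chrom = "chr1",
                      strand = sample(c("+", "-"), 40, replace = TRUE),
                      position = sample(900:7200, 40))
  n_u3 <- function(e) {
    a <- assign_regions(q, extend_utr3(toy_models(), e))
    sum(a$region == "UTR3")
  }
  expect_lte(n_u3(0), n_u3(50))
})

test_that("region_distribution returns percentages summing to 100", {
  a <- tibble::tibble(region = factor(
    c("UTR3", "UTR3", "CDS", "INTRON", "UTR5", "INTERGENIC"),
    levels = c("UTR5", "UTR3", "CDS", "INTRON", "INTERGENIC")))
  rd <- region_distribution(a)
  expect_equal(sum(rd$pct), 100, tolerance = 0.01)
  expect_equal(rd$pct[rd$region == "UTR3"], 100 * 2 / 6)
  all_u3 <- region_distribution(
    tibble::tibble(region = rep("UTR3", 5)))
  expect_equal(all_u3$pct[all_u3$region == "UTR3"], 100)
  expect_equal(sum(all_u3$pct[all_u3$region != "UTR3"]), 0)
  expect_error(region_distribution(a[0, ]), "no assignments")
})

test_that("distance_profile bins distances and reports cumulative fractions", {
  a <- tibble::tibble(region = "INTERGENIC", dist_to_3p = c(10, 10, 10))
  dp <- distance_profile(a, cutoffs = 50)
  expect_equal(dp$cumulative$fraction, 1)
  a2 <- tibble::tibble(region = "INTERGENIC", dist_to_3p = c(10, 500))
  dp2 <- distance_profile(a2, cutoffs = c(50, 600))
  expect_equal(dp2$cumulative$fraction, c(0.5, 1))
  expect_equal(sum(dp2$histogram$n), 2L)
  expect_equal(dp2$histogram$n[dp2$histogram$bin_start == 0], 1L)
})

test_that("GFF3 output written by the simulator round-trips into gene models", {
  cfg <- sim_config(seed = 8, n_genes = 4, genome_length = 30000,
                    decoy_count = 0)
  sim <- simulate_genome(cfg)
  d <- withr::local_tempdir()
  paths <- write_sim(sim, d)
  gm <- read_gene_models(paths[["gff"]])
  orig <- as_gene_models(sim$features)
  for (ty in c("gene", "exon", "CDS", "three_prime_UTR", "intron")) {
    a <- dplyr::arrange(dplyr::filter(as_tibble(gm), type == ty), start)
    b <- dplyr::arrange(dplyr::filter(as_tibble(orig), type == ty), start)
    expect_equal(a$start, b$start, info = ty)
    expect_equal(a$end, b$end, info = ty)
    expect_equal(a$strand, b$strand, info = ty)
  }
  # planted-region ground truth is reproduced exactly by the assignment
  rd <- simulate_reads(sim)
  # small flank set: the Markov-background stability warning is expected
  res <- suppressWarnings(run_apa_pipeline(rd$reads, sim$genome, gm))
  joined <- dplyr::inner_join(
    res$assignments,
    sim$truth_sites, by = c("chrom", "strand"),
    relationship = "many-to-many") %>%
    dplyr::filter(abs(position.x - position.y) <= 5)
  expect_true(all(as.character(joined$region.x) == joined$region.y))
})
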