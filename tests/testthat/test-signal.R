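# k-mer scanning modes, profiles, PSSMs and Markov-background Z-scores.

test_that("the gap-spaced distribution mode counts ATATATAT correctly", {
  # with gap = 2, ATATATAT yields one count each for ATATAT and TATATA;
  # overlapping mode sees both starts of ATATAT
  dist <- count_kmers("ATATATAT", k = 6, mode = "distribution", gap = 2)
  expect_equal(dist$count[dist$kmer == "AUAUAU"], 1L)
  expect_equal(dist$count[dist$kmer == "UAUAUA"], 1L)
  over <- count_kmers("ATATATAT", k = 6, mode = "overlapping")
  expect_equal(over$count[over$kmer == "AUAUAU"], 2L)
  expect_equal(over$count[over$kmer == "UAUAUA"], 1L)
})

test_that("frequency mode records the occurrence closest to the site", {
  # UGUAA at window labels -25 and -10: one count, at -10
  w <- strrep("C", 24)
  substr(w, 4, 8) <- "TGTAA"    # start label -25
  substr(w, 19, 23) <- "TGTAA"  # start label -10
  labels <- -28:-5
  fr <- count_kmers(w, k = 5, mode = "frequency", labels = labels)
  expect_equal(fr$count[fr$kmer == "UGUAA"], 1L)
  ps <- motif_pssm(tibble::tibble(pac_id = "p", seq = w, padded = FALSE),
                   "UGUAA", window = c(-28, -5), mode = "frequency",
                   positions = labels)
  expect_equal(ps$count[ps$position == -10], 1L)
  expect_equal(ps$count[ps$position == -25], 0L)
})

test_that("scan modes agree with the brute-force regex oracle", {
  withr::local_seed(202)
  seqs <- replicate(60, rand_dna(sample(c(24, 80, 150), 1)))
  seqs[1] <- rand_dna(10000)  # one long input
  for (mode in c("overlapping", "distribution", "frequency")) {
    gap <- if (mode == "distribution") sample(0:3, 1) else 0L
    got <- count_kmers(seqs, k = 5, mode = mode, gap = gap)
    # oracle: per sequence, count every k-mer present via regex lookahead
    want <- new.env()
    for (s in seqs) {
      kms <- unique(substring(s, 1:(nchar(s) - 4), 5:nchar(s)))
      kms <- kms[!grepl("[^ACGT]", kms)]
      for (km in kms) {
        cnt <- oracle_motif_count(s, km, mode, gap)
        key <- chartr("T", "U", km)
        want[[key]] <- (want[[key]] %||% 0L) + cnt
      }
    }
    for (km in got$kmer[got$count > 0]) {
      expect_equal(got$count[got$kmer == km], as.integer(want[[km]]),
                   info = paste(mode, km))
    }
    expect_equal(sum(got$count),
                 sum(unlist(as.list(want))), info = mode)
  }
})

test_that("mode counts are monotone: overlapping >= distribution >= frequency", {
  withr::local_seed(17)
  seqs <- replicate(40, rand_dna(60, c(A = .4, C = .1, G = .1, T = .4)))
  ov <- count_kmers(seqs, k = 5, mode = "overlapping")
  di <- count_kmers(seqs, k = 5, mode = "distribution", gap = 1)
  fr <- count_kmers(seqs, k = 5, mode = "frequency")
  expect_true(all(ov$count[order(ov$kmer)] >= di$count[order(di$kmer)]))
  expect_true(all(di$count[order(di$kmer)] >= fr$count[order(fr$kmer)]))
})

test_that("overlapping-mode totals conserve the number of scanned windows", {
  withr::local_seed(23)
  seqs <- c(replicate(20, rand_dna(50)), paste0(rand_dna(20), "N", rand_dna(20)))
  ov <- count_kmers(seqs, k = 5, mode = "overlapping")
  n_windows <- sum(vapply(seqs, function(s) {
    kms <- substring(s, 1:(nchar(s) - 4), 5:nchar(s))
    sum(!grepl("N", kms, fixed = TRUE))
  }, integer(1)))
  expect_equal(sum(ov$count), n_windows)
  expect_equal(attr(ov, "n_positions"), n_windows)
})

test_that("nucleotide profiles normalise rows and expose planted signals", {
  prof <- nucleotide_profile(c("AAAA", "AAAA"), positions = -4:-1)
  expect_true(all(prof$A == 1))
  withr::local_seed(31)
  n <- 400; rate <- 0.8
  seqs <- replicate(n, rand_dna(150))
  plant <- seq_len(n) <= rate * n
  # UGUAA planted at labels -22..-18 = flank indices 79..83
  for (i in which(plant)) substr(seqs[i], 79, 83) <- "TGTAA"
  prof <- nucleotide_profile(seqs)
  expect_true(all(abs(rowSums(prof[, c("A", "C", "G", "U")]) - 1) < 1e-9))
  # closed-form mixture: U at -22 ~ rate + (1 - rate)/4
  expect_gt(prof$U[prof$position == -22], rate + (1 - rate) / 4 - 0.07)
  expect_gt(prof$A[prof$position == -19], rate + (1 - rate) / 4 - 0.07)
})

test_that("motif PSSMs capture start distributions", {
  seqs <- replicate(30, rand_dna(24, c(A = .1, C = .4, G = .4, T = .1)))
  # absent motif: all-zero matrix
  ps <- motif_pssm(seqs, "UGUAA", window = c(-28, -5), positions = -28:-5)
  expect_true(all(ps$count == 0))
  # planted at one fixed label in all sequences: unit mass there
  for (i in seq_along(seqs)) substr(seqs[i], 7, 11) <- "TGTAA"
  ps <- motif_pssm(seqs, "UGUAA", window = c(-28, -5), positions = -28:-5)
  expect_equal(ps$freq[ps$position == -22], 1)
  expect_equal(sum(ps$count), 30L)
  expect_equal(ps$U[ps$position == -22], 1)
  # uniform random sequences: approximately uniform start distribution
  withr::local_seed(47)
  big <- replicate(10000, rand_dna(24))
  pu <- motif_pssm(big, "AC", window = c(-28, -5), positions = -28:-5,
                   mode = "overlapping")
  cs <- suppressWarnings(stats::chisq.test(pu$count))
  expect_gt(cs$p.value, 0.001)
})

test_that("Markov backgrounds give closed-form probabilities", {
  # order 0 on balanced bases: every pentamer has probability (1/4)^5
  bg0 <- train_markov(strrep("ACGT", 64), order = 0)
  expect_equal(motif_prob("TGTAA", bg0), 0.25^5, tolerance = 1e-12)
  expect_equal(motif_prob("AAAAA", bg0), 0.25^5, tolerance = 1e-12)

  # order 1 on a long ACAC... sequence: alternation dominates
  bg1 <- suppressWarnings(train_markov(strrep("AC", 3000), order = 1))
  expect_gt(motif_prob("CACAC", bg1), 0.2)
  expect_lt(motif_prob("TGTAA", bg1), 1e-4)

  # add-one smoothing keeps unseen grams strictly positive
  bg3 <- suppressWarnings(train_markov(strrep("ACGT", 200), order = 3))
  expect_gt(motif_prob("TTTTT", bg3), 0)
  expect_error(motif_prob("ACG", bg3), "order")
})

test_that("Z-scores are zero at expectation and increase with observation", {
  bg <- train_markov(strrep("ACGT", 64), order = 0)
  n <- 1000
  e <- n * 0.25^5
  expect_equal(motif_zscore(e, "UGUAA", bg, n)$zscore, 0)
  zs <- vapply(c(e, e + 5, e + 20), function(o) {
    motif_zscore(o, "UGUAA", bg, n)$zscore
  }, numeric(1))
  expect_true(all(diff(zs) > 0))
})

test_that("Z-scores are null-calibrated on uniform sequences", {
  withr::local_seed(59)
  seqs <- replicate(3000, rand_dna(24))
  tab <- count_kmers(seqs, k = 5, mode = "overlapping")
  tab <- add_zscores(tab, background = train_markov(seqs, order = 0))
  expect_lt(abs(mean(tab$zscore)), 0.1)
})
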