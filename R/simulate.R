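# Synthetic data with planted ground truth.
#
# The generator emulates the statistical structure the pipeline assumes in
# a GC-rich alga-like genome: iid GC-biased background sequence, genes with
# 5'UTR / alternating CDS exons and introns / 3'UTR on either strand, true
# poly(A) sites with the canonical UGUAA signal planted in the near
# upstream element (-22..-18), cleavage microheterogeneity around each
# site, multi-PAC (APA) genes, platform-specific tail lengths and purity,
# nontemplated additions, poly(T)-headed antisense reads, and genomic
# A-run decoys emulating oligo(dT) internal priming. Read bodies are
# unspliced genomic 3'-terminal fragments (the mapper is exact-match, not
# spliced); FASTQ qualities, paralogs and expression models beyond the
# per-site read-count law are out of scope.

#' Configuration for the synthetic-data generator
#'
#' Defaults are the package's standing study conditions: a 100-kb
#' single-contig genome at the Chlamydomonas-like GC fraction 0.6345,
#' twenty genes of which 30% carry two to three poly(A) site clusters, the
#' UGUAA near-upstream element planted at -22..-18 of every true site,
#' 1-nt cleavage microheterogeneity, Poisson(15) reads per site (floored
#' at 5), 1% tail impurity, 20% antisense (poly(T)-headed) reads and eight
#' planted A-run internal-priming decoys of 6-12 nt.
#'
#' @param seed Integer seed; fixing it makes every output byte-identical.
#' @param genome_length Contig length in nt.
#' @param gc_fraction Genome GC fraction in `[0, 1]`.
#' @param n_genes Number of genes.
#' @param introns_per_gene Length-2 inclusive range of introns per gene.
#' @param apa_gene_fraction Fraction of genes given two or more true sites.
#' @param pacs_per_apa_gene Length-2 range of true sites per APA gene.
#' @param nue_motif DNA motif planted upstream of every true site.
#' @param nue_start Position label of the motif's first base (default -22).
#' @param microheterogeneity_sd SD (nt) of individual cleavage positions
#'   around the true site.
#' @param mode `"est"` (400-nt reads, strict tails) or `"ngs"` (50-nt
#'   reads, 95%-purity tails); sets read length and the tail-length law.
#' @param read_length Read length in nt (defaults 400 EST / 50 NGS).
#' @param tail_impurity_rate Per-base probability of a non-A in the tail.
#' @param nontemplated_rate Probabilities of 0..3 nontemplated bases
#'   between the aligned end and the tail.
#' @param antisense_fraction Fraction of reads emitted reverse-complemented
#'   (poly(T) head).
#' @param decoy_count Number of genomic A-runs (6-12 nt) planted in
#'   CDS/introns as internal-priming traps.
#' @param reads_lambda Poisson mean of reads per site.
#' @param reads_min Lower floor of reads per site.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 100000L,
                       gc_fraction = 0.6345,
                       n_genes = 20L,
                       introns_per_gene = c(1L, 3L),
                       apa_gene_fraction = 0.3,
                       pacs_per_apa_gene = c(2L, 3L),
                       nue_motif = "TGTAA",
                       nue_start = -22L,
                       microheterogeneity_sd = 1,
                       mode = c("est", "ngs"),
                       read_length = NULL,
                       tail_impurity_rate = 0.01,
                       nontemplated_rate = c(0.7, 0.15, 0.1, 0.05),
                       antisense_fraction = 0.2,
                       decoy_count = 8L,
                       reads_lambda = 15,
                       reads_min = 5L) {
  mode <- match.arg(mode)
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              gc_fraction = gc_fraction, n_genes = as.integer(n_genes),
              introns_per_gene = as.integer(introns_per_gene),
              apa_gene_fraction = apa_gene_fraction,
              pacs_per_apa_gene = as.integer(pacs_per_apa_gene),
              nue_motif = toupper(chartr("U", "T", nue_motif)),
              nue_start = as.integer(nue_start),
              microheterogeneity_sd = microheterogeneity_sd,
              mode = mode,
              read_length = as.integer(read_length %||%
                                         if (mode == "est") 400L else 50L),
              tail_impurity_rate = tail_impurity_rate,
              nontemplated_rate = nontemplated_rate,
              antisense_fraction = antisense_fraction,
              decoy_count = as.integer(decoy_count),
              reads_lambda = reads_lambda,
              reads_min = as.integer(reads_min))
  fr <- c(cfg$gc_fraction, cfg$apa_gene_fraction, cfg$tail_impurity_rate,
          cfg$antisense_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (abs(sum(cfg$nontemplated_rate) - 1) > 1e-8) {
    stop("nontemplated_rate must sum to 1")
  }
  stopifnot(cfg$genome_length > 0, cfg$n_genes >= 0,
            cfg$microheterogeneity_sd >= 0, cfg$reads_min >= 1)
  structure(cfg, class = "sim_config")
}

sample_range <- function(rng, n = 1L) {
  if (rng[1] == rng[2]) rep(rng[1], n) else sample(seq(rng[1], rng[2]), n,
                                                   replace = TRUE)
}

# overwrite genome (character, one contig) with motif in transcript sense at
# labels label_start.. relative to a site (site at -1)
plant_motif <- function(genome_seq, strand, site, motif, label_start) {
  k <- nchar(motif)
  if (strand == "+") {
    lo <- site + label_start + 1L
    substr(genome_seq, lo, lo + k - 1L) <- motif
  } else {
    hi <- site - label_start - 1L
    substr(genome_seq, hi - k + 1L, hi) <- revcomp(motif)
  }
  genome_seq
}

#' Simulate a GC-biased genome with genes and planted poly(A) ground truth
#'
#' @param config A [sim_config()].
#' @return A `polya_sim` list: `genome` (one-contig
#'   [Biostrings::DNAStringSet]), `features` (GFF3-style feature tibble),
#'   `truth_sites` (planted sites with region labels and expected read
#'   support), `decoys` (planted A-runs with the artifact site a misprimed
#'   read would produce), `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  p <- c(A = (1 - config$gc_fraction) / 2, C = config$gc_fraction / 2,
         G = config$gc_fraction / 2, T = (1 - config$gc_fraction) / 2)
  gseq <- paste(sample(names(p), config$genome_length, replace = TRUE,
                       prob = p), collapse = "")
  features <- list(); truth <- list()
  cursor <- 1L
  gene_meta <- list()
  for (gi in seq_len(config$n_genes)) {
    spacer <- sample(300:800, 1)
    n_introns <- sample_range(config$introns_per_gene)
    utr5 <- sample(150:250, 1); utr3 <- sample(220:320, 1)
    cds_lens <- sample(200:400, n_introns + 1L, replace = TRUE)
    intron_lens <- if (n_introns > 0) sample(100:250, n_introns,
                                             replace = TRUE) else integer(0)
    blocks <- c(list(c("five_prime_UTR", utr5)))
    for (j in seq_len(n_introns + 1L)) {
      blocks <- c(blocks, list(c("CDS", cds_lens[j])))
      if (j <= n_introns) blocks <- c(blocks, list(c("intron", intron_lens[j])))
    }
    blocks <- c(blocks, list(c("three_prime_UTR", utr3)))
    footprint <- sum(vapply(blocks, function(b) as.integer(b[2]), integer(1)))
    gstart <- cursor + spacer
    gend <- gstart + footprint - 1L
    if (gend > config$genome_length - 400L) {
      stop("gene footprints exceed genome length; enlarge genome_length ",
           "or reduce n_genes")
    }
    strand <- sample(c("+", "-"), 1)
    gene_id <- sprintf("gene%03d", gi)
    tx_id <- paste0(gene_id, ".t1")
    # map transcript-order blocks to genomic intervals
    offs <- cumsum(c(0L, vapply(blocks, function(b) as.integer(b[2]),
                                integer(1))))
    rows <- list()
    for (j in seq_along(blocks)) {
      len <- as.integer(blocks[[j]][2])
      if (strand == "+") {
        s <- gstart + offs[j]; e <- s + len - 1L
      } else {
        e <- gend - offs[j]; s <- e - len + 1L
      }
      rows[[j]] <- tibble(type = blocks[[j]][1], start = s, end = e)
    }
    ft <- bind_rows(rows)
    # exons = maximal non-intron runs in transcript order
    is_int <- ft$type == "intron"
    run <- cumsum(c(TRUE, is_int[-1] | is_int[-length(is_int)]))
    exons <- ft[!is_int, ] %>%
      mutate(.run = run[!is_int]) %>%
      group_by(.data$.run) %>%
      summarise(start = min(.data$start), end = max(.data$end),
                .groups = "drop") %>%
      mutate(type = "exon") %>% select("type", "start", "end")
    gene_rows <- bind_rows(
      tibble(type = "gene", start = gstart, end = gend),
      tibble(type = "mRNA", start = gstart, end = gend),
      exons,
      dplyr::filter(ft, .data$type != "intron")) %>%
      mutate(gene_id = gene_id,
             transcript_id = if_else(.data$type == "gene", NA_character_,
                                     tx_id),
             chrom = "chr1", strand = strand)
    features[[gi]] <- gene_rows
    u3 <- dplyr::filter(ft, .data$type == "three_prime_UTR")
    cds <- dplyr::filter(ft, .data$type == "CDS")
    intr <- dplyr::filter(ft, .data$type == "intron")
    gene_meta[[gi]] <- list(gene_id = gene_id, strand = strand,
                            gstart = gstart, gend = gend,
                            utr3 = u3, cds = cds, introns = intr)
    cursor <- gend + 1L
  }
  features <- if (length(features)) bind_rows(features) else
    tibble(gene_id = character(), transcript_id = character(),
           type = character(), chrom = character(), strand = character(),
           start = integer(), end = integer())
  # --- plant true sites -----------------------------------------------
  n_apa <- round(config$apa_gene_fraction * config$n_genes)
  apa_genes <- if (config$n_genes > 0 && n_apa > 0) {
    sample(seq_len(config$n_genes), n_apa)
  } else integer(0)
  site_rows <- list()
  for (gi in seq_len(config$n_genes)) {
    gm <- gene_meta[[gi]]
    sense_end3 <- if (gm$strand == "+") gm$gend else gm$gstart
    # primary site: inside the 3'UTR, or occasionally just downstream of
    # the annotated end (within the 50-nt extension zone)
    in_ext <- runif(1) < 0.15
    off <- if (in_ext) -sample(5:40, 1) else sample(5:40, 1)
    pos1 <- if (gm$strand == "+") sense_end3 - off else sense_end3 + off
    sites <- tibble(position = pos1, region = "UTR3")
    if (gi %in% apa_genes) {
      n_extra <- sample_range(config$pacs_per_apa_gene) - 1L
      for (e in seq_len(n_extra)) {
        reg <- sample(c("UTR3", "CDS", "INTRON"), 1,
                      prob = c(0.5, 0.25, 0.25))
        if (reg == "UTR3") {
          off2 <- off + sample(60:120, 1)
          pos <- if (gm$strand == "+") sense_end3 - off2 else sense_end3 + off2
        } else if (reg == "CDS" && nrow(gm$cds)) {
          iv <- gm$cds[sample(nrow(gm$cds), 1), ]
          pos <- sample(seq(iv$start + 30L, iv$end - 30L), 1)
        } else if (reg == "INTRON" && nrow(gm$introns)) {
          iv <- gm$introns[sample(nrow(gm$introns), 1), ]
          pos <- sample(seq(iv$start + 30L, iv$end - 30L), 1)
          reg <- "INTRON"
        } else next
        if (reg == "CDS") reg <- "CDS"
        # enforce separation from already planted sites of this gene
        if (any(abs(pos - sites$position) < 60L)) next
        sites <- bind_rows(sites, tibble(position = pos, region = reg))
      }
    }
    sites$gene_id <- gm$gene_id
    sites$strand <- gm$strand
    site_rows[[gi]] <- sites
  }
  truth_sites <- if (length(site_rows)) bind_rows(site_rows) else
    tibble(position = integer(), region = character(),
           gene_id = character(), strand = character())
  if (nrow(truth_sites)) {
    truth_sites <- truth_sites %>%
      mutate(chrom = "chr1",
             site_id = sprintf("site%03d", row_number()),
             expected_support = pmax(rpois(dplyr::n(), config$reads_lambda),
                                     config$reads_min)) %>%
      select("site_id", "chrom", "strand", "position", "region",
             "gene_id", "expected_support")
    for (i in seq_len(nrow(truth_sites))) {
      gseq <- plant_motif(gseq, truth_sites$strand[i],
                          truth_sites$position[i], config$nue_motif,
                          config$nue_start)
    }
  } else {
    truth_sites <- tibble(site_id = character(), chrom = character(),
                          strand = character(), position = integer(),
                          region = character(), gene_id = character(),
                          expected_support = integer())
  }
  # --- plant internal-priming decoys ----------------------------------
  decoys <- tibble(decoy_id = character(), chrom = character(),
                   strand = character(), run_start = integer(),
                   run_length = integer(), artifact_site = integer())
  if (config$decoy_count > 0 && length(gene_meta)) {
    pool <- bind_rows(lapply(gene_meta, function(gm) {
      iv <- bind_rows(gm$cds, gm$introns)
      iv$strand <- gm$strand
      iv
    })) %>% dplyr::filter(.data$end - .data$start > 120L)
    placed <- 0L; tries <- 0L
    while (placed < config$decoy_count && tries < 500L && nrow(pool)) {
      tries <- tries + 1L
      iv <- pool[sample(nrow(pool), 1), ]
      len <- sample(6:12, 1)
      p0 <- sample(seq(iv$start + 40L, iv$end - 40L - len), 1)
      if (nrow(truth_sites) &&
          any(abs(p0 - truth_sites$position) < 100L)) next
      if (nrow(decoys) && any(abs(p0 - decoys$run_start) < 60L)) next
      fill <- if (iv$strand == "+") strrep("A", len) else strrep("T", len)
      substr(gseq, p0, p0 + len - 1L) <- fill
      art <- if (iv$strand == "+") p0 - 1L else p0 + len
      placed <- placed + 1L
      decoys <- bind_rows(decoys, tibble(
        decoy_id = sprintf("decoy%02d", placed), chrom = "chr1",
        strand = iv$strand,
        run_start = if (iv$strand == "+") p0 else p0 + len - 1L,
        run_length = len, artifact_site = art))
    }
  }
  genome <- Biostrings::DNAStringSet(setNames(gseq, "chr1"))
  structure(list(genome = genome, features = features,
                 truth_sites = truth_sites, decoys = decoys,
                 config = config),
            class = "polya_sim")
}

#' @export
print.polya_sim <- function(x, ...) {
  cat(sprintf(
    "<polya_sim> %d nt genome (GC %.3f target), %d genes, %d true sites, %d decoys\n",
    sum(nchar(as.character(x$genome))), x$config$gc_fraction,
    x$config$n_genes, nrow(x$truth_sites), nrow(x$decoys)))
  invisible(x)
}

sim_tail_length <- function(n, config) {
  if (config$mode == "est") {
    pmin(pmax(round(rnorm(n, 45, 10)), 12L), 120L)
  } else {
    sample(16:25, n, replace = TRUE)
  }
}

random_tail <- function(len, impurity) {
  if (len == 0L) return("")
  bases <- rep("A", len)
  bad <- runif(len) < impurity
  if (any(bad)) bases[bad] <- sample(c("C", "G", "T"), sum(bad),
                                     replace = TRUE)
  paste(bases, collapse = "")
}

#' Simulate tailed reads from planted ground truth
#'
#' Draws, for each true site, `expected_support` reads whose cleavage
#' positions scatter around the site (discretised normal, truncated to the
#' transcribed span), appends nontemplated bases and an impure poly(A)
#' tail, and reverse-complements an `antisense_fraction` of reads
#' (poly(T) heads). Decoy reads cover each planted A-run and end at its
#' end with no synthetic tail: their only A's are genomic.
#'
#' @param sim A `polya_sim` from [simulate_genome()].
#' @param config Configuration; defaults to the one inside `sim`.
#' @return List with `reads` (tibble `read_id`, `seq`) and `truth`
#'   (per-read tibble with origin, source site, cleavage position, tail
#'   length/impurities, nontemplated count, antisense flag).
#' @export
simulate_reads <- function(sim, config = sim$config) {
  set.seed(config$seed + 99991L)
  gchr <- genome_chars(sim$genome)[["chr1"]]
  glen <- nchar(gchr)
  reads <- list(); truth <- list()
  ridx <- 0L
  gene_span <- sim$features %>%
    dplyr::filter(.data$type == "gene") %>%
    select("gene_id", "start", "end")
  for (i in seq_len(nrow(sim$truth_sites))) {
    st <- sim$truth_sites[i, ]
    if (st$position < 1L || st$position > glen) {
      stop("true site outside the genome")
    }
    gs <- gene_span[gene_span$gene_id == st$gene_id, ]
    lo_span <- min(gs$start, st$position); hi_span <- max(gs$end, st$position)
    n <- st$expected_support
    jit <- round(rnorm(n, 0, config$microheterogeneity_sd))
    cleave <- pmin(pmax(st$position + jit, lo_span), hi_span)
    tails <- sim_tail_length(n, config)
    nts <- sample(0:3, n, replace = TRUE, prob = config$nontemplated_rate)
    for (j in seq_len(n)) {
      body_len <- config$read_length - tails[j] - nts[j]
      if (st$strand == "+") {
        s <- max(1L, cleave[j] - body_len + 1L)
        body <- substr(gchr, s, cleave[j])
      } else {
        e <- min(glen, cleave[j] + body_len - 1L)
        body <- revcomp(substr(gchr, cleave[j], e))
      }
      ntseq <- if (nts[j] > 0) paste(sample(c("C", "G", "T"), nts[j],
                                            replace = TRUE), collapse = "")
               else ""
      tail <- random_tail(tails[j], config$tail_impurity_rate)
      seq <- paste0(body, ntseq, tail)
      anti <- runif(1) < config$antisense_fraction
      if (anti) seq <- revcomp(seq)
      ridx <- ridx + 1L
      reads[[ridx]] <- seq
      truth[[ridx]] <- tibble(
        read_id = sprintf("read%05d", ridx), origin = "site",
        source_id = st$site_id, chrom = st$chrom, strand = st$strand,
        true_position = st$position, cleavage = cleave[j],
        tail_length = tails[j], n_nontemplated = nts[j], antisense = anti)
    }
  }
  for (i in seq_len(nrow(sim$decoys))) {
    dc <- sim$decoys[i, ]
    n <- max(rpois(1, config$reads_lambda), config$reads_min)
    for (j in seq_len(n)) {
      if (dc$strand == "+") {
        run_end <- dc$run_start + dc$run_length - 1L
        s <- max(1L, run_end - config$read_length + 1L)
        seq <- substr(gchr, s, run_end)
      } else {
        run_end <- dc$run_start - dc$run_length + 1L
        e <- min(glen, run_end + config$read_length - 1L)
        seq <- revcomp(substr(gchr, run_end, e))
      }
      anti <- runif(1) < config$antisense_fraction
      if (anti) seq <- revcomp(seq)
      ridx <- ridx + 1L
      reads[[ridx]] <- seq
      truth[[ridx]] <- tibble(
        read_id = sprintf("read%05d", ridx), origin = "decoy",
        source_id = dc$decoy_id, chrom = dc$chrom, strand = dc$strand,
        true_position = dc$artifact_site, cleavage = NA_integer_,
        tail_length = 0L, n_nontemplated = 0L, antisense = anti)
    }
  }
  list(reads = tibble(read_id = vapply(truth, function(t) t$read_id,
                                       character(1)),
                      seq = unlist(reads) %||% character(0)),
       truth = if (length(truth)) bind_rows(truth) else
         tibble(read_id = character(), origin = character(),
                source_id = character(), chrom = character(),
                strand = character(), true_position = integer(),
                cleavage = integer(), tail_length = integer(),
                n_nontemplated = integer(), antisense = logical()))
}

#' Write simulated data to standard file formats
#'
#' Writes `genome.fa` (FASTA), `genes.gff3` (GFF3), `truth_sites.bed`
#' (BED6, score = expected support), `decoys.tsv`, and, when reads are
#' supplied, `reads.fasta` or `reads.fastq` (constant qualities) plus
#' `read_truth.tsv`.
#'
#' @param sim A `polya_sim`.
#' @param dir Output directory (created if needed).
#' @param reads Optional result of [simulate_reads()].
#' @param format `"fasta"` or `"fastq"` for the reads file.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_sim <- function(sim, dir, reads = NULL, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             gff = file.path(dir, "genes.gff3"),
             bed = file.path(dir, "truth_sites.bed"),
             decoys = file.path(dir, "decoys.tsv"))
  Biostrings::writeXStringSet(sim$genome, paths[["genome"]])
  gr <- GenomicRanges::GRanges(
    seqnames = sim$features$chrom,
    ranges = IRanges::IRanges(sim$features$start, sim$features$end),
    strand = sim$features$strand)
  gr$type <- sim$features$type
  gr$ID <- if_else(sim$features$type == "gene", sim$features$gene_id,
                   if_else(sim$features$type == "mRNA",
                           sim$features$transcript_id, NA_character_))
  gr$Parent <- if_else(sim$features$type == "gene", NA_character_,
                       if_else(sim$features$type == "mRNA",
                               sim$features$gene_id,
                               sim$features$transcript_id))
  gr$phase <- if_else(sim$features$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, paths[["gff"]], format = "gff3")
  if (nrow(sim$truth_sites)) {
    bed <- GenomicRanges::GRanges(
      seqnames = sim$truth_sites$chrom,
      ranges = IRanges::IRanges(sim$truth_sites$position, width = 1L),
      strand = sim$truth_sites$strand,
      name = sim$truth_sites$site_id,
      score = sim$truth_sites$expected_support)
    rtracklayer::export(bed, paths[["bed"]], format = "bed")
  } else file.create(paths[["bed"]])
  readr::write_tsv(sim$decoys, paths[["decoys"]])
  if (!is.null(reads)) {
    rs <- Biostrings::DNAStringSet(setNames(reads$reads$seq,
                                            reads$reads$read_id))
    if (format == "fasta") {
      paths[["reads"]] <- file.path(dir, "reads.fasta")
      Biostrings::writeXStringSet(rs, paths[["reads"]])
    } else {
      paths[["reads"]] <- file.path(dir, "reads.fastq")
      Biostrings::writeXStringSet(
        rs, paths[["reads"]], format = "fastq",
        qualities = Biostrings::BStringSet(
          vapply(nchar(reads$reads$seq), strrep, character(1), x = "I")))
    }
    paths[["read_truth"]] <- file.path(dir, "read_truth.tsv")
    readr::write_tsv(reads$truth, paths[["read_truth"]])
  }
  invisible(paths)
}
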