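---
title: "Methods: poly(A) site clustering and APA analysis with pacfinder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: poly(A) site clustering and APA analysis with pacfinder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacfinder)
library(dplyr)
```

`pacfinder` reconstructs, as a tested and reusable pipeline, a
genome-wide analysis of mRNA cleavage/polyadenylation in a GC-rich algal
genome: poly(A) tail detection in sequencing reads, cleavage-site calling
and internal-priming filtering, clustering of microheterogeneous sites
into poly(A) site clusters (PACs), genic-region assignment, poly(A)
signal scanning, APA site classification, and the interplay between
intronic polyadenylation and splicing. This vignette documents the model
behind each stage, the tunable parameters with their defaults and units,
the numerical choices, what the synthetic-data generator does and does
not emulate, and the known limitations.

## Tail detection and read orientation

A poly(A) tail is evidence that a read reaches the transcript's 3' end.
Because cDNA can be sequenced from either strand, a tail shows up either
as a trailing A-run (sense) or a leading T-run (antisense);
`orient_reads()` reverse-complements reads whose only qualifying signal
is a T-head. When a read carries both, the A-tail wins: treating such
(usually chimeric) reads as sense avoids counting them twice.

`find_tails()` defines the tail as the *longest terminal window* whose
adenosine fraction is at least `min_purity` and whose length is at least
`min_tail_length`. Two presets mirror the two families of input data:

| mode | `min_tail_length` | `min_purity` | read length (sim) |
|------|-------------------|--------------|-------------------|
| `est` | 10 nt | 1.00 (strict A-run) | 400 nt |
| `ngs` | 15 nt | 0.95 | 50 nt |

The EST preset reads the "valid tail of at least 10 nt" rule
conservatively as a pure A-run, since EST processing defines tails from
trace data; the NGS preset matches the 15-nt/95%-purity rule used for
short-read tail detection. Purity is evaluated over the terminal window,
so a tail may absorb an occasional non-A, and with 95% purity it may
also swallow a trailing body base — the site caller compensates (below).
Both presets cap genomic adenosines absorbed into the tail at 4 nt and
nontemplated additions at 3 nt.

## Mapping and site calling

Synthetic and real 3'-terminal fragments are placed by a deliberately
simple unique-placement mapper (`map_reads()`): the body's 3'-terminal
20-mer is matched exactly against both strands and extended maximally to
the 5' side; a read is kept only if its best-scoring placement is
unique. Full spliced alignment is out of scope — bodies are modelled as
unspliced 3'-terminal fragments, which holds for 3'-UTR-proximal
evidence and for the generator's reads.

A subtlety matters for recovery: when a tail contains an impurity, the
strict EST tail ends at the last non-A, leaving a residual (partial
A-run plus the impurity) on the body. The mapper therefore retries its
seed after clipping terminal bases, counting **only clipped non-A
bases** against the 3-nt nontemplated cap: clipped adenosines adjacent
to the detected tail are tail material by the same logic that reassigns
templated A's at the aligned end. Clipping is capped at `max_clip`
(default 100 nt, effectively bounded by the non-A budget).

`call_sites()` then applies the "−1 position" convention: the site is
the last genome-templated base. Up to `max_genomic_a = 4` trailing
aligned adenosines (transcript sense) are pushed into the tail — a
templated A directly upstream of a poly(A) tail is indistinguishable
from it — and reads with more are rejected, as are reads whose aligned
3' end sits at the contig edge (reason codes are kept in the output).

`flag_internal_priming()` removes oligo(dT) artifacts: a site is dropped
when the sense-strand −10..+10 genomic window (21 nt, clamped and
flagged at contig edges) contains a run of ≥ `run_threshold = 6`
consecutive adenosines *or* ≥ `count_threshold = 7` A's in any fully
contained 10-nt subwindow. The published rule ("6–7 consecutive
adenines from 10 nt-window") is ambiguous between these two readings, so
both are applied disjunctively and both thresholds are exposed.

## PAC clustering

Cleavage is sloppy: reads from one biological site scatter over a few
nucleotides. After keeping unique sites with ≥ `min_support = 3` reads,
`cluster_pacs()` merges adjacent sites per chromosome and strand under
Ward's minimum-variance objective, each site weighted by its read
support. The published method names Ward clustering but not the cut
rule; we define the clustering as the contiguous partition with the
**fewest clusters subject to a maximum genomic span per cluster**
(`max_span = 24` nt) and, among those, the **minimum support-weighted
within-cluster sum of squares**. In one dimension this optimum is
computed exactly by dynamic programming over contiguous partitions
(greedy agglomeration can be suboptimal), after pre-splitting at gaps no
cluster could bridge; tests verify equivalence against exhaustive
enumeration of all contiguous partitions for up to six sites. The 24-nt
span cap is a package parameter chosen on the scale of observed
microheterogeneity, not a literature constant; a gap-based
single-linkage alternative is available via `method = "gap"` for
comparison. Each PAC is represented by its highest-support member, ties
broken toward the most 3' position in transcript sense.

`pac_flanks()` extracts the 150-nt flank: labels −100..−1 (site at −1)
then +1..+50, sense strand, reverse-complemented on the minus strand,
N-padded and flagged at contig edges. On the plus strand a site at
position *p* yields genomic bases *p*−99..*p*+50; on the minus strand
the exact mirror, *p*−50..*p*+99 reverse-complemented, so the site base
sits at label −1 on both strands.

## Genic regions

`read_gene_models()`/`as_gene_models()` build a feature table from GFF3
(introns derived as exon gaps). `extend_utr3()` grows each 3'-UTR
`utr3_extension = 50` nt downstream in transcript sense — incomplete
3'-end annotation otherwise misclassifies genuine 3'-UTR sites as
intergenic — truncated at the next same-strand gene start and the contig
edge. `assign_regions()` uses strand-matched containment with precedence
**UTR3 (extended) > CDS > UTR5 > intron**; among genes tied at the same
precedence the gene with the nearest annotated 3' end wins. The
precedence choice (an extended UTR3 beats another gene's intron) follows
the motivation for the extension: rescuing misannotated 3' ends.
Antisense containment does not count; such sites are intergenic, with
the signed distance to the nearest same-strand annotated 3' end
reported, which also feeds `distance_profile()`.

## Signal scanning and significance

`scan_kmers()` performs an exhaustive fixed-length motif census (default
pentamers) within a labelled window — NUE −28..−5, FUE −100..−28 — in
three modes:

* **overlapping** — every match start counts;
* **distribution** — greedy left-to-right with a spacing rule: a match
  at start *s* counts only if *s* ≥ previous counted start + *k* + `gap`.
  With `gap = 2`, the 8-mer ATATATAT counts once for ATATAT and once for
  TATATA; `gap = 0` means adjacent non-overlapping counting. The
  overlapping census is kept as a separate mode rather than `gap = 0`
  because the two are distinct counting semantics;
* **frequency** — at most one count per sequence: the occurrence closest
  to the site (label −1), ties to the more 3' occurrence.

Counts divide by the number of scanned sequences, so overlapping-mode
"frequencies" can exceed 1; windows containing N are excluded from both
counts and the scanned-position total. Motifs are reported in the RNA
alphabet. `nucleotide_profile()` and `motif_pssm()` provide the
single-nucleotide profile and the positional distribution of counted
occurrences.

Significance uses an order-*m* Markov background (`train_markov()`,
default *m* = 3) estimated from the scanned sequences themselves with
add-one smoothing, so every motif probability is strictly inside (0, 1);
an external background can be supplied instead. The Z-score is the
binomial-approximation standardisation
Z = (obs − n·p)/√(n·p·(1−p)) with *n* the total number of scanned
windows — a deliberate simplification of the exact occurrence-count
variance; expected counts match the Markov expectation. Z-scores are
calibrated for overlapping-mode counts (tests verify a mean Z within
±0.1 of zero over all 1024 pentamers on 10,000 uniform sequences) and
are reported alongside the other modes as a ranking heuristic.
Backgrounds warn when fewer (m+1)-grams than alphabet combinations are
available.

## APA classification and splicing interplay

Genic PACs (any non-intergenic label) are grouped per gene. Single-PAC
genes carry a *constitutive* site. In multi-PAC genes, a PAC with at
least `strong_fraction = 0.75` (inclusive) of the gene's supporting
reads is *strong* and its siblings *weak*; without a strong site all are
*median*. `apa_extent()` is the percentage of PAC-bearing genes with ≥2
PACs — the denominator is PAC-bearing genes, not all annotated genes,
the reading consistent with dataset-specific extents; gene percentages
in `pac_category_table()` appear only when an annotated-gene denominator
is supplied. `extent_size_correlation()` is a plain Pearson correlation
with the t-based two-sided p (n − 2 df).

`intron_pac_table()` crosses intronic PACs with intron classes supplied
as input (constitutive/retained × coding/noncoding — isoform deduction
is explicitly out of scope). An intron "contains" a PAC when the
representative site lies within it (inclusive interval; `by = "span"`
switches to span overlap), and multi-PAC introns count once (PAC-level
hits are reported alongside). Class means average the cell percentages
across the other classification. Length comparisons draw `n_groups = 3`
control groups of PAC-free features without replacement
(`sample_controls()`, seedable) and test shifts with a hand-rolled
two-sided Wilcoxon rank-sum (`rank_sum_test()`): exact enumeration of
the midrank-sum distribution when both groups have ≤ 8 observations
(two-sided p = probability of a rank sum at least as far from its mean
as observed), otherwise the normal approximation with tie and continuity
corrections. `stats::wilcox.test` serves as an independent cross-check
in the test suite, never as the implementation.

## The synthetic-data generator

`simulate_genome()`/`simulate_reads()` emulate the statistical structure
the analysis assumes. Standing study conditions (the `sim_config()`
defaults): one 100-kb contig at GC fraction 0.6345 (the *C.
reinhardtii*-like bias); 20 genes of fixed architecture — 5'UTR
(150–250 nt), alternating CDS exons (200–400 nt) and introns
(100–250 nt; 1–3 per gene), 3'UTR (220–320 nt) — on random strands with
300–800-nt intergenic spacers; every gene gets one true site in its
3'UTR (15% just downstream of the annotated end, inside the 50-nt
extension zone), and 30% of genes get 2–3 sites total, extra sites
falling in the 3'UTR, a CDS exon, or an intron (≥60 nt apart, beyond
twice the cluster span cap); UGUAA is planted at labels −22..−18 of
every site; reads per site are Poisson(15) floored at 5;
microheterogeneity is a discretised normal with SD 1 nt truncated to the
transcribed span; tails are N(45, 10) clipped to 12–120 nt (EST) or
uniform 16–25 nt (NGS) with 1% per-base impurity; 0–3 nontemplated
C/G/T bases occur with probabilities (0.7, 0.15, 0.1, 0.05); 20% of
reads are emitted antisense (poly(T) heads); and eight 6–12-nt A-runs
are planted in CDS/introns as internal-priming decoys whose reads end at
the run with no synthetic tail. Values the source material does not
state — tail-length laws, read-count law, gene-geometry ranges, the
antisense and decoy rates — are the package's own choices of realistic
desk-scale conditions, fixed once.

What the generator does *not* emulate bounds what passing tests show
about real data: no sequencing errors outside the tail, no paralogs or
repeats (so unique mapping is nearly always achievable), no spliced read
bodies, no expression model beyond the read-count law, constant FASTQ
qualities. Real libraries will lose more reads at mapping and carry
repeat-driven multi-mapping ambiguity that the uniqueness rule simply
discards.

End-to-end behaviour under these conditions, asserted in the test suite
on three fixed seeds: ≥95% (in practice 96–100%) of planted sites are
recovered as PACs whose representative lies within 5 nt of truth, no
planted decoy survives the internal-priming filter, the regional
distribution of recovered PACs matches the planted ground truth exactly,
and planted UGUAA tops the frequency-mode NUE ranking.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive in the tabular API; BED exports are
  0-based half-open. There is no position 0 in flank labels.
* Clustering ties (equal WSS) resolve to the first optimum found by the
  DP scan; representative ties resolve 3'-most in sense.
* `aggregate_sites()` on empty input returns an empty table; empty PAC
  sets flow through clustering, flank extraction and assignment as empty
  tibbles; `region_distribution()` and `classify_pac_sites()` error on
  empty input rather than returning 0/0 percentages.
* Site calls at contig edges are rejected with a distinct reason;
  internal-priming windows at edges are clamped, evaluated on the
  available bases, and flagged.
* Problem sizes in the shipped tests and acceptance script (100-kb
  genome, ~20 genes, ~500 reads, 10,000 null sequences for Z
  calibration) were chosen as the smallest scales at which the
  statistical assertions are stable.

## Known limitations

* The mapper requires a unique exact seed: repetitive genomes and
  spliced 3' fragments need an external aligner (alignments can be
  ingested as tabular coordinates in place of `map_reads()`).
* Z-scores use the binomial variance approximation, not the exact
  occurrence-count distribution; for distribution/frequency-mode counts
  they are ranking heuristics.
* Intron splice classes are trusted inputs; no isoform inference.
* Gene-level percentages require an external annotated-gene count.
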