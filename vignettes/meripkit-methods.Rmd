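---
title: "Models and methods in meripkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in meripkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

meripkit analyses MeRIP-seq experiments: an anti-m6A antibody enriches
methylated RNA fragments into an IP library that is compared against a
non-enriched Input library from the same sample. This vignette explains
the statistical model behind each stage, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the design decisions taken where the method left room.

## Peak calling

The genome is tiled with non-overlapping windows of `window = 20` bp
anchored at coordinate 0. A read increments every window it overlaps by
at least one base, so neighbouring window counts are positively
correlated whenever reads are longer than a window — peaks therefore
appear as runs of significant windows rather than isolated hits.

Each covered window is tested with a one-sided Fisher exact test on the
2×2 table

|           | in window | rest of library |
|-----------|-----------|-----------------|
| IP        | a         | N_IP − a        |
| Input     | c         | N_In − c        |

i.e. against the *library totals*, not a local background. Under the
null of equal per-base rates the window IP count follows the
hypergeometric distribution conditioned on the margins, and the p-value
is the exact upper tail P(X ≥ a), computed with `stats::phyper`. Only
the IP-greater direction is of interest because only IP excess indicates
antibody enrichment.

Parameters and defaults:

* `alpha = 0.05` on the raw p-value. No multiple-testing correction is
  applied by default — the method is deliberately liberal at the window
  level and relies on merging; Benjamini–Hochberg is available via
  `p_adjust = "BH"`.
* `min_cov = 10` combined reads: with fewer than ~10 reads a window
  cannot reach p < 0.05 in this design, so testing below that floor
  only adds noise. Configurable.
* `max_gap = 0`: strictly adjacent significant windows merge into one
  peak; the peak p-value is the minimum member p (no peak-level model is
  defined — the minimum is reported alongside the summed counts), and
  peak enrichment is the pseudocounted reads-per-library ratio.
* `min_windows = 1`: no minimum run length, matching the merging rule as
  stated; a floor of 2–3 windows is available and markedly reduces
  isolated false windows on real data.
* Counting is strand-aware by default (stranded libraries);
  `stranded = FALSE` collapses strands.

Because the IP library carries the enrichment mass of all true peaks,
its total N_IP exceeds the Input total at equal background rates. This
makes the test conservative at background windows (their IP *proportion*
is below their Input proportion), which is why the realized
false-discovery proportion in simulations sits well below what a uniform
5% window-level error rate would suggest.

## Differential and condition-specific peaks

Peaks called independently in the two conditions are matched by ≥ 1 bp
same-strand overlap, merging transitively into union intervals. A union
interval covered by only one condition's peaks is *condition-specific*.
Matched intervals are tested two-sided on

|        | in interval | rest of IP library |
|--------|-------------|--------------------|
| coarse | a           | N_IP,coarse − a    |
| fine   | c           | N_IP,fine − c      |

(`mode = "ip_vs_total"`). The Input libraries enter through the effect
estimate, not the test: the reported `log2_methylation_ratio` is the log2
ratio of reads-per-million-normalized (IP/Input) ratios with a
pseudocount of 0.5, so expression differences cancel in the ratio while
the IP-only test remains sensitive to them — a deliberate property of
this construction, and the reason differential-methylation calls
correlate with differential expression. An alternative four-way table of
IP and Input counts (`mode = "ip_vs_input"`) is provided for users who
want the test itself conditioned on expression. Classes: `up` / `down`
at p < alpha by ratio sign, `ns` otherwise; specific intervals keep
their condition label and inherit their originating peak's p-value.
Gene-level summaries count each gene once by its most significant peak,
with exact up/down ties resolved to `up`.

The label set is exactly symmetric: swapping the condition labels swaps
up with down and coarse-specific with fine-specific (verified as a test
invariant).

## UMI consensus deduplication

Reads sharing a UMI are one PCR family. Within a family, reads are
greedily sub-clustered: the most abundant sequence (ties broken
lexicographically) seeds a sub-cluster, and members join if their global
alignment identity to the seed *exceeds* 0.95 — the boundary value 0.95
itself is excluded, reading "identity over 95%" strictly. Alignment is
end-to-end with match +1, mismatch −1, gap −2 (Biostrings); identity is
matches over alignment columns. The published description does not state
whether identity is computed against a seed or all-versus-all; the
greedy seed was chosen for determinism and linear cost, and is
documented as an interpretation.

The consensus is a star alignment: each member is pairwise-aligned to
the seed and projected onto seed coordinates (member insertions are
dropped — a documented simplification of full multiple alignment that is
exact for the gapless near-identical duplicates this step sees). Columns
are resolved by majority vote; ties break by summed base quality, then
prefer a base over a deletion, then alphabetically. Consensus quality is
the per-column maximum.

Consequences worth knowing: with substitution errors at rate *e* per
base and read length *L*, a member carrying more than `(1 − 0.95) · L`
errors (plus any seed errors) necessarily fails the strict threshold and
splits into its own singleton sub-cluster. At *e* = 1% and *L* = 100
this affects on the order of 1% of reads, so the consensus count
slightly exceeds the true molecule count unless *e* = 0, where recovery
is exact. Consensus sequences built from ≥ 5 duplicates are essentially
always the true template (per-column majority error ≈ C(5,3)e³).

## The synthetic-data generator

`simulation_config()` defines the study conditions; its defaults are the
conditions under which the package's statistical claims are tested:

* 100 genes of 1.2–3 kb mRNA on one chromosome, 10% non-coding
  (NP_exon), single-exon by default (multi-exon supported), random
  strand, intergenic gaps of 300 bp. Coding mRNAs split 15% 5'UTR /
  60% CDS / 25% 3'UTR.
* True peaks on 50% of genes, 150 bp wide, placed immediately 3' of the
  stop codon with probability `stop_codon_bias = 0.8` (m6A concentrates
  near stop codons) and uniformly along the transcript otherwise; the
  GGACT motif is written into the genome at each peak centre in
  transcript orientation.
* `peak_enrichment = 8` and `depth_per_library = 200000`:
  the Input library draws exactly `depth_per_library` molecules
  multinomially over genes (weights = expression × length, expression
  log-normal with sdlog 0.5); the IP library has the *same per-base
  background rate* plus an 8-fold rate for fragments overlapping a true
  peak, so its total exceeds the Input total by the planted enrichment
  mass and the expected within-peak IP:Input count ratio equals the
  configured enrichment exactly. Normalizing the IP total back to the
  Input depth would shrink that ratio by the mean enrichment factor,
  which is why it is not done.
* 20% of true peaks are condition-specific (half coarse-only, half
  fine-only) — a field the method comparison needs that the generator
  therefore provides.
* 20% of genes differentially expressed at fold 4 (half up, half down
  in coarse).
* Each molecule carries an error-free 8-bp UMI; PCR copies
  (1 + Poisson(`pcr_duplication_rate`)) share the UMI and receive
  independent substitution errors at `seq_error_rate` (default 0.001,
  i.e. ~Q30) on the fragment. Reads are 100 bp, matching the fragment
  scale of the protocol; fragments are placed within single exons so
  aligned records need no split-read handling.

The generator emits both already-placed aligned records (one per
molecule — read alignment itself is an external, solved step) and
FASTQ-style sequenced copies to exercise deduplication. Everything is
driven by one seed: fixed seed, byte-identical outputs.

What it does **not** emulate: transcript isoforms, indel errors,
coverage biases (GC, position), quality-score variation, biological
replicates, and UMI errors. Passing tests therefore demonstrate the
correctness and calibration of the computation under idealised sampling,
not robustness to those real-data artefacts.

## Annotation, metagene, motifs

Region classification assigns an interval to the feature class with
maximal base overlap; ties follow the fixed priority CDS > 3'UTR >
5'UTR > NP_exon > intron > intergenic (no priority is canonical; CDS
first reflects that coding overlap is the most specific claim).
NP_exon is any exon of a transcript with no CDS. Coordinates are 0-based
half-open internally; GTF is converted on ingest, BED written natively.
Peak-to-gene assignment takes the gene with maximal overlap, ties
alphabetical.

Metagene profiles bin a ±`flank` window around the TSS or the stop codon
(first base of the 3'UTR) into equal bins laid out in transcript
orientation, so bin 1 is always the most 5' bin; windows clipped by a
sequence edge keep zeros and are flagged.

Motif enrichment counts k-mer *presence per sequence* (not occurrences)
in peak sequences versus a background, scored with the same one-sided
Fisher machinery and BH-corrected across the 4^k tests; k defaults to 5,
the RRACH width. The default background is an Altschul–Erickson
dinucleotide-preserving shuffle of the target sequences (seeded), which
controls for composition; user-supplied backgrounds are accepted. RRACH
scanning uses IUPAC matching on the oriented sequence only.

## Expression, overlaps, qPCR

RPKM is `C · 10^9 / (N · L)` with N the Input library size and L the
summed exon length; gene counts use Input libraries only (the Input
plays the RNA-seq role). Fold change is coarse/fine on pseudocounted
(+0.5) RPKM; classes use strict thresholds (fold > 2 up, < 0.5 down,
boundaries not significant). The mapping summary reproduces
standard report arithmetic: mapped% of total reads, unique% and
non-unique% of *mapped* reads — the denominator was inferred by
reproducing all published table cells exactly — rounded to two decimals.
Overlap analysis reports the pairwise and triple intersections of
up-/specific-methylated gene sets with up-/down-expressed sets. The
over-representation test is the one-sided hypergeometric tail with BH
correction over user-supplied categories; no live database is consulted.

qPCR relative quantities follow 2^−ΔΔCt with the reference gene ΔCt and
a calibrator group (the fine group's mean ΔCt by default, fine being the
reference phenotype). The published description names no significance
test; Welch's t on replicate ΔCt values was chosen as the standard
companion to this design.

## Numerical choices and problem sizes

Fisher p-values are exact hypergeometric tails (`phyper`), verified in
the test suite against direct `lchoose` enumeration to 1e-10 over a
systematic grid of ~1.7e4 tables with margins up to 200. Pseudocounts
are 0.5 throughout ratio computations. All randomness flows through
explicit seeds (`withr::with_seed`), leaving the caller's RNG state
untouched; derived seeds stay below 2^31.

The test and acceptance runs use the default study conditions (200k
reads/library, 100 genes, 10 seeds) for peak recovery and type-I
control, and smaller libraries (≈800–2,500 molecules) for the
alignment-heavy deduplication checks and the pipeline orchestration
tests — sizes chosen so the full suite completes in minutes while
keeping every statistical check at its stated conditions.

## Known limitations

* No replicate-aware dispersion modelling: one pooled library per
  condition, as in the motivating design.
* Peak boundaries are window-quantised; no sub-window refinement.
* The IP-versus-total differential test confounds methylation with
  expression by construction (see above); use the ratio, or the
  four-way mode, when that matters.
* UMI error correction across distinct UMI strings (directional
  networks) is out of scope; colliding UMIs merge families and are
  resolved only by the identity sub-clustering.
* The consensus star alignment drops member insertions relative to the
  seed.
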