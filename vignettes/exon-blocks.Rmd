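---
title: "Methods: coordinated exon blocks and cotranscriptional splicing statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coordinated exon blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

The exon junction complex (EJC) is deposited roughly 24 nt upstream of each
exon–exon junction as splicing proceeds. If that deposition helps the
spliceosome recognize the *next* exon as the pre-mRNA is synthesized, then
depleting an EJC core factor should not merely shift isolated alternative
exons — it should cause *groups of neighboring exons* to drop out together,
as one unit bounded by the junction between their flanking exons. This
package implements the downstream analysis that turns exon-level
differential inclusion tables and spliced alignments into evidence for or
against that picture: block calling, single-molecule validation,
intron-efficiency and intron-order statistics, splice-site strength
comparisons, and cohort-level enrichment tests.

# The exon ladder

All stages share one data model (`build_gene_model()`): per gene, the exons
of all annotated transcripts are collapsed by exact coordinates into a
single ladder ordered transcriptionally (index 1 is the 5′-most exon on the
gene's strand). "Adjacent" always means consecutive ladder indices, and
"upstream/downstream" are transcriptional, also on the minus strand.
Design choices here were genuinely open:

* **Overlapping-but-unequal exon variants** are kept as separate ladder
  entries rather than merged into one node. The alternative (merging) would
  let a block span two variants of the same genomic region, which we judged
  uninterpretable; the cost is that no intron is defined between overlapping
  variants (those ladder positions carry `NA` introns and are skipped by the
  intron-level statistics).
* **Constitutive** means present, with exactly matching coordinates, in
  every annotated transcript of the gene — a deliberately strict,
  annotation-only definition that is monotone under removing transcripts.

Coordinates are 0-based half-open internally; GTF is read/written 1-based
inclusive, SJ junction tables 1-based first/last intronic base, BED 0-based
half-open — each format exactly per its standard.

# Block calling

Significant exons satisfy `probability >= 0.9` and `|dPSI| >= 0.10`, both
inclusive, with dPSI the replicate-mean difference treatment − control. A
**block** is a maximal run of consecutive significant ladder exons in which
every neighboring pair (i) shares the dPSI sign and (ii) differs in dPSI by
at most `pair_tolerance = 0.02`.

Two rules were open to interpretation:

* **Chain-wise vs all-pairs tolerance.** We apply the 0.02 bound to each
  consecutive pair (the literal reading of "an adjacent exon with a dPSI
  difference of maximal 0.02"); a long block may therefore drift more than
  0.02 end to end. The all-pairs variant is available
  (`call_blocks(all_pairs = TRUE)`).
* **Shared sign.** Mixed-direction runs are not blocks by default, since the
  phenomenon under study is coordinated skipping; `same_sign = FALSE`
  disables the requirement. In practice the choice is nearly moot because
  the large majority of significant exons move in the skipping direction.

With the chain-wise rule, window validity is equivalent to validity of all
consecutive pairs, so maximal runs are unique and disjoint; the test suite
checks the caller against an independent brute-force enumeration on random
tables, and checks that shrinking the tolerance only ever refines the block
set.

The **block-skipping junction** of a block is the genomic interval from the
3′ end of the nearest non-block exon upstream to the 5′ start of the nearest
one downstream — the gap a spliceosome would excise when joining the flanks
directly. Blocks touching the first or last ladder exon have no junction and
are excluded from read-level validation. A block is **frame-preserving**
when its summed member lengths are divisible by three.

# Read-level validation

`reconstruct_geometry()` rebuilds reference-space geometry from POS and
CIGAR: M/=/X consume reference and read; D and N consume reference only and
are treated alike as gaps (long-read aligners emit either for a skipped
block); I/S consume read only; H/P neither. Adjacent gap operations merge,
and merged gaps shorter than `min_gap = 20` nt are reclassified as
aligned-internal — indels, not splice gaps. The 20 nt default sits safely
below the smallest human introns (≈ 30 nt) while absorbing sequencing
indels. Degenerate leading/trailing gaps are folded into the aligned span so
blocks and gaps always alternate and tile the alignment exactly (a
fuzz-tested invariant).

A read votes **SKIP** for a block when one of its gaps matches the skip
junction within `tolerance_nt = 8` at both ends (long-read alignment wobble;
configurable), **INCLUSION** when it has aligned sequence on at least one
member exon *and* on both flanking exons, and is otherwise uninformative and
excluded from the denominator — a read that does not span the locus cannot
vote. Short-read junction tables are matched exactly (splice-aware aligners
report precise junctions). Junction counts normalize to RPM =
count × 10⁶ / mapped reads; a junction is "detected" at ≥ 1 read
(`min_reads` configurable) in at least one sample of a condition.

# Splicing efficiency and order

**SPI** (splicing per intron) is spliced / (spliced + unspliced), where
spliced reads carry a gap exactly matching the intron and unspliced reads
cross an exon–intron boundary contiguously with ≥ 3 nt on both sides. The
formula and filters are this package's own specification of the
per-intron-efficiency idea (the overhang requirement suppresses
boundary-ambiguous alignments); SPI is reported only at
spliced + unspliced ≥ `min_cov = 10`.

**Differential SPI** pools replicate counts per condition into a 2×2 table;
p comes from a chi-square with continuity correction, or Fisher's exact test
when any cell is below 5, and significance needs p ≤ 0.01 *and*
|ΔSPI| ≥ 0.10 on the replicate means. The threshold is applied to raw
p-values by default (Benjamini–Hochberg available as a flag), because the
procedure it mirrors applies a raw cutoff; a replicate-level test is not the
default since per-replicate SPI values at moderate coverage are too coarse.

Introns are categorized relative to blocks — `block_internal` (between
members), `block_flanking` (immediately up/downstream of a block), `other` —
with internal taking precedence when one intron is internal to one block and
flanking another, so every intron gets exactly one label.

**F_UPFI** (fraction of upstream intron spliced first) for an exon uses
reads spanning both flanking introns with unambiguous status for each: n_up
counts reads with the upstream intron spliced and the downstream one not,
n_down the reverse, F_UPFI = n_up / (n_up + n_down), reported at ≥ 5
informative reads. Both-spliced and both-unspliced reads carry no order
information. Under the model, first block exons should show F_UPFI ≈ 0 (the
block-internal intron is removed before the upstream flanking intron) and
last block exons F_UPFI ≈ 1.

# Splice-site strength

Donor sites are 9-mers (last 3 exonic + first 6 intronic nt), acceptors
23-mers (last 20 intronic + 3 exonic), reverse-complemented on minus strands
so motifs read 5′→3′. When a directory with the canonical MaxEnt table files
(`me2x5`, `me2x3acc1..9`) is supplied, `load_maxent_tables()` reproduces the
reference two-level lookup exactly (verified in tests against direct table
arithmetic on synthetic tables in the same file format). Those tables are
third-party data and are not shipped; the default is a log-odds PWM trained
on the annotation's own splice sites (pseudocount 1, uniform background).

The recursive-donor scan asks whether the junction formed after
upstream-intron splicing (upstream exon's last 3 nt + candidate exon's first
6 nt) reconstitutes a donor able to re-splice the exon away. In MaxEnt units
the conventional cutoff is 5.52, the score that captures 90% of human
canonical 5′ splice sites — i.e. the 10th percentile of true-site scores.
PWM scores live on a different scale, so with the PWM fallback the scan
instead uses the 10th percentile of the model's training donor scores, and
labels the threshold kind explicitly rather than silently reusing 5.52.

The EJC footprint window is the 10 nt centered on the position 24 nt
upstream of an exon's 3′ end (transcript coordinates; for a 100 nt exon,
positions 71–80); exons shorter than offset + window/2 yield no window.
Category comparisons (site scores, exon/intron/gene lengths) use two-sided
Mann–Whitney tests against the reference category, uncorrected by default
with a BH option, reporting medians alongside p-values.

# Cohort statistics

The permutation test drops the observed number of significant events
uniformly at random **with replacement** onto the quantified genes
(multinomial placement — the without-replacement variant would need an
arbitrary per-gene capacity) and counts genes with ≥ k = 2 events; the
one-sided p uses the add-one estimator (1 + #{null ≥ obs}) / (1 + n_perm),
which never returns 0. A per-gene weight vector (e.g. quantified exon
counts) is accepted, since long genes can host more events.

Paired-ΔPSI correlation contributes each unordered within-gene pair once,
lower ladder index first; the random-pairing control redraws pairs from the
pooled significant exons ignoring genes, under an explicit seed.

Relative RBP block enrichment divides each knockdown's fraction of regulated
events that are blocks by the median fraction over qualifying RBPs (≥ 1
block event; zero-block RBPs are excluded from the median and flagged rather
than scored). With an odd number of qualifying RBPs the median RBP maps to
exactly 1.0; with an even number the midpoint convention means the two
central RBPs straddle 1.0 without touching it. The statistic is invariant
under rescaling all counts.

# The synthetic-data generator

`sim_config()` defines the study the tests and the acceptance script run.
Defaults, with rationale:

| parameter | default | why |
|---|---|---|
| genes / blocks | 20 / 8, one block per gene | smallest cohort where every statistic has n ≥ 8 |
| exons per gene | 6–10 | room for a block plus flanks plus background |
| exon length | 80–200 nt | typical internal-exon scale; always ≥ read anchors |
| intron length: internal / other / flanking | 80–160 / 150–400 / 800–2000 nt | plants the short-internal, long-flanking architecture the analysis should detect |
| block size | 2–3, weighted 75/25 | two-exon blocks dominate cohort-scale calls |
| block effect | −0.198 mean, between-gene sd 0.05 (magnitude clamped ≥ 0.12), within-block spread ≤ 0.016 | a clearly significant skipping effect whose gene-to-gene variation makes the paired-correlation statistic informative; the spread bound keeps planted blocks coordinated by construction (below the 0.02 tolerance) |
| member / replicate noise sd | 0.005 / 0.003 | small but non-zero, so recovery is exercised, not assumed |
| site consensus fraction: internal / other / flanking | 0.95 / 0.85 / 0.55 | weak flanking, strong internal sites |
| SPI truth: internal / other / flanking | 0.9 / 0.7 / 0.35 | efficient internal, inefficient flanking splicing |
| long reads | 200 per gene per condition, skip fraction 0 (ctrl) / 0.5 (treat) | binomial error ≈ 3.5% at n = 200 |
| nascent reads | 100 per intron, 60 order reads per exon | SPI binomial error ≈ 5% at the planted efficiencies |

Reads are emitted pre-aligned as SAM text with exact M/N geometry and no
sequencing errors (alignment is out of scope); a `wobble` knob jitters gap
ends by up to ±n nt purely to stress the tolerance logic. Replicate PSI
noise is truncated Gaussian — the empirical noise structure of real PSI
estimates is unknown and not modelled. Intron order is derived from intron
classes (internal-before-flanking, giving first/last block exons order
probabilities 0/1) with a default of 0.5 elsewhere, overridable per exon.

What the generator does **not** emulate — and hence what green tests do not
demonstrate about real data: overlapping gene loci, alternative first/last
exons, soft-clipped or error-containing alignments, multi-mapping reads,
coverage heterogeneity along genes, NMD feedback on isoform abundance, and
any sequence determinants beyond splice-site motifs. Order-informative reads
also carry per-intron splicing status, so on the full simulation SPI is a
mixture of efficiency and order information; SPI calibration therefore uses
simulations with order reads disabled.

# Numerical conventions and degenerate inputs

Thresholds are inclusive (≥ / ≤) everywhere they are stated that way above;
the recursive-scan threshold is strict (score > threshold). Empty inputs
return empty summaries rather than errors where a cohort can legitimately be
empty (no blocks, empty histogram category); contract violations (terminal
block without junction, first-exon F_UPFI, mixed strands in one gene) are
errors. Duplicate SJ junction lines are summed with a warning. Percent vs
fraction scaling of dPSI inputs is fixed per table dialect, never guessed
from magnitudes. All stochastic operations take explicit seeds and restore
the caller's RNG state where they are library calls rather than generators.

# Problem sizes used by the test suite

The packaged checks run, per suite execution: 500 random genes (≤ 30 exons)
against the brute-force block oracle; 10,000 random CIGARs for geometry
conservation; 200 long reads per block at skip fractions {0, 0.25, 0.5}
with ±3 nt jitter; 50 introns × 100 reads at efficiencies {0.1, 0.5, 0.9};
500 order-informative reads per exon for F_UPFI; 1000 null datasets × 200
permutations for p-value calibration; 10,000 random pairs and 5,000 coupled
pairs for the correlation controls; and 80 genes (≥ 100 sites per category)
for splice-site separation. These sizes were chosen so each statistic's
sampling error is several-fold smaller than the effect it must resolve.

# Known limitations

* Block calling consumes an exon-level differential table; it cannot rescue
  exons the upstream quantifier missed, and ladder indices must match
  between table and annotation.
* The chain-wise rule can, in principle, chain slow dPSI gradients into one
  block; use `all_pairs = TRUE` where that matters.
* The PWM fallback is annotation-dependent: scores and the percentile
  threshold are not comparable across annotations, and are not on the
  MaxEnt scale.
* `differential_spi` pools replicates, so between-replicate overdispersion
  is not propagated into the p-value.
* The long-read denominator counts only locus-spanning reads; strong 3′
  coverage bias would need the uninformative class to be stratified, which
  is not implemented.
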