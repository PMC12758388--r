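# exonblocks

Detection and characterization of **coordinated exon blocks** — runs of two
or more adjacent exons whose inclusion changes together when a trans-acting
splicing factor (prototypically the exon junction complex core component
EIF4A3) is depleted — together with the read-level and cohort-level
statistics needed to validate them.

## Who this is for

Computational RNA biologists with exon-level differential splicing output
(Whippet-style PSI tables), spliced short/long-read alignments and a
GTF/FASTA annotation, who want to ask: do significant exons change alone, or
in coordinated neighboring groups? Are whole blocks excised as one unit in
single transcripts? Are the surrounding introns spliced late and bounded by
weak splice sites, as an exon-definition model predicts?

## What it computes

Let PSI be the percent-spliced-in of an exon and
ΔPSI = PSI(treatment) − PSI(control), averaged over replicates. The pipeline:

1. **Significant exons** — probability ≥ 0.9 and |ΔPSI| ≥ 0.10 (both
   boundaries inclusive).
2. **Blocks** — maximal runs of consecutive ladder exons (on the collapsed,
   strand-aware exon ladder of each gene) in which every neighboring pair
   shares the ΔPSI sign and satisfies |ΔPSI_i − ΔPSI_{i+1}| ≤ 0.02.
   Runs of length one are "single regulated" exons. Each block gets its
   **block-skipping junction**: the genomic gap from the upstream flanking
   exon's 3′ end to the downstream flanking exon's 5′ start.
3. **Read-level validation** — reference-space geometry is rebuilt from each
   alignment's CIGAR (M/=/X aligned; N/D gaps, merged, with gaps < 20 nt
   treated as indels); a long read is a SKIP read when a gap matches the
   skip junction within ±8 nt, an INCLUSION read when it covers a member
   exon and both flanks. Junction counts are RPM-normalized
   (count × 10⁶ / mapped reads).
4. **Splicing efficiency and order** — per intron,
   SPI = spliced / (spliced + unspliced) reads (exact-gap vs
   boundary-crossing with ≥ 3 nt overhang); differential SPI uses a pooled
   2×2 chi-square (Fisher when any cell < 5) with significance at p ≤ 0.01
   and |ΔSPI| ≥ 0.10. Per exon, F_UPFI is the fraction of order-informative
   reads with the upstream flanking intron removed first.
5. **Splice-site strength** — canonical MaxEnt table scoring (9-mer donors,
   23-mer acceptors) when table files are supplied, otherwise a log-odds PWM
   trained on the annotation's own sites; recursive 5′-donor scan at the
   exon's upstream junction; EJC footprint window (10 nt centered 24 nt
   upstream of the exon 3′ end); Mann–Whitney comparisons across exon/intron
   categories.
6. **Cohort statistics** — multinomial permutation test for multi-event
   genes, within-gene paired-ΔPSI correlation with a random-pairing control,
   and per-RBP relative block-event enrichment (fraction of regulated events
   that are blocks, divided by the cohort median).

A synthetic-data generator (`sim_config()`, `generate_annotation()`,
`generate_diff_table()`, `simulate_long_reads()`, `simulate_nascent_reads()`)
plants all of this structure with a complete truth manifest, so the entire
pipeline is testable end to end without external data.

## Worked example

The numbered scripts under `analysis/` run the whole study on the reference
simulation (20 genes, 8 planted blocks):

```sh
Rscript analysis/01_simulate.R          # writes results/sim/*
Rscript analysis/02_call_blocks.R
Rscript analysis/03_longread_skipping.R
Rscript analysis/04_splicing_metrics.R
Rscript analysis/05_splice_sites.R
Rscript analysis/06_cohort_stats.R
```

Stage 2 prints, for the default seed:

```
22 of 157 exons significant; 91 % more skipped.
10 similarly affected within-gene pairs; 90 % adjacent.
8 blocks over 8 genes ( 17 member exons ); 87.5 % two-exon blocks; mean |dPSI| 21.4 %; 12.5 % frame-preserving.
Constitutive fraction: block members 100 % vs singles 80 %.
Recovery vs planted truth: recall 1 , precision 1
```

i.e. all 8 planted blocks are recovered exactly, most significant exons are
skipped upon "depletion", similarly affected exon pairs are overwhelmingly
adjacent, and block members are constitutive — the signature the method is
built to detect. Stage 3 then finds ~49% block-skipping long reads in the
treatment condition and none in the control; stage 4 recovers the planted
SPI ordering (block-internal introns high, flanking introns low) and F_UPFI
of 0 at first and 1 at last block exons; stage 5 shows block-flanking splice
sites are significantly weaker than block-internal ones.

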