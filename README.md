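# markstates

Epigenome–transcriptome integration for time-course ChIP-seq/RNA-seq studies
of differentiating trophoblast stem cells (TSCs). The package classifies
genes as transcriptionally active or silent, reads histone-mark and
transcription-factor occupancy at promoters and gene bodies across
timepoints (D0/D2/D6), and asks how combinatorial occupancy states, their
gain/loss dynamics, and co-factor complexes relate to gene expression — the
analysis layer that sits downstream of alignment, FPKM estimation and peak
calling.

It is written for computational biologists who have per-sample FPKM tables
and MACS2-style peak sets in hand and want a tested, deterministic,
fully-scriptable version of this integration, including a synthetic-study
generator with planted ground truth for validating every classification
end to end.

## What it computes

**Active/silent calls (zFPKM).** Per sample, over genes with FPKM > 0, let
x = log2(FPKM). A Gaussian-kernel density (Silverman bandwidth, fixed
512-point grid on [min(x) − 3, max(x) + 3]) gives the mode μ; with
U = mean{x : x > μ}, the half-normal relation yields

    σ = (U − μ) · sqrt(π/2),   z = (x − μ)/σ .

A gene is active at a timepoint iff z > −3 (strict) in at least one
replicate; zero-FPKM genes are excluded from the fit and auto-silent.

**DEGs.** fold = (mean FPKM later + 0.1)/(mean FPKM earlier + 0.1); up if
fold > 1.5, down if fold < 1/1.5.

**Regulatory taxonomy.** Promoter = [TSS − 3 kb, TSS + 500 bp) strand-aware;
gene body = the annotated span; putative enhancer = base-level
H3K4me1 ∩ H3K27ac outside promoters; per-factor peak sets are cut to the
top 65,000 peaks by FDR-corrected q-value. Overlap everywhere means ≥ 1 bp
intersection; peak classes use precedence promoter > enhancer > gene body >
other.

**Integration.** Gene-level mark status (JMJD2B and H3K9me3 at promoters,
H3K36me3 at gene bodies) per timepoint; 8-state occupancy codes such as
`J+K9+K36-`; gain/loss dynamics per differentiation phase ("gain" =
absence→presence, "loss" = presence→absence); DEG × dynamics crosstabs with
negative correlation = (up ∧ loss) ∨ (down ∧ gain); co-factor complex
categories (JMJD2B–TFAP2C–LSD1, TFAP2C–LSD1, …) at promoters.

**Randomized control.** Peaks are re-placed uniformly within their own
chromosomes; the maximum target-overlap count over 10,000 shuffles is the
null reference for observed overlap percentages.

**Metagene signal.** Scaled-region matrices (3 kb flanks, 100 body bins,
30 flank bins, 5′→3′ oriented) and mean profiles; Spearman correlation of
promoter signal between two tracks.

## Worked example

Simulate a small study with planted truth, write it out as standard text
formats (chrom.sizes, BED12, narrowPeak, bedGraph, TSV), and run the whole
pipeline on the files:

```r
library(markstates)

cfg <- simulate_config(seed = 42, n_genes = 400, chrom_length = 9e6,
                       n_enhancers = 50, n_decoys = 100)
study <- simulate_study(cfg)
dir <- file.path(tempdir(), "toy_study")
write_study(study, dir)

report <- run_pipeline(analysis_config(dir, n_shuffles = 500,
                                       metagene_genes = 100))
print(report)
```

```
Summary report
  genes: 400; active per timepoint: D0=125, D2=140, D6=143
  silent genes at D0 bound by JMJD2B: 100/275 (36%)
  of those also H3K9me3-marked: 47 (47%); persistent: 25 (53%)
  DEGs negatively associated with H3K9me3: 2/108 gene-phase events
  active promoters triple-bound: 92/125 (74%)
  TFAP2C vs JMJD2B: observed 8.7%, shuffle-null max 3.0%
  LSD1 vs JMJD2B: observed 7.7%, shuffle-null max 3.0%
```

Reading the output: 125 of 400 genes are called active at D0 through the
zFPKM path; 36% of the silent genes carry promoter JMJD2B, about half of
those are co-marked by H3K9me3, and half of the co-marked subset stays
silent and co-enriched through D6 — the stable repressed compartment.
Three-quarters of active promoters are bound by the full
JMJD2B–TFAP2C–LSD1 complex, and the observed TFAP2C/LSD1 overlap with
JMJD2B peaks is about three times the maximum seen in 500 within-chromosome
shuffles. `write_report(report, dir)` emits the same numbers as JSON and
TSV tables, each percentage paired with its exact numerator/denominator.

Because the study is synthetic, every classification can be compared with
the generator's truth table (`truth_table(study)`); the test suite asserts
that mark states, dynamics labels and complex categories are recovered
exactly, and activity/DEG calls at ≥ 95% accuracy.

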