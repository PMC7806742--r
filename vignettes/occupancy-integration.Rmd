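---
title: "Integrating mark occupancy with gene activity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating mark occupancy with gene activity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
rules it implements, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the design choices made where the
design was genuinely open. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The analysis in one paragraph

Trophoblast stem cells (TSCs) differentiating over three timepoints
(D0, D2, D6) are profiled by RNA-seq (two replicates per timepoint, FPKM
units) and ChIP-seq for the histone demethylase JMJD2B, the repressive mark
H3K9me3, the elongation mark H3K36me3, the co-factors TFAP2C and LSD1, and
the enhancer marks H3K4me1/H3K27ac. The package classifies each gene as
active or silent per timepoint, reads each mark's presence in its
compartment (promoter or gene body), and integrates the two: combinatorial
occupancy states, their gain/loss dynamics along differentiation, their
relation to differential expression, and the complex composition at
promoters and enhancers — with a within-chromosome shuffle null as the
randomized control for overlap claims.

## Active/silent calling: the zFPKM transform

Per sample, genes with FPKM > 0 enter the fit; x = log2(FPKM). The location
is the mode of a Gaussian-kernel density of x, and the spread comes from
the right half of the distribution via the half-normal relation:

- mu = argmax of the kernel density,
- U = mean of {x : x > mu},
- sigma = (U − mu) · sqrt(pi/2),
- z = (x − mu)/sigma.

A gene is **active** at a timepoint when z > −3 — strictly; z = −3 exactly
is silent — in **at least one replicate** of that timepoint.

Numerical choices, all made for determinism across runs:

- Bandwidth by Silverman's rule (`bw.nrd0`), the conventional default.
- The density is evaluated on a fixed 512-point grid spanning
  [min(x) − 3, max(x) + 3]. Because the grid endpoints, the bandwidth rule
  and the mode are all translation-equivariant, multiplying every FPKM by a
  constant c > 0 shifts x and mu by log2(c) and leaves z unchanged to
  floating-point precision; the test suite checks this at 1e-6.
- The fit is per sample, not pooled across replicates: the transform is a
  per-library normalization, and library-specific depth/composition shifts
  are exactly what it absorbs.
- Samples with fewer than 100 non-zero genes are rejected: the mode of a
  kernel density on fewer points is too unstable to anchor a threshold.

Two open design points and how they are resolved:

- *Zero-FPKM genes.* They are excluded from the density fit and
  automatically silent. Including exact zeros (−Inf on the log scale) is
  impossible, and imputing them would move the mode; exclusion plus
  auto-silent is the only self-consistent reading.
- *Replicate rule.* Activity per timepoint must be called from duplicate
  libraries. The default is the permissive any-replicate rule (active if
  z > −3 in ≥ 1 replicate), which is monotone — adding a replicate can only
  preserve or extend the active set; the strict all-replicates rule is
  available via `call_active(rule = "all")`.

A caveat worth stating: the mode of a kernel density over a nearly flat
maximum is a noisy estimator. On 10,000 genes drawn from a single normal,
the recovered mu is typically within a few hundredths of the truth but
occasional samples deviate by ~0.1–0.3; the induced z error is small near
the mode and amplified in the tails. The acceptance script reports the
actual recovery errors for its seed.

## DEG classification

fold = (mean FPKM at the later timepoint + 0.1)/(mean FPKM at the earlier
timepoint + 0.1); direction is up above 1.5, down below 1/1.5. The
pseudocount (0.1 FPKM) exists only to make the ratio defined at zero; no
statistical test is attached, by design — this mirrors a pure fold-change
selection, and count-based differential testing is out of scope.
Swapping the comparison order maps up to down and leaves unchanged fixed
(tested as a property).

## Regulatory-element taxonomy

- **Promoter**: [TSS − 3000 bp, TSS + 500 bp), strand-aware, clipped to the
  chromosome; a window entirely outside its chromosome is an error.
- **Gene body**: the full annotated span, strand-independent.
- **Putative enhancer**: the base-level intersection of H3K4me1 and H3K27ac
  peaks minus promoters. Base-level (not whole-peak reciprocal) overlap is
  used because the definition concerns *regions* of co-enrichment, and it
  makes the result independent of how peak callers fragment the signal.
- **Top-N selection**: per factor/timepoint, the 65,000 peaks with the
  smallest linear-scale q-value, with the deterministic tie-break
  (q ascending, score descending, chromosome, start). narrowPeak −log10
  q-values are converted to linear scale at parse time so "sorted by q"
  is unambiguous.
- **Peak classes** use ≥ 1 bp overlap and the precedence promoter >
  enhancer > gene body > other. Precedence is required because the classes
  are reported as mutually exclusive percentages; promoter-first matches
  the promoter-centric questions the analysis asks. Tallies always
  partition the peak set (tested).

All interval algebra runs on Bioconductor `GRanges` (1-based, closed) as the
single internal convention; BED/narrowPeak/bedGraph coordinates are
converted at the parse and write boundary. The test suite checks every set
operation base-for-base against an independent per-base bitmap oracle on
random toy genomes.

## Mark status, states, dynamics, complexes

Each mark is read in a fixed compartment: JMJD2B and H3K9me3 at promoters,
H3K36me3 at gene bodies (the compartments in which each is interpretable
against expression); other pairings are a config away
(`build_mark_status(mark_regions = ...)`). Presence is ≥ 1 bp overlap of
the gene's window with ≥ 1 peak of that mark and timepoint.

States concatenate the three presence bits into codes such as `J+K9+K36-`
(8 states, an exhaustive partition). Dynamics reduce each mark's presence
over (D0, D2, D6) to a trajectory string (e.g. "PPA") and per-phase labels:
gain = absence to presence, loss = presence to absence, else persistent
present/absent.

Negative correlation between expression and a mark is operationalized per
phase as (up-DEG ∧ mark loss) ∨ (down-DEG ∧ mark gain), and the global
count is the union over the two phases de-duplicated by gene. The
ambiguity of whether such a count enumerates genes or gene-phase events is
resolved by emitting both. For the reverse-pattern subset, a second mark's
phase label must move opposite to the first's (gain vs loss).

Complex categories at a locus come from the triple of overlap indicators
against JMJD2B, TFAP2C and LSD1 peak sets — eight categories, exactly one
per locus. For genome-wide distributions of triple-bound versus
TFAP2C–LSD1 loci, the JMJD2B peak list is the reference universe for the
triple overlap, and TFAP2C peaks overlapping LSD1 but not JMJD2B define the
pair-only loci; using merged peak unions instead is a plausible alternative
the interfaces leave open.

Percentages are reported as nearest-integer, rounding half away from zero,
always alongside the exact numerator/denominator, so every printed
percentage is recomputable.

## The shuffle null

Randomized controls re-place each peak uniformly at random on its own
chromosome with identical length, preserving the per-chromosome
multiplicity and length multiset exactly. Shuffled peaks may overlap one
another: no exclusion rule is imposed, matching the default behaviour of
the standard shuffling tools when no exclusion flags are given. For each of
n shuffles (default 10,000) the number of target regions intersected is
counted; the maximum over shuffles is the null reference. Shuffle i draws
from seed + i, so results are reproducible and independent of execution
order; per-shuffle counts are retained only up to 1,000 shuffles to bound
memory, while max/mean/95th percentile are always reported.

Overlap percentages need an orientation: the default denominator is the
comparison factor's peak set (the fraction of, say, TFAP2C peaks landing on
JMJD2B regions), with the reverse available — the published bar charts do
not state the orientation, so both are computable and labelled.

## Metagene profiles and promoter correlation

Scaled-region matrices use fixed flanks (default 3 kb), the body scaled
into 100 equal-base bins (remainder bases to the leftmost bins) and 30 bins
per flank; rows are oriented 5′→3′ regardless of strand, flank bases beyond
chromosome ends contribute 0, and genes with bodies shorter than the bin
count are skipped with a logged message. Bin values are mean per-base
signal; on a constant track every cell equals the constant exactly
(tested), and all rows agree with a per-base averaging oracle on toy
genomes. The flank and bin counts are this package's defaults — the
published figures do not state theirs — and are fully configurable.

Promoter-level correlation between two tracks is Spearman by default
(robust to the heavy-tailed signal distributions of ChIP coverage), Pearson
on request, with a two-sided p-value; zero-variance inputs are an error
rather than an NA.

## The synthetic-study generator

The generator emits a complete toy study — chrom.sizes, BED12 annotation,
FPKM table, narrowPeak sets per factor/timepoint, bedGraph tracks, a truth
table and the generating config — deterministic and byte-identical under a
fixed seed.

Study conditions (the defaults): 1,500 genes on two 30-Mb chromosomes,
alternating strands, 10–14 kb spacing, log-normal gene lengths with median
20 kb (2 kb floor); two 30-Mb chromosomes are the smallest genome that
holds 1,500 such genes with headroom. Expression is a bimodal log2-FPKM
mixture: active mode N(5, 1.5²), silent mode N(−4, 1²) with a point mass at
exactly 0, replicate noise 0.25 (log2), 28% of genes active at D0, 5% of
genes switching activity per phase, and 10% of stably active genes planted
as up- (and another 10% as down-) DEGs per phase with a log2 shift of 1.5 —
chosen to exceed log2(1.5) + 3 × replicate noise so planted directions are
recoverable.

The zero point mass is set to 0.85 of silent genes, and it matters: with
~28% active genes, a substantially smaller zero mass would leave enough
non-zero silent genes that the kernel-density mode lands on the *silent*
peak and the zFPKM calls invert. Real RNA-seq silent genes are
overwhelmingly undetected (FPKM = 0), which is exactly the regime the
transform assumes; the generator reproduces it. A silent gene is either
"undetected" across its silent timepoints or consistently "low", so that a
silent-silent gene cannot flicker between 0 and 0.06 FPKM and fake a DEG
through the pseudocount.

Occupancy is planted to echo the published proportions: 75% of active
promoters triple-bound (JMJD2B–TFAP2C–LSD1), small TFAP2C–LSD1 and
JMJD2B-only compartments; among silent genes 36% JMJD2B-bound, 61% of those
H3K9me3 co-marked, and 40% of the co-enriched subset forced to persist
(marks and silence) through D6; H3K36me3 on 85% of active and 5% of silent
gene bodies; marks otherwise flip between phases with probability 0.15.
H3K9me3 dynamics are coupled to DEGs so that ~3% of DEG events are
negatively correlated (up with loss, down with gain) and the remaining DEG
genes keep a persistent H3K9me3 state over that phase. 200 enhancer loci
are planted intergenically as overlapping H3K4me1/H3K27ac peak pairs, 46%
of them TFAP2C+LSD1 co-bound.

Planting is deterministic given the truth labels: a planted "present" cell
always yields one peak fully inside its window (strong q-values,
U(1e−8, 1e−4)), windows of different genes cannot cross-contaminate
(spacing ≥ 10 kb vs promoter reach 3 kb; gene-body peaks keep 600 bp off
the TSS so they cannot touch the promoter), and decoy background peaks
(weak q-values, U(1e−4, 0.1)) live in intergenic space clear of all
windows. This separates interval-logic correctness — where recovery must be
*exact*, and the tests assert exactness for states, dynamics and complexes —
from statistical power, which is exercised only through the expression
noise, the q-value separation and the track noise.

What the generator does **not** emulate: read-level sampling noise, peak
caller artefacts (fragmented or merged peaks, summit offsets), GC and
mappability bias, copy-number structure, overlapping genes and alternative
TSSs, and marks bleeding across compartment boundaries. Passing tests
therefore demonstrate the correctness of the integration logic and the
calibration of the pipeline under clean planted signal — not robustness to
every failure mode of real ChIP-seq.

## Problem sizes used in validation

The shipped validation runs at desk scale, chosen to keep the full suite in
minutes: the end-to-end study uses the default 1,500 genes with 200–1,000
shuffles and a 100–200-gene metagene subsample; shuffle-null calibration
uses 10,000 shuffles of a single 1-bp peak (where the closed-form placement
probability is known); the interval-algebra oracle runs 500 random
instances on ≤ 60 kb toy genomes; zFPKM recovery uses 10,000 genes. The
analysis constants themselves (top 65,000 peaks, 10,000 shuffles, −3
threshold, 1.5-fold, −3 kb/+500 bp) are the defaults of
`analysis_config()` and appear in every report's provenance block.

## Known limitations

- Fold-change-only DEGs carry no error model; borderline genes flip with
  replicate noise (about 1–2% of stably expressed genes at the default
  noise), which is why DEG recovery is asserted at ≥ 95% rather than
  exactly.
- The mode estimator of the zFPKM fit is intrinsically noisy (see above);
  with threshold −3 the activity call is far from the mode and insensitive
  to this in practice, but the reported mu/sigma should not be
  over-interpreted.
- The shuffle null preserves chromosome and length only — no GC,
  mappability or distance-to-gene matching; it answers the same question
  the published control answers, not more.
- One peak set per factor/timepoint: replicate ChIP libraries must be
  merged or intersected upstream; the package deliberately takes no
  position on which.
- bedGraph only for signal (no bigWig), gene-level spans only (no
  transcript models), and no enhancer–promoter pairing.
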