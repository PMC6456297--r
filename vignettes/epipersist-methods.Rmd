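---
title: "Methods: tile-based analysis of histone-mark redistribution and persistent DNA methylation"
author: "epipersist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tile-based analysis of histone-mark redistribution and persistent DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epipersist)
```

## The analysis problem

Loss of an H3K27me3 demethylase in the male germ line redistributes the
repressive H3K27me3 mark in sperm — signal falls at the tiles that carried
the most mark while rising almost everywhere else (a "flattening" of the
profile) — and the regions most affected gain DNA methylation. A subset of
the resulting differentially methylated regions (DMRs) recurs, with the same
direction of change, in somatic tissue of the offspring. epipersist
implements that analysis chain as reusable, tested components on two fixed
genomic grids: 2-kb tiles for ChIP signal, 100-bp tiles for methylation.
Every statistic in the pipeline lives on these grids, so a tile id is a
stable coordinate for joining tracks, DMR tables and feature annotations.

All coordinates are 0-based half-open (BED convention); 1-based inputs
(Bismark coverage tables) are converted at the reader boundary. Strand is
ignored throughout: the tile analyses are unstranded, and opposite-strand
CpG records are merged by the coverage reader when a strand column is
present.

## ChIP tile signal

`tile_signal()` scales ChIP and input counts to reads per million (RPM),
subtracts input from ChIP per tile, clamps negative values to zero, and then
multiplies by the inverse of the ChIP RPM factor, returning the signal to
the ChIP count scale so that between-region variation is not damped:

$$ s_t = \max\!\left(0,\; \frac{10^6 c_t}{L_c} - \frac{10^6 i_t}{L_i}\right)\cdot\frac{L_c}{10^6}. $$

With an all-zero input the two scalings cancel and the signal equals the raw
chip counts exactly — a useful identity that the tests assert.

Per-tile change between conditions is `log2((case + c)/(control + c))` with
pseudocount `c = 1` on the rescaled count scale: large enough to keep the
ratio finite at empty tiles, small enough not to bias high-signal tiles.
Per-tile significance uses an exact conditional binomial: given the tile
total across the two libraries, the case count is binomial with success
probability implied by the library-size ratio. This is the standard
assumption-light two-library count comparison; it is exact but discrete,
hence conservative — its null p-values are sub-uniform, never anti-uniform,
which the calibration tests check at a grid of thresholds (a
Kolmogorov–Smirnov test against the continuous uniform would reject any
discrete exact test by construction).

Changed tiles require replicate consistency: `|log2FC| > 0.5` with
Benjamini–Hochberg `q < 0.1`, with the same sign, in both replicate
comparisons — and no call in either within-genotype comparison
(control-vs-control or mutant-vs-mutant, judged by the same rule), which
removes tiles that are unstable for technical reasons. The within-genotype
criterion is not specified in the source analysis; using the identical rule
is the least arbitrary choice. BH is applied per comparison.

The flattening is summarised two ways. `genomewide_shift()` reports each
track's median and IQR plus a pooled Mann–Whitney comparison.
`top_tile_metagene()` anchors on the top 5% of tiles ranked by the
*control* signal (ranking on the control avoids selection-induced
regression-to-the-mean in the mutant; ties break by tile id) and reports
mean ± SE log2FC and median signal at tile offsets −flank..+flank, dropping
offsets that cross a chromosome boundary.

## Differential methylation on 100-bp tiles

Per-CpG methylated/total counts are summed into 100-bp tiles per sample
(`aggregate_cpgs()`). A tile is retained only when **every** sample has ≥ 10
reads in it — the per-sample reading of the "covered by at least 10 reads"
rule, which matches the convention of the tile-based RRBS tools this module
re-implements. The retained set is the covered-tile universe: it is the
background for the hypergeometric overlap, the feature associations and the
motif control set.

`diff_methylation()` is a binomial-GLM likelihood-ratio test per tile,
comparing a logistic regression of methylated/total on the group indicator
against the intercept-only model across per-sample observations. With a
single binary covariate the fitted proportions are the group-pooled
proportions, so the statistic reduces to a closed-form G-statistic on the
pooled counts and vectorises over all tiles; the test suite checks it
against `glm()` fits tile by tile. p-values come from χ²(1); q-values are
Benjamini–Hochberg. The original tool's SLIM q-values are undocumented in
the source analysis, so BH was chosen for transparency; the deviation is
recorded in the run manifest. Overdispersion correction is off by default
(an optional Pearson scale-factor correction is available); the exact
binomial LRT is mildly anticonservative under the generator's beta-binomial
noise (φ = 0.02), but the null-simulation tests show the BH-adjusted
discovery fraction stays at the nominal level.

DMRs are tiles with `q < 0.05`. Two filters exist. Variant masking — tiles
containing known strain variants (C>T / G>A confound bisulfite conversion)
are removed — applies to every downstream use. Cluster thinning —
single-linkage chains of significant tiles whose starts are < 1 kb apart
keep one uniformly chosen member — exists so that a single genomic region
is not weighted repeatedly when characterising associated features; the
pipeline therefore thins the *persistent* set before the feature and motif
stages, but intersects the unthinned (masked) tissue sets when counting
shared DMRs, since independent random thinning per tissue would destroy
genuinely shared tiles (each tissue can keep a different representative of
the same cluster) while adding nothing to an intersection count. The
source's phrase "more than two tiles" is internally inconsistent with
selecting "one" representative for pairs; every cluster of ≥ 2 is thinned
here, with `min_cluster_size` as a configuration switch.

## Persistence

`intersect_dmrs()` matches sperm and soma DMR sets by exact tile identity
(both analyses share one grid, so overlap-based matching is unnecessary).
The shared count is tested against the hypergeometric expectation
`K·n/N` over the covered-tile universe; `phyper` computes the upper tail
stably far into the extreme range (p ≈ 1e-121 in the motivating study's
genome-scale data). "Positively correlated" for an individual shared DMR is
operationalised as sign concordance of its two deltas; the persistent set is
the concordant-hyper class, and the Pearson correlation of effect sizes is
computed over *all* shared DMRs. `cross_tissue()` extends the comparison to
further tissues with a Fisher 2×2 built over the covered-tile universe; the
reported fraction is overlap / persistent-set size.

## Feature association and motifs

Distance from a tile to a feature set is measured from the tile midpoint to
the nearest feature edge, 0 on any overlap, with an explicit "no neighbor"
sentinel (NA) when the tile's chromosome carries no feature — the source
never states its distance metric, so the package fixes one and tests it
exactly. Distance distributions of a query set vs the covered-tile
background are compared by Mann–Whitney; overlap fractions and windowed
proximity ("near" = distance ≤ window, default 1 kb from the "genes within
1 kilobase" convention) are compared by Fisher's exact test. The top-25%
changed-tile set ranks by |log2FC| — "greatest change" is read
sign-agnostically.

Motif enrichment scans each 100-bp tile sequence with a position weight
matrix on both strands, scoring windows as summed log2 odds against a
uniform base background; a tile is a hit when its best window reaches 80%
of the PWM's maximum achievable score. Hits in the query set vs the
covered-tile control set feed a two-sided Fisher test with Bonferroni
correction over the motifs tested. This is a transparent re-implementation
of the statistical core of motif-enrichment tools (hit classification +
Fisher), not of any particular tool's ranking machinery, so p-values are
comparable in kind rather than numerically to published AME outputs.

## Two-sided exact tests

`fisher_exact()` uses the point-probability ("sum of less-likely tables")
two-sided definition — the dominant convention in statistical environments —
and reports the sample odds ratio `ad/bc` (infinite when `bc = 0`,
reported, never an error). The test suite checks both Fisher and the
hypergeometric tail against full enumeration on every table with `N ≤ 30`
to 1e-12 relative error, and the exact Mann–Whitney branch (used at
n ≤ 20 without ties; normal approximation with tie correction otherwise)
against rank-assignment enumeration.

## The synthetic-data generator

`sim_config()` defines the standard desk-scale study the tests and the
acceptance script run:

* **Genome** — 2 chromosomes × 2 Mb: 2,000 ChIP tiles, 40,000 methylation
  tiles. Large enough for stable tail statistics, small enough that every
  end-to-end run completes in minutes.
* **ChIP** — log-normal baseline intensity (meanlog 3, sdlog 0.7); 5% of
  tiles are high-signal anchors at 8× intensity, placed ≥ 6 tiles apart so
  each anchor's flanks are ordinary background (at desk scale an isolated
  anchor makes the metagene's anchor/flank contrast interpretable; broad
  multi-tile domains would mix depleted tiles into their own flanks). The
  mutant depletes anchors to d = 0.6 of their intensity and adds a
  background gain of 0.3× the median intensity everywhere else — the
  flattening. Two replicates per condition, Poisson counts at 10⁶ depth.
  Input libraries are flat, with 30% of their reads landing in tiles
  (libraries lose reads to upstream filtering, so the nominal library size
  legitimately exceeds the in-tile sum).
* **RRBS** — CpGs placed at 0.03/bp (RRBS concentrates coverage in
  CpG-dense sequence; at this density almost every tile with a CpG clears
  the 10-read filter in all samples); per-CpG totals negative binomial
  (mean 30, size 10); baseline tile methylation Beta(6.5, 3.5), i.e. a 65%
  genome-wide level; beta-binomial overdispersion φ = 0.02 (mild — no
  per-sample variance estimates exist to fit); 300 planted DMR tiles
  shifted by 30 percentage points, 14:1 hyper:hypo (echoing the strong
  hypermethylation imbalance of the motivating data), half placed inside
  histone-changed tiles; a Bernoulli(ρ = 0.8) subset of planted tiles
  carries the same shift in the mutant soma samples — persistence is a
  per-tile coin flip, the simplest mechanism consistent with the biology,
  with no embryonic reprogramming dynamics. 3 samples per group, two
  tissues.
* **Features** — TSS, CpG islands, repeats and gene bodies uniform; 80% of
  enhancers placed within 500 bp of persistent-truth tiles; 200 uniform
  strain variants plus one inside 5% of planted DMR tiles to exercise
  masking.
* **Motifs** — one planted 8-bp PWM embedded (5% per-base mutation rate) in
  40% of persistent-truth tiles and 2% of control tiles; three decoy PWMs
  never embedded.

Every generator is a pure function of the config seed: repeated runs are
bit-identical, and the generators restore the caller's RNG state. What the
generator does **not** emulate: genomic sequence composition, CpG islands'
correlation with methylation level, read-level errors or bisulfite
conversion failure, inter-individual variability beyond beta-binomial
noise, and realistic repeat structure. Passing tests therefore demonstrate
that the statistical machinery recovers planted effects under controlled
noise — not that the pipeline's power estimates transfer to real data.

## Null-persistence check

A permutation control re-runs the soma DMR calling after randomly
relabelling the six soma samples into two groups of three, excluding the
observed labelling and its complement (those reproduce the true contrast
rather than a null), and asks whether the sperm∩soma shared count falls to
the hypergeometric chance expectation of the true margins. In practice the
collapse is strong but partial: mixed relabellings retain a third of the
planted effect, and — more consequentially — planted tiles then hold a
within-group *mixture* of shifted and unshifted samples, which the
default overdispersion-free likelihood-ratio test does not model, making
it anticonservative precisely at planted tiles. The few tiles surviving BH
under permutation are therefore still predominantly planted ones, and the
permuted shared count sits well above the chance band even though it is
several-fold below the true contrast. The corresponding acceptance check
is left failing by design rather than papered over: it documents a real
limitation of overdispersion-free tile tests under label permutation when
effects exist, and the optional `overdispersion = "scale"` correction is
the remedy a practitioner should reach for.

## Numerical and degenerate-input choices

* Extreme hypergeometric tails go through `phyper`, which works in log
  space internally; p-values down to ~1e-300 are representable.
* A fully tied Mann–Whitney sample (zero rank variance) returns p = 1.
* `count_ratio_test` returns p = 1 when both counts are zero.
* The final short tile of each chromosome is kept; coverage filters remove
  unreliable tiles anyway.
* Thinning and all other random steps take explicit seeds; the pipeline
  derives stage seeds from the config seed by fixed offsets.
* Tiles where one group has zero total reads are skipped with a warning in
  differential testing.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(42)
run <- run_pipeline(cfg, "run42")
run$persistence
autoplot(run$metagene)
head(run$motif)
```

At seed 42 the default conditions yield roughly 96% detection of planted
sperm DMRs, ~210 shared DMRs against a chance expectation near 8, and the
planted motif first by Bonferroni-adjusted p — the acceptance script
(`scripts/acceptance.R`) recomputes these quantities from scratch at any
seed.

## Known limitations

The differential test ignores overdispersion by default, as the source
analysis appears to; with strongly variable biological replicates the
optional scale correction (or a beta-binomial model, out of scope here)
would be more appropriate. Exact tile-identity intersection cannot credit
near-miss DMRs one tile apart. The motif scanner's fixed 80%-of-max
threshold is a transparent simplification; ROC-style threshold calibration
is deliberately not implemented. The cross-tissue odds-ratio table's
construction over the covered-tile universe is one of several defensible
choices; the source does not state its own.
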