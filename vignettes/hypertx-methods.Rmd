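---
title: "hypertx: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hypertx: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: what each stage
computes, which assumptions it makes, why the defaults are what they
are, and where the design was genuinely open. It states no empirical
result that the test suite does not itself compute.

## The measurement model

The input is a library of mapped fragments per sample — intervals
`(chrom, start, end)` in 0-based half-open BED convention — from an
antibody-tethered tagmentation assay targeting engaged RNA polymerase
II. Samples come in matched tumor/normal pairs. Three assumptions carry
the whole analysis:

1. **Fragment coverage is proportional to local RNAPII occupancy.**
   Coverage counts every base a fragment spans (not midpoints), matching
   the standard genome-coverage track construction.
2. **Only relative signal is identified.** Without a spike-in, library
   depth is arbitrary; all comparisons are made after genome-scaled
   normalization and, across samples of a pair, after fragment-count
   equalization. Genome-scaled normalization sets
   `n_i = (c_i / T) * G` with `T = sum(c_i)` (the summed per-bp count
   mass, equal to total fragment bp) and `G` the genome size, so a
   uniform library has `n_i = 1` everywhere and every track sums to
   `G`. A consequence worth keeping in mind throughout: the measurement
   is *compositional*. A genuine gain somewhere must be paid for
   somewhere else in the normalized track. In the data this package
   emulates the payer is chiefly the mitochondrial chromosome (tumors
   carry less mtDNA), which is also why `G` includes chrM: depletion of
   chrM slightly inflates autosomal normalized values, as in the real
   assay.
3. **Per-element signal is comparable after length-averaging.** Regions
   of different widths are compared on mean normalized counts
   (`region_signal()`); the histone-cluster proxy deliberately uses sums
   (`region_sum()`) because the quantity of interest there is the
   aggregate output of the cluster, not its density.

## Tumor − normal statistics

`pair_diff()` computes, per region, the primary statistic `D = T − N`
in normalized count units (Bland–Altman difference), the average
`(T + N)/2`, and the MA pair (`log2_fc`, `log10_avg`). The raw
difference is primary because a fold change cannot distinguish a weak
signal doubling from a strong signal doubling, while hypertranscription
is specifically an increase of *already high* transcription. Rankings
(`rank_regions()`) use `|D|`, `T − N`, or `N − T` with ties broken by
`(chrom, start)` for reproducibility. `rank_curve()` plots the positive
parts of both orientations; under the no-effect null the two curves are
near mirror images, so their divergence is a global upregulation
readout. `max_diff_composite()` takes the per-region maximum of `D`
across pairs, the "is it up in at least one tumor" summary.

Numerical choices: a pseudo-value `eps = 1e-6` guards the two log
scales only — the raw difference needs none and gets none. Regions with
`avg = 0` therefore sit at `log10(1e-6)` in MA space but remain in all
tables. The histone paired *t*-test is two-sided and requires at least
two replicate pairs with nonzero variance; with one pair the excess is
reported and the p-value is `NA`.

## QC and sample preparation

A sample passes QC with at least 100,000 fragments **and** at least
10,000,000 bp of summed fragment length; "read counts" is interpreted
as fragment count, the unit used throughout the pipeline (paired-end
fragments, unstranded, only the first three BED columns consulted).
Duplicates are exact `(chrom, start, end)` coordinate matches, the
fragment-level equivalent of paired-end duplicate marking; dedup is
idempotent and keeps first occurrences. When both dedup and
equalization are requested, dedup runs first. Equalization downsamples
the larger member of a pair, uniformly without replacement, to the
smaller member's count, under an explicit seed. Whether to dedup at all
is exposed as a pipeline option (`dedup =`), since sparse mouse-scale
data is commonly analyzed with all mapped fragments while deeper pooled
human data is deduplicated; the package takes no position beyond the
default `TRUE`.

## Peak calling against a matched control

Sparse tagmentation data is mostly zero; the caller therefore
segments each normalized track into **blocks** — maximal runs of
strictly positive signal — and thresholds blocks on their AUC (summed
normalized counts). The control (the paired normal) is scaled by
`s = sum(target)/sum(control)` and the candidate thresholds are the
merged block AUCs of both tracks. For each candidate `t` the gain
`gain(t) = frac_target(auc > t) − frac_control(s·auc > t)` measures the
excess of surviving target blocks.

**Design deviation, and why.** A first implementation selected the
threshold by maximizing the raw gain and returned no peaks only when
the maximum gain was non-positive. That rule is pathologically
sensitive at the bottom of the AUC distribution: at a threshold that
retains nearly every block, a sampling fluctuation of a single block
produces a spurious positive gain of order `1/N`, and because the rule
then keeps *all* blocks above that bottom threshold, a reversed
(normal-as-target) call on well-matched data returned essentially the
entire block population — hundreds of "peaks" — in every
parameterization we examined, analytically and empirically. The
shipped rule instead standardizes the gain,
`z(t) = gain(t) / SE(gain(t))` with the binomial standard error, picks
the threshold maximizing `z` (`stringent`) or the smallest threshold
reaching 90% of the maximum `z` (`relaxed`), and calls **no peaks**
unless some candidate reaches `z_min = 3.5`. The floor is a
multiplicity-adjusted two-population proportion test (the scan visits
~2N correlated candidates) chosen a priori, not fitted to any test.
With it, a matched control yields zero peaks, genuine enrichment yields
a sharp threshold, and the forward/reverse asymmetry that motivates the
method emerges cleanly. `relaxed` remains intentionally more
permissive than `stringent`; recovery-precision checks in the test
suite use the `stringent` (argmax) threshold, which is the sharper
estimator of the target/control separation, and verify the asymmetry
in both modes.

## Tiling, local regression, and summits

`tile_counts()` partitions a window into fixed-size bins (default
1 kb, last bin may be partial) and sums normalized counts per bin for
both samples. `loess_fit()` implements local polynomial regression
directly: for each bin, a weighted quadratic over the
`ceiling(span · n)` nearest bins with tricube weights
`(1 − (d/dmax)^3)^3`, falling back to degree 1 (with a message) when
the neighborhood cannot support a quadratic. A noiseless quadratic is
reproduced exactly; this is the contract the tests pin. Spans 0.2 and
0.5 are both exposed because both are in standard use — 0.2 for
localizing summits in a 1 Mb window, 0.5 for heavily smoothed zoomed
overlays; 0.2 is the default.

`detect_summits()` works on the smoothed tumor − normal excess: local
maxima with prominence (height above the lower of the two flanking
minima) at least `min_prominence`, default twice the median absolute
deviation of the excess series since broad summits in the source
analyses were identified visually and no numeric criterion exists.
Width is measured at half prominence; if promoter anchors are supplied
the offset to the nearest anchor midpoint is reported. A practical
limit worth stating: a ~100-kb-scale multiplicative bump has a flat
top, so its detected center is only as stable as the emission terrain
it rides on — over a coarse landscape (few, large elements) the
maximum can wander several kb at any sequencing depth. The summit
acceptance scenario therefore uses a dense fine-grained landscape
(4,000 × 200 bp elements with 30% diffuse background), which is also
the more faithful miniature of a megabase locus.

`window_fold_change()` is the plain ratio of summed normalized counts
in a window, tumor over normal (`NA` with a warning if the normal
window is empty). Note the compositional effect again: with an
amplified segment elsewhere, windows outside it show ratios slightly
below 1 — that is a property of normalized data, not an artifact.

## Clustering

`build_matrix()` counts fragments overlapping each region by ≥ 1 bp (a
fragment spanning k regions counts in each). `tfidf_normalize()` is
the standard LSI transform for sparse accessibility data,
`ln(1 + 1e4 · TF · IDF)`; the formula is the conventional one because
the source method is cited by name without one. Depth invariance
(doubling a sample's counts leaves its column unchanged) is the
property the tests pin. `reduce_and_embed()` keeps the top rows by
total signal (default all, capped at 25,000), scales features with a
`|z| ≤ 10` cap, runs PCA on samples, keeps up to 50 PCs (lowered with
a warning when exceeding `n_samples − 1`), and projects to 2-D with
UMAP via `uwot` (single-threaded, seeded, hence reproducible) or — if
`uwot` is unavailable — classical MDS on PC-space distances, which for
cohorts of this size preserves the same neighborhood structure.
Quantitative claims in the tests are made in PC space (1-NN label
purity), not on the 2-D picture.

## The synthetic world

`simulate_pair()` draws each fragment from a finite mixture:
background (uniform over non-mitochondrial chromosomes), one component
per annotated region (midpoint Normal at the region center, SD =
width/4), and chrM (uniform). Fragment length is Normal
(mean 110 bp, SD 25, clipped to [30, 250]) — sub-nucleosomal
tagmentation scale, and consistent with the QC thresholds (100k
fragments × 110 bp > 10 Mbp). With probability `q` (default 0.1) a
fragment is re-emitted verbatim, matching the exact-coordinate dedup
definition. The tumor re-weights the mixture: `h` (default 2) on a
fraction `f` (default 0.1) of cCREs, `histone_factor` (default 2) on
the histone genes, chrM probability multiplied by `d` (default 0.5),
and everything inside a declared amplicon multiplied by
`a · summit(x)`, `summit(x) = 1 + Σ extra·exp(−(x−c)²/2σ²)`. The
default genome is 2 × 1 Mb + 16 kb chrM with 1,000 non-overlapping
300 bp cCREs (class mix promoter 0.25, H3K4me3 0.10, proximal enhancer
0.20, distal enhancer 0.35, CTCF 0.10) and one 120 kb histone cluster
of 64 genes — the annotated single-exon replication-coupled histone
gene count. Effect magnitudes `h = 2`, `f = 0.1` are test
conveniences: the source study reports no per-element effect sizes.

The generator is deterministic given (config, seed), emits exactly
`n_fragments` per sample sorted by coordinate, and returns a truth
ledger (planted ids, per-region emission weights for both conditions,
amplicon/summit geometry, expected chrM fractions).

One world deserves its own note. The peak-calling acceptance scenario
("50 planted 5× blocks over matched background") chooses its free
parameters so that the planted excess emission mass is funded
*entirely* by mitochondrial depletion: `d` solves
`1 − p_chrM·d = (1 − p_chrM) + extra`. Then, after equalization, the
background and the 630 non-planted elements have *identical* emission
weights in tumor and normal — the control is genuinely matched, and
the only systematic target/control difference is the 50 planted
blocks. The rejected alternative (letting renormalization depress the
non-planted elements) manufactures spurious "hypotranscription"
blocks that are artifacts of compositional closure rather than
properties of the stated world. The funding mechanism also mirrors the
actual biology this package targets: hypertranscribed tumors with
depleted mitochondrial signal.

What the generator does **not** emulate — and hence what a green test
does not establish: no sequence, mappability, or GC structure; no
fragment-length dependence on signal class; no single-cell structure;
no replicate-level batch effects; no spatially correlated background;
real cCRE annotations are ~10³ times larger and genuinely non-uniform.
Tests on this world validate the algebra and the statistical behavior
of the pipeline, not assay-level performance on real tissue.

## Degenerate inputs and numeric edges

Empty fragment sets are rejected where an answer would be undefined
(tracks, equalization, chrM fraction with zero mass) and pass through
harmlessly elsewhere (reading an empty BED). Zero-length regions are
errors. bedGraph values are written with `%.17g` so a round trip is
bit-exact; overlapping intervals on read are errors. Regions abutting
a mask end-to-start share no base pair under half-open semantics and
survive `subtract_regions()`. All randomized steps (simulation,
downsampling, embedding) take explicit integer seeds and restore the
caller's RNG state.

## Known limitations

- The peak caller is a fully specified variant in the spirit of
  sparse-enrichment calling; equivalence with any external caller is
  not claimed, and `z_min` trades a small amount of sensitivity for
  robustness on small block populations.
- Per-element significance (FDR over cCREs) is out of scope; the
  package computes MA values but makes no significance calls.
- No BAM input in the core path; fragments arrive as BED.
- LOESS is O(n · span · n) per series; fine for the intended
  ~10³-bin windows, not for whole-genome tiling at 1 kb.
- The 2-D embedding is for visualization; all quantitative statements
  should be made in PC space.
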