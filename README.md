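# hypertx

Quantification of RNA polymerase II **hypertranscription** from paired
tumor/normal fragment data.

Antibody-tethered tagmentation assays (CUT&Tag / CUTAC, including the
FFPE variant that works on fixed paraffin sections) map
RNAPII-associated open chromatin as sparse libraries of mapped
fragments. In many cancers the engaged-RNAPII signal rises genome-wide
relative to the matched normal tissue. `hypertx` implements the
downstream analysis that detects and localizes this excess from nothing
but fragment BED files and a region annotation:

- **Genome-scaled coverage**: per-bp normalized counts
  `n_i = (c_i / T) * G`, where `c_i` counts fragments spanning base `i`,
  `T = sum(c_i)` and `G` is the genome size, so uniform coverage has
  value 1 everywhere and every track sums to `G`.
- **Per-element tumor − normal statistics** over candidate
  cis-regulatory elements (cCREs): Bland–Altman differences
  `D = T − N`, MA values (`log2 FC` vs `log10` average), rank-ordered
  difference curves, and a cross-tumor max-difference composite.
- **Proliferation and mtDNA proxies**: summed-signal excess over
  replication-coupled histone gene clusters with a paired *t*-test, and
  the percentage of coverage mass on the mitochondrial chromosome
  (typically depleted in tumors).
- **Paired-control sparse-enrichment peak calling**: maximal
  positive-signal blocks thresholded on their AUC; the threshold
  maximizes the standardized excess of surviving target blocks over
  surviving (scaled) control blocks, with the matched normal sample as
  the control. Reversing target and control probes hypotranscription —
  asymmetry in the two counts is the annotation-free signature of
  genome-wide upregulation.
- **Amplicon and broad-summit analysis**: 1-kb tiling of a window,
  local polynomial regression (LOESS, tricube weights, degree 2, span
  0.2/0.5), summit detection on the smoothed tumor excess with
  promoter-anchor offsets, and window fold changes.
- **Sample embedding**: region × sample fragment-count matrix → TF-IDF
  (LSI) normalization → top features → scaling → PCA (≤ 50 PCs) → 2-D
  UMAP.
- **A synthetic-data generator** (`sim_config()`, `make_genome()`,
  `simulate_pair()`) that emits paired tumor/normal fragment sets from a
  finite mixture with planted hypertranscribed elements, histone-cluster
  upregulation, chrM depletion, duplicates, and amplified segments
  carrying Gaussian summits — plus the ground-truth ledger every test is
  scored against.

Intended users: computational epigenomics groups analyzing low-depth
paired tumor/normal tagmentation data, or anyone needing a tested,
self-contained reference implementation of this analysis.

## Worked example

A complete synthetic cohort on a 2 Mb toy genome (two 1 Mb chromosomes
plus a 16 kb chrM, 1,000 cCREs, one 64-gene histone cluster; tumor
plants a 2× gain on 10% of cCREs, 2× histone upregulation, and 50%
chrM depletion):

```r
library(hypertx)

cfg <- sim_config(seed = 42, n_fragments = 100000)
gm  <- make_genome(cfg)
sim <- simulate_pair(cfg, gm$genome, gm$regions)

ccre <- gm$regions[S4Vectors::mcols(gm$regions)$class != "histone"]
hist <- gm$regions[S4Vectors::mcols(gm$regions)$class == "histone"]
tt <- make_track(sim$tumor,  gm$genome)
tn <- make_track(sim$normal, gm$genome)

pr  <- pair_diff(region_signal(tt, ccre), region_signal(tn, ccre))
top <- rank_regions(pr, "tumor_minus_normal")
head(top[, c("region_id", "class", "T", "N", "diff", "log2_fc")], 3)
#>     region_id           class        T        N     diff  log2_fc
#> 1: ccre_00872        promoter 12.53214 4.798680 7.733464 1.384923
#> 2: ccre_00965        promoter 11.13608 4.736360 6.399723 1.233391
#> 3: ccre_00262 distal_enhancer 10.62364 4.306226 6.317417 1.302782
```

The three leading elements carry ~5 normalized counts per bp in the
normal section and ~11–13 in the tumor: a tumor-minus-normal excess of
6–8 normalized count units. Of the top 100 elements by `T − N`, 98 are
planted hypertranscribed elements (`sim$truth$hyper_ccre_ids`).

```r
histone_excess(list(sim[c("tumor", "normal")]), hist, gm$genome)
#> histone excess over 1 replicate pair(s):
#>   mean excess = 81680 normalized count units, SD = NA

mito_compare(list(sim[c("tumor", "normal")]), gm$genome)
#>      pair tumor_pct normal_pct     ratio flagged
#> 1:  pair1    4.9607   9.859742 0.5031268   FALSE

call_peaks(tt, tn, mode = "stringent")
#> peak_call (stringent): 261 peaks, threshold AUC 2412, max z 7.27
```

The histone cluster shows a positive summed-count excess (the planted
2× upregulation), the chrM percentage drops from 9.9% to 5.0% (the
planted `d = 0.5`), and the paired-control peak caller reports 261
tumor-over-normal peaks.

One-command demo writing every stage's outputs plus a run manifest:

```sh
Rscript -e 'hypertx::run_demo(seed = 1, out_dir = "demo_out")'
# or, via the CLI wrapper:
exec/hypertx demo --seed 1 --out demo_out
```

## Documentation

The methods vignette (`vignettes/hypertx-methods.Rmd`) describes the
model, the synthetic world and its defaults, numerical choices, and
known limitations. Every exported function carries roxygen
documentation.
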