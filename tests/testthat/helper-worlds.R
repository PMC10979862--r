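# The "matched-background" peak-calling world: 50 cCREs planted at a 5x
# emission gain among 680 elements on a 2 Mb genome. The planted excess
# mass is funded exactly by mitochondrial depletion (d solves
# 1 - p_chrM*d = (1 - p_chrM) + extra), so after count equalization the
# non-planted elements and the background have identical emission
# weights in tumor and normal: the control is genuinely matched and the
# only target/control difference is the 50 planted blocks.
peak_world_config <- function(n_fragments = 100000, seed = 1,
                              hyper_factor = 5) {
  n_ccres <- 680
  p_bg <- 0.002
  p_m <- 0.30
  w <- (1 - p_bg - p_m) / n_ccres
  extra <- 50 * w * (hyper_factor - 1)
  stopifnot(extra < p_m)
  sim_config(n_ccres = n_ccres, ccre_width = 400, histone_cluster = NULL,
             p_background = p_bg, p_chrM_normal = p_m,
             chrM_depletion_factor = 1 - extra / p_m,
             hyper_fraction = 50 / n_ccres, hyper_factor = hyper_factor,
             histone_factor = 1, duplicate_rate = 0,
             n_fragments = n_fragments, seed = seed)
}

# cohort of 3 signature groups x n samples sharing one genome/annotation:
# each group plants its own disjoint 100-cCRE hypertranscription signature
signature_cohort <- function(samples_per_group = 4, n_fragments = 50000,
                             h = 2) {
  base <- sim_config(n_ccres = 1000, n_fragments = n_fragments,
                     hyper_factor = h, chrM_depletion_factor = 1,
                     histone_factor = 1, duplicate_rate = 0, seed = 99)
  gm <- make_genome(base)
  ccre_ids <- S4Vectors::mcols(gm$regions)$region_id
  ccre_ids <- ccre_ids[S4Vectors::mcols(gm$regions)$class != "histone"]
  sig <- split(ccre_ids[1:300], rep(1:3, each = 100))
  samples <- list()
  labels <- character()
  for (g in 1:3) {
    cfg <- base
    cfg$hyper_ids <- sig[[g]]
    for (j in seq_len(samples_per_group)) {
      sim <- simulate_pair(cfg, gm$genome, gm$regions,
                           seed = 1000 * g + j,
                           pair_id = sprintf("g%ds%d", g, j))
      s <- sim$tumor
      s$sample_id <- sprintf("g%d_s%d", g, j)
      samples <- c(samples, list(s))
      labels <- c(labels, paste0("g", g))
    }
  }
  list(samples = samples, labels = labels, gm = gm,
       regions = gm$regions[S4Vectors::mcols(gm$regions)$class != "histone"])
}

# precision/recall of a peak call against the planted truth regions
peak_pr <- function(call, truth_regions) {
  p <- call$peaks
  tr <- data.frame(chrom = as.character(GenomicRanges::seqnames(truth_regions)),
                   start = GenomicRanges::start(truth_regions) - 1,
                   end = GenomicRanges::end(truth_regions))
  if (nrow(p) == 0) return(list(recall = 0, precision = NA_real_))
  hit_truth <- vapply(seq_len(nrow(tr)), function(i) {
    any(p$chrom == tr$chrom[i] &
          bed_overlaps(p$start, p$end, tr$start[i], tr$end[i]))
  }, TRUE)
  hit_peak <- vapply(seq_len(nrow(p)), function(i) {
    any(tr$chrom == p$chrom[i] &
          bed_overlaps(tr$start, tr$end, p$start[i], p$end[i]))
  }, TRUE)
  list(recall = mean(hit_truth), precision = mean(hit_peak))
}
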