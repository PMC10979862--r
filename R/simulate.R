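#' Simulation configuration
#'
#' Describes the synthetic world the paired tumor/normal fragment
#' generator draws from: a small multi-chromosome genome with a
#' mitochondrial contig, non-overlapping annotated regulatory elements
#' (cCREs) of several classes, a replication-coupled histone gene
#' cluster, and the planted tumor effects the downstream analysis is
#' meant to recover — hypertranscribed cCREs (emission multiplier `h` on
#' a fraction `f` of elements), histone-cluster upregulation,
#' mitochondrial depletion (`d`), and an amplified segment (copy number
#' `a`) optionally carrying broad Gaussian summits.
#'
#' Fragments are drawn from a finite mixture: background (uniform over
#' non-mitochondrial chromosomes), one component per annotated region
#' (fragment midpoints Normal around the region center), and chrM
#' (uniform). The tumor sample re-weights this mixture by the planted
#' multipliers; all emissions inside the amplicon are further multiplied
#' by `a * summit(x)` where `summit(x) = 1 + sum_k extra_k *
#' exp(-(x - center_k)^2 / (2 * sd_k^2))`.
#'
#' @param n_chroms number of non-mitochondrial chromosomes.
#' @param chrom_length length of each such chromosome (bp).
#' @param chrM_length mitochondrial chromosome length (bp).
#' @param n_ccres number of cCREs to place.
#' @param ccre_class_mix named proportions over cCRE classes.
#' @param ccre_width cCRE width (bp).
#' @param histone_cluster list(chrom, start, end, n_genes) or `NULL`.
#' @param p_background probability a fragment is background.
#' @param p_chrM_normal probability a normal-sample fragment is chrM.
#' @param chrM_depletion_factor d in (0, 1]; tumor chrM probability is
#'   `p_chrM_normal * d`.
#' @param hyper_fraction f, fraction of cCREs planted hypertranscribed.
#' @param hyper_factor h >= 1, tumor emission multiplier on planted cCREs.
#' @param histone_factor tumor emission multiplier on histone genes.
#' @param amplicon list(chrom, start, end, copy_number) or `NULL`.
#' @param summits list of list(center, width_sd, extra) inside the
#'   amplicon; empty for none.
#' @param fragment_length list(mean, sd, min, max) in bp.
#' @param duplicate_rate q, probability a fragment is an exact re-emission
#'   of an earlier one.
#' @param n_fragments fragments per sample.
#' @param hyper_ids optional explicit character vector of planted cCRE
#'   ids (overrides random selection; used for cohort signatures).
#' @param seed integer seed; the generator is fully deterministic given
#'   (config, seed).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2,
                       chrom_length = 1e6,
                       chrM_length = 16000,
                       n_ccres = 1000,
                       ccre_class_mix = c(promoter = 0.25, H3K4me3 = 0.10,
                                          proximal_enhancer = 0.20,
                                          distal_enhancer = 0.35,
                                          CTCF = 0.10),
                       ccre_width = 300,
                       histone_cluster = list(chrom = "chr1", start = 700000,
                                              end = 820000, n_genes = 64),
                       p_background = 0.05,
                       p_chrM_normal = 0.10,
                       chrM_depletion_factor = 0.5,
                       hyper_fraction = 0.1,
                       hyper_factor = 2,
                       histone_factor = 2,
                       amplicon = NULL,
                       summits = list(),
                       fragment_length = list(mean = 110, sd = 25,
                                              min = 30, max = 250),
                       duplicate_rate = 0.1,
                       n_fragments = 100000,
                       hyper_ids = NULL,
                       seed = 1L) {
  cfg <- list(n_chroms = as.integer(n_chroms),
              chrom_length = as.numeric(chrom_length),
              chrM_length = as.numeric(chrM_length),
              n_ccres = as.integer(n_ccres),
              ccre_class_mix = ccre_class_mix,
              ccre_width = as.integer(ccre_width),
              histone_cluster = histone_cluster,
              p_background = p_background,
              p_chrM_normal = p_chrM_normal,
              chrM_depletion_factor = chrM_depletion_factor,
              hyper_fraction = hyper_fraction,
              hyper_factor = hyper_factor,
              histone_factor = histone_factor,
              amplicon = amplicon,
              summits = summits,
              fragment_length = fragment_length,
              duplicate_rate = duplicate_rate,
              n_fragments = as.integer(n_fragments),
              hyper_ids = hyper_ids,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$p_background, cfg$p_chrM_normal, cfg$duplicate_rate,
             cfg$hyper_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$p_background + cfg$p_chrM_normal >= 1) {
    stop("p_background + p_chrM_normal must leave mass for regions")
  }
  if (cfg$hyper_factor < 1) stop("hyper_factor h must be >= 1")
  if (cfg$chrM_depletion_factor <= 0 || cfg$chrM_depletion_factor > 1) {
    stop("chrM_depletion_factor d must be in (0, 1]")
  }
  if (any(cfg$ccre_class_mix < 0) || sum(cfg$ccre_class_mix) <= 0) {
    stop("ccre_class_mix must be non-negative with positive sum")
  }
  fl <- cfg$fragment_length
  if (fl$min < 1 || fl$max < fl$min) stop("invalid fragment_length bounds")
  if (!is.null(cfg$amplicon)) {
    a <- cfg$amplicon
    if (a$copy_number < 1) stop("amplicon copy_number a must be >= 1")
    if (!a$chrom %in% sim_chrom_names(cfg)) {
      stop("amplicon chromosome not in declared genome")
    }
    if (a$start < 0 || a$end > cfg$chrom_length || a$start >= a$end) {
      stop("amplicon bounds outside chromosome")
    }
    for (s in cfg$summits) {
      if (s$center < a$start || s$center > a$end) {
        stop("summit center outside amplicon bounds")
      }
    }
  } else if (length(cfg$summits) > 0) {
    stop("summits require an amplicon")
  }
  invisible(cfg)
}

sim_chrom_names <- function(cfg) {
  c(paste0("chr", seq_len(cfg$n_chroms)), "chrM")
}

# evaluate seed-scoped expression without clobbering the caller's RNG
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Build the synthetic genome and its region annotation
#'
#' Lays out `n_chroms` equal-length chromosomes plus chrM, then places
#' `n_ccres` non-overlapping cCREs of width `ccre_width` by sampling
#' disjoint width-sized slots on the non-mitochondrial chromosomes
#' (slots overlapping the histone cluster are excluded), assigning class
#' labels from `ccre_class_mix`. The histone cluster is filled with
#' `n_genes` evenly spaced gene regions of class `"histone"`.
#' Deterministic under `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (a [genome_spec()]) and `regions` (a region
#'   `GRanges`, cCREs then histone genes).
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  chroms <- sim_chrom_names(config)
  lengths <- c(rep(config$chrom_length, config$n_chroms), config$chrM_length)
  genome <- genome_spec(chroms, lengths, chrM = "chrM")
  autosomes <- chroms[chroms != "chrM"]

  w <- config$ccre_width
  slot_tab <- data.table::rbindlist(lapply(autosomes, function(ch) {
    n_slot <- floor(config$chrom_length / w)
    data.table::data.table(chrom = ch, start = (seq_len(n_slot) - 1) * w)
  }))
  slot_tab[, "end" := slot_tab$start + w]
  hc <- config$histone_cluster
  if (!is.null(hc)) {
    if (!hc$chrom %in% autosomes) stop("histone cluster chromosome unknown")
    drop <- slot_tab$chrom == hc$chrom & slot_tab$start < hc$end &
      slot_tab$end > hc$start
    slot_tab <- slot_tab[!drop]
  }
  if (config$n_ccres > nrow(slot_tab)) {
    stop("cannot place ", config$n_ccres, " cCREs of width ", w,
         " on this genome: only ", nrow(slot_tab), " disjoint slots")
  }
  mix <- config$ccre_class_mix / sum(config$ccre_class_mix)
  picked <- with_seed(config$seed, {
    idx <- sort(sample.int(nrow(slot_tab), config$n_ccres))
    cls <- sample(names(mix), config$n_ccres, replace = TRUE, prob = mix)
    list(idx = idx, cls = cls)
  })
  ccre <- slot_tab[picked$idx]
  ccre[, "region_id" := sprintf("ccre_%05d", seq_len(nrow(ccre)))]
  ccre[, "class" := picked$cls]

  hist_dt <- NULL
  if (!is.null(hc)) {
    span <- hc$end - hc$start
    gw <- max(50L, as.integer(floor(span / (2 * hc$n_genes))))
    centers <- hc$start + (seq_len(hc$n_genes) - 0.5) / hc$n_genes * span
    hist_dt <- data.table::data.table(
      chrom = hc$chrom,
      start = as.integer(round(centers - gw / 2)),
      end = as.integer(round(centers + gw / 2)),
      region_id = sprintf("histone_%03d", seq_len(hc$n_genes)),
      class = "histone")
  }
  all_dt <- data.table::rbindlist(list(ccre, hist_dt), use.names = TRUE,
                                  fill = TRUE)
  regions <- region_set(all_dt$chrom, all_dt$start, all_dt$end,
                        region_id = all_dt$region_id, class = all_dt$class,
                        genome = genome)
  list(genome = genome, regions = regions)
}

# multiplicative summit profile at positions x (bp) on the amplicon chrom
summit_profile <- function(x, summits) {
  m <- rep(1, length(x))
  for (s in summits) {
    m <- m + s$extra * exp(-(x - s$center)^2 / (2 * s$width_sd^2))
  }
  m
}

# per-component emission tables for one condition
build_emission <- function(config, genome, regions, tumor, hyper_ids) {
  rdt <- regions_to_dt(regions)
  rdt[, "center" := (rdt$start + rdt$end) / 2]
  rdt[, "width" := rdt$end - rdt$start]
  n_reg <- nrow(rdt)
  p_reg_total <- 1 - config$p_background - config$p_chrM_normal
  w_reg <- rep(p_reg_total / n_reg, n_reg)
  w_bg_total <- config$p_background
  p_chrM <- config$p_chrM_normal

  amp <- config$amplicon
  autosomes <- genome$chroms[genome$chroms != genome$chrM]
  # background segments outside the amplicon, plus fine bins across it
  seg <- data.table::rbindlist(lapply(autosomes, function(ch) {
    data.table::data.table(chrom = ch, start = 0,
                           end = genome$lengths[[ch]])
  }))
  amp_bins <- NULL
  if (!is.null(amp)) {
    pre <- seg[seg$chrom == amp$chrom]
    seg <- seg[seg$chrom != amp$chrom]
    pieces <- data.table::data.table(
      chrom = amp$chrom, start = c(0, amp$end),
      end = c(amp$start, genome$lengths[[amp$chrom]]))
    seg <- data.table::rbindlist(list(seg, pieces[pieces$end > pieces$start]))
    bin <- 1000
    bs <- seq(amp$start, amp$end - 1, by = bin)
    amp_bins <- data.table::data.table(chrom = amp$chrom, start = bs,
                                       end = pmin(bs + bin, amp$end))
    amp_bins[, "mult" := 1]
  }
  seg[, "w" := seg$end - seg$start]
  if (!is.null(amp_bins)) amp_bins[, "w" := amp_bins$end - amp_bins$start]

  if (tumor) {
    p_chrM <- config$p_chrM_normal * config$chrM_depletion_factor
    hyper <- rdt$region_id %in% hyper_ids
    w_reg[hyper] <- w_reg[hyper] * config$hyper_factor
    hist <- rdt$class == "histone"
    w_reg[hist] <- w_reg[hist] * config$histone_factor
    if (!is.null(amp)) {
      inside <- rdt$chrom == amp$chrom & rdt$center >= amp$start &
        rdt$center < amp$end
      w_reg[inside] <- w_reg[inside] * amp$copy_number *
        summit_profile(rdt$center[inside], config$summits)
      mid <- (amp_bins$start + amp_bins$end) / 2
      amp_bins[, "mult" := amp$copy_number * summit_profile(mid, config$summits)]
    }
  }
  # background weight proportional to bp, amplicon bins carry multipliers
  bg_w <- seg$w
  bin_w <- if (!is.null(amp_bins)) amp_bins$w * amp_bins$mult else numeric()
  bg_scale <- w_bg_total / (sum(seg$w) + sum(
    if (!is.null(amp_bins)) amp_bins$w else 0))
  # note: in the tumor, amplified background gains mass relative to the
  # rest of the background, as amplified DNA does in real libraries
  bg_w <- bg_w * bg_scale
  bin_w <- bin_w * bg_scale

  # renormalize non-chrM mass to (1 - p_chrM) so chrM probability is exact
  non_chrM <- sum(w_reg) + sum(bg_w) + sum(bin_w)
  scale <- (1 - p_chrM) / non_chrM
  list(regions = rdt, w_reg = w_reg * scale,
       seg = seg, w_bg = bg_w * scale,
       amp_bins = amp_bins, w_bin = bin_w * scale,
       p_chrM = p_chrM)
}

# draw n fragments for one sample from an emission table
draw_sample <- function(config, genome, em, n, sample_id, condition,
                        pair_id, replicate) {
  fl <- config$fragment_length
  q <- config$duplicate_rate
  dup <- stats::runif(n) < q
  dup[1] <- FALSE
  n_base <- sum(!dup)

  # component index space: regions | background segments | amplicon bins | chrM
  n_reg <- length(em$w_reg)
  n_seg <- nrow(em$seg)
  n_bin <- length(em$w_bin)
  probs <- c(em$w_reg, em$w_bg, em$w_bin, em$p_chrM)
  comp <- sample.int(length(probs), n_base, replace = TRUE, prob = probs)

  chrom <- character(n_base)
  mid <- numeric(n_base)
  is_reg <- comp <= n_reg
  if (any(is_reg)) {
    ri <- comp[is_reg]
    chrom[is_reg] <- em$regions$chrom[ri]
    mid[is_reg] <- stats::rnorm(sum(is_reg), mean = em$regions$center[ri],
                                sd = em$regions$width[ri] / 4)
  }
  is_bg <- comp > n_reg & comp <= n_reg + n_seg
  if (any(is_bg)) {
    si <- comp[is_bg] - n_reg
    chrom[is_bg] <- em$seg$chrom[si]
    mid[is_bg] <- em$seg$start[si] +
      stats::runif(sum(is_bg)) * (em$seg$end[si] - em$seg$start[si])
  }
  is_bin <- comp > n_reg + n_seg & comp <= n_reg + n_seg + n_bin
  if (any(is_bin)) {
    bi <- comp[is_bin] - n_reg - n_seg
    chrom[is_bin] <- em$amp_bins$chrom[bi]
    mid[is_bin] <- em$amp_bins$start[bi] +
      stats::runif(sum(is_bin)) * (em$amp_bins$end[bi] - em$amp_bins$start[bi])
  }
  is_m <- comp == length(probs)
  if (any(is_m)) {
    chrom[is_m] <- genome$chrM
    mid[is_m] <- stats::runif(sum(is_m)) * genome$lengths[[genome$chrM]]
  }

  len <- round(stats::rnorm(n_base, fl$mean, fl$sd))
  len <- pmin(pmax(len, fl$min), fl$max)
  clen <- genome$lengths[chrom]
  len <- pmin(len, clen)  # tiny chroms cannot carry longer fragments
  start <- round(mid - len / 2)
  start <- pmin(pmax(start, 0), clen - len)
  base <- data.table::data.table(chrom = chrom, start = as.integer(start),
                                 end = as.integer(start + len))
  n_dup <- n - n_base
  out <- if (n_dup > 0) {
    src <- sample.int(n_base, n_dup, replace = TRUE)
    data.table::rbindlist(list(base, base[src]))
  } else base
  data.table::setorder(out, chrom, start, end)
  fragment_set(out, sample_id = sample_id, condition = condition,
               pair_id = pair_id, replicate = replicate, genome = genome)
}

#' Simulate one tumor/normal fragment pair with ground truth
#'
#' Draws `n_fragments` fragments for a normal and a tumor sample from the
#' mixture described in [sim_config()], and returns the planted-effect
#' ledger (`truth`) used by tests: hypertranscribed cCRE ids, per-region
#' emission weights for both conditions, amplicon/summit geometry, the
#' expected chrM fractions, and the planted multipliers.
#'
#' @param config a [sim_config()].
#' @param genome,regions output of [make_genome()] under the same config.
#' @param seed seed for this pair (defaults to `config$seed`); distinct
#'   seeds give independent replicate pairs from the same world.
#' @param pair_id,replicate metadata stamped on both samples.
#' @return list with `tumor`, `normal` (both [fragment_set()]) and
#'   `truth` (class `sim_truth`).
#' @export
simulate_pair <- function(config, genome, regions, seed = config$seed,
                          pair_id = "pair1", replicate = "rep1") {
  stopifnot(inherits(config, "sim_config"),
            inherits(genome, "genome_spec"))
  if (length(regions) == 0) stop("simulate_pair: empty region set")
  if (config$n_fragments <= 0) stop("n_fragments must be positive")

  rdt <- regions_to_dt(regions)
  ccre_ids <- rdt$region_id[rdt$class != "histone"]
  truth_env <- with_seed(seed, {
    hyper_ids <- if (!is.null(config$hyper_ids)) {
      missing <- setdiff(config$hyper_ids, ccre_ids)
      if (length(missing)) stop("unknown hyper_ids: ", missing[1])
      config$hyper_ids
    } else {
      n_h <- round(config$hyper_fraction * length(ccre_ids))
      sample(ccre_ids, n_h)
    }
    em_n <- build_emission(config, genome, regions, tumor = FALSE,
                           hyper_ids = hyper_ids)
    em_t <- build_emission(config, genome, regions, tumor = TRUE,
                           hyper_ids = hyper_ids)
    normal <- draw_sample(config, genome, em_n, config$n_fragments,
                          sample_id = paste0(pair_id, "_normal"),
                          condition = "normal", pair_id, replicate)
    tumor <- draw_sample(config, genome, em_t, config$n_fragments,
                         sample_id = paste0(pair_id, "_tumor"),
                         condition = "tumor", pair_id, replicate)
    list(hyper_ids = hyper_ids, em_n = em_n, em_t = em_t,
         normal = normal, tumor = tumor)
  })
  truth <- structure(list(
    hyper_ccre_ids = sort(truth_env$hyper_ids),
    region_weights = data.table::data.table(
      region_id = rdt$region_id,
      w_normal = truth_env$em_n$w_reg,
      w_tumor = truth_env$em_t$w_reg),
    amplicon = config$amplicon,
    summits = config$summits,
    chrM_expected = c(normal = config$p_chrM_normal,
                      tumor = config$p_chrM_normal *
                        config$chrM_depletion_factor),
    hyper_factor = config$hyper_factor,
    histone_factor = config$histone_factor), class = "sim_truth")
  list(tumor = truth_env$tumor, normal = truth_env$normal, truth = truth)
}

#' Write simulator outputs to plain-text files
#'
#' Fragments as BED3, the truth ledger as JSON, the genome as a
#' chrom-sizes file, regions as 5-column BED and the config as YAML.
#'
#' @param sim result of [simulate_pair()].
#' @param genome,regions,config the matching simulator inputs.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, genome, regions, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fragments(sim$tumor, file.path(dir, "tumor.bed"))
  write_fragments(sim$normal, file.path(dir, "normal.bed"))
  write_chrom_sizes(genome, file.path(dir, "genome.chrom.sizes"))
  write_regions(regions, file.path(dir, "regions.bed"))
  truth <- sim$truth
  truth$region_weights <- as.list(truth$region_weights)
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg <- unclass(config)
  cfg$ccre_class_mix <- as.list(cfg$ccre_class_mix)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
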