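# shared amplicon world: 2x copy gain over chr2:300k-600k, no summit
amp_world <- function(copy_number = 2, summits = list(), n = 100000,
                      seed = 51) {
  sim_config(hyper_factor = 1, hyper_fraction = 0,
             chrM_depletion_factor = 1, histone_factor = 1,
             duplicate_rate = 0, n_fragments = n, seed = seed,
             amplicon = list(chrom = "chr2", start = 300000, end = 600000,
                             copy_number = copy_number),
             summits = summits)
}

test_that("tile_counts sums bins correctly (per-bp oracle)", {
  g <- genome_spec("chr1", 100000)
  # uniform track: every full 1 kb bin sums to 1000
  s <- seq(0, 99900, by = 100)
  tru <- make_track(frags(rep("chr1", 1000), s, s + 100), g)
  tc <- tile_counts(tru, tru, list(chrom = "chr1", start = 0, end = 100000))
  expect_equal(nrow(tc$bins), 100)
  expect_true(all(abs(tc$bins$tumor - 1000) < 1e-9))
  expect_identical(tc$bins$tumor, tc$bins$normal)

  # single 10-bp fragment: the covering bin carries the whole mass
  g2 <- genome_spec("chr1", 100)
  tr1 <- make_track(frags("chr1", 0, 10), g2)
  tc2 <- tile_counts(tr1, tr1, list(chrom = "chr1", start = 0, end = 100),
                     bin_size = 20)
  expect_equal(tc2$bins$tumor, c(100, 0, 0, 0, 0))
  expect_error(tile_counts(tr1, tr1, list(chrom = "chr1", start = 0,
                                          end = 100), bin_size = 0),
               "bin_size")
  # partial final bin allowed
  tc3 <- tile_counts(tr1, tr1, list(chrom = "chr1", start = 0, end = 90),
                     bin_size = 40)
  expect_equal(tc3$bins$end - tc3$bins$start, c(40, 40, 10))
})

test_that("loess_fit reproduces quadratics and reduces noise", {
  x <- seq_len(80)
  y <- 2 + 0.5 * x + 0.01 * x^2
  for (span in c(0.2, 0.5)) {
    fit <- loess_fit(y, span = span)
    expect_lt(max(abs(fit - y) / abs(y)), 1e-6)
  }
  # constant series untouched
  expect_equal(loess_fit(rep(3, 50), span = 0.3), rep(3, 50))
  # variance reduction on noisy quadratic, 20 seeds
  sigma <- 5
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    noisy <- y + rnorm(length(y), 0, sigma)
    sm <- loess_fit(noisy, span = 0.5)
    sqrt(mean((sm - y)^2)) < sigma
  }, TRUE)
  expect_true(all(wins))
  expect_error(loess_fit(1:5), "at least 10")
  expect_error(loess_fit(1:20, span = 0), "span")
  # tiny neighborhoods fall back to degree 1 with a message
  expect_message(loess_fit(seq_len(20) + 0, span = 0.1), "degree 1")
})

test_that("copy-number linearity: planted a recovered by in/out ratio", {
  for (a in c(1.5, 2, 3)) {
    cfg <- amp_world(copy_number = a, n = 100000, seed = 50 + a * 10)
    gm <- make_genome(cfg)
    sim <- simulate_pair(cfg, gm$genome, gm$regions)
    tt <- make_track(sim$tumor, gm$genome)
    tn <- make_track(sim$normal, gm$genome)
    tc <- tile_counts(tt, tn, list(chrom = "chr2", start = 0, end = 1e6))
    inside <- tc$bins$start >= 3e5 & tc$bins$end <= 6e5
    ratio_in <- sum(tc$bins$tumor[inside]) / sum(tc$bins$normal[inside])
    ratio_out <- sum(tc$bins$tumor[!inside]) / sum(tc$bins$normal[!inside])
    expect_equal(ratio_in / ratio_out, a, tolerance = 0.1)
  }
})

test_that("amplicon boundaries recovered from the smoothed excess", {
  cfg <- amp_world(copy_number = 3, n = 200000, seed = 61)
  gm <- make_genome(cfg)
  sim <- simulate_pair(cfg, gm$genome, gm$regions)
  tc <- tile_counts(make_track(sim$tumor, gm$genome),
                    make_track(sim$normal, gm$genome),
                    list(chrom = "chr2", start = 150000, end = 750000),
                    span = 0.2)
  excess <- tc$bins$tumor_smooth - tc$bins$normal_smooth
  half <- (max(excess) + min(excess)) / 2
  above <- which(excess > half)
  left_bp <- tc$bins$start[min(above)]
  right_bp <- tc$bins$end[max(above)]
  # half-height crossings of the smoothed step sit near the true bounds;
  # span 0.2 over 600 bins blurs edges by ~tens of kb, so allow 25 kb
  expect_lt(abs(left_bp - 300000), 25000)
  expect_lt(abs(right_bp - 600000), 25000)
})

# denser fine-grained regulatory terrain for summit localization: many
# small elements plus substantial diffuse background so the broad bump
# rides a smooth landscape, as a 1-Mb locus does at pooled depth
dense_amp_world <- function(summits, n = 400000, seed = 71,
                            copy_number = 2) {
  sim_config(hyper_factor = 1, hyper_fraction = 0,
             chrM_depletion_factor = 1, histone_factor = 1,
             duplicate_rate = 0, n_fragments = n, seed = seed,
             n_ccres = 4000, ccre_width = 200, p_background = 0.3,
             amplicon = list(chrom = "chr2", start = 300000, end = 600000,
                             copy_number = copy_number),
             summits = summits)
}

test_that("planted summits are detected centered on their promoters", {
  # 50-kb-sd Gaussian summit, 3x multiplier, on a promoter at 450 kb
  cfg <- dense_amp_world(list(list(center = 450000, width_sd = 50000,
                                   extra = 3)), seed = 71)
  gm <- make_genome(cfg)
  sim <- simulate_pair(cfg, gm$genome, gm$regions)
  tc <- tile_counts(make_track(sim$tumor, gm$genome),
                    make_track(sim$normal, gm$genome),
                    list(chrom = "chr2", start = 150000, end = 750000),
                    span = 0.2)
  anchors <- region_set("chr2", 449500, 450500, region_id = "promoter")
  sm <- detect_summits(tc, anchors = anchors)
  expect_gte(nrow(sm), 1)
  top <- sm[which.max(sm$prominence)]
  expect_lt(abs(top$center - 450000), 5000)
  expect_lt(abs(top$anchor_offset), 5000)
  # FWHM of the planted Gaussian is 2.355 * 50 kb ~ 118 kb; accept 2x
  expect_lt(top$width_at_half_prominence, 2 * 118000)
  # flat excess -> no summits
  flat <- tc
  flat$bins$tumor_smooth <- 1
  flat$bins$normal_smooth <- 1
  expect_equal(nrow(detect_summits(flat)), 0)
})

test_that("two well-separated summits are both recovered", {
  cfg <- amp_world(copy_number = 2,
                   summits = list(list(center = 370000, width_sd = 20000,
                                       extra = 2),
                                  list(center = 530000, width_sd = 20000,
                                       extra = 2)),
                   n = 200000, seed = 81)
  gm <- make_genome(cfg)
  sim <- simulate_pair(cfg, gm$genome, gm$regions)
  tc <- tile_counts(make_track(sim$tumor, gm$genome),
                    make_track(sim$normal, gm$genome),
                    list(chrom = "chr2", start = 200000, end = 700000),
                    span = 0.2)
  sm <- detect_summits(tc)
  sm <- sm[order(-sm$prominence)][1:2]
  centers <- sort(sm$center)
  expect_lt(abs(centers[1] - 370000), 10000)
  expect_lt(abs(centers[2] - 530000), 10000)
})

test_that("window_fold_change measures planted window multipliers", {
  cfg <- amp_world(copy_number = 2, n = 100000, seed = 91)
  gm <- make_genome(cfg)
  sim <- simulate_pair(cfg, gm$genome, gm$regions)
  tt <- make_track(sim$tumor, gm$genome)
  tn <- make_track(sim$normal, gm$genome)
  expect_equal(window_fold_change(tt, tt,
                                  list(chrom = "chr2", start = 3e5,
                                       end = 6e5)), 1)
  # outside the amplicon both samples lose the same renormalized share,
  # so the ratio equals the tumor renormalization factor, below 1
  out <- window_fold_change(tt, tn, list(chrom = "chr1", start = 0,
                                         end = 1e6))
  expect_lt(out, 1)
  # in a fully null world any window ratio is ~1
  cfg0 <- amp_world(copy_number = 1, n = 50000, seed = 92)
  gm0 <- make_genome(cfg0)
  sim0 <- simulate_pair(cfg0, gm0$genome, gm0$regions)
  null_r <- window_fold_change(make_track(sim0$tumor, gm0$genome),
                               make_track(sim0$normal, gm0$genome),
                               list(chrom = "chr1", start = 0, end = 1e6))
  expect_equal(null_r, 1, tolerance = 0.05)
  # zero normal signal flagged
  empty_win <- list(chrom = "chrM", start = 15900, end = 16000)
  tn0 <- tn
  tn0$values$chrM <- S4Vectors::Rle(0, 16000)
  expect_warning(res <- window_fold_change(tt, tn0, empty_win), "zero")
  expect_true(is.na(res))
})
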