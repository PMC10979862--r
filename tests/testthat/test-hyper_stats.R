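# shared small simulated pair for the statistics tests
local_pair <- local({
  cfg <- fast_config(n_fragments = 30000, duplicate_rate = 0, seed = 31)
  gm <- make_genome(cfg)
  sim <- simulate_pair(cfg, gm$genome, gm$regions)
  ccre <- gm$regions[S4Vectors::mcols(gm$regions)$class != "histone"]
  tt <- make_track(sim$tumor, gm$genome)
  tn <- make_track(sim$normal, gm$genome)
  list(cfg = cfg, gm = gm, sim = sim, ccre = ccre,
       pr = pair_diff(region_signal(tt, ccre), region_signal(tn, ccre)))
})

test_that("pair_diff computes Bland-Altman and MA fields coherently", {
  pr <- local_pair$pr
  expect_equal(pr$diff, pr$T - pr$N)
  expect_equal(pr$avg, (pr$T + pr$N) / 2)
  expect_true(all(sort(pr$rank_by_absdiff) == seq_len(nrow(pr))))
  # antisymmetry under argument swap
  tt <- make_track(local_pair$sim$tumor, local_pair$gm$genome)
  tn <- make_track(local_pair$sim$normal, local_pair$gm$genome)
  rev <- pair_diff(region_signal(tn, local_pair$ccre),
                   region_signal(tt, local_pair$ccre))
  expect_equal(rev$diff, -pr$diff)
  # identical inputs -> all zero
  same <- pair_diff(region_signal(tt, local_pair$ccre),
                    region_signal(tt, local_pair$ccre))
  expect_true(all(same$diff == 0))
  expect_true(all(same$log2_fc == 0))
  # id mismatch rejected
  shuffled <- region_signal(tn, rev(local_pair$ccre))
  expect_error(pair_diff(region_signal(tt, local_pair$ccre), shuffled),
               "do not match")
})

test_that("planted hypertranscribed cCREs separate from the rest", {
  pr <- local_pair$pr
  planted <- pr$region_id %in% local_pair$sim$truth$hyper_ccre_ids
  expect_gt(mean(pr$diff[planted]), mean(pr$diff[!planted]))
  w <- stats::wilcox.test(pr$diff[planted], pr$diff[!planted],
                          alternative = "greater")
  expect_lt(w$p.value, 0.01)
})

test_that("rank_regions sorts by the requested key with stable ties", {
  pr3 <- local_pair$pr[1:3]
  pr3$diff <- c(3, -5, 1)
  expect_equal(rank_regions(pr3, "absdiff")$diff, c(-5, 3, 1))
  up <- rank_regions(pr3, "tumor_minus_normal")$diff
  down <- rank_regions(pr3, "normal_minus_tumor")$diff
  expect_equal(up, rev(down))
  # planted enrichment in the top decile of the T - N ranking
  pr <- local_pair$pr
  ranked <- rank_regions(pr, "tumor_minus_normal")
  k <- ceiling(nrow(ranked) / 10)
  top_ids <- ranked$region_id[seq_len(k)]
  planted <- local_pair$sim$truth$hyper_ccre_ids
  tab <- table(top = pr$region_id %in% top_ids,
               planted = pr$region_id %in% planted)
  or <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2] + 0.5)
  expect_gt(or, 1)
})

test_that("rank_curve splits positive differences into mirror series", {
  pr <- local_pair$pr
  rc <- rank_curve(pr)
  expect_equal(rc$n_up + rc$n_down, sum(pr$diff != 0))
  expect_true(all(diff(rc$up) <= 0))
  expect_true(all(rc$down > 0))
  # hyper simulation: upregulation curve dominates
  expect_gt(sum(rc$up), sum(rc$down))
  # degenerate all-zero input
  z <- pr[1:5]
  z$diff <- 0
  rc0 <- rank_curve(z)
  expect_equal(rc0$n_up, 0)
  expect_equal(rc0$n_down, 0)
})

test_that("rank_curve is symmetric under the null world", {
  cfg <- fast_config(hyper_factor = 1, hyper_fraction = 0,
                     chrM_depletion_factor = 1, histone_factor = 1,
                     duplicate_rate = 0, n_fragments = 10000)
  gm <- make_genome(cfg)
  ccre <- gm$regions[S4Vectors::mcols(gm$regions)$class != "histone"]
  ratios <- vapply(1:20, function(s) {
    sim <- simulate_pair(cfg, gm$genome, gm$regions, seed = 500 + s)
    pr <- pair_diff(
      region_signal(make_track(sim$tumor, gm$genome), ccre),
      region_signal(make_track(sim$normal, gm$genome), ccre))
    rc <- rank_curve(pr)
    sum(rc$up) / sum(rc$down)
  }, 0)
  expect_gt(mean(ratios), 0.8)
  expect_lt(mean(ratios), 1.25)
})

test_that("max_diff_composite takes the elementwise maximum", {
  pr <- local_pair$pr
  a <- data.table::copy(pr); a$diff <- rep_len(c(2, -1, 5), nrow(pr))
  b <- data.table::copy(pr); b$diff <- rep_len(c(-1, 5, 2), nrow(pr))
  c3 <- data.table::copy(pr); c3$diff <- rep_len(c(5, 2, -1), nrow(pr))
  comp <- max_diff_composite(list(a, b, c3))
  expect_true(all(comp$max_diff == 5))
  expect_true(all(comp$max_diff >= a$diff & comp$max_diff >= b$diff))
  single <- max_diff_composite(list(pr))
  expect_equal(single$max_diff, pr$diff)
  bad <- data.table::copy(pr)[seq_len(nrow(pr) - 1)]
  expect_error(max_diff_composite(list(pr, bad)), "differ")
})

test_that("histone_excess recovers planted cluster upregulation", {
  cfg <- fast_config(histone_factor = 2, n_fragments = 30000,
                     duplicate_rate = 0)
  gm <- make_genome(cfg)
  hist <- gm$regions[S4Vectors::mcols(gm$regions)$class == "histone"]
  pairs <- lapply(1:3, function(i) {
    sim <- simulate_pair(cfg, gm$genome, gm$regions, seed = 600 + i,
                         pair_id = paste0("p", i))
    sim[c("tumor", "normal")]
  })
  hs <- histone_excess(pairs, hist, gm$genome)
  expect_true(all(hs$per_pair$excess > 0))
  expect_lt(hs$p_value, 0.05)
  # single replicate: excess reported, p undefined
  h1 <- histone_excess(pairs[1], hist, gm$genome)
  expect_true(is.finite(h1$mean_excess))
  expect_true(is.na(h1$p_value))
  # identical tumor/normal input -> excess exactly zero
  same <- list(list(tumor = pairs[[1]]$tumor, normal = pairs[[1]]$tumor))
  expect_equal(histone_excess(same, hist, gm$genome)$per_pair$excess, 0)
  expect_error(histone_excess(pairs, hist[0], gm$genome), "empty histone")
})

test_that("mito_compare reports per-pair percentages and ratio", {
  sim <- local_pair$sim
  mt <- mito_compare(list(list(tumor = sim$tumor, normal = sim$normal)),
                     local_pair$gm$genome)
  expect_equal(mt$ratio, mt$tumor_pct / mt$normal_pct)
  expect_false(mt$flagged)
  # tumor without chrM fragments -> 0%, ratio 0
  no_m <- sim$tumor
  no_m$fragments <- no_m$fragments[no_m$fragments$chrom != "chrM"]
  mt2 <- mito_compare(list(list(tumor = no_m, normal = sim$normal)),
                      local_pair$gm$genome)
  expect_equal(mt2$tumor_pct, 0)
  expect_equal(mt2$ratio, 0)
  # zero normal chrM -> flagged, ratio NA
  mt3 <- mito_compare(list(list(tumor = sim$tumor, normal = no_m)),
                      local_pair$gm$genome)
  expect_true(mt3$flagged)
  expect_true(is.na(mt3$ratio))
})
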