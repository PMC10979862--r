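#' Per-region tumor minus normal statistics
#'
#' Joins tumor and normal per-region mean normalized signal (from
#' [region_signal()], computed on fragment-count-equalized samples) into
#' one table carrying the Bland-Altman and MA quantities: the raw
#' difference `diff = T - N` (the primary hypertranscription statistic,
#' in normalized count units), the average `avg = (T + N) / 2`,
#' `log10_avg = log10(avg + eps)`, and `log2_fc = log2((T + eps) /
#' (N + eps))` with a small pseudo-value `eps` guarding zero-signal
#' regions. `rank_by_absdiff` ranks regions by `|diff|` descending (1 =
#' largest absolute difference), ties broken by (chrom, start).
#'
#' @param tumor,normal [region_signal()] tables over the same region set.
#' @param eps pseudo-value for the log scales (default 1e-6). The raw
#'   difference needs no pseudo-value and gets none.
#' @return a `data.table` (class `pair_result`): region_id, chrom, start,
#'   end, class, T, N, diff, avg, log10_avg, log2_fc, rank_by_absdiff.
#' @export
pair_diff <- function(tumor, normal, eps = 1e-6) {
  if (nrow(tumor) != nrow(normal) ||
      !identical(tumor$region_id, normal$region_id)) {
    stop("pair_diff: tumor and normal region ids do not match")
  }
  dt <- data.table::data.table(
    region_id = tumor$region_id, chrom = tumor$chrom,
    start = tumor$start, end = tumor$end, class = tumor$class,
    T = tumor$value, N = normal$value)
  dt[, "diff" := dt$T - dt$N]
  dt[, "avg" := (dt$T + dt$N) / 2]
  dt[, "log10_avg" := log10(dt$avg + eps)]
  dt[, "log2_fc" := log2((dt$T + eps) / (dt$N + eps))]
  ord <- order(-abs(dt$diff), dt$chrom, dt$start)
  rk <- integer(nrow(dt))
  rk[ord] <- seq_len(nrow(dt))
  dt[, "rank_by_absdiff" := rk]
  data.table::setattr(dt, "class", c("pair_result", class(dt)))
  dt[]
}

#' Rank regions by tumor/normal difference
#'
#' Stable descending sort by the chosen key: `absdiff` (largest absolute
#' differences first, the ordering used to pick top hypertranscribed
#' elements), `tumor_minus_normal` (global upregulation) or
#' `normal_minus_tumor` (global downregulation). Ties are broken by
#' (chrom, start) so the ordering is reproducible.
#'
#' @param pr a [pair_diff()] result.
#' @param mode ranking key.
#' @return the reordered `pair_result`.
#' @export
rank_regions <- function(pr, mode = c("absdiff", "tumor_minus_normal",
                                      "normal_minus_tumor")) {
  mode <- match.arg(mode)
  key <- switch(mode, absdiff = abs(pr$diff), tumor_minus_normal = pr$diff,
                normal_minus_tumor = -pr$diff)
  pr[order(-key, pr$chrom, pr$start)]
}

#' Rank-ordered difference curves
#'
#' Two descending series for log-scale display: positive T - N
#' differences sorted decreasing (upregulation curve) and positive N - T
#' differences sorted decreasing (downregulation curve). Under a null of
#' no hypertranscription the two curves should be near-mirror images;
#' genome-wide upregulation makes the first dominate.
#'
#' @param pr a [pair_diff()] result.
#' @return list with numeric vectors `up` and `down` and their lengths
#'   `n_up`, `n_down`.
#' @export
rank_curve <- function(pr) {
  up <- sort(pr$diff[pr$diff > 0], decreasing = TRUE)
  down <- sort(-pr$diff[pr$diff < 0], decreasing = TRUE)
  list(up = up, down = down, n_up = length(up), n_down = length(down))
}

#' Cross-pair maximum difference composite
#'
#' Elementwise maximum of `diff` across several tumor/normal pairs on the
#' same region set — the "max diffs" composite used to summarize which
#' elements are hypertranscribed in at least one tumor.
#'
#' @param prs list of [pair_diff()] results on identical region sets.
#' @return a `data.table`: region_id, chrom, start, end, class, max_diff.
#' @export
max_diff_composite <- function(prs) {
  stopifnot(length(prs) >= 1)
  ids <- prs[[1]]$region_id
  for (p in prs[-1]) {
    if (!identical(p$region_id, ids)) {
      stop("max_diff_composite: region sets differ between pairs")
    }
  }
  m <- do.call(cbind, lapply(prs, `[[`, "diff"))
  out <- prs[[1]][, c("region_id", "chrom", "start", "end", "class"),
                  with = FALSE]
  out[, "max_diff" := apply(m, 1, max)]
  out[]
}

#' Histone-cluster excess with paired t-test
#'
#' The replication-coupled histone gene proxy for proliferation: for each
#' replicate pair, the summed normalized counts over the histone regions
#' in the normal sample are subtracted from those in the tumor sample
#' (sum, not mean). Across replicate pairs the mean excess, its SD and a
#' two-sided paired t-test are reported; the p-value is only defined for
#' two or more replicates.
#'
#' @param pairs list of `list(tumor = fragment_set, normal =
#'   fragment_set)` replicate pairs.
#' @param histones non-empty histone region `GRanges`.
#' @param genome a [genome_spec()].
#' @param equalize_seed when non-`NULL`, each pair is fragment-count
#'   equalized with [downsample_equalize()] first.
#' @return list of class `histone_stat`: per_pair (data.table pair,
#'   tumor_sum, normal_sum, excess), mean_excess, sd_excess, t_stat, p_value.
#' @export
histone_excess <- function(pairs, histones, genome, equalize_seed = NULL) {
  if (length(histones) == 0) stop("histone_excess: empty histone set")
  stopifnot(length(pairs) >= 1)
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    if (!is.null(equalize_seed)) {
      eq <- downsample_equalize(p$tumor, p$normal,
                                seed = equalize_seed + i)
      p <- list(tumor = eq$a, normal = eq$b)
    }
    ts <- sum(region_sum(make_track(p$tumor, genome), histones)$value)
    ns <- sum(region_sum(make_track(p$normal, genome), histones)$value)
    data.table::data.table(pair = p$tumor$pair_id, tumor_sum = ts,
                           normal_sum = ns, excess = ts - ns)
  })
  per_pair <- data.table::rbindlist(rows)
  ex <- per_pair$excess
  res <- list(per_pair = per_pair, mean_excess = mean(ex),
              sd_excess = if (length(ex) >= 2) stats::sd(ex) else NA_real_,
              t_stat = NA_real_, p_value = NA_real_)
  if (length(ex) >= 2 && stats::sd(ex) > 0) {
    tt <- stats::t.test(ex, mu = 0, alternative = "two.sided")
    res$t_stat <- unname(tt$statistic)
    res$p_value <- tt$p.value
  }
  structure(res, class = "histone_stat")
}

#' @export
print.histone_stat <- function(x, ...) {
  cat("histone excess over", nrow(x$per_pair), "replicate pair(s):\n")
  cat("  mean excess =", signif(x$mean_excess, 4),
      "normalized count units, SD =", signif(x$sd_excess, 4), "\n")
  if (!is.na(x$p_value)) {
    cat("  paired t =", signif(x$t_stat, 4), ", two-sided p =",
        signif(x$p_value, 3), "\n")
  }
  invisible(x)
}

#' Mitochondrial fraction comparison across pairs
#'
#' Per pair: tumor and normal chrM percentages (via [chrM_fraction()])
#' and their ratio. A depleted mitochondrial signal in the tumor gives a
#' ratio below 1. A zero normal percentage leaves the ratio `NA` with
#' `flagged = TRUE`.
#'
#' @param pairs list of `list(tumor =, normal =)` [fragment_set()] pairs.
#' @param genome a [genome_spec()] with chrM designated.
#' @return data.table: pair, tumor_pct, normal_pct, ratio, flagged.
#' @export
mito_compare <- function(pairs, genome) {
  rows <- lapply(pairs, function(p) {
    tp <- chrM_fraction(p$tumor, genome)
    np <- chrM_fraction(p$normal, genome)
    data.table::data.table(
      pair = p$tumor$pair_id, tumor_pct = tp, normal_pct = np,
      ratio = if (np == 0) NA_real_ else tp / np, flagged = np == 0)
  })
  data.table::rbindlist(rows)
}
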