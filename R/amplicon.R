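#' Tile a window with bins and sum tumor/normal signal
#'
#' Partitions a genomic window into consecutive bins (default 1 kb; the
#' last bin may be partial) and sums normalized counts from
#' count-equalized tumor and normal tracks within each bin. The binned
#' series are then smoothed by [loess_fit()] at the configured span,
#' producing the curve pair used for amplicon and broad-summit
#' inspection.
#'
#' @param tumor,normal [make_track()] tracks on the same genome.
#' @param window list(chrom, start, end) in BED convention.
#' @param bin_size bin width in bp (default 1000).
#' @param span smoothing span as a fraction of bins (default 0.2;
#'   0.5 gives the heavier smoothing used for zoomed summit overlays).
#' @return list of class `tile_curve`: window, bin_size, span, and a
#'   data.table `bins` with chrom, start, end, tumor, normal,
#'   tumor_smooth, normal_smooth.
#' @export
tile_counts <- function(tumor, normal, window, bin_size = 1000,
                        span = 0.2) {
  stopifnot(inherits(tumor, "coverage_track"),
            inherits(normal, "coverage_track"))
  if (bin_size <= 0) stop("bin_size must be positive")
  ch <- window$chrom
  if (!ch %in% names(tumor$values)) stop("window chromosome unknown: ", ch)
  len <- tumor$genome$lengths[[ch]]
  if (window$start < 0 || window$end > len || window$start >= window$end) {
    stop("window outside genome bounds")
  }
  bs <- seq(window$start, window$end - 1, by = bin_size)
  be <- pmin(bs + bin_size, window$end)
  sum_bins <- function(track) {
    vw <- IRanges::Views(track$values[[ch]], start = bs + 1, end = be)
    IRanges::viewSums(vw)
  }
  bins <- data.table::data.table(chrom = ch, start = bs, end = be,
                                 tumor = sum_bins(tumor),
                                 normal = sum_bins(normal))
  if (nrow(bins) >= 10) {
    bins[, "tumor_smooth" := loess_fit(bins$tumor, span = span)]
    bins[, "normal_smooth" := loess_fit(bins$normal, span = span)]
  } else {
    bins[, "tumor_smooth" := bins$tumor]
    bins[, "normal_smooth" := bins$normal]
  }
  structure(list(window = window, bin_size = bin_size, span = span,
                 bins = bins), class = "tile_curve")
}

#' Local polynomial regression smoothing
#'
#' Classic LOESS on an equally spaced series: for each point, a weighted
#' quadratic is fitted over the `ceiling(span * n)` nearest points with
#' tricube weights `w = (1 - (d / dmax)^3)^3`, and the fitted value at
#' the point is returned. A noiseless quadratic input is reproduced
#' exactly; when the local neighborhood is too small for a quadratic the
#' degree falls back to 1 (with a message).
#'
#' @param y numeric series (length >= 10).
#' @param span fraction of points in each local neighborhood, in (0, 1].
#' @return smoothed series, same length as `y`.
#' @export
loess_fit <- function(y, span = 0.2) {
  n <- length(y)
  if (n < 10) stop("loess_fit: need at least 10 points")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  k <- max(2L, as.integer(ceiling(span * n)))
  degree <- 2L
  if (k < 3L) {
    message("loess_fit: neighborhood too small for quadratic; using degree 1")
    degree <- 1L
  }
  x <- seq_len(n)
  out <- numeric(n)
  for (i in x) {
    d <- abs(x - i)
    nb <- order(d)[seq_len(k)]
    dmax <- max(d[nb])
    w <- if (dmax > 0) (1 - (d[nb] / dmax)^3)^3 else rep(1, k)
    w[w < 0] <- 0
    xc <- x[nb] - i
    X <- if (degree == 2L) cbind(1, xc, xc^2) else cbind(1, xc)
    fit <- tryCatch(stats::lm.wfit(X, y[nb], w),
                    error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) {
      fit <- stats::lm.wfit(cbind(1, xc), y[nb], w)   # degree-1 fallback
    }
    out[i] <- fit$coefficients[1]
  }
  out
}

#' Detect broad summits of smoothed tumor excess
#'
#' Operates on the smoothed tumor minus smoothed normal series of a
#' [tile_counts()] curve: local maxima whose prominence (height above
#' the lower of the two flanking minima) reaches `min_prominence` are
#' reported, with their width at half prominence and, when promoter
#' anchors are supplied, the offset from the nearest anchor midpoint —
#' how precisely each broad summit centers on a promoter peak.
#'
#' @param tc a [tile_counts()] result.
#' @param min_prominence minimum prominence in normalized count units;
#'   default `NULL` uses 2 x the median absolute deviation of the excess
#'   series.
#' @param anchors optional region `GRanges` of promoter peaks.
#' @return data.table: center (bp), height, prominence,
#'   width_at_half_prominence (bp), anchor_offset (bp or NA).
#' @export
detect_summits <- function(tc, min_prominence = NULL, anchors = NULL) {
  stopifnot(inherits(tc, "tile_curve"))
  b <- tc$bins
  excess <- b$tumor_smooth - b$normal_smooth
  n <- length(excess)
  if (is.null(min_prominence)) {
    min_prominence <- 2 * stats::mad(excess)
  }
  empty <- data.table::data.table(center = numeric(), height = numeric(),
                                  prominence = numeric(),
                                  width_at_half_prominence = numeric(),
                                  anchor_offset = numeric())
  if (n < 3) return(empty)
  is_max <- which(diff(sign(diff(excess))) < 0) + 1L
  if (length(is_max) == 0) return(empty)
  rows <- lapply(is_max, function(i) {
    h <- excess[i]
    # flanking minima: lowest point between this summit and the previous /
    # next local maximum (or series edge)
    left_bound <- max(c(1L, is_max[is_max < i]))
    right_bound <- min(c(n, is_max[is_max > i]))
    left_min <- min(excess[left_bound:i])
    right_min <- min(excess[i:right_bound])
    prom <- h - min(left_min, right_min)
    if (prom < min_prominence) return(NULL)
    half <- h - prom / 2
    li <- i
    while (li > 1 && excess[li - 1] >= half) li <- li - 1
    ri <- i
    while (ri < n && excess[ri + 1] >= half) ri <- ri + 1
    center_bp <- (b$start[i] + b$end[i]) / 2
    data.table::data.table(
      center = center_bp, height = h, prominence = prom,
      width_at_half_prominence = b$end[ri] - b$start[li],
      anchor_offset = NA_real_)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(empty)
  out <- data.table::rbindlist(rows)
  if (!is.null(anchors) && length(anchors) > 0) {
    on_ch <- anchors[as.character(GenomicRanges::seqnames(anchors)) ==
                       tc$window$chrom]
    if (length(on_ch) > 0) {
      mids <- (GenomicRanges::start(on_ch) - 1 +
                 GenomicRanges::end(on_ch)) / 2
      out[, "anchor_offset" := vapply(out$center, function(cc) {
        d <- cc - mids
        d[which.min(abs(d))]
      }, 0)]
    }
  }
  out[]
}

#' Window fold change between tumor and normal
#'
#' Ratio of summed normalized counts in a genomic window, tumor over
#' normal — the statistic used to report e.g. a 5.4-fold promoter-window
#' increase. Requires positive normal signal in the window; a zero
#' denominator yields `NA` with a warning.
#'
#' @param tumor,normal [make_track()] tracks.
#' @param window list(chrom, start, end), BED convention.
#' @return numeric ratio (possibly `NA`).
#' @export
window_fold_change <- function(tumor, normal, window) {
  reg <- region_set(window$chrom, window$start, window$end,
                    region_id = "window")
  ts <- region_sum(tumor, reg)$value
  ns <- region_sum(normal, reg)$value
  if (ns <= 0) {
    warning("window_fold_change: zero normal signal in window")
    return(NA_real_)
  }
  ts / ns
}
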