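#' Signal blocks of a coverage track
#'
#' A signal block is a maximal run of strictly positive track values
#' (flanked by zero signal or a chromosome edge). Each block carries its
#' AUC (summed normalized counts over the block) and maximum height —
#' the statistics thresholded during sparse-enrichment peak calling.
#'
#' @param track a [make_track()] coverage track.
#' @return data.table sorted by (chrom, start): chrom, start, end (BED
#'   half-open), auc, max_height. Empty for an all-zero track.
#' @export
find_blocks <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  rows <- lapply(names(track$values), function(ch) {
    r <- track$values[[ch]]
    vw <- IRanges::slice(r, lower = 0, includeLower = FALSE)
    if (length(vw) == 0) return(NULL)
    data.table::data.table(
      chrom = ch,
      start = IRanges::start(vw) - 1L,
      end = IRanges::end(vw),
      auc = IRanges::viewSums(vw),
      max_height = IRanges::viewMaxs(vw))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), auc = numeric(),
                                  max_height = numeric()))
  }
  dt <- data.table::rbindlist(rows)
  data.table::setorder(dt, chrom, start)
  dt[]
}

#' Paired-control sparse-enrichment peak calling
#'
#' Calls peaks on a target track against a matched control track (here:
#' tumor against its paired normal), in the spirit of sparse-enrichment
#' callers for low-depth tagmentation data. The procedure:
#'
#' 1. the control is scaled by `s = sum(target) / sum(control)` so both
#'    tracks carry equal total signal ("norm");
#' 2. signal blocks and their AUCs are computed on each track;
#' 3. over candidate thresholds `t` drawn from the merged sorted multiset
#'    of block AUCs, the gain `gain(t) = frac_target(auc > t) -
#'    frac_control(s * auc > t)` measures how much more of the target
#'    block population than the control block population survives `t`.
#'    Because a raw ECDF difference is dominated by sampling noise at
#'    thresholds retaining nearly all blocks (a spurious `+1/N` spike at
#'    the bottom of the distribution would admit the entire genome), the
#'    threshold is selected by the standardized gain `z(t) = gain(t) /
#'    SE(gain(t))` with the binomial standard error
#'    `SE = sqrt(f_t(1-f_t)/N_t + f_c(1-f_c)/N_c)`;
#' 4. `stringent` picks the smallest `t` maximizing `z`; `relaxed` picks
#'    the smallest `t` achieving at least `relax_frac` (default 0.9) of
#'    the maximum `z` — a more permissive threshold admitting more peaks;
#' 5. peaks are the target blocks with `auc > t*`. If no candidate
#'    reaches `z_min` (default 3.5, a multiplicity-adjusted floor for the
#'    ~2N correlated candidates scanned), the target is not separable
#'    from its control and no peaks are returned — in particular when
#'    target and control are identical.
#'
#' Swapping target and control probes the opposite tail: with genuine
#' hypertranscription the reversed call yields few or no peaks.
#'
#' @param target,control [make_track()] tracks on the same genome.
#' @param mode `"relaxed"` (default) or `"stringent"`.
#' @param relax_frac fraction of the maximum standardized gain the
#'   relaxed threshold must reach (default 0.9).
#' @param z_min significance floor on the standardized gain below which
#'   no peaks are called (default 3.5).
#' @return list of class `peak_call`: `peaks` (block table as
#'   [find_blocks()]), `threshold_auc`, `control_scale`,
#'   `n_target_blocks`, `n_control_blocks`, `mode`, `max_gain`, `max_z`.
#' @export
call_peaks <- function(target, control, mode = c("relaxed", "stringent"),
                       relax_frac = 0.9, z_min = 3.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(target, "coverage_track"),
            inherits(control, "coverage_track"))
  if (!identical(names(target$values), names(control$values))) {
    stop("call_peaks: target and control on different genomes")
  }
  tsum <- track_sum(target)
  csum <- track_sum(control)
  if (csum <= 0) stop("call_peaks: empty control track")
  s <- tsum / csum
  tb <- find_blocks(target)
  cb <- find_blocks(control)
  empty <- function(mz) list(
    peaks = tb[0], threshold_auc = Inf, control_scale = s,
    n_target_blocks = nrow(tb), n_control_blocks = nrow(cb),
    mode = mode, max_gain = 0, max_z = mz)
  if (nrow(tb) == 0 || nrow(cb) == 0) {
    return(structure(empty(NA_real_), class = "peak_call"))
  }
  ca <- cb$auc * s
  cand <- sort(unique(c(tb$auc, ca)))
  # frac of blocks strictly above each candidate threshold
  frac_above <- function(auc, t) {
    n <- length(auc)
    (n - findInterval(t, sort(auc))) / n
  }
  ft <- frac_above(tb$auc, cand)
  fc <- frac_above(ca, cand)
  gain <- ft - fc
  se <- sqrt(ft * (1 - ft) / nrow(tb) + fc * (1 - fc) / nrow(cb))
  z <- ifelse(se > 0, gain / se, 0)
  mz <- max(z)
  if (mz < z_min) return(structure(empty(mz), class = "peak_call"))
  tstar <- if (mode == "stringent") {
    cand[which.max(z)]                      # smallest t on ties: which.max
  } else {
    cand[which(z >= relax_frac * mz)[1]]
  }
  peaks <- tb[tb$auc > tstar]
  structure(list(peaks = peaks, threshold_auc = tstar, control_scale = s,
                 n_target_blocks = nrow(tb), n_control_blocks = nrow(cb),
                 mode = mode, max_gain = max(gain), max_z = mz),
            class = "peak_call")
}

#' @export
print.peak_call <- function(x, ...) {
  cat("peak_call (", x$mode, "): ", nrow(x$peaks), " peaks, threshold AUC ",
      signif(x$threshold_auc, 4), ", max z ", signif(x$max_z, 3),
      "\n", sep = "")
  invisible(x)
}

#' Write peaks as BED6-style text
#' @param call a [call_peaks()] result.
#' @param path output path; columns chrom, start, end, name, auc, ".".
#' @export
write_peaks <- function(call, path) {
  p <- call$peaks
  dt <- data.table::data.table(
    chrom = p$chrom, start = p$start, end = p$end,
    name = sprintf("peak_%05d", seq_len(nrow(p))),
    score = p$auc, strand = ".")
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Overlap of top-ranked regions with peak calls across pairs
#'
#' For each of the top `K` regions of a ranked region list, counts in how
#' many tumor/normal pairs the region overlaps (>= 1 bp) at least one
#' called peak, and reports the mean of those counts — the statistic used
#' to ask whether the most hypertranscribed elements recur across tumors.
#'
#' @param ranked a ranked `pair_result` (see [rank_regions()]) or any
#'   table with region_id, chrom, start, end in BED convention.
#' @param peakcalls named list mapping pair id to [call_peaks()] results.
#' @param K number of top regions to examine (`K <= nrow(ranked)`).
#' @return list: `per_region` (data.table region_id, n_pairs_overlapping)
#'   and `mean_overlap`.
#' @export
overlap_top_regions <- function(ranked, peakcalls, K) {
  stopifnot(K >= 1, K <= nrow(ranked), length(peakcalls) >= 1)
  top <- ranked[seq_len(K)]
  top_gr <- GenomicRanges::GRanges(
    top$chrom, IRanges::IRanges(top$start + 1L, top$end))
  counts <- integer(K)
  for (pc in peakcalls) {
    p <- pc$peaks
    if (nrow(p) == 0) next
    pg <- GenomicRanges::GRanges(p$chrom,
                                 IRanges::IRanges(p$start + 1L, p$end))
    hit <- GenomicRanges::countOverlaps(top_gr, pg, minoverlap = 1L) > 0
    counts <- counts + as.integer(hit)
  }
  list(per_region = data.table::data.table(region_id = top$region_id,
                                           n_pairs_overlapping = counts),
       mean_overlap = mean(counts))
}
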