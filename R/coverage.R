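#' Genome-scaled normalized coverage tracks
#'
#' A `coverage_track` stores per-chromosome run-length-encoded normalized
#' counts. Raw coverage c_i counts the fragments whose half-open span
#' covers base pair i; the normalized value is n_i = (c_i / T) * G where
#' T = sum_j c_j (total per-bp count mass, equal to the summed fragment
#' lengths) and G is the genome size. Uniform raw coverage therefore maps
#' to n_i = 1 everywhere, and sum_i n_i = G for every non-empty input.
#'
#' @param fs a non-empty [fragment_set()].
#' @param genome a [genome_spec()].
#' @return an object of class `coverage_track` with fields `values`
#'   (a [IRanges::RleList] of normalized per-bp values, one element per
#'   chromosome), `genome`, and `total_mass` (T).
#' @export
make_track <- function(fs, genome) {
  stopifnot(inherits(fs, "fragment_set"), inherits(genome, "genome_spec"))
  if (n_fragments(fs) == 0) stop("make_track: empty fragment set")
  dt <- fs$fragments
  validate_intervals(dt$chrom, dt$start, dt$end, genome, what = "fragment")
  covs <- lapply(genome$chroms, function(ch) {
    sub <- dt[dt$chrom == ch]
    if (nrow(sub) == 0) {
      S4Vectors::Rle(0, genome$lengths[[ch]])
    } else {
      ir <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
      IRanges::coverage(ir, width = genome$lengths[[ch]])
    }
  })
  names(covs) <- genome$chroms
  covs <- methods::as(covs, "RleList")
  total <- sum(vapply(covs, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                             S4Vectors::runLength(r)), 0))
  g <- genome_size(genome)
  norm <- methods::as(lapply(covs, function(r) r * (g / total)), "RleList")
  structure(list(values = norm, genome = genome, total_mass = total),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track over", length(x$values), "chromosomes, G =",
      format(genome_size(x$genome), big.mark = ","), "bp, raw mass =",
      format(x$total_mass, big.mark = ","), "\n")
  invisible(x)
}

#' Sum of track values (should equal G for any track from make_track)
#' @param track a [make_track()] result.
#' @export
track_sum <- function(track) {
  sum(vapply(track$values,
             function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                               S4Vectors::runLength(r)), 0))
}

# Views over the track for a set of regions; regions as GRanges
region_views <- function(track, regions) {
  chroms <- as.character(GenomicRanges::seqnames(regions))
  unknown <- setdiff(unique(chroms), names(track$values))
  if (length(unknown)) stop("regions on unknown chromosome: ", unknown[1])
  s <- GenomicRanges::start(regions)
  e <- GenomicRanges::end(regions)
  lens <- track$genome$lengths[chroms]
  if (any(e > lens) || any(s < 1)) stop("region outside genome bounds")
  list(chroms = chroms, start = s, end = e)
}

#' Per-region summed normalized counts
#'
#' Sums track values over each region (whole-bp membership; region bounds
#' are half-open BED intervals converted internally). The summed statistic
#' is the one used for histone-cluster excess; the length-averaged variant
#' is [region_signal()].
#'
#' @param track a [make_track()] coverage track.
#' @param regions region `GRanges` (see [region_set()]).
#' @return data.table: region_id, chrom, start, end, class, value.
#' @export
region_sum <- function(track, regions) {
  stopifnot(inherits(track, "coverage_track"))
  if (any(GenomicRanges::width(regions) < 1)) stop("zero-length region")
  v <- region_views(track, regions)
  vals <- numeric(length(regions))
  for (ch in unique(v$chroms)) {
    idx <- which(v$chroms == ch)
    vw <- IRanges::Views(track$values[[ch]],
                         start = v$start[idx], end = v$end[idx])
    vals[idx] <- IRanges::viewSums(vw)
  }
  dt <- regions_to_dt(regions)
  dt[, "value" := vals]
  dt[]
}

#' Per-region mean normalized counts
#'
#' Length-averaged normalized signal: value(r) = (sum of n_i over r) /
#' len(r). Averaging makes regions of different widths comparable; a
#' region spanning the whole genome of a uniform track scores exactly 1.
#'
#' @inheritParams region_sum
#' @return data.table: region_id, chrom, start, end, class, value.
#' @export
region_signal <- function(track, regions) {
  dt <- region_sum(track, regions)
  dt[, "value" := dt$value / (dt$end - dt$start)]
  dt[]
}

#' Write/read bedGraph coverage tracks
#'
#' Four-column bedGraph (chrom, start, end, value), 0-based half-open,
#' emitted run-length-encoded with zero runs omitted. Reading expands back
#' to per-bp values; overlapping intervals are an error. A round trip is
#' exact.
#'
#' @param track a [make_track()] coverage track.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  rows <- lapply(names(track$values), function(ch) {
    r <- track$values[[ch]]
    rl <- S4Vectors::runLength(r)
    rv <- S4Vectors::runValue(r)
    ends <- cumsum(as.numeric(rl))
    starts <- ends - as.numeric(rl)
    keep <- rv != 0
    if (!any(keep)) return(NULL)
    data.table::data.table(chrom = ch, start = starts[keep],
                           end = ends[keep], value = rv[keep])
  })
  dt <- data.table::rbindlist(rows[!vapply(rows, is.null, TRUE)])
  if (nrow(dt) == 0) {
    file.create(path)
  } else {
    # %.17g guarantees an exact double round trip through the text file
    dt[, "value" := sprintf("%.17g", dt$value)]
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_bedgraph
#' @param genome a [genome_spec()] giving chromosome bounds for expansion.
#' @return `read_bedgraph` returns a `coverage_track` (with `total_mass`
#'   `NA`: raw mass is not recoverable from a normalized file).
#' @export
read_bedgraph <- function(path, genome) {
  stopifnot(inherits(genome, "genome_spec"))
  empty <- file.size(path) == 0
  dt <- if (empty) {
    data.table::data.table(chrom = character(), start = numeric(),
                           end = numeric(), value = numeric())
  } else {
    data.table::fread(path, header = FALSE, sep = "\t",
                      col.names = c("chrom", "start", "end", "value"),
                      colClasses = list(character = 1))
  }
  if (nrow(dt) > 0) {
    validate_intervals(dt$chrom, dt$start, dt$end, genome,
                       what = "bedGraph interval")
  }
  vals <- lapply(genome$chroms, function(ch) {
    sub <- dt[dt$chrom == ch]
    sub <- sub[order(sub$start)]
    len <- genome$lengths[[ch]]
    if (nrow(sub) == 0) return(S4Vectors::Rle(0, len))
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)])) {
      stop("overlapping bedGraph intervals on ", ch)
    }
    # interleave zero gaps with value runs
    prev_end <- c(0, sub$end[-nrow(sub)])
    run_val <- as.vector(rbind(0, sub$value))
    run_len <- as.vector(rbind(sub$start - prev_end, sub$end - sub$start))
    run_val <- c(run_val, 0)
    run_len <- c(run_len, len - sub$end[nrow(sub)])
    keep <- run_len > 0
    S4Vectors::Rle(run_val[keep], run_len[keep])
  })
  names(vals) <- genome$chroms
  structure(list(values = methods::as(vals, "RleList"), genome = genome,
                 total_mass = NA_real_),
            class = "coverage_track")
}

#' Remove regions overlapping a mask
#'
#' Region-subtraction filter with `intersect -v` semantics: a region is
#' dropped if it shares at least 1 bp with any mask interval, kept
#' otherwise. With half-open inputs, a region abutting a mask end-to-start
#' shares no base pair and is retained. Typical use: removing regulatory
#' elements that fall in repeat-masked parts of the genome before
#' tumor/normal comparison.
#'
#' @param regions region `GRanges` to filter.
#' @param mask `GRanges` of intervals to exclude.
#' @return the retained subset of `regions`, order preserved.
#' @export
subtract_regions <- function(regions, mask) {
  if (length(regions) == 0 || length(mask) == 0) return(regions)
  hits <- GenomicRanges::findOverlaps(regions, mask, minoverlap = 1L,
                                      ignore.strand = TRUE)
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop) == 0) regions else regions[-drop]
}
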