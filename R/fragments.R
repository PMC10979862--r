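#' Fragment sets
#'
#' A `fragment_set` holds one sample's mapped fragments (chrom, start, end
#' in 0-based half-open BED convention) together with sample metadata:
#' `sample_id`, `condition` ("tumor" or "normal"), `pair_id` and
#' `replicate`. Fragments are kept as a `data.table`; order is meaningful
#' (file order preserved on read, coordinate-sorted on simulation output).
#'
#' @param fragments a data.frame/data.table with columns chrom, start, end.
#' @param sample_id sample identifier.
#' @param condition "tumor", "normal" or NA.
#' @param pair_id tumor/normal pair identifier.
#' @param replicate replicate identifier.
#' @param genome optional [genome_spec()]; coordinates validated when given.
#' @return an object of class `fragment_set`.
#' @export
fragment_set <- function(fragments, sample_id = "sample",
                         condition = NA_character_, pair_id = NA_character_,
                         replicate = NA_character_, genome = NULL) {
  dt <- data.table::as.data.table(fragments)
  if (nrow(dt) > 0) {
    stopifnot(all(c("chrom", "start", "end") %in% names(dt)))
    dt <- dt[, list(chrom = as.character(chrom), start = as.integer(start),
                    end = as.integer(end))]
    if (!is.null(genome)) {
      validate_intervals(dt$chrom, dt$start, dt$end, genome,
                         what = "fragment")
    } else if (any(dt$start < 0 | dt$start >= dt$end)) {
      i <- which(dt$start < 0 | dt$start >= dt$end)[1]
      stop("fragment ", i, ": start >= end or negative start")
    }
  } else {
    dt <- data.table::data.table(chrom = character(), start = integer(),
                                 end = integer())
  }
  structure(list(sample_id = sample_id, condition = condition,
                 pair_id = pair_id, replicate = replicate, fragments = dt),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("fragment_set '", x$sample_id, "' (", x$condition, "): ",
      nrow(x$fragments), " fragments\n", sep = "")
  invisible(x)
}

#' Number of fragments in a fragment_set
#' @param fs a [fragment_set()].
#' @export
n_fragments <- function(fs) nrow(fs$fragments)

#' Total fragment length in bp
#' @param fs a [fragment_set()].
#' @export
total_fragment_bp <- function(fs) {
  if (nrow(fs$fragments) == 0) return(0)
  sum(as.numeric(fs$fragments$end - fs$fragments$start))
}

#' Read mapped fragments from a BED3(+) file
#'
#' Only the first three tab-separated columns are consulted; extra columns
#' (name, score, strand) are ignored — fragments are unstranded throughout.
#' Input order is preserved. Each line is validated against the genome;
#' a coordinate outside its chromosome, start >= end, or an unknown
#' chromosome is an error naming the offending line.
#'
#' @param path BED file path (plain text, tab-separated, 0-based half-open).
#' @param genome a [genome_spec()].
#' @param sample_id,condition,pair_id,replicate metadata stored on the
#'   returned set; `sample_id` defaults to the file base name.
#' @return a [fragment_set()]. An empty file yields an empty set.
#' @export
read_fragments <- function(path, genome, sample_id = NULL,
                           condition = NA_character_,
                           pair_id = NA_character_,
                           replicate = NA_character_) {
  if (!file.exists(path)) stop("no such fragment file: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(bed|txt)(\\.gz)?$", "", basename(path))
  }
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                      colClasses = list(character = 1)),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e)))
  if (nrow(dt) == 0) {
    return(fragment_set(NULL, sample_id = sample_id, condition = condition,
                        pair_id = pair_id, replicate = replicate))
  }
  if (ncol(dt) < 3) stop("BED file needs >= 3 columns: ", path)
  frags <- data.table::data.table(chrom = dt[[1]],
                                  start = as.integer(dt[[2]]),
                                  end = as.integer(dt[[3]]))
  validate_intervals(frags$chrom, frags$start, frags$end, genome,
                     what = paste0(basename(path), " line"))
  fragment_set(frags, sample_id = sample_id, condition = condition,
               pair_id = pair_id, replicate = replicate)
}

#' Write a fragment_set as BED3
#' @param fs a [fragment_set()].
#' @param path output path (tab-separated, LF line endings).
#' @export
write_fragments <- function(fs, path) {
  data.table::fwrite(fs$fragments, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Remove exact-coordinate duplicate fragments
#'
#' A duplicate is a fragment identical in (chrom, start, end) to an earlier
#' one; the first occurrence is kept. This is the fragment-level equivalent
#' of duplicate marking for paired-end data, where both mates share
#' coordinates. Idempotent.
#'
#' @param fs a [fragment_set()].
#' @return list with `fragments` (the deduplicated [fragment_set()]) and
#'   `n_removed` (count of fragments dropped).
#' @export
deduplicate <- function(fs) {
  stopifnot(inherits(fs, "fragment_set"))
  dt <- fs$fragments
  keep <- !duplicated(dt, by = c("chrom", "start", "end"))
  out <- fs
  out$fragments <- dt[keep]
  list(fragments = out, n_removed = sum(!keep))
}

#' Equalize fragment counts between a sample pair by downsampling
#'
#' The larger of the two sets is downsampled (uniform, without
#' replacement) to the size of the smaller; the smaller set is returned
#' unchanged. Deterministic under `seed`.
#'
#' @param a,b [fragment_set()]s, both non-empty.
#' @param seed integer RNG seed.
#' @return list with elements `a` and `b`, both of size `min(|a|, |b|)`.
#' @export
downsample_equalize <- function(a, b, seed = 1L) {
  if (n_fragments(a) == 0 || n_fragments(b) == 0) {
    stop("downsample_equalize: both fragment sets must be non-empty")
  }
  n <- min(n_fragments(a), n_fragments(b))
  take <- function(fs) {
    if (n_fragments(fs) == n) return(fs)
    idx <- sort(sample.int(n_fragments(fs), n))
    fs$fragments <- fs$fragments[idx]
    fs
  }
  withr_seed <- function(expr) {   # local RNG scope, no global side effect
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    expr
  }
  withr_seed(list(a = take(a), b = take(b)))
}

#' Pool fragment sets
#'
#' Concatenates fragments from multiple sets (e.g. replicates of one
#' sample merged across experiments). Metadata is taken from the first set
#' unless overridden.
#'
#' @param sets list of [fragment_set()]s on the same genome.
#' @param sample_id optional id for the merged set.
#' @return a [fragment_set()] with `sum(sapply(sets, n_fragments))` rows.
#' @export
merge_fragmentsets <- function(sets, sample_id = NULL) {
  stopifnot(length(sets) >= 1,
            all(vapply(sets, inherits, TRUE, "fragment_set")))
  out <- sets[[1]]
  out$fragments <- data.table::rbindlist(lapply(sets, `[[`, "fragments"))
  if (!is.null(sample_id)) out$sample_id <- sample_id
  out
}

#' Sample quality-control filter
#'
#' A sample passes QC when it has at least `min_fragments` fragments and at
#' least `min_total_bp` of summed fragment length. Defaults follow the
#' standard low-depth CUTAC thresholds of 100,000 fragments and
#' 10,000,000 bp.
#'
#' @param sets list of [fragment_set()]s.
#' @param min_fragments minimum fragment count (default 1e5).
#' @param min_total_bp minimum total fragment length in bp (default 1e7).
#' @return data.table with columns sample_id, n_fragments,
#'   total_fragment_bp, passed.
#' @export
qc_filter <- function(sets, min_fragments = 100000, min_total_bp = 1e7) {
  stopifnot(all(vapply(sets, inherits, TRUE, "fragment_set")))
  dt <- data.table::data.table(
    sample_id = vapply(sets, `[[`, "", "sample_id"),
    n_fragments = vapply(sets, n_fragments, 0),
    total_fragment_bp = vapply(sets, total_fragment_bp, 0))
  dt[, "passed" := dt$n_fragments >= min_fragments &
       dt$total_fragment_bp >= min_total_bp]
  dt[]
}

#' Mitochondrial signal fraction (percent)
#'
#' The percentage of normalized-count mass on the mitochondrial
#' chromosome. Because genome-scaled normalization divides every per-bp
#' count by the same total, this equals 100 x (summed fragment length on
#' chrM) / (summed fragment length overall), computed here directly from
#' fragments.
#'
#' @param fs a [fragment_set()].
#' @param genome a [genome_spec()] with a designated mitochondrial
#'   chromosome.
#' @return percentage in `[0, 100]`.
#' @export
chrM_fraction <- function(fs, genome) {
  stopifnot(inherits(genome, "genome_spec"))
  if (is.na(genome$chrM)) stop("genome has no mitochondrial chromosome")
  tot <- total_fragment_bp(fs)
  if (tot == 0) stop("chrM_fraction: zero total coverage")
  dt <- fs$fragments
  m <- dt$chrom == genome$chrM
  100 * sum(as.numeric(dt$end[m] - dt$start[m])) / tot
}
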