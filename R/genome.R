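#' Genome specification
#'
#' A `genome_spec` is the package's minimal genome description: an ordered
#' set of chromosome names with lengths, one of which is designated the
#' mitochondrial chromosome. It defines the total genome size `G` used by
#' genome-scaled normalization (uniform coverage corresponds to a normalized
#' value of 1 at every base pair).
#'
#' @param chroms character vector of chromosome names (unique, non-empty).
#' @param lengths integer/numeric vector of chromosome lengths in bp,
#'   parallel to `chroms`.
#' @param chrM name of the mitochondrial chromosome. Must be one of
#'   `chroms`, or `NA` for genomes with no mitochondrial contig.
#' @return An object of class `genome_spec` with fields `chroms`,
#'   `lengths` (named) and `chrM`.
#' @examples
#' g <- genome_spec(c("chr1", "chrM"), c(1e6, 16000), chrM = "chrM")
#' genome_size(g)
#' @export
genome_spec <- function(chroms, lengths, chrM = NA_character_) {
  chroms <- as.character(chroms)
  if (anyDuplicated(chroms)) stop("duplicated chromosome names")
  if (length(chroms) != length(lengths)) {
    stop("chroms and lengths must have equal length")
  }
  lengths <- as.numeric(lengths)
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("chromosome lengths must be positive and finite")
  }
  if (!is.na(chrM) && !chrM %in% chroms) {
    stop("mitochondrial chromosome '", chrM, "' not among declared chroms")
  }
  names(lengths) <- chroms
  structure(list(chroms = chroms, lengths = lengths, chrM = chrM),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", length(x$chroms), "chromosomes,",
      format(genome_size(x), big.mark = ","), "bp")
  if (!is.na(x$chrM)) cat(" (chrM =", x$chrM, ")")
  cat("\n")
  invisible(x)
}

#' Total genome size G in bp
#' @param genome a [genome_spec()].
#' @return numeric scalar, the sum of chromosome lengths.
#' @export
genome_size <- function(genome) {
  stopifnot(inherits(genome, "genome_spec"))
  sum(genome$lengths)
}

#' Read/write two-column chrom-sizes files
#'
#' The standard `<chrom>\t<length>` text format. The mitochondrial
#' designation is not representable in the format and is supplied on read.
#'
#' @param path file path.
#' @param chrM mitochondrial chromosome name, or `NA`.
#' @return `read_chrom_sizes` returns a [genome_spec()];
#'   `write_chrom_sizes` returns `path` invisibly.
#' @export
read_chrom_sizes <- function(path, chrM = NA_character_) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"),
                          colClasses = list(character = 1))
  if (is.na(chrM) && "chrM" %in% dt$chrom) chrM <- "chrM"
  genome_spec(dt$chrom, dt$length, chrM = chrM)
}

#' @rdname read_chrom_sizes
#' @param genome a [genome_spec()] to write.
#' @export
write_chrom_sizes <- function(genome, path) {
  stopifnot(inherits(genome, "genome_spec"))
  data.table::fwrite(
    data.table::data.table(chrom = genome$chroms,
                           length = format(genome$lengths, scientific = FALSE,
                                           trim = TRUE)),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Annotated region sets
#'
#' Regions (cCREs, histone genes, tiles, masks) are held as a
#' [GenomicRanges::GRanges] with two metadata columns: `region_id` (unique
#' identifier) and `class` (annotation class such as `promoter`,
#' `distal_enhancer`, `histone`). Coordinates are stored 1-based closed
#' (GRanges convention); all file I/O converts to/from 0-based half-open BED.
#'
#' @param chrom,start,end vectors describing intervals in BED convention
#'   (0-based half-open).
#' @param region_id unique ids; generated as `region_00001`... when `NULL`.
#' @param class annotation class labels, recycled; default "region".
#' @param genome optional [genome_spec()]; when given, coordinates are
#'   validated against chromosome bounds.
#' @return a `GRanges` with `region_id` and `class` metadata columns.
#' @export
region_set <- function(chrom, start, end, region_id = NULL,
                       class = "region", genome = NULL) {
  n <- length(chrom)
  stopifnot(length(start) == n, length(end) == n)
  if (n > 0 && any(start < 0 | end <= start)) {
    stop("invalid region coordinates: need 0 <= start < end")
  }
  if (is.null(region_id)) {
    region_id <- sprintf("region_%05d", seq_len(max(n, 1))[seq_len(n)])
  }
  if (anyDuplicated(region_id)) stop("region_id values must be unique")
  if (!is.null(genome)) {
    validate_intervals(chrom, start, end, genome, what = "region")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end)))
  S4Vectors::mcols(gr)$region_id <- as.character(region_id)
  S4Vectors::mcols(gr)$class <- rep_len(as.character(class), n)
  gr
}

# shared bounds check; BED coords in, errors name offending entries
validate_intervals <- function(chrom, start, end, genome, what = "interval") {
  unknown <- !chrom %in% genome$chroms
  if (any(unknown)) {
    stop("unknown chromosome '", chrom[which(unknown)[1]], "' in ", what,
         " ", which(unknown)[1])
  }
  lens <- genome$lengths[chrom]
  bad <- start < 0 | end > lens | start >= end
  if (any(bad)) {
    i <- which(bad)[1]
    stop(what, " ", i, " (", chrom[i], ":", start[i], "-", end[i],
         ") outside chromosome bounds or start >= end")
  }
  invisible(TRUE)
}

#' Read/write BED region files
#'
#' Plain tab-separated BED, 0-based half-open. Columns 4 and 5, when
#' present, are taken as `region_id` and `class`; extra columns are
#' ignored. Writing emits 5 columns.
#'
#' @param path file path.
#' @param genome optional [genome_spec()] for validation.
#' @return `read_regions` returns a region `GRanges`; `write_regions`
#'   returns `path` invisibly.
#' @export
read_regions <- function(path, genome = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1))
  if (nrow(dt) == 0) {
    return(region_set(character(), integer(), integer()))
  }
  if (ncol(dt) < 3) stop("BED file needs >= 3 columns: ", path)
  id <- if (ncol(dt) >= 4) as.character(dt[[4]]) else NULL
  cls <- if (ncol(dt) >= 5) as.character(dt[[5]]) else "region"
  region_set(dt[[1]], dt[[2]], dt[[3]], region_id = id, class = cls,
             genome = genome)
}

#' @rdname read_regions
#' @param regions region `GRanges` to write.
#' @export
write_regions <- function(regions, path) {
  dt <- regions_to_dt(regions)
  data.table::fwrite(dt[, c("chrom", "start", "end", "region_id", "class"),
                        with = FALSE],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# GRanges -> data.table in BED coords
regions_to_dt <- function(regions) {
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions) - 1L,
    end = GenomicRanges::end(regions),
    region_id = S4Vectors::mcols(regions)$region_id,
    class = S4Vectors::mcols(regions)$class)
}
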