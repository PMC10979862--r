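#' Region-by-sample raw count matrix
#'
#' Entry (r, s) is the number of fragments of sample s overlapping
#' region r by at least 1 bp; a fragment spanning several regions counts
#' once in each. Rows are regions (ids from the region set), columns are
#' samples. Samples should have passed [qc_filter()] first.
#'
#' @param samples list of [fragment_set()]s.
#' @param regions non-empty region `GRanges`.
#' @return integer matrix with region_id rownames and sample_id colnames.
#' @export
build_matrix <- function(samples, regions) {
  if (length(regions) == 0) stop("build_matrix: empty region set")
  stopifnot(length(samples) >= 1,
            all(vapply(samples, inherits, TRUE, "fragment_set")))
  ids <- vapply(samples, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  m <- vapply(samples, function(fs) {
    dt <- fs$fragments
    if (nrow(dt) == 0) return(integer(length(regions)))
    fr <- GenomicRanges::GRanges(dt$chrom,
                                 IRanges::IRanges(dt$start + 1L, dt$end))
    GenomicRanges::countOverlaps(regions, fr, minoverlap = 1L)
  }, integer(length(regions)))
  m <- matrix(m, nrow = length(regions),
              dimnames = list(S4Vectors::mcols(regions)$region_id, ids))
  m
}

#' TF-IDF normalization of a count matrix
#'
#' The standard latent-semantic-indexing transform for sparse
#' accessibility counts: term frequency (per-sample depth normalization)
#' times inverse document frequency (upweighting regions open in few
#' samples), log-transformed:
#' `x_rs = ln(1 + 1e4 * (c_rs / colsum_s) * (S / n_samples_with_region_r))`
#' where `S` is the number of samples. Rows with no occurrences in any
#' sample are dropped with a warning. Doubling every count of a sample
#' leaves its column unchanged (depth invariance).
#'
#' @param m count matrix from [build_matrix()].
#' @param scale_factor the 1e4 constant above.
#' @return real-valued matrix over the retained rows.
#' @export
tfidf_normalize <- function(m, scale_factor = 1e4) {
  cs <- colSums(m)
  if (any(cs == 0)) {
    stop("tfidf_normalize: all-zero column(s): ",
         paste(colnames(m)[cs == 0], collapse = ", "))
  }
  df <- rowSums(m > 0)
  if (any(df == 0)) {
    warning("dropping ", sum(df == 0), " region(s) with zero occurrences")
    m <- m[df > 0, , drop = FALSE]
    df <- df[df > 0]
  }
  tf <- sweep(m, 2, cs, "/")
  idf <- ncol(m) / df
  log1p(scale_factor * tf * idf)
}

#' Top features, scaling, PCA and 2-D embedding of samples
#'
#' Selects the `n_features` rows with the largest total (row sum of the
#' TF-IDF matrix — total accessibility), centers and unit-variance
#' scales each feature across samples with z-values capped at
#' `|z| <= 10`, runs PCA on the samples, retains up to `n_pcs`
#' components (lowered with a warning when exceeding `n_samples - 1`),
#' and projects the PC coordinates to 2-D with UMAP (via the `uwot`
#' package when available; otherwise classical MDS on PC-space
#' distances, which preserves the same neighborhood structure for the
#' small cohorts this package targets). Deterministic under `seed`.
#'
#' @param x TF-IDF matrix from [tfidf_normalize()].
#' @param n_features number of top rows to keep (default
#'   `min(25000, nrow(x))`).
#' @param n_pcs number of principal components (default 50).
#' @param seed integer seed for the embedding.
#' @param z_cap cap on scaled values (default 10).
#' @return list of class `sample_embedding`: `coords` (samples x 2),
#'   `pcs` (samples x retained PCs), `feature_ids`, `sdev`, `method`.
#' @export
reduce_and_embed <- function(x, n_features = min(25000L, nrow(x)),
                             n_pcs = 50L, seed = 1L, z_cap = 10) {
  stopifnot(is.matrix(x), ncol(x) >= 2)
  n_features <- min(n_features, nrow(x))
  keep <- order(rowSums(x), decreasing = TRUE)[seq_len(n_features)]
  xs <- x[sort(keep), , drop = FALSE]
  # center + unit variance per feature across samples, capped
  mu <- rowMeans(xs)
  sdv <- apply(xs, 1, stats::sd)
  sdv[sdv == 0] <- 1
  z <- (xs - mu) / sdv
  z[z > z_cap] <- z_cap
  z[z < -z_cap] <- -z_cap
  n_samp <- ncol(z)
  max_pcs <- n_samp - 1L
  if (n_pcs > max_pcs) {
    warning("n_pcs lowered from ", n_pcs, " to ", max_pcs,
            " (only ", n_samp, " samples)")
    n_pcs <- max_pcs
  }
  pca <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pca$x))
  pcs <- pca$x[, seq_len(n_pcs), drop = FALSE]
  coords <- embed_2d(pcs, seed = seed)
  structure(list(coords = coords$xy, pcs = pcs,
                 feature_ids = rownames(xs), sdev = pca$sdev,
                 method = coords$method),
            class = "sample_embedding")
}

# 2-D neighborhood-preserving projection of PC coordinates
embed_2d <- function(pcs, seed = 1L) {
  n <- nrow(pcs)
  if (requireNamespace("uwot", quietly = TRUE) && n >= 4) {
    nn <- max(2L, min(15L, n - 1L))
    xy <- with_seed(seed, uwot::umap(pcs, n_neighbors = nn,
                                     n_components = 2, n_threads = 1,
                                     n_sgd_threads = 1, verbose = FALSE))
    rownames(xy) <- rownames(pcs)
    colnames(xy) <- c("UMAP1", "UMAP2")
    return(list(xy = xy, method = "umap"))
  }
  d <- stats::dist(pcs)
  xy <- stats::cmdscale(d, k = 2)
  if (ncol(xy) < 2) xy <- cbind(xy, 0)   # degenerate all-coincident input
  rownames(xy) <- rownames(pcs)
  colnames(xy) <- c("MDS1", "MDS2")
  list(xy = xy, method = "mds")
}

#' @export
print.sample_embedding <- function(x, ...) {
  cat("sample_embedding (", x$method, "): ", nrow(x$coords), " samples, ",
      ncol(x$pcs), " PCs, ", length(x$feature_ids), " features\n", sep = "")
  invisible(x)
}

#' Write/read count matrices as MatrixMarket triplets
#'
#' Sparse triplet MTX plus two sidecar files (`<path>.rows`,
#' `<path>.cols`) holding the region and sample ids, one per line.
#'
#' @param m matrix from [build_matrix()].
#' @param path output `.mtx` path.
#' @export
write_count_matrix <- function(m, path) {
  sm <- methods::as(Matrix::Matrix(m, sparse = TRUE), "TsparseMatrix")
  Matrix::writeMM(sm, path)
  writeLines(rownames(m), paste0(path, ".rows"))
  writeLines(colnames(m), paste0(path, ".cols"))
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  sm <- Matrix::readMM(path)
  m <- as.matrix(sm)
  storage.mode(m) <- "integer"
  rownames(m) <- readLines(paste0(path, ".rows"))
  colnames(m) <- readLines(paste0(path, ".cols"))
  m
}
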