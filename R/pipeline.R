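#' Run the full hypertranscription pipeline
#'
#' Orchestrates the stages over one or more tumor/normal pairs:
#' QC filtering, optional exact-duplicate removal, fragment-count
#' equalization, coverage tracks, per-region signal, tumor-minus-normal
#' statistics, histone-cluster excess, mitochondrial comparison,
#' paired-control peak calling, amplicon tiling/summits, and (with >= 3
#' samples) the TF-IDF/PCA embedding. Writes TSV/BED/bedGraph outputs
#' and a JSON manifest with input descriptions, seeds and md5 checksums
#' of every output under `out_dir`. Any stage failure halts with the
#' stage name in the error.
#'
#' @param pairs list of `list(tumor =, normal =)` [fragment_set()] pairs.
#' @param genome a [genome_spec()].
#' @param regions cCRE region `GRanges`.
#' @param histones histone region `GRanges` (or `NULL` to skip).
#' @param out_dir output directory.
#' @param dedup remove exact duplicates first (default TRUE).
#' @param equalize_seed seed for per-pair downsampling.
#' @param peak_mode `"relaxed"` or `"stringent"`.
#' @param amplicon_window optional list(chrom, start, end) to tile.
#' @param bin_size,span tiling parameters.
#' @param n_pcs,embed_seed embedding parameters.
#' @param min_fragments,min_total_bp QC thresholds.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(pairs, genome, regions, histones = NULL,
                         out_dir, dedup = TRUE, equalize_seed = 1L,
                         peak_mode = "relaxed", amplicon_window = NULL,
                         bin_size = 1000, span = 0.2, n_pcs = 50L,
                         embed_seed = 1L, min_fragments = 100000,
                         min_total_bp = 1e7) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[hypertx] stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  outputs <- character()
  emit <- function(path) outputs <<- c(outputs, path)

  all_samples <- unlist(lapply(pairs, function(p) list(p$tumor, p$normal)),
                        recursive = FALSE)
  qc <- stage("qc", qc_filter(all_samples, min_fragments, min_total_bp))
  data.table::fwrite(qc, file.path(out_dir, "qc.tsv"), sep = "\t")
  emit(file.path(out_dir, "qc.tsv"))

  prepped <- stage("prepare", lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    if (dedup) {
      p$tumor <- deduplicate(p$tumor)$fragments
      p$normal <- deduplicate(p$normal)$fragments
    }
    eq <- downsample_equalize(p$tumor, p$normal, seed = equalize_seed + i)
    list(tumor = eq$a, normal = eq$b)
  }))

  tracks <- stage("tracks", lapply(prepped, function(p) {
    list(tumor = make_track(p$tumor, genome),
         normal = make_track(p$normal, genome))
  }))

  prs <- stage("signal", lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    pr <- pair_diff(region_signal(tr$tumor, regions),
                    region_signal(tr$normal, regions))
    f <- file.path(out_dir, sprintf("pair%02d_regions.tsv", i))
    data.table::fwrite(pr, f, sep = "\t")
    emit(f)
    pr
  }))

  if (length(prs) > 1) {
    comp <- stage("composite", max_diff_composite(prs))
    data.table::fwrite(comp, file.path(out_dir, "max_diffs.tsv"), sep = "\t")
    emit(file.path(out_dir, "max_diffs.tsv"))
  }

  if (!is.null(histones) && length(histones) > 0) {
    hs <- stage("histone", histone_excess(prepped, histones, genome))
    data.table::fwrite(hs$per_pair, file.path(out_dir, "histone.tsv"),
                       sep = "\t")
    emit(file.path(out_dir, "histone.tsv"))
  } else hs <- NULL

  mito <- stage("mito", mito_compare(prepped, genome))
  data.table::fwrite(mito, file.path(out_dir, "mito.tsv"), sep = "\t")
  emit(file.path(out_dir, "mito.tsv"))

  calls <- stage("peaks", lapply(seq_along(tracks), function(i) {
    pc <- call_peaks(tracks[[i]]$tumor, tracks[[i]]$normal,
                     mode = peak_mode)
    f <- file.path(out_dir, sprintf("pair%02d_peaks.bed", i))
    write_peaks(pc, f)
    emit(f)
    pc
  }))
  names(calls) <- sprintf("pair%02d", seq_along(calls))

  summits <- NULL
  if (!is.null(amplicon_window)) {
    summits <- stage("amplicon", {
      tc <- tile_counts(tracks[[1]]$tumor, tracks[[1]]$normal,
                        amplicon_window, bin_size = bin_size, span = span)
      f <- file.path(out_dir, "tiles.tsv")
      data.table::fwrite(tc$bins, f, sep = "\t")
      emit(f)
      sm <- detect_summits(tc)
      f2 <- file.path(out_dir, "summits.tsv")
      data.table::fwrite(sm, f2, sep = "\t")
      emit(f2)
      sm
    })
  }

  emb <- NULL
  if (length(all_samples) >= 3) {
    emb <- stage("cluster", {
      m <- build_matrix(all_samples, regions)
      e <- reduce_and_embed(tfidf_normalize(m), n_pcs = n_pcs,
                            seed = embed_seed)
      f <- file.path(out_dir, "embedding.tsv")
      data.table::fwrite(data.table::data.table(
        sample_id = rownames(e$coords),
        x = e$coords[, 1], y = e$coords[, 2]), f, sep = "\t")
      emit(f)
      e
    })
  }

  manifest <- list(
    package = as.character(utils::packageVersion("hypertx")),
    n_pairs = length(pairs),
    genome = list(chroms = genome$chroms,
                  lengths = unname(genome$lengths), chrM = genome$chrM),
    n_regions = length(regions),
    options = list(dedup = dedup, equalize_seed = equalize_seed,
                   peak_mode = peak_mode, bin_size = bin_size, span = span,
                   n_pcs = n_pcs, embed_seed = embed_seed,
                   min_fragments = min_fragments,
                   min_total_bp = min_total_bp),
    outputs = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, qc = qc, pair_results = prs,
                 histone = hs, mito = mito, peaks = calls,
                 summits = summits, embedding = emb))
}

#' One-command synthetic end-to-end demo
#'
#' Simulates a small paired cohort on a 2 Mb toy genome and runs the full
#' pipeline, writing all outputs plus the simulation truth under
#' `out_dir`.
#'
#' @param seed integer master seed.
#' @param out_dir output directory.
#' @param n_pairs number of tumor/normal pairs (default 2).
#' @param n_fragments fragments per sample (default 100000).
#' @return the pipeline result, invisibly.
#' @export
run_demo <- function(seed = 1L, out_dir = tempfile("hypertx_demo"),
                     n_pairs = 2, n_fragments = 100000) {
  cfg <- sim_config(seed = seed, n_fragments = n_fragments,
                    amplicon = list(chrom = "chr2", start = 300000,
                                    end = 600000, copy_number = 2),
                    summits = list(list(center = 450000, width_sd = 40000,
                                        extra = 1)))
  gm <- make_genome(cfg)
  pairs <- lapply(seq_len(n_pairs), function(i) {
    sim <- simulate_pair(cfg, gm$genome, gm$regions, seed = seed + i,
                         pair_id = paste0("pair", i))
    sim[c("tumor", "normal")]
  })
  sim1 <- simulate_pair(cfg, gm$genome, gm$regions, seed = seed + 1,
                        pair_id = "pair1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_simulation(sim1, gm$genome, gm$regions, cfg,
                   file.path(out_dir, "sim"))
  ccres <- gm$regions[S4Vectors::mcols(gm$regions)$class != "histone"]
  hist <- gm$regions[S4Vectors::mcols(gm$regions)$class == "histone"]
  res <- run_pipeline(pairs, gm$genome, ccres, histones = hist,
                      out_dir = out_dir,
                      amplicon_window = list(chrom = "chr2",
                                             start = 200000, end = 700000),
                      min_fragments = min(100000, n_fragments))
  invisible(res)
}
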