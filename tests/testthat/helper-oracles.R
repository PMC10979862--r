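# Brute-force oracles, deliberately independent of the package's
# Rle/Views code paths: dense per-bp vectors built by per-fragment loops,
# and O(n*m) pairwise interval scans.

# dense per-bp raw coverage, one numeric vector per chromosome
oracle_coverage <- function(fs, genome) {
  dense <- lapply(genome$lengths, function(L) numeric(L))
  dt <- fs$fragments
  for (i in seq_len(nrow(dt))) {
    ch <- dt$chrom[i]
    idx <- (dt$start[i] + 1):dt$end[i]
    dense[[ch]][idx] <- dense[[ch]][idx] + 1
  }
  dense
}

oracle_normalized <- function(fs, genome) {
  dense <- oracle_coverage(fs, genome)
  total <- sum(vapply(dense, sum, 0))
  G <- sum(genome$lengths)
  lapply(dense, function(v) v / total * G)
}

# per-region sum/mean from a dense per-bp list
oracle_region_sum <- function(dense, chrom, start, end) {
  vapply(seq_along(chrom), function(i) {
    sum(dense[[chrom[i]]][(start[i] + 1):end[i]])
  }, 0)
}

# maximal positive runs via index-gap splitting
oracle_blocks <- function(dense_chrom) {
  pos <- which(dense_chrom > 0)
  if (length(pos) == 0) {
    return(data.frame(start = integer(), end = integer(), auc = numeric()))
  }
  grp <- cumsum(c(1, diff(pos) > 1))
  do.call(rbind, lapply(split(pos, grp), function(p) {
    data.frame(start = min(p) - 1L, end = max(p),
               auc = sum(dense_chrom[p]))
  }))
}

# any-overlap test for half-open intervals
bed_overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

oracle_subtract <- function(reg, mask) {
  keep <- vapply(seq_len(nrow(reg)), function(i) {
    !any(reg$chrom[i] == mask$chrom &
           bed_overlaps(reg$start[i], reg$end[i], mask$start, mask$end))
  }, TRUE)
  reg[keep, , drop = FALSE]
}

oracle_count_matrix <- function(samples, reg) {
  m <- matrix(0L, nrow(reg), length(samples))
  for (s in seq_along(samples)) {
    dt <- samples[[s]]$fragments
    for (r in seq_len(nrow(reg))) {
      m[r, s] <- sum(dt$chrom == reg$chrom[r] &
                       bed_overlaps(reg$start[r], reg$end[r],
                                    dt$start, dt$end))
    }
  }
  m
}

# fragment_set from a compact matrix-like spec
frags <- function(chrom, start, end, id = "s", ...) {
  fragment_set(data.frame(chrom = chrom, start = start, end = end),
               sample_id = id, ...)
}

# small uniform random fragment set on a genome
random_frags <- function(genome, n, id = "s", min_len = 20, max_len = 120) {
  ch <- sample(genome$chroms, n, replace = TRUE,
               prob = genome$lengths / sum(genome$lengths))
  len <- sample(min_len:max_len, n, replace = TRUE)
  len <- pmin(len, genome$lengths[ch])
  start <- floor(runif(n) * (genome$lengths[ch] - len))
  frags(ch, start, start + len, id = id)
}

# random disjoint regions via slot sampling
random_regions <- function(genome, n, width = 200) {
  slots <- do.call(rbind, lapply(genome$chroms, function(ch) {
    k <- floor(genome$lengths[[ch]] / width)
    data.frame(chrom = ch, start = (seq_len(k) - 1) * width)
  }))
  pick <- slots[sort(sample.int(nrow(slots), n)), ]
  region_set(pick$chrom, pick$start, pick$start + width,
             region_id = sprintf("r%04d", seq_len(n)))
}

# toy 116 kb genome used across unit tests (fast dense oracles)
toy_genome <- function() {
  genome_spec(c("chr1", "chr2", "chrM"), c(50000, 50000, 16000),
              chrM = "chrM")
}

# fast small simulator config for unit tests (overridable defaults)
fast_config <- function(...) {
  defaults <- list(n_ccres = 200, n_fragments = 20000,
                   histone_cluster = list(chrom = "chr1", start = 700000,
                                          end = 760000, n_genes = 16))
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
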