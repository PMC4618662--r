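# Shared fixtures: scenarios are generated once per test session and cached.
.fixture_cache <- new.env(parent = emptyenv())

# Small single-chromosome scenario for fast unit tests.
mini_config <- function(seed = 11L) {
  cfg <- default_scenario_config(seed = seed)
  cfg$n_chroms <- 1L
  cfg$chrom_length <- 4e6
  cfg$n_pre_existing <- 60L
  cfg$n_de_novo <- 40L
  cfg$n_genes <- 250L
  validate_scenario_config(cfg)
  cfg
}

mini_scenario <- function() {
  if (is.null(.fixture_cache$mini)) {
    dir <- file.path(tempdir(), "ek_mini_scenario")
    .fixture_cache$mini <- generate_scenario(mini_config(), dir)
  }
  .fixture_cache$mini
}

# Study-default scenario (seed 1) and its pipeline report, shared by the
# acceptance suite.
demo_scenario <- function() {
  if (is.null(.fixture_cache$demo)) {
    dir <- file.path(tempdir(), "ek_demo_scenario")
    .fixture_cache$demo <- generate_scenario(default_scenario_config(seed = 1L),
                                             dir)
  }
  .fixture_cache$demo
}

demo_report <- function() {
  if (is.null(.fixture_cache$demo_report)) {
    t0 <- Sys.time()
    sc <- demo_scenario()
    .fixture_cache$demo_report <- run_pipeline(sc)
    .fixture_cache$demo_elapsed <-
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }
  .fixture_cache$demo_report
}

demo_elapsed <- function() {
  demo_report()
  .fixture_cache$demo_elapsed
}

# Random peak set on a small genome, for oracle comparisons.
random_peaks <- function(n, chrom_len = 10000L, chroms = "chr1",
                         max_width = 200L) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(chrom_len - max_width, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  peak_set(chrom, start, pmin(start + width, chrom_len))
}

# Per-base union oracle: merge by marking covered bases.
brute_merge <- function(peaks, chrom_len) {
  out <- list()
  for (chr in unique(as.character(GenomicRanges::seqnames(peaks)))) {
    p <- peaks[GenomicRanges::seqnames(peaks) == chr]
    covered <- logical(chrom_len)
    for (i in seq_along(p)) {
      covered[GenomicRanges::start(p)[i]:GenomicRanges::end(p)[i]] <- TRUE
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (any(keep)) {
      out[[chr]] <- data.frame(chrom = chr, start = starts[keep] - 1L,
                               end = ends[keep])
    }
  }
  do.call(rbind, out)
}

# Quadratic overlap-pair oracle.
brute_intersect <- function(a, b, min_overlap = 1L) {
  n <- 0L
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (as.character(GenomicRanges::seqnames(a))[i] !=
        as.character(GenomicRanges::seqnames(b))[j]) next
    ov <- min(GenomicRanges::end(a)[i], GenomicRanges::end(b)[j]) -
      max(GenomicRanges::start(a)[i], GenomicRanges::start(b)[j]) + 1L
    if (ov >= min_overlap) n <- n + 1L
  }
  n
}

# Exhaustive nearest-TSS oracle with the lexicographic tie-break.
brute_nearest <- function(sites, genes) {
  mid <- interval_midpoint(sites)
  out <- data.frame(gene_id = rep(NA_character_, length(sites)),
                    distance = rep(NA_integer_, length(sites)))
  for (i in seq_along(sites)) {
    chr <- as.character(GenomicRanges::seqnames(sites))[i]
    gi <- which(as.character(GenomicRanges::seqnames(genes)) == chr)
    if (!length(gi)) next
    d <- abs(mid[i] - genes$tss[gi])
    best <- gi[d == min(d)]
    best <- best[order(genes$gene_id[best])][1]
    out$gene_id[i] <- genes$gene_id[best]
    out$distance[i] <- mid[i] - genes$tss[best]
  }
  out
}
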