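# Mean per-base coverage over 0-based half-open windows [start0, end0),
# truncated at chromosome ends. Vectorized via Rle Views per chromosome.
#' @noRd
.window_means <- function(track, chrom, start0, end0, warn_truncate = TRUE) {
  lens <- .chrom_lengths(track$genome)
  out <- numeric(length(chrom))
  s <- pmax(start0, 0L)
  e <- pmin(end0, lens[chrom])
  if (warn_truncate && (any(s != start0) || any(e != end0))) {
    warning("window(s) truncated at chromosome bounds")
  }
  if (any(e <= s)) stop("empty window after truncation")
  for (chr in unique(chrom)) {
    i <- which(chrom == chr)
    v <- IRanges::Views(track$cov[[chr]],
                        start = s[i] + 1L, end = e[i])
    out[i] <- IRanges::viewMeans(v)
  }
  out
}

#' Estimate genomic background coverage
#'
#' The background level of a track is the median of mean coverages over
#' `n_windows` windows drawn uniformly at random from the genome
#' (deterministic given `seed`). An all-zero median is floored at a small
#' epsilon so fold enrichments stay defined.
#'
#' @param track a `coverage_track`.
#' @param n_windows number of sampled windows (default 2000).
#' @param window window width in bp (default 1000).
#' @param seed RNG seed (default 1).
#' @param eps floor returned when the median is 0.
#' @return Scalar background coverage per bp.
#' @export
estimate_background <- function(track, n_windows = 2000L, window = 1000L,
                                seed = 1L, eps = 1e-6) {
  lens <- .chrom_lengths(track$genome)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  chrom <- sample(names(lens), n_windows, replace = TRUE,
                  prob = lens / sum(lens))
  start0 <- floor(stats::runif(n_windows) * (lens[chrom] - window))
  m <- stats::median(.window_means(track, chrom, start0, start0 + window,
                                   warn_truncate = FALSE))
  if (m <= 0) eps else m
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
#' @noRd
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Call the mark state at site centers
#'
#' Fold enrichment is the mean coverage in `center +/- half_window` divided by
#' the genomic background; a site is *marked* when the fold reaches
#' `threshold`.
#'
#' @param centers integer vector of 0-based anchor positions.
#' @param chrom chromosome of each center.
#' @param track `coverage_track` for one mark.
#' @param half_window half-width of the scoring window in bp (default 1000).
#' @param background scalar background per bp (see [estimate_background()]).
#' @param threshold fold-enrichment cutoff (default 2).
#' @return data.frame with `fold` and logical `marked`.
#' @export
call_mark_state <- function(centers, chrom, track, half_window = 1000L,
                            background, threshold = 2.0) {
  if (background <= 0) stop("background must be > 0")
  m <- .window_means(track, chrom, centers - half_window, centers + half_window)
  fold <- m / background
  data.frame(fold = fold, marked = fold >= threshold)
}

#' Mark-based enhancer class
#'
#' Distal sites are *pre-existing* when decorated with H3K4Me1 and H3K27Ac and
#' depleted for H3K27Me3 ("depleted" operationalized as not marked), and
#' *de novo* when none of the active marks (H3K4Me1, H3K27Ac, P300) is
#' present; anything else is *ambiguous*. P300 is recorded but not required
#' for the pre-existing call unless `require_p300 = TRUE`.
#'
#' @param k4me1,k27ac,p300,k27me3 logical vectors of marked states (recycled
#'   to a common length).
#' @param require_p300 also require P300 for pre-existing (default FALSE).
#' @return factor with levels `pre_existing`, `de_novo`, `ambiguous`.
#' @export
classify_by_marks <- function(k4me1, k27ac, p300, k27me3, require_p300 = FALSE) {
  n <- max(length(k4me1), length(k27ac), length(p300), length(k27me3))
  k4me1 <- rep_len(k4me1, n); k27ac <- rep_len(k27ac, n)
  p300 <- rep_len(p300, n); k27me3 <- rep_len(k27me3, n)
  pre <- k4me1 & k27ac & !k27me3
  if (require_p300) pre <- pre & p300
  de <- !k4me1 & !k27ac & !p300
  cls <- ifelse(pre, "pre_existing", ifelse(de, "de_novo", "ambiguous"))
  factor(cls, levels = c("pre_existing", "de_novo", "ambiguous"))
}

#' Promoter state from H3K4Me3/H3K27Me3 at the TSS
#'
#' Active = H3K4Me3 only; bivalent = both marks; inactive = H3K27Me3 only or
#' no marks.
#'
#' @param tss 0-based TSS positions.
#' @param chrom chromosomes.
#' @param k4me3,k27me3 `coverage_track`s.
#' @param promoter_half_window bp around the TSS (default 1000).
#' @param background_k4me3,background_k27me3 background levels per track.
#' @param threshold fold cutoff (default 2).
#' @return factor with levels `active`, `bivalent`, `inactive`.
#' @export
classify_promoter <- function(tss, chrom, k4me3, k27me3,
                              promoter_half_window = 1000L,
                              background_k4me3, background_k27me3,
                              threshold = 2.0) {
  m4 <- call_mark_state(tss, chrom, k4me3, promoter_half_window,
                        background_k4me3, threshold)$marked
  m27 <- call_mark_state(tss, chrom, k27me3, promoter_half_window,
                         background_k27me3, threshold)$marked
  st <- ifelse(m4 & m27, "bivalent", ifelse(m4, "active", "inactive"))
  factor(st, levels = c("active", "bivalent", "inactive"))
}

#' Keep distal sites (putative enhancers)
#'
#' @param sites `GRanges`.
#' @param genes gene table (`GRanges` from [read_gene_table()]).
#' @param min_tss_distance sites with `|midpoint - nearest TSS|` at or below
#'   this are removed (default 2000 bp).
#' @return Subset of `sites` with `nearest_gene` and `tss_distance` metadata
#'   columns attached.
#' @export
select_distal <- function(sites, genes, min_tss_distance = 2000L) {
  nt <- nearest_tss(sites, genes)
  keep <- !is.na(nt$distance) & abs(nt$distance) > min_tss_distance
  out <- sites[keep]
  out$nearest_gene <- nt$gene_id[keep]
  out$tss_distance <- nt$distance[keep]
  out
}

#' Build enhancer records: marks, classes, promoter states
#'
#' Runs the full classification of distal stable sites: per-mark fold
#' enrichment and marked state at the site midpoint, the mark-based class,
#' the nearest gene's promoter state, and the refined final class (see
#' [finalize_classes()]).
#'
#' @param sites distal `GRanges` from [select_distal()] (must carry
#'   `nearest_gene`, `tss_distance`).
#' @param marks named list of `coverage_track`s; must contain `k4me1`,
#'   `k27ac`, `p300`, `k27me3`, `k4me3` (baseline, t = 0).
#' @param genes gene table `GRanges`.
#' @param half_window,promoter_half_window scoring windows (bp).
#' @param threshold fold cutoff for marked (default 2).
#' @param backgrounds optional named numeric of per-track backgrounds;
#'   estimated with [estimate_background()] when missing.
#' @param background_seed seed for background estimation.
#' @param require_p300 see [classify_by_marks()].
#' @return data.frame (one row per site): coordinates, per-mark folds,
#'   `mark_class`, `promoter_state`, `final_class`, `nearest_gene`,
#'   `tss_distance`.
#' @export
build_enhancer_records <- function(sites, marks, genes,
                                   half_window = 1000L,
                                   promoter_half_window = 1000L,
                                   threshold = 2.0, backgrounds = NULL,
                                   background_seed = 1L,
                                   require_p300 = FALSE) {
  needed <- c("k4me1", "k27ac", "p300", "k27me3", "k4me3")
  if (!all(needed %in% names(marks))) {
    stop("marks must include: ", paste(needed, collapse = ", "))
  }
  if (is.null(backgrounds)) backgrounds <- numeric(0)
  for (mk in needed) {
    if (is.null(backgrounds[mk]) || is.na(backgrounds[mk])) {
      backgrounds[mk] <- estimate_background(marks[[mk]], seed = background_seed)
    }
  }
  mid <- interval_midpoint(sites)
  chrom <- as.character(GenomicRanges::seqnames(sites))
  states <- lapply(c(k4me1 = "k4me1", k27ac = "k27ac", p300 = "p300",
                     k27me3 = "k27me3"), function(mk) {
    call_mark_state(mid, chrom, marks[[mk]], half_window,
                    backgrounds[mk], threshold)
  })
  mark_class <- classify_by_marks(states$k4me1$marked, states$k27ac$marked,
                                  states$p300$marked, states$k27me3$marked,
                                  require_p300 = require_p300)
  gidx <- match(sites$nearest_gene, genes$gene_id)
  if (anyNA(gidx)) stop("nearest_gene not found in gene table")
  promoter_state <- classify_promoter(
    genes$tss[gidx], as.character(GenomicRanges::seqnames(genes))[gidx],
    marks$k4me3, marks$k27me3, promoter_half_window,
    backgrounds["k4me3"], backgrounds["k27me3"], threshold)
  rec <- data.frame(
    chrom = chrom,
    start = GenomicRanges::start(sites) - 1L,
    end = GenomicRanges::end(sites),
    center = mid,
    fold_k4me1 = states$k4me1$fold, fold_k27ac = states$k27ac$fold,
    fold_p300 = states$p300$fold, fold_k27me3 = states$k27me3$fold,
    mark_class = mark_class,
    promoter_state = promoter_state,
    nearest_gene = sites$nearest_gene,
    tss_distance = sites$tss_distance,
    stringsAsFactors = FALSE
  )
  finalize_classes(rec)
}

#' Refine enhancer classes by promoter state
#'
#' The final class pairs the mark class with the nearest promoter's state:
#' mark-class pre-existing enhancers with an active promoter stay
#' *pre_existing*; mark-class de novo enhancers with an inactive promoter
#' stay *de_novo*; every other combination (including ambiguous mark classes)
#' is *excluded* rather than force-assigned.
#'
#' @param records data.frame with `mark_class` and `promoter_state` columns.
#' @return `records` with a `final_class` factor column
#'   (`pre_existing`/`de_novo`/`excluded`).
#' @export
finalize_classes <- function(records) {
  fc <- ifelse(records$mark_class == "pre_existing" &
                 records$promoter_state == "active", "pre_existing",
        ifelse(records$mark_class == "de_novo" &
                 records$promoter_state == "inactive", "de_novo", "excluded"))
  records$final_class <- factor(fc, levels = c("pre_existing", "de_novo",
                                               "excluded"))
  records
}

#' Per-class fraction of enhancers bound by another factor
#'
#' @param records enhancer record data.frame (needs coordinates and
#'   `final_class`).
#' @param factor_peaks `GRanges` of the factor's peaks.
#' @param flank bp added to each side of the enhancer region before overlap
#'   (default 0).
#' @param classes which classes to report (default the two final classes).
#' @return named numeric vector of bound fractions per class.
#' @export
overlap_with_factor <- function(records, factor_peaks, flank = 0L,
                                classes = c("pre_existing", "de_novo")) {
  gr <- records_to_granges(records, flank = flank)
  hit <- GenomicRanges::countOverlaps(gr, factor_peaks,
                                      ignore.strand = TRUE) > 0
  vapply(classes, function(cl) {
    i <- records$final_class == cl
    if (!any(i)) return(NA_real_)
    mean(hit[i])
  }, numeric(1))
}

#' Enhancer records as GRanges
#' @param records enhancer record data.frame.
#' @param flank bp added to each side.
#' @return `GRanges`.
#' @export
records_to_granges <- function(records, flank = 0L) {
  GenomicRanges::GRanges(records$chrom,
                         IRanges::IRanges(pmax(records$start - flank, 0L) + 1L,
                                          records$end + flank))
}
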