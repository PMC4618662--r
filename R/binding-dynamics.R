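#' Build a region x time presence matrix for one factor
#'
#' The region universe is the non-redundant merge of the factor's peaks over
#' all time points (or a caller-supplied universe, e.g. when two factors must
#' share the same regions); `presence[r, t]` is `TRUE` iff a peak at time `t`
#' overlaps region `r` by at least `min_overlap` bp.
#'
#' @param peaksets named list of `GRanges`, one per time point; names are the
#'   time labels, in order.
#' @param times numeric time values (same order); defaults to
#'   `as.numeric(names(peaksets))`.
#' @param min_overlap minimum overlap in bp (default 1).
#' @param regions optional `GRanges` universe; default
#'   `merge_intervals` of all peaks pooled.
#' @param factor_label free-text factor name.
#' @param time_unit `"hpi"` or `"min"` (annotation only).
#' @return A `tc_presence` object: list with `regions`, `times`,
#'   `time_labels`, logical matrix `presence`, `factor_label`, `time_unit`.
#' @export
build_presence <- function(peaksets, times = NULL, min_overlap = 1L,
                           regions = NULL, factor_label = "factor",
                           time_unit = "hpi") {
  if (length(peaksets) < 1L) stop("need at least one time point")
  if (is.null(times)) times <- as.numeric(names(peaksets))
  if (anyNA(times)) stop("time values could not be derived from names")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (is.null(regions)) {
    pooled <- do.call(c, lapply(unname(peaksets), GenomicRanges::granges))
    regions <- merge_intervals(pooled, min_gap = 0)
  }
  presence <- matrix(FALSE, nrow = length(regions), ncol = length(peaksets),
                     dimnames = list(NULL, names(peaksets)))
  for (j in seq_along(peaksets)) {
    h <- GenomicRanges::findOverlaps(regions, peaksets[[j]],
                                     minoverlap = as.integer(min_overlap),
                                     ignore.strand = TRUE)
    presence[unique(S4Vectors::queryHits(h)), j] <- TRUE
  }
  structure(list(regions = regions, times = times,
                 time_labels = names(peaksets), presence = presence,
                 factor_label = factor_label, time_unit = time_unit),
            class = "tc_presence")
}

#' @export
print.tc_presence <- function(x, ...) {
  cat("tc_presence:", x$factor_label, "-", nrow(x$presence), "regions x",
      ncol(x$presence), "time points (", x$time_unit, ")\n")
  invisible(x)
}

#' Classify regions as stably or transiently bound
#'
#' A region is *stable* when it is present at the terminal time point and
#' (in the default `"gapfree"` mode) at every sampled post-induction time from
#' its first detection through the terminal point; any interruption makes it
#' transient. `"terminal"` mode only requires presence at the terminal time.
#' Baseline (t = 0) presence is ignored: low-level leaky binding before
#' induction should not decide stability.
#'
#' @param p a `tc_presence`.
#' @param terminal_time numeric terminal time (must be one of `p$times`).
#' @param mode `"gapfree"` (default) or `"terminal"`.
#' @param ignore_baseline drop time 0 from consideration (default TRUE).
#' @return factor vector (`"stable"`/`"transient"`), one per region; regions
#'   never present post-induction are `"transient"`.
#' @export
classify_stability <- function(p, terminal_time, mode = c("gapfree", "terminal"),
                               ignore_baseline = TRUE) {
  mode <- match.arg(mode)
  ti <- which(p$times == terminal_time)
  if (length(ti) != 1L) stop("terminal_time not in time axis")
  use <- seq_along(p$times)
  if (ignore_baseline) use <- use[p$times[use] != 0]
  use <- use[p$times[use] <= terminal_time]
  m <- p$presence[, use, drop = FALSE]
  at_terminal <- p$presence[, ti]
  if (mode == "terminal") {
    lab <- ifelse(at_terminal, "stable", "transient")
  } else {
    gapfree <- apply(m, 1L, function(row) {
      first <- which(row)[1]
      !is.na(first) && all(row[first:length(row)])
    })
    lab <- ifelse(at_terminal & gapfree, "stable", "transient")
  }
  factor(lab, levels = c("stable", "transient"))
}

#' First detection time of a region
#'
#' @param p a `tc_presence`.
#' @param region_id region row index (vectorized).
#' @return numeric vector of earliest times with presence; `NA` if never
#'   present.
#' @export
first_detection <- function(p, region_id = seq_len(nrow(p$presence))) {
  vapply(region_id, function(r) {
    j <- which(p$presence[r, ])[1]
    if (is.na(j)) NA_real_ else p$times[j]
  }, numeric(1))
}

#' Classify the binding order of two factors at shared regions
#'
#' Uses detection order only (categorical), not signal magnitude: factor A is
#' first iff its first detection precedes B's, or B is never detected while A
#' is; equal first detections are simultaneous; regions where neither factor
#' is detected are unclassified.
#'
#' @param pa,pb `tc_presence` objects for factors A and B over the same
#'   region universe and time axis.
#' @param region_id region indices (default all).
#' @return data.frame with `region_id`, `order` (factor with levels
#'   `a_first`, `simultaneous`, `b_first`, `unclassified`), `first_a`,
#'   `first_b`.
#' @export
classify_binding_order <- function(pa, pb, region_id = seq_len(nrow(pa$presence))) {
  if (nrow(pa$presence) != nrow(pb$presence) || !all(pa$times == pb$times)) {
    stop("presence matrices must share regions and time axis")
  }
  fa <- first_detection(pa, region_id)
  fb <- first_detection(pb, region_id)
  order <- ifelse(is.na(fa) & is.na(fb), "unclassified",
           ifelse(is.na(fb), "a_first",
           ifelse(is.na(fa), "b_first",
           ifelse(fa < fb, "a_first",
           ifelse(fb < fa, "b_first", "simultaneous")))))
  data.frame(region_id = region_id,
             order = factor(order, levels = c("a_first", "simultaneous",
                                              "b_first", "unclassified")),
             first_a = fa, first_b = fb)
}

#' Fraction of sites pre-bound by a baseline factor
#'
#' @param sites `GRanges` (e.g. stable binding regions).
#' @param baseline_peaks `GRanges` of the partner factor in the starting cell
#'   state.
#' @param min_overlap minimum overlap in bp (default 1).
#' @return Fraction of `sites` overlapping `baseline_peaks`.
#' @export
prebound_fraction <- function(sites, baseline_peaks, min_overlap = 1L) {
  if (length(sites) == 0L) stop("prebound fraction undefined for empty site set")
  hit <- GenomicRanges::countOverlaps(sites, baseline_peaks,
                                      minoverlap = as.integer(min_overlap),
                                      ignore.strand = TRUE) > 0
  mean(hit)
}
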