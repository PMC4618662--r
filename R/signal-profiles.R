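#' Binned signal matrix around anchor positions
#'
#' `values[i, j]` is the mean per-base coverage of bin `j` of the window
#' centered on `centers[i]`, multiplied by `1e7 / library_scale` so tracks of
#' different depth are comparable (coverage per 10 million signal units).
#' Anchors whose window would cross a chromosome end are kept but their
#' out-of-bounds bins are `NA` and the row is flagged truncated (truncated
#' rows are dropped from [average_profile()]).
#'
#' @param track `coverage_track`.
#' @param centers 0-based anchor positions.
#' @param chrom chromosome of each anchor.
#' @param window total window span in bp (must be divisible by `bin`).
#' @param bin bin width in bp.
#' @param scale_to library-normalization target (default 1e7); use `NA` to
#'   skip scaling.
#' @return A `signal_matrix`: numeric matrix (anchors x bins) with attributes
#'   `window`, `bin`, `offsets` (bin start offsets relative to the center)
#'   and `truncated` (logical per row).
#' @export
binned_matrix <- function(track, centers, chrom, window, bin,
                          scale_to = 1e7) {
  if (window %% bin != 0) stop("window must be divisible by bin")
  nb <- window %/% bin
  lens <- .chrom_lengths(track$genome)
  half <- window %/% 2L
  win_start <- centers - half # 0-based start of the window
  scale <- if (is.na(scale_to) || track$library_scale == 0) 1 else
    scale_to / track$library_scale
  values <- matrix(NA_real_, nrow = length(centers), ncol = nb)
  truncated <- logical(length(centers))
  offs <- (seq_len(nb) - 1L) * bin - half
  for (chr in unique(chrom)) {
    i <- which(chrom == chr)
    L <- lens[[chr]]
    # 0-based bin starts, nb consecutive bins per anchor
    bs <- rep(win_start[i], each = nb) + rep((seq_len(nb) - 1L) * bin,
                                             times = length(i))
    be <- bs + bin
    ok <- bs >= 0 & be <= L
    v <- rep(NA_real_, length(bs))
    if (any(ok)) {
      vw <- IRanges::Views(track$cov[[chr]], start = bs[ok] + 1L, end = be[ok])
      v[ok] <- IRanges::viewMeans(vw) * scale
    }
    values[i, ] <- matrix(v, ncol = nb, byrow = TRUE)
    truncated[i] <- tapply(!ok, rep(seq_along(i), each = nb), any)
  }
  structure(values, class = c("signal_matrix", "matrix"),
            window = window, bin = bin, offsets = offs, truncated = truncated)
}

#' Average (metagene) profile of a signal matrix
#'
#' Column means over anchors; rows flagged as truncated at chromosome ends
#' are dropped first.
#'
#' @param m `signal_matrix` (or plain matrix).
#' @return Numeric vector of per-bin means.
#' @export
average_profile <- function(m) {
  if (nrow(m) == 0L) stop("empty signal matrix")
  tr <- attr(m, "truncated")
  keep <- if (is.null(tr)) rep(TRUE, nrow(m)) else !tr
  if (!any(keep)) stop("all rows truncated")
  colMeans(m[keep, , drop = FALSE])
}

#' Peak-bin summary of a profile
#'
#' The single number used to compare mark kinetics across time points: the
#' bin with the highest coverage.
#'
#' @param profile numeric vector.
#' @return `max(profile)`.
#' @export
peak_bin_summary <- function(profile) {
  if (length(profile) == 0L) stop("empty profile")
  max(profile)
}

#' Center-bin summary of a profile
#'
#' The value at the central bin; for even bin counts the left-of-center bin
#' is used (recorded convention).
#'
#' @param profile numeric vector.
#' @return The central element.
#' @export
center_summary <- function(profile) {
  n <- length(profile)
  if (n == 0L) stop("empty profile")
  profile[[(n + 1L) %/% 2L]]
}

#' Median-subtracted MNase nucleosome profile
#'
#' Counts MNase-protected fragment midpoints at each bp offset from the
#' anchor centers (window default 6 kb, bin 1 bp), sums over anchors and
#' subtracts the profile median, so phased nucleosomes appear as positive
#' peaks and nucleosome-depleted regions as a central valley below 0.
#'
#' @param fragments `GRanges` of MNase-protected fragments.
#' @param centers 0-based anchor positions.
#' @param chrom chromosome of each anchor.
#' @param window total span in bp (even; offsets run `-window/2 ..
#'   window/2 - 1`).
#' @param mode `"midpoint"` (default) counts fragment midpoints; `"coverage"`
#'   accumulates full fragment spans.
#' @return Numeric vector of length `window`, median-subtracted, with an
#'   `offsets` attribute.
#' @export
mnase_profile <- function(fragments, centers, chrom, window = 6000L,
                          mode = c("midpoint", "coverage")) {
  mode <- match.arg(mode)
  half <- window %/% 2L
  counts <- numeric(window)
  fchrom <- as.character(GenomicRanges::seqnames(fragments))
  fmid <- interval_midpoint(fragments)
  fstart <- GenomicRanges::start(fragments) - 1L
  fend <- GenomicRanges::end(fragments)
  for (chr in unique(chrom)) {
    ci <- which(chrom == chr)
    fi <- which(fchrom == chr)
    if (!length(fi)) next
    for (cc in centers[ci]) {
      lo <- cc - half
      if (mode == "midpoint") {
        off <- fmid[fi] - lo
        off <- off[off >= 0 & off < window]
        if (length(off)) {
          t <- tabulate(off + 1L, nbins = window)
          counts <- counts + t
        }
      } else {
        s <- pmax(fstart[fi] - lo, 0L)
        e <- pmin(fend[fi] - lo, window)
        keep <- e > s
        if (any(keep)) {
          d <- numeric(window + 1L)
          for (k in which(keep)) {
            d[s[k] + 1L] <- d[s[k] + 1L] + 1
            d[e[k] + 1L] <- d[e[k] + 1L] - 1
          }
          counts <- counts + cumsum(d)[seq_len(window)]
        }
      }
    }
  }
  prof <- counts - stats::median(counts)
  attr(prof, "offsets") <- seq_len(window) - 1L - half
  prof
}

#' Sort signal-matrix rows by total signal
#'
#' Heatmap display order: rows reordered by descending row sum (stable, so
#' ties keep their input order); `NA` bins are ignored in the sum.
#'
#' @param m `signal_matrix`.
#' @return The matrix with rows (and row attributes) reordered; attribute
#'   `order` holds the permutation.
#' @export
sort_rows <- function(m) {
  tot <- rowSums(m, na.rm = TRUE)
  ord <- order(-tot) # order() is stable
  out <- m[ord, , drop = FALSE]
  attrs <- attributes(m)
  attributes(out) <- c(attributes(out)[c("dim", "dimnames")],
                       attrs[setdiff(names(attrs), c("dim", "dimnames",
                                                     "truncated"))])
  attr(out, "truncated") <- attr(m, "truncated")[ord]
  attr(out, "order") <- ord
  class(out) <- class(m)
  out
}
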