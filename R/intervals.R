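#' Merge a peak set into non-redundant regions
#'
#' Overlapping (and, for `min_gap > 0`, nearby) intervals are collapsed so
#' that no two output regions are within `min_gap` bp of each other. With
#' `min_gap = 0` the union of covered bases is preserved exactly. This is the
#' construction behind the non-redundant binding-region universe.
#'
#' @param peaks `GRanges`.
#' @param min_gap minimum allowed gap (bp) between output regions.
#' @return A sorted, strand-ignorant `GRanges` of merged regions.
#' @export
merge_intervals <- function(peaks, min_gap = 0) {
  if (min_gap < 0) stop("min_gap must be >= 0")
  GenomicRanges::reduce(peaks, min.gapwidth = min_gap + 1L,
                        ignore.strand = TRUE)
}

#' Overlapping pairs between two peak sets
#'
#' @param a,b `GRanges`.
#' @param min_overlap minimum overlap in bp (>= 1) for a pair to be reported.
#' @return A data.frame with columns `a` and `b`: indices of overlapping
#'   pairs.
#' @export
intersect_peaks <- function(a, b, min_overlap = 1L) {
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  h <- GenomicRanges::findOverlaps(a, b, minoverlap = as.integer(min_overlap),
                                   ignore.strand = TRUE)
  data.frame(a = S4Vectors::queryHits(h), b = S4Vectors::subjectHits(h))
}

#' Nearest TSS for each site
#'
#' Distance is `site midpoint - TSS` in bp, signed in genome coordinates
#' (positive when the site center lies right of the TSS, irrespective of gene
#' strand). Ties between equidistant genes are broken by the
#' lexicographically smaller `gene_id` for determinism. Sites on chromosomes
#' without any gene are flagged unassigned (`NA` gene and distance).
#'
#' @param sites `GRanges` of sites.
#' @param genes `GRanges` from [read_gene_table()] (needs `gene_id`, `tss`).
#' @return data.frame with columns `gene_id` and `distance` (one row per
#'   site).
#' @export
nearest_tss <- function(sites, genes) {
  out <- data.frame(gene_id = rep(NA_character_, length(sites)),
                    distance = rep(NA_integer_, length(sites)))
  if (length(sites) == 0L || length(genes) == 0L) return(out)
  mid <- interval_midpoint(sites)
  schrom <- as.character(GenomicRanges::seqnames(sites))
  gchrom <- as.character(GenomicRanges::seqnames(genes))
  for (chr in unique(schrom)) {
    gi <- which(gchrom == chr)
    si <- which(schrom == chr)
    if (length(gi) == 0L) next
    # order genes by (tss, gene_id) so ties resolve to the smaller id;
    # genes sharing a TSS can never beat the smaller-id one, so drop them
    gi <- gi[order(genes$tss[gi], genes$gene_id[gi])]
    gi <- gi[!duplicated(genes$tss[gi])]
    tss <- genes$tss[gi]
    pos <- mid[si]
    right <- findInterval(pos, tss) # index of rightmost tss <= pos
    left_idx <- pmax(right, 1L)
    right_idx <- pmin(right + 1L, length(tss))
    d_left <- abs(pos - tss[left_idx])
    d_right <- abs(pos - tss[right_idx])
    has_left <- right >= 1L
    has_right <- right < length(tss)
    pick <- ifelse(!has_left, right_idx,
                   ifelse(!has_right, left_idx,
                          ifelse(d_left < d_right, left_idx,
                                 ifelse(d_right < d_left, right_idx,
                                        # equidistant: smaller gene_id
                                        ifelse(genes$gene_id[gi[left_idx]] <=
                                                 genes$gene_id[gi[right_idx]],
                                               left_idx, right_idx)))))
    out$gene_id[si] <- genes$gene_id[gi[pick]]
    out$distance[si] <- pos - tss[pick]
  }
  out
}
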