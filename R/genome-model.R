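#' Construct a genome model
#'
#' A genome model is the coordinate frame every interval and coverage track in
#' the pipeline refers to: an ordered set of uniquely named chromosomes with
#' known lengths. Internally it is a [GenomeInfoDb::Seqinfo] object, the
#' standard Bioconductor container for this information.
#'
#' @param chrom_names character vector of unique chromosome identifiers.
#' @param chrom_lengths integer vector of chromosome lengths in bp (all > 0).
#' @return A `Seqinfo` object.
#' @examples
#' gm <- genome_model(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_model <- function(chrom_names, chrom_lengths) {
  if (length(chrom_names) != length(chrom_lengths)) {
    stop("chrom_names and chrom_lengths must have equal length")
  }
  if (anyDuplicated(chrom_names)) stop("chromosome names must be unique")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  GenomeInfoDb::Seqinfo(seqnames = as.character(chrom_names),
                        seqlengths = as.integer(chrom_lengths))
}

#' @noRd
.chrom_lengths <- function(genome) {
  stats::setNames(GenomeInfoDb::seqlengths(genome),
                  GenomeInfoDb::seqnames(genome))
}

# Validate that a GRanges fits inside a genome model; error otherwise.
#' @noRd
.check_bounds <- function(gr, genome, what = "interval") {
  lens <- .chrom_lengths(genome)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  unknown <- !(chrom %in% names(lens))
  if (any(unknown)) {
    stop("unknown chromosome(s): ", paste(unique(chrom[unknown]), collapse = ", "))
  }
  if (any(GenomicRanges::end(gr) > lens[chrom]) || any(GenomicRanges::start(gr) < 1)) {
    stop(what, "(s) out of chromosome bounds")
  }
  invisible(TRUE)
}

#' Build a peak set
#'
#' Peak sets are plain [GenomicRanges::GRanges] objects; this helper builds one
#' from 0-based half-open coordinates (the convention of every on-disk format
#' this package reads and writes) and attaches an optional source label.
#' Internally `GRanges` uses 1-based closed coordinates; conversion happens
#' here and in the readers/writers only.
#'
#' @param chrom,start,end vectors of chromosome, 0-based start, exclusive end.
#' @param strand,name,score optional per-interval annotations.
#' @param genome optional `Seqinfo`; when given, bounds are validated and the
#'   seqinfo is attached.
#' @param source_label free-text label (factor, time point, cell type).
#' @return A `GRanges` with `name` and `score` metadata columns.
#' @export
peak_set <- function(chrom, start, end, strand = ".", name = NA_character_,
                     score = NA_real_, genome = NULL, source_label = NULL) {
  if (any(start < 0)) stop("start must be >= 0 (0-based half-open)")
  if (any(end <= start)) stop("end must be > start")
  strand <- rep_len(strand, length(chrom))
  strand <- ifelse(strand %in% c("+", "-"), strand, "*")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand,
    name = rep_len(as.character(name), length(chrom)),
    score = rep_len(as.numeric(score), length(chrom))
  )
  if (!is.null(genome)) {
    .check_bounds(gr, genome)
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(genome)
    GenomeInfoDb::seqinfo(gr) <- genome
  }
  if (!is.null(source_label)) S4Vectors::metadata(gr)$source_label <- source_label
  gr
}

#' Interval midpoints
#'
#' The anchoring position used for TSS distances and signal profiles is the
#' integer midpoint `floor((start0 + end0) / 2)` of the 0-based half-open
#' interval, i.e. site centers as used throughout the pipeline.
#'
#' @param gr a `GRanges`.
#' @return Integer vector of 0-based midpoint positions.
#' @export
interval_midpoint <- function(gr) {
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  as.integer(floor((start0 + end0) / 2))
}
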