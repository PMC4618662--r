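#' Read a BED file into a peak set
#'
#' Accepts BED3 through BED6, tab-separated, no header; lines starting with
#' `#`, `track` or `browser` are skipped. Coordinates on disk are 0-based
#' half-open and are converted to the internal 1-based `GRanges`
#' representation.
#'
#' @param path file path.
#' @param genome optional `Seqinfo` for bounds validation.
#' @param source_label optional label stored in the metadata of the result.
#' @return A `GRanges` with `name` and `score` columns.
#' @export
read_bed <- function(path, genome = NULL, source_label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(peak_set(character(), integer(), integer(), genome = genome,
                    source_label = source_label))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", idx[which(nf < 3L)[1]], " in ", path,
         ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("malformed BED line ", idx[bad[1]], " in ", path,
         ": non-integer coordinates")
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop("invalid BED line ", idx[bad[1]], " in ", path, ": start >= end")
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""),
                 NA_character_)
  score <- suppressWarnings(
    as.numeric(ifelse(nf >= 5L, vapply(fields, function(f) f[min(5L, length(f))], ""),
                      NA_character_)))
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) f[min(6L, length(f))], ""),
                   ".")
  peak_set(chrom, start, end, strand = strand, name = name, score = score,
           genome = genome, source_label = source_label)
}

#' Write a peak set as BED6
#'
#' Output is sorted by (chromosome, start) and uses 0-based half-open
#' coordinates; missing names become `.` and missing scores `0`.
#' `read_bed(write_bed(x))` reproduces `x` up to sorting.
#'
#' @param peaks a `GRanges`.
#' @param path output file path.
#' @export
write_bed <- function(peaks, path) {
  ord <- order(as.character(GenomicRanges::seqnames(peaks)),
               GenomicRanges::start(peaks), GenomicRanges::end(peaks))
  peaks <- peaks[ord]
  name <- if (!is.null(peaks$name)) peaks$name else rep(NA_character_, length(peaks))
  score <- if (!is.null(peaks$score)) peaks$score else rep(NA_real_, length(peaks))
  strand <- as.character(GenomicRanges::strand(peaks))
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = ifelse(is.na(name), ".", name),
    score = ifelse(is.na(score), 0, score),
    strand = ifelse(strand == "*", ".", strand)
  )
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 4-column bedGraph into a coverage track
#'
#' Per-base signal is stored run-length encoded (one `Rle` per chromosome,
#' built with [IRanges::coverage()]); bases not covered by any record are 0
#' and overlapping records are summed, treating records as additive fragment
#' piles.
#'
#' @param path bedGraph file (chrom, start0, end, value), `#`/`track` comments
#'   tolerated.
#' @param genome a `Seqinfo`; records must lie within its bounds.
#' @return A `coverage_track`: list with elements `cov` (an `RleList`),
#'   `genome` (the `Seqinfo`) and `library_scale` (total signal, the sum of
#'   value x width over all records).
#' @export
read_bedgraph <- function(path, genome) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- if (file.size(path) == 0) {
    data.table::data.table()
  } else {
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                      colClasses = list(character = 1))
  }
  if (nrow(dt) > 0) {
    dt <- dt[!grepl("^(#|track|browser)", dt[[1]])]
  }
  lens <- .chrom_lengths(genome)
  if (nrow(dt) == 0) {
    cov <- IRanges::RleList(lapply(lens, function(l) S4Vectors::Rle(0, l)),
                            compress = FALSE)
    return(coverage_track(cov, genome, library_scale = 0))
  }
  if (ncol(dt) < 4) stop("bedGraph must have 4 columns: ", path)
  data.table::setnames(dt, 1:4, c("chrom", "start", "end", "value"))
  if (any(!(dt$chrom %in% names(lens)))) {
    stop("unknown chromosome in bedGraph: ",
         setdiff(unique(dt$chrom), names(lens))[1])
  }
  if (any(dt$value < 0)) stop("negative value in bedGraph: ", path)
  if (any(dt$start < 0) || any(dt$end > lens[dt$chrom])) {
    stop("bedGraph record out of chromosome bounds in ", path)
  }
  gr <- GenomicRanges::GRanges(dt$chrom,
                               IRanges::IRanges(dt$start + 1L, dt$end),
                               seqinfo = genome)
  cov <- GenomicRanges::coverage(gr, weight = dt$value)
  coverage_track(cov, genome,
                 library_scale = sum(dt$value * (dt$end - dt$start)))
}

#' Construct a coverage track from an RleList
#'
#' @param cov `RleList`, one run-length vector per chromosome.
#' @param genome `Seqinfo`.
#' @param library_scale total signal used for library-size normalization; when
#'   `NULL` it is computed as the sum over all bases.
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(cov, genome, library_scale = NULL) {
  lens <- .chrom_lengths(genome)
  if (!setequal(names(cov), names(lens))) {
    stop("coverage chromosomes do not match genome model")
  }
  cov <- cov[names(lens)]
  if (any(vapply(cov, length, 0L) != lens)) {
    stop("coverage length does not match chromosome length")
  }
  if (is.null(library_scale)) {
    library_scale <- sum(vapply(cov, function(x) sum(as.numeric(S4Vectors::runValue(x)) *
                                                       S4Vectors::runLength(x)), 0))
  }
  structure(list(cov = cov, genome = genome, library_scale = library_scale),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track over", length(x$cov), "chromosome(s);",
      "library_scale =", format(x$library_scale), "\n")
  invisible(x)
}

#' Read a gene annotation table
#'
#' The gene table is BED6 with the name column holding the gene identifier;
#' the TSS is derived from the strand (start for `+`, end - 1 for `-`,
#' 0-based).
#'
#' @param path BED6 file of gene bodies.
#' @param genome optional `Seqinfo`.
#' @return A `GRanges` with `gene_id` and 0-based `tss` metadata columns.
#' @export
read_gene_table <- function(path, genome = NULL) {
  gr <- read_bed(path, genome = genome)
  if (length(gr) && anyDuplicated(gr$name)) stop("gene ids must be unique")
  gr$gene_id <- gr$name
  gr$tss <- gene_tss(gr)
  gr
}

#' 0-based TSS positions of genes
#'
#' @param genes `GRanges` of gene bodies with strand.
#' @return Integer vector: start (0-based) for `+`/unstranded genes, end-1 for
#'   `-` genes.
#' @export
gene_tss <- function(genes) {
  s <- as.character(GenomicRanges::strand(genes))
  ifelse(s == "-", GenomicRanges::end(genes) - 1L, GenomicRanges::start(genes) - 1L)
}

#' Read an expression table
#'
#' @param path TSV with first column `gene_id` and one column per condition
#'   (time point or cell type).
#' @return A numeric matrix, genes x conditions, with gene ids as row names.
#' @export
read_expression <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  if (any(m < 0)) stop("expression values must be >= 0")
  m
}

#' Write an expression matrix as TSV
#' @param expr genes x conditions matrix with row names.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  dt <- data.table::data.table(gene_id = rownames(expr))
  for (j in colnames(expr)) dt[[j]] <- expr[, j]
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
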