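#' Call regulated genes from a baseline/terminal comparison
#'
#' Fold change is `(terminal + floor) / (baseline + floor)`; the additive
#' floor keeps folds defined for silent genes and tames ratios between
#' background-level values. Genes are `up` when fold exceeds
#' `fold_threshold`, `down` below `1/fold_threshold`, `unchanged` otherwise.
#'
#' @param expr genes x conditions matrix (row names = gene ids).
#' @param baseline,terminal column names or indices.
#' @param fold_threshold fold cutoff (default 2).
#' @param floor additive pseudo-expression (default 1).
#' @return data.frame with `gene_id`, `fold`, `label`
#'   (factor up/down/unchanged).
#' @export
call_regulated <- function(expr, baseline, terminal, fold_threshold = 2.0,
                           floor = 1.0) {
  if (floor <= 0) stop("floor must be > 0")
  fold <- (expr[, terminal] + floor) / (expr[, baseline] + floor)
  label <- ifelse(fold > fold_threshold, "up",
                  ifelse(fold < 1 / fold_threshold, "down", "unchanged"))
  data.frame(gene_id = rownames(expr), fold = unname(fold),
             label = factor(label, levels = c("up", "down", "unchanged")),
             stringsAsFactors = FALSE)
}

#' Sliding-window site-gene association curve
#'
#' For each window size, the fraction of the given genes whose TSS lies
#' within that distance of the nearest site center
#' (`|TSS - nearest site center| <= window`). The curve is monotone
#' non-decreasing in the window size.
#'
#' @param genes gene table `GRanges` restricted to the genes of interest
#'   (e.g. upregulated genes).
#' @param sites `GRanges` of sites (e.g. stable binding regions).
#' @param windows ascending window sizes in bp (default 0 to 1 Mb, step
#'   10 kb).
#' @return data.frame with `window` and `fraction`.
#' @export
window_fraction_curve <- function(genes, sites,
                                  windows = seq(0, 1e6, by = 1e4)) {
  if (is.unsorted(windows)) stop("windows must be sorted ascending")
  if (length(genes) == 0L) stop("no genes supplied")
  mid <- interval_midpoint(sites)
  schrom <- as.character(GenomicRanges::seqnames(sites))
  gchrom <- as.character(GenomicRanges::seqnames(genes))
  tss <- genes$tss
  dist <- rep(Inf, length(genes))
  for (chr in unique(gchrom)) {
    si <- which(schrom == chr)
    gi <- which(gchrom == chr)
    if (!length(si)) next
    pos <- sort(mid[si])
    r <- findInterval(tss[gi], pos)
    dl <- ifelse(r >= 1, abs(tss[gi] - pos[pmax(r, 1L)]), Inf)
    dr <- ifelse(r < length(pos), abs(tss[gi] - pos[pmin(r + 1L, length(pos))]),
                 Inf)
    dist[gi] <- pmin(dl, dr)
  }
  data.frame(window = windows,
             fraction = vapply(windows, function(w) mean(dist <= w), numeric(1)))
}

#' Per-class expression kinetics of enhancer target genes
#'
#' For each final enhancer class, takes the upregulated genes nearest to
#' enhancers of that class and reports, per time point, the median expression
#' fold over baseline. The fold here is a plain ratio
#' `value / max(baseline, floor)` (the floor only guards division by zero),
#' unlike the additive floor used by [call_regulated()] for thresholding.
#'
#' @param records enhancer record data.frame (`final_class`, `nearest_gene`).
#' @param expr genes x time matrix.
#' @param regulated output of [call_regulated()]; only genes with
#'   `label == label_filter` are used.
#' @param baseline baseline column of `expr`.
#' @param label_filter regulation label to keep (default `"up"`).
#' @param floor divide-by-zero guard (default 1e-9).
#' @param classes classes to report.
#' @return data.frame with `class`, `time` (column label), `median_fold`,
#'   `n_genes`.
#' @export
class_expression_kinetics <- function(records, expr, regulated,
                                      baseline = 1L, label_filter = "up",
                                      floor = 1e-9,
                                      classes = c("pre_existing", "de_novo")) {
  keep_genes <- regulated$gene_id[regulated$label == label_filter]
  out <- list()
  times <- colnames(expr)
  if (is.null(times)) times <- as.character(seq_len(ncol(expr)))
  for (cl in classes) {
    g <- unique(records$nearest_gene[records$final_class == cl])
    g <- g[g %in% keep_genes & g %in% rownames(expr)]
    if (!length(g)) next
    base <- pmax(expr[g, baseline], floor)
    med <- vapply(seq_len(ncol(expr)),
                  function(j) stats::median(expr[g, j] / base), numeric(1))
    out[[cl]] <- data.frame(class = cl, time = times, median_fold = med,
                            n_genes = length(g), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Normalize a cell-type expression table by column means
#'
#' Cross-cell-type normalization: each value is divided by the average over
#' all listed genes of its cell type, so every column mean becomes 1. The
#' operation is idempotent.
#'
#' @param expr genes x cell-type matrix.
#' @return Matrix of the same shape with unit column means.
#' @export
normalize_celltypes <- function(expr) {
  mu <- colMeans(expr)
  if (any(mu == 0)) stop("cannot normalize a zero-mean column")
  sweep(expr, 2L, mu, "/")
}

#' Two-group comparison statistics
#'
#' The two tests used for group comparisons: the two-tailed Wilcoxon
#' rank-sum test (exact null when the combined sample size is at most 20 and
#' there are no ties, normal approximation with tie and continuity correction
#' otherwise) and the one-tailed Student's t test.
#'
#' @param a,b numeric samples.
#' @param test `"wilcoxon_two_tailed"` or `"t_one_tailed"`.
#' @param alternative for the one-tailed t test: `"greater"` (default) tests
#'   mean(a) > mean(b), `"less"` the reverse.
#' @return list with `statistic` and `p`.
#' @export
compare_groups <- function(a, b, test = c("wilcoxon_two_tailed", "t_one_tailed"),
                           alternative = "greater") {
  test <- match.arg(test)
  if (test == "wilcoxon_two_tailed") {
    exact <- (length(a) + length(b) <= 20) && !anyDuplicated(c(a, b))
    ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                              exact = exact, correct = TRUE))
  } else {
    ht <- stats::t.test(a, b, alternative = alternative)
  }
  list(statistic = unname(ht$statistic), p = min(max(ht$p.value, 0), 1))
}
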