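#' Construct a lineage tree
#'
#' A lineage tree is a named parent vector (`NA` for the single root),
#' validated to be acyclic with exactly one root.
#'
#' @param parents named character vector: `parents["child"] = "parent"`,
#'   root has `NA`.
#' @return A `lineage_tree` object (the validated named vector).
#' @export
lineage_tree <- function(parents) {
  if (is.null(names(parents)) || anyDuplicated(names(parents))) {
    stop("parents must be uniquely named by cell type")
  }
  root <- names(parents)[is.na(parents)]
  if (length(root) != 1L) stop("tree must have exactly one root")
  known <- names(parents)
  bad <- !is.na(parents) & !(parents %in% known)
  if (any(bad)) stop("unknown parent(s): ", paste(parents[bad], collapse = ", "))
  for (ct in known) { # walk to root; cycles never reach it
    seen <- character()
    cur <- ct
    while (!is.na(parents[[cur]])) {
      if (cur %in% seen) stop("cycle detected at ", cur)
      seen <- c(seen, cur)
      cur <- parents[[cur]]
    }
  }
  structure(parents, class = "lineage_tree")
}

#' Read a lineage tree from a "child: parent" config file
#'
#' One `child: parent` pair per line; the root is a line `name: .` (or an
#' empty parent). `#` comments tolerated.
#'
#' @param path config file path.
#' @return A `lineage_tree`.
#' @export
read_lineage_tree <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  kv <- strsplit(lines, ":", fixed = TRUE)
  child <- trimws(vapply(kv, `[[`, "", 1L))
  parent <- trimws(vapply(kv, function(x) if (length(x) > 1) x[[2]] else "", ""))
  parent[parent %in% c("", ".")] <- NA_character_
  lineage_tree(stats::setNames(parent, child))
}

#' Packaged hematopoietic lineage tree
#'
#' The standard hematopoietic hierarchy used for the enhancer-activity atlas:
#' LT-HSC -> ST-HSC -> MPP branching into the myeloid arm (CMP -> GMP ->
#' {Gn, Mphi}; CMP -> MEP -> Ery) and the lymphoid arm (CLP -> {B, T}).
#'
#' @return A `lineage_tree`.
#' @export
default_lineage_tree <- function() {
  lineage_tree(c(LT_HSC = NA_character_, ST_HSC = "LT_HSC", MPP = "ST_HSC",
                 CMP = "MPP", CLP = "MPP", GMP = "CMP", MEP = "CMP",
                 Gn = "GMP", Mphi = "GMP", Ery = "MEP", B = "CLP", T = "CLP"))
}

#' Enhancer activity fractions across cell types
#'
#' For each cell type and final enhancer class, the fraction of enhancer
#' regions (extended by `flank` bp per side) overlapping that cell type's
#' peak set (H3K27Ac/H3K4Me1 enhancer calls) by at least 1 bp. The flank
#' absorbs center-vs-summit offsets between datasets; the overlap is binary,
#' so duplicated peaks do not change fractions.
#'
#' @param records enhancer record data.frame.
#' @param peaks_by_type named list of `GRanges`, one per cell type.
#' @param flank bp per side (default 500).
#' @param classes final classes to report; `"pooled"` adds both classes
#'   combined.
#' @return data.frame with `cell_type`, `class`, `fraction`, `n`.
#' @export
activity_fractions <- function(records, peaks_by_type, flank = 500L,
                               classes = c("pre_existing", "de_novo")) {
  gr <- records_to_granges(records, flank = flank)
  out <- list()
  for (ct in names(peaks_by_type)) {
    hit <- GenomicRanges::countOverlaps(gr, peaks_by_type[[ct]],
                                        ignore.strand = TRUE) > 0
    for (cl in classes) {
      i <- if (cl == "pooled") records$final_class %in%
             c("pre_existing", "de_novo") else records$final_class == cl
      out[[length(out) + 1L]] <- data.frame(
        cell_type = ct, class = cl,
        fraction = if (any(i)) mean(hit[i]) else NA_real_,
        n = sum(i), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Factor occupancy fractions across cell types
#'
#' Same contract as [activity_fractions()], applied to transcription-factor
#' peak sets (e.g. C/EBPa ChIP in progenitors, GMPs and macrophages).
#'
#' @inheritParams activity_fractions
#' @param cebpa_peaks_by_type named list of `GRanges` per cell type.
#' @return data.frame with `cell_type`, `class`, `fraction`, `n`.
#' @export
occupancy_fractions <- function(records, cebpa_peaks_by_type, flank = 500L,
                                classes = c("pre_existing", "de_novo",
                                            "pooled")) {
  activity_fractions(records, cebpa_peaks_by_type, flank = flank,
                     classes = classes)
}

#' Root-to-leaf activity trajectories along the lineage tree
#'
#' @param tree a `lineage_tree`.
#' @param activity data.frame from [activity_fractions()]; every cell type in
#'   the tree must appear.
#' @return Named list (one element per leaf) of data.frames: the cell types
#'   on the root-to-leaf path in order, with per-class fractions as columns.
#' @export
trajectory_report <- function(tree, activity) {
  types <- names(tree)
  missing <- setdiff(types, unique(activity$cell_type))
  if (length(missing)) {
    stop("cell type(s) missing from activity table: ",
         paste(missing, collapse = ", "))
  }
  leaves <- setdiff(types, stats::na.omit(unclass(tree)))
  paths <- lapply(leaves, function(leaf) {
    path <- leaf
    while (!is.na(tree[[path[1]]])) path <- c(tree[[path[1]]], path)
    path
  })
  names(paths) <- leaves
  lapply(paths, function(path) {
    wide <- lapply(path, function(ct) {
      sub <- activity[activity$cell_type == ct, ]
      row <- data.frame(cell_type = ct, stringsAsFactors = FALSE)
      for (k in seq_len(nrow(sub))) row[[sub$class[k]]] <- sub$fraction[k]
      row
    })
    do.call(rbind, wide)
  })
}
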