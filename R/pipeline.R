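#' Load a previously generated scenario directory
#'
#' Rebuilds the `synthetic_scenario` handle (genome model, file map, truth
#' tables, config) from a directory written by [generate_scenario()].
#'
#' @param dir scenario directory.
#' @return A `synthetic_scenario` list.
#' @export
load_scenario <- function(dir) {
  cfg_path <- file.path(dir, "scenario_config.yaml")
  if (!file.exists(cfg_path)) stop("not a scenario directory: ", dir)
  cfg <- read_scenario_config(cfg_path)
  gdt <- data.table::fread(file.path(dir, "genome.tsv"))
  genome <- genome_model(gdt$chrom, gdt$length)
  paths <- list.files(dir, pattern = "\\.(bed|bedgraph|tsv|yaml)$",
                      full.names = TRUE)
  files <- stats::setNames(as.list(paths),
                           tools::file_path_sans_ext(basename(paths)))
  names(files)[names(files) == "expression_timecourse"] <- "expression"
  names(files)[names(files) == "scenario_config"] <- "config"
  truth <- list(
    enhancers = as.data.frame(data.table::fread(files$truth_enhancers)),
    genes = as.data.frame(data.table::fread(files$truth_genes)))
  structure(list(dir = dir, genome = genome, files = files, truth = truth,
                 config = cfg),
            class = "synthetic_scenario")
}

#' @noRd
.as_scenario <- function(scenario) {
  if (inherits(scenario, "synthetic_scenario")) return(scenario)
  if (is.character(scenario) && length(scenario) == 1L) {
    return(load_scenario(scenario))
  }
  stop("scenario must be a synthetic_scenario or a directory path")
}

#' Run the full enhancer-classification pipeline
#'
#' Executes every analysis stage on a scenario directory in dependency
#' order: non-redundant region construction and stability classification of
#' the induced factor's time course; PU.1 pre-binding; distal filtering;
#' baseline mark and promoter classification into pre-existing/de novo
#' enhancers; minute-scale binding-order inference at de novo enhancers;
#' regulated-gene calling, sliding-window gene association and per-class
#' expression kinetics; lineage-wide activity and occupancy fractions with
#' root-to-leaf trajectories. Deterministic given the scenario seed and
#' `background_seed`.
#'
#' @param scenario a `synthetic_scenario` (or scenario directory path).
#' @param out_dir optional directory; when given, a JSON report and per-stage
#'   TSVs are written there.
#' @param min_overlap bp overlap for presence calls (default 1).
#' @param stability_mode `"gapfree"` or `"terminal"` (see
#'   [classify_stability()]).
#' @param min_tss_distance distal threshold in bp (default 2000).
#' @param half_window,promoter_half_window mark scoring windows (bp).
#' @param threshold fold-enrichment cutoff for marked states.
#' @param flank bp flank for lineage overlap (default 500).
#' @param fold_threshold,floor regulated-gene call parameters.
#' @param background_seed seed for background estimation.
#' @param tree `lineage_tree` for trajectories (default packaged tree).
#' @return A `pipeline_report` list; see Details in the methods vignette.
#' @export
run_pipeline <- function(scenario, out_dir = NULL, min_overlap = 1L,
                         stability_mode = "gapfree",
                         min_tss_distance = 2000L, half_window = 1000L,
                         promoter_half_window = 1000L, threshold = 2.0,
                         flank = 500L, fold_threshold = 2.0, floor = 1.0,
                         background_seed = 1L,
                         tree = default_lineage_tree()) {
  scenario <- .as_scenario(scenario)
  cfg <- scenario$config
  genome <- scenario$genome
  files <- scenario$files
  need <- function(key) {
    p <- files[[key]]
    if (is.null(p) || !file.exists(p)) stop("missing scenario file: ", key)
    p
  }
  genes <- read_gene_table(need("genes"), genome = genome)

  ## stage 1: non-redundant regions + stability -----------------------------
  hpi <- cfg$time_points_hpi
  cebpa_sets <- lapply(hpi, function(t) {
    read_bed(need(paste0("cebpa_t", t, "hpi")), genome = genome)
  })
  names(cebpa_sets) <- as.character(hpi)
  presence <- build_presence(cebpa_sets, times = hpi,
                             min_overlap = min_overlap,
                             factor_label = "CEBPA", time_unit = "hpi")
  stability <- classify_stability(presence, terminal_time = max(hpi),
                                  mode = stability_mode)
  stable <- presence$regions[stability == "stable"]

  ## stage 2: PU.1 pre-binding ----------------------------------------------
  pu1_t0 <- read_bed(need("pu1_t0hpi"), genome = genome)
  prebound <- prebound_fraction(stable, pu1_t0, min_overlap = min_overlap)

  ## stage 3: distal filter + mark/promoter classification ------------------
  distal <- select_distal(stable, genes, min_tss_distance = min_tss_distance)
  marks <- lapply(c(k4me1 = "k4me1", k27ac = "k27ac", p300 = "p300",
                    k27me3 = "k27me3", k4me3 = "k4me3"), function(mk) {
    read_bedgraph(need(paste0(mk, "_t0hpi")), genome)
  })
  records <- build_enhancer_records(distal, marks, genes,
                                    half_window = half_window,
                                    promoter_half_window = promoter_half_window,
                                    threshold = threshold,
                                    background_seed = background_seed)
  promoter_dist <- function(cl) {
    i <- records$mark_class == cl
    if (!any(i)) return(c(active = NA_real_, bivalent = NA_real_,
                          inactive = NA_real_))
    prop.table(table(records$promoter_state[i]))[c("active", "bivalent",
                                                   "inactive")]
  }

  ## stage 4: binding order at de novo enhancers ----------------------------
  et <- cfg$early_time_points_min
  de_regions <- records_to_granges(records[records$final_class == "de_novo", ])
  read_early <- function(fac) {
    sets <- lapply(et, function(t) {
      read_bed(need(paste0(fac, "_early_", t, "min")), genome = genome)
    })
    names(sets) <- as.character(et)
    build_presence(sets, times = et, min_overlap = min_overlap,
                   regions = de_regions, factor_label = fac,
                   time_unit = "min")
  }
  order_calls <- if (length(de_regions)) {
    classify_binding_order(read_early("cebpa"), read_early("pu1"))
  } else NULL
  frac_a_first <- if (!is.null(order_calls)) {
    mean(order_calls$order == "a_first")
  } else NA_real_

  ## stage 5: expression linkage --------------------------------------------
  expr <- read_expression(need("expression"))
  regulated <- call_regulated(expr, baseline = 1L, terminal = ncol(expr),
                              fold_threshold = fold_threshold, floor = floor)
  up_genes <- genes[genes$gene_id %in%
                      regulated$gene_id[regulated$label == "up"]]
  curve <- window_fraction_curve(up_genes, stable)
  frac_100kb <- curve$fraction[curve$window == 1e5]
  kinetics <- class_expression_kinetics(records, expr, regulated,
                                        baseline = 1L)
  terminal_lab <- colnames(expr)[ncol(expr)]
  terminal_fold <- function(cl) {
    v <- kinetics$median_fold[kinetics$class == cl & kinetics$time ==
                                terminal_lab]
    if (length(v)) v else NA_real_
  }

  ## stage 6: lineage atlas ---------------------------------------------------
  act_types <- cfg$lineage_activity$cell_type
  k27ac_by_type <- lapply(stats::setNames(act_types, act_types), function(ct) {
    read_bed(need(paste0("k27ac_", ct)), genome = genome)
  })
  activity <- activity_fractions(records, k27ac_by_type, flank = flank)
  occ_types <- cfg$occupancy$cell_type
  cebpa_by_type <- lapply(stats::setNames(occ_types, occ_types), function(ct) {
    read_bed(need(paste0("cebpa_", ct)), genome = genome)
  })
  occupancy <- occupancy_fractions(records, cebpa_by_type, flank = flank)
  trajectories <- trajectory_report(tree, activity)

  report <- list(
    n_regions = length(presence$regions),
    n_stable = length(stable),
    n_transient = sum(stability == "transient"),
    pct_prebound_pu1 = 100 * prebound,
    n_distal = nrow(records),
    class_counts = as.list(table(records$final_class)),
    mark_class_counts = as.list(table(records$mark_class)),
    promoter_dist_pre_existing = as.list(100 * promoter_dist("pre_existing")),
    promoter_dist_de_novo = as.list(100 * promoter_dist("de_novo")),
    pct_cebpa_first_de_novo = 100 * frac_a_first,
    pct_upregulated_within_100kb = 100 * frac_100kb,
    terminal_fold_pre_existing = terminal_fold("pre_existing"),
    terminal_fold_de_novo = terminal_fold("de_novo"),
    activity = activity,
    occupancy = occupancy,
    trajectories = trajectories,
    params = list(min_overlap = min_overlap, stability_mode = stability_mode,
                  min_tss_distance = min_tss_distance,
                  half_window = half_window,
                  promoter_half_window = promoter_half_window,
                  threshold = threshold, flank = flank,
                  fold_threshold = fold_threshold, floor = floor,
                  background_seed = background_seed, seed = cfg$seed)
  )
  class(report) <- "pipeline_report"
  attr(report, "records") <- records
  attr(report, "regulated") <- regulated
  attr(report, "curve") <- curve
  attr(report, "kinetics") <- kinetics
  attr(report, "order_calls") <- order_calls
  attr(report, "stable") <- stable
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report:\n",
      " regions:", x$n_regions, "(stable", x$n_stable, ")\n",
      " PU.1 pre-bound:", round(x$pct_prebound_pu1, 1), "%\n",
      " final classes: pre_existing", x$class_counts$pre_existing,
      "/ de_novo", x$class_counts$de_novo,
      "/ excluded", x$class_counts$excluded, "\n",
      " pioneer-first (de novo):", round(x$pct_cebpa_first_de_novo, 1), "%\n",
      " upregulated within 100 kb:",
      round(x$pct_upregulated_within_100kb, 1), "%\n",
      " terminal folds:", round(x$terminal_fold_pre_existing, 2), "(pre) /",
      round(x$terminal_fold_de_novo, 2), "(de novo)\n")
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` (headline summary) plus per-stage TSVs
#' (`enhancer_records.tsv`, `regulated_genes.tsv`, `window_curve.tsv`,
#' `expression_kinetics.tsv`, `binding_order.tsv`, `activity.tsv`,
#' `occupancy.tsv`).
#'
#' @param report a `pipeline_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json <- report[setdiff(names(report), c("activity", "occupancy",
                                          "trajectories"))]
  json$activity <- report$activity
  json$occupancy <- report$occupancy
  json$trajectories <- report$trajectories
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  tsv <- function(df, name) {
    if (!is.null(df)) data.table::fwrite(df, file.path(out_dir, name),
                                         sep = "\t", quote = FALSE)
  }
  tsv(attr(report, "records"), "enhancer_records.tsv")
  tsv(attr(report, "regulated"), "regulated_genes.tsv")
  tsv(attr(report, "curve"), "window_curve.tsv")
  tsv(attr(report, "kinetics"), "expression_kinetics.tsv")
  tsv(attr(report, "order_calls"), "binding_order.tsv")
  tsv(report$activity, "activity.tsv")
  tsv(report$occupancy, "occupancy.tsv")
  invisible(out_dir)
}
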