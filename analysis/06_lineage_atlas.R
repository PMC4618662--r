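#!/usr/bin/env Rscript
# Stage 6: enhancer activity and C/EBPa occupancy across the lineage tree.
#
# Intersects the two enhancer classes with per-cell-type H3K27Ac enhancer
# calls (activity) and C/EBPa peak sets (occupancy) across the hematopoietic
# hierarchy, then serializes root-to-leaf activity trajectories.

suppressPackageStartupMessages(library(enhancerKinetics))

sc <- load_scenario("scratch/scenario")
cfg <- sc$config
rec <- as.data.frame(data.table::fread("scratch/derived/enhancer_records.tsv"))

types <- cfg$lineage_activity$cell_type
k27ac <- lapply(stats::setNames(types, types), function(ct) {
  read_bed(sc$files[[paste0("k27ac_", ct)]], genome = sc$genome)
})
activity <- activity_fractions(rec, k27ac)
data.table::fwrite(activity, "results/06_lineage_activity.tsv", sep = "\t")
message("H3K27Ac activity fractions:")
for (ct in c("LT_HSC", "GMP", "Mphi", "T")) {
  a <- activity[activity$cell_type == ct, ]
  message(sprintf("  %-7s pre-existing %.0f%% / de novo %.0f%%", ct,
                  100 * a$fraction[a$class == "pre_existing"],
                  100 * a$fraction[a$class == "de_novo"]))
}

occ_types <- cfg$occupancy$cell_type
cebpa <- lapply(stats::setNames(occ_types, occ_types), function(ct) {
  read_bed(sc$files[[paste0("cebpa_", ct)]], genome = sc$genome)
})
occupancy <- occupancy_fractions(rec, cebpa)
data.table::fwrite(occupancy, "results/06_occupancy.tsv", sep = "\t")
for (ct in occ_types) {
  o <- occupancy[occupancy$cell_type == ct, ]
  message(sprintf("  C/EBPa in %-5s %.0f%% of all enhancers", ct,
                  100 * o$fraction[o$class == "pooled"]))
}

tree <- default_lineage_tree()
tj <- trajectory_report(tree, activity)
jsonlite::write_json(tj, "results/06_trajectories.json", auto_unbox = TRUE,
                     digits = NA, dataframe = "rows", pretty = TRUE)
message("-> results/06_lineage_activity.tsv, results/06_occupancy.tsv, results/06_trajectories.json")
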