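#!/usr/bin/env Rscript
# Stage 3: pre-existing vs de novo enhancer classification.
#
# Restricts stable C/EBPa sites to distal (> 2 kb from any TSS) putative
# enhancers, calls baseline (t = 0) mark states at each site
# (H3K4Me1/H3K27Ac/P300 decoration, H3K27Me3 depletion), classifies the
# nearest promoter from H3K4Me3/H3K27Me3, and refines the two classes:
# pre-existing enhancers pair with active promoters, de novo enhancers with
# inactive ones; everything else is excluded.

suppressPackageStartupMessages(library(enhancerKinetics))

sc <- load_scenario("scratch/scenario")
genes <- read_gene_table(sc$files$genes, genome = sc$genome)
stable <- read_bed("scratch/derived/stable_sites.bed", genome = sc$genome)

distal <- select_distal(stable, genes)
message(length(distal), " of ", length(stable), " stable sites are distal")

marks <- lapply(c(k4me1 = "k4me1", k27ac = "k27ac", p300 = "p300",
                  k27me3 = "k27me3", k4me3 = "k4me3"), function(mk) {
  read_bedgraph(sc$files[[paste0(mk, "_t0hpi")]], sc$genome)
})
records <- build_enhancer_records(distal, marks, genes)

message("mark classes: ",
        paste(names(table(records$mark_class)), table(records$mark_class),
              collapse = ", ", sep = " = "))
for (cl in c("pre_existing", "de_novo")) {
  d <- prop.table(table(records$promoter_state[records$mark_class == cl]))
  message(sprintf("  %s promoters: %.0f%% active / %.0f%% bivalent / %.0f%% inactive",
                  cl, 100 * d["active"], 100 * d["bivalent"],
                  100 * d["inactive"]))
}
message("final classes: ",
        paste(names(table(records$final_class)), table(records$final_class),
              collapse = ", ", sep = " = "))

# partner-factor overlap in the starting state (Ebf1 analogue)
ebf1 <- read_bed(sc$files$ebf1_preB, genome = sc$genome)
fr <- overlap_with_factor(records, ebf1)
message(sprintf("Ebf1-bound: %.1f%% of pre-existing, %.1f%% of de novo",
                100 * fr["pre_existing"], 100 * fr["de_novo"]))

data.table::fwrite(records, "scratch/derived/enhancer_records.tsv", sep = "\t")
data.table::fwrite(as.data.frame(table(mark_class = records$mark_class,
                                       promoter_state = records$promoter_state,
                                       final_class = records$final_class)),
                   "results/03_class_composition.tsv", sep = "\t")
message("-> scratch/derived/enhancer_records.tsv, results/03_class_composition.tsv")
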