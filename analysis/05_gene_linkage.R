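#!/usr/bin/env Rscript
# Stage 5: regulated genes, sliding-window association, expression kinetics.
#
# Calls >2-fold up/downregulated genes between 0 and 48 hpi, measures the
# fraction of upregulated genes within increasing windows of a stable
# C/EBPa site (the 100-kb value is the headline), computes per-class median
# expression folds over time for upregulated genes nearest each enhancer
# class, and compares the two classes' terminal folds with the two-tailed
# Wilcoxon rank-sum test.

suppressPackageStartupMessages(library(enhancerKinetics))

sc <- load_scenario("scratch/scenario")
genes <- read_gene_table(sc$files$genes, genome = sc$genome)
stable <- read_bed("scratch/derived/stable_sites.bed", genome = sc$genome)
rec <- as.data.frame(data.table::fread("scratch/derived/enhancer_records.tsv"))
expr <- read_expression(sc$files$expression)

regulated <- call_regulated(expr, baseline = 1L, terminal = ncol(expr))
message(sum(regulated$label == "up"), " upregulated / ",
        sum(regulated$label == "down"), " downregulated / ",
        sum(regulated$label == "unchanged"), " unchanged genes (>2-fold rule)")

for (lab in c("up", "down")) {
  sel <- genes[genes$gene_id %in% regulated$gene_id[regulated$label == lab]]
  curve <- window_fraction_curve(sel, stable)
  if (lab == "up") {
    data.table::fwrite(curve, "results/05_window_curve_up.tsv", sep = "\t")
  }
  message(sprintf("%.1f%% of %sregulated genes within 100 kb of a stable site",
                  100 * curve$fraction[curve$window == 1e5], lab))
}

kin <- class_expression_kinetics(rec, expr, regulated, baseline = 1L)
data.table::fwrite(kin, "results/05_expression_kinetics.tsv", sep = "\t")
terminal <- colnames(expr)[ncol(expr)]
for (cl in c("pre_existing", "de_novo")) {
  k <- kin[kin$class == cl, ]
  message(sprintf("%s targets (n = %d): median fold %s",
                  cl, k$n_genes[1],
                  paste(sprintf("%.2f", k$median_fold), collapse = " -> ")))
}

# per-gene terminal folds for the two classes, rank-sum compared
fold_of <- function(cl) {
  g <- unique(rec$nearest_gene[rec$final_class == cl])
  g <- g[g %in% regulated$gene_id[regulated$label == "up"]]
  expr[g, ncol(expr)] / pmax(expr[g, 1L], 1e-9)
}
ws <- compare_groups(fold_of("de_novo"), fold_of("pre_existing"),
                     "wilcoxon_two_tailed")
message(sprintf("de novo vs pre-existing terminal folds: Wilcoxon W = %.0f, p = %.3g",
                ws$statistic, ws$p))
message("-> results/05_window_curve_up.tsv, results/05_expression_kinetics.tsv")
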