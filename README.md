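# enhancerKinetics

An R package (plus a numbered analysis workflow) for dissecting how a
pioneer transcription factor rewires the enhancer landscape during induced
transdifferentiation — the C/EBPα-driven conversion of pre-B cells into
macrophages being the motivating system. It is aimed at regulatory-genomics
analysts who have per-time-point ChIP-seq peak calls, coverage tracks and
expression tables and want the full integrative analysis: stable-site
selection, enhancer classification, binding-order inference, signal and
nucleosome profiling, gene linkage, and lineage-wide activity tracking.

## What it computes

Given peak calls for the induced factor across an induction time course
(hour-scale 0–48 hpi plus a minute-scale 10/30/60-min series), baseline
histone-mark/P300 coverage, a gene annotation, expression tables and
per-cell-type peak sets:

1. **Stable binding sites.** Per-time-point peaks are merged into a
   non-redundant region universe; a region is *stable* iff it is present at
   the terminal time point and at every sampled time from its first
   post-induction detection (gap-free rule; a terminal-only mode is
   available). Baseline binding is ignored for stability but defines the
   partner factor's *pre-bound* fraction.
2. **Enhancer classes.** Distal stable sites (>2 kb from any TSS) are
   classified from baseline marks — *pre-existing*:
   H3K4Me1 ∧ H3K27Ac ∧ ¬H3K27Me3; *de novo*: none of
   {H3K4Me1, H3K27Ac, P300} — where "marked" means fold enrichment ≥ 2 of
   the ±1 kb window mean over a sampled genomic background. Classes are
   refined by the nearest promoter's state (H3K4Me3-only = active, both
   marks = bivalent, H3K27Me3/none = inactive): pre-existing ∧ active and
   de novo ∧ inactive survive; everything else is excluded.
3. **Binding order.** First-detection times over the minute-scale series
   give a categorical call per de novo site: pioneer-first, simultaneous,
   partner-first, or unclassified.
4. **Profiles.** Binned signal matrices (6 kb / 100 bp, per-10M library
   scaling) with peak-bin and center-bin summaries; median-subtracted MNase
   fragment-midpoint profiles (6 kb / 1 bp) that expose nucleosome-depleted
   valleys versus dense chromatin.
5. **Gene linkage.** >2-fold regulated-gene calls with an additive floor, a
   sliding-window curve of the fraction of upregulated genes within
   0–1 Mb of a stable site, per-class median expression-fold kinetics, and
   Wilcoxon rank-sum / one-tailed t statistics for group comparisons.
6. **Lineage atlas.** Fractions of each class overlapping per-cell-type
   H3K27Ac (activity) and factor (occupancy) peak sets across a
   user-supplied lineage tree, with root-to-leaf trajectories.

A bundled synthetic-cohort generator (`generate_scenario`) emulates the
statistical structure of such a study — time-resolved peak appearance,
Gaussian mark peaks on Poisson background, two enhancer classes with
distinct mark/promoter/expression behavior, phased versus dense nucleosome
fragments, per-cell-type activity — with every headline quantity planted by
exact counts and recorded in a truth table, so the whole pipeline is
testable without any external download. See `vignettes/methods.Rmd` for the
model, parameter semantics and design decisions.

## Worked example

```r
library(enhancerKinetics)

cfg <- default_scenario_config(seed = 1)   # study-default synthetic cohort
sc  <- generate_scenario(cfg, "scratch/scenario")
rep <- run_pipeline(sc, out_dir = "results/report")
print(rep)
```

prints (numbers from this exact run):

```
pipeline_report:
  regions: 7000 (stable 1400 )
  PU.1 pre-bound: 40 %
  final classes: pre_existing 584 / de_novo 264 / excluded 552
  pioneer-first (de novo): 74.2 %
  upregulated within 100 kb: 70.1 %
  terminal folds: 3.97 (pre) / 8.69 (de novo)
```

Reading: of 7,000 non-redundant factor-bound regions, 1,400 are stably
bound through 48 hpi; 40% of those were already PU.1-bound in the starting
cells. Classification yields 584 pre-existing and 264 de novo enhancers
(552 mixed combinations excluded). The pioneer factor arrives before its
partner at 74.2% of de novo sites; 70.1% of >2-fold upregulated genes lie
within 100 kb of a stable site; and the median terminal expression fold of
upregulated target genes is ~4× for pre-existing versus ~9× for de novo
enhancers — the hallmark kinetic difference between hyper-activated open
chromatin and newly pioneered chromatin.

The same analysis, stage by stage with commentary and per-stage tables
under `results/`, is the numbered workflow:

```sh
Rscript analysis/01_simulate_cohort.R     # synthetic cohort + truth tables
Rscript analysis/02_binding_dynamics.R    # stable sites, pre-binding, order
Rscript analysis/03_classify_enhancers.R  # mark + promoter classification
Rscript analysis/04_signal_profiles.R     # H3K27Ac kinetics, MNase profiles
Rscript analysis/05_gene_linkage.R        # window curve, expression kinetics
Rscript analysis/06_lineage_atlas.R       # activity/occupancy across the tree
Rscript analysis/07_full_report.R         # consolidated JSON report
```

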