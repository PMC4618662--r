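#!/usr/bin/env Rscript
# Stage 7: one-shot end-to-end report.
#
# Re-runs every stage through the run_pipeline() orchestrator on the
# generated scenario and writes the consolidated JSON report plus per-stage
# tables under results/report/. Deterministic: re-running produces
# byte-identical output.

suppressPackageStartupMessages(library(enhancerKinetics))

rep <- run_pipeline("scratch/scenario", out_dir = "results/report")
print(rep)
message("consolidated report -> results/report/report.json")
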