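#!/usr/bin/env Rscript
# Stage 1 -- generate the synthetic diel microarray data set.
#
# Emulates an 8-time-point, 36-h field campaign on a two-day light/dark
# cycle: 400 genes (30% with a planted 24-h cosinor rhythm, 65% at array
# background), 6 probes per gene, duplicate chips at four time points, and
# chip-to-chip affine intensity distortions that the preprocessing stage
# must remove. Everything downstream runs from these files.

suppressPackageStartupMessages(library(dieltx))

cfg <- diel_config()
out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- simulate_ucyna_dataset(seed = cfg$seed, n_genes = cfg$n_genes)
write_expression_matrix(sim$probes, file.path(out, "probe_matrix.tsv"))
write_report(sim$probe_map, file.path(out, "probe_map.tsv"))
write_report(sim$truth, file.path(out, "truth.tsv"))
write_run_metadata(
  c(unclass(cfg), list(stage = "simulate")),
  file.path(out, "metadata.json")
)

cat(sprintf(
  "simulated %d probes x %d chips (%d genes: %d periodic, %d background)\n",
  nrow(sim$probes$values), ncol(sim$probes$values), nrow(sim$truth),
  sum(sim$truth$is_periodic), sum(sim$truth$is_background)
))
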