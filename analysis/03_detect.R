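#!/usr/bin/env Rscript
# Stage 3 -- detection calls: per-chip background (mean of the lowest 5% of
# signals), SNR = (S - BG)/BG, detected when SNR >= 5 on any chip.

suppressPackageStartupMessages(library(dieltx))

cfg <- diel_config()
genes <- read_expression_matrix("results/02_preprocess/gene_matrix.tsv",
  scale = "log2"
)
truth <- read_report("results/01_simulate/truth.tsv")

calls <- snr_detect(delog2(genes),
  threshold = cfg$snr_threshold,
  rule = cfg$snr_rule
)
dir.create("results/03_detect", showWarnings = FALSE)
write_report(as.data.frame(calls), "results/03_detect/detection.tsv")

planted <- mean(!truth$is_background)
cat(sprintf(
  "detected %d / %d genes (%.1f%%; planted expressed fraction %.1f%%)\n",
  sum(calls$detected), nrow(calls), 100 * mean(calls$detected), 100 * planted
))
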