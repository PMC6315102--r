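#!/usr/bin/env Rscript
# Stage 7 -- probe selection cascade on synthetic gene sequences: tile six
# 60-mers per gene, delete probes with >= 95% gapless identity to an
# off-target database, collapse >= 95%-identical probes, and remove probes
# shared with a sister strain (conserved nifH-like genes whitelisted).

suppressPackageStartupMessages(library(dieltx))

set.seed(diel_config()$seed + 40L)
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
mutate_at <- function(seq, k) {
  v <- strsplit(seq, "")[[1]]
  for (p in sample(seq_along(v), k)) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  }
  paste(v, collapse = "")
}

genes <- stats::setNames(
  vapply(1:25, function(i) rand_dna(420), ""),
  c("nifH", sprintf("gene%02d", 2:25))
)
# an environmental sequence carrying a near-identical copy (58/60) of one of
# gene05's probes, as a cross-hybridization hazard
g5_probe <- tile_candidates(genes[["gene05"]], "gene05")$sequence[2]
off_target <- c(env1 = paste0(
  rand_dna(60), mutate_at(g5_probe, 2), rand_dna(60)
))
other_strain <- stats::setNames(
  vapply(genes[1:6], function(g) mutate_at(g, 6), ""),
  paste0(names(genes)[1:6], "_B")
)

res <- probe_filter_cascade(
  genes,
  off_target_db = off_target,
  other_strain_db = other_strain,
  whitelist = "nifH"
)

dir.create("results/07_probes", recursive = TRUE, showWarnings = FALSE)
write_report(res$probes, "results/07_probes/probe_table.tsv")
write_report(res$attrition, "results/07_probes/attrition.tsv")

att <- res$attrition
cat(sprintf(
  "probes: %d candidates -> %d after cross-hyb -> %d after redundancy -> %d final (nifH probes kept: %d/%d)\n",
  att$remaining[1], att$remaining[2], att$remaining[3], att$remaining[4],
  sum(res$probes$status == "kept" & res$probes$gene_id == "nifH"),
  sum(res$probes$gene_id == "nifH")
))
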