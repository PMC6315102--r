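#!/usr/bin/env Rscript
# Stage 5 -- peak-phase clades: standardize each diel gene's averaged course,
# cluster by Pearson distance with complete linkage, cut into 4 clades, and
# report each clade's peak hour.

suppressPackageStartupMessages(library(dieltx))

cfg <- diel_config()
genes <- read_expression_matrix("results/02_preprocess/gene_matrix.tsv",
  scale = "log2"
)
rhythm <- read_report("results/04_rhythm/periodicity.tsv")
diel <- rhythm$gene_id[rhythm$is_diel]

z <- standardize_courses(subset_matrix(average_replicates(genes), diel))
clusters <- phase_cluster(pearson_distance(z), k = cfg$k_clusters)
cs <- cluster_summary(clusters, z)

dir.create("results/05_cluster", showWarnings = FALSE)
write_report(
  data.frame(gene_id = names(clusters$assignment),
             cluster = unname(clusters$assignment)),
  "results/05_cluster/assignments.tsv"
)
write_report(cs$summary, "results/05_cluster/clade_summary.tsv")

cat(sprintf(
  "clustered %d diel genes into %d clades; sizes %s; peak hours %s\n",
  length(diel), cfg$k_clusters,
  paste(cs$summary$size, collapse = "/"),
  paste(round(cs$summary$peak_hour, 1), collapse = "/")
))
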