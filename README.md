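# dieltx — diel transcription analysis for light/dark time-course arrays

Cyanobacteria organize their metabolism around the day/night (diel) cycle,
and whole-genome expression arrays sampled over 36 h of light/dark cycling
are the standard way to read that program: which genes are transcribed at
detectable levels, which of them cycle with a 24-h period, when each gene
peaks, and whether two organisms — say, a daytime N₂ fixer and a nighttime
one — run their ortholog rhythms in phase or in antiphase. `dieltx`
implements this analysis chain for R, together with the probe-selection
cascade used when such arrays are designed, and a synthetic-data generator
with planted ground truth so that every stage is testable end to end.

The package is aimed at microbial ecologists and transcriptome analysts who
work with diel time courses (microarray or any intensity matrix) and want a
small, fully tested implementation of the classic pipeline rather than a
platform-specific stack.

## What it computes

* **Preprocessing** — floor/log2, quantile normalization across chips, and
  Tukey median-polish summarization of each gene's probe block
  (`preprocess_probes()`, `median_polish()`, `quantile_normalize()`).
* **Detection** — per-chip background BG = mean of the lowest 5% of
  signals; SNR = (S − BG)/BG; a gene is detected when SNR ≥ 5 on any chip
  (`snr_detect()`), plus an abundance/IQR filter
  (`abundance_iqr_filter()`).
* **Periodicity** — the single-frequency Fourier score
  `F = √((Σ z·cos ωt)² + (Σ z·sin ωt)²)/n` at ω = 2π/24 h on the true
  (possibly irregular) sampling hours, with a seeded permutation null,
  Benjamini–Hochberg FDR (diel at q < 0.25), least-squares peak-hour
  estimates, and Welch light-vs-dark contrasts (`periodicity_test()`,
  `peak_hour()`, `light_dark_contrast()`).
* **Peak-phase clades** — per-gene standardization, Pearson distance
  d = 1 − r, complete-linkage clustering cut into k clades with per-clade
  peak hours (`phase_cluster()`, `cluster_summary()`).
* **Cross-organism networks** — Stineman monotone interpolation onto a
  common hourly grid, reciprocal-best-hit ortholog calling, and a
  correlation network with edges at r > 0.5
  (`stineman_interpolate()`, `align_to_grid()`, `reciprocal_best_hits()`,
  `build_network()`).
* **Probe design** — six 60-mers per gene, ≥95%-identity
  cross-hybridization deletion, 95% redundancy clustering, and cross-strain
  specificity filtering with a conserved-gene whitelist
  (`probe_filter_cascade()`).
* **Synthetic data** — planted cosinor rhythms, probe affinities, chip
  distortions and background genes under a reproducible seed
  (`simulate_ucyna_dataset()`, `simulate_two_organisms()`).

See `vignettes/diel-transcription-methods.Rmd` for the models, defaults and
design choices.

## Worked example

The `analysis/` directory holds the numbered workflow; each script is a
thin driver over the package functions and writes its tables under
`results/`. Running it from the repository root:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_detect.R
Rscript analysis/04_rhythm.R
Rscript analysis/05_cluster.R
Rscript analysis/06_network.R
Rscript analysis/07_probe_design.R
```

prints:

```
simulated 2400 probes x 12 chips (400 genes: 120 periodic, 260 background)
summarized 400 genes on 12 chips; post-normalization medians span 0.068 log2 units
detected 140 / 400 genes (35.0%; planted expressed fraction 35.0%)
diel genes: 127 / 140 detected (31.8% of all genes); sensitivity 1.00, FDP 0.06
clustered 127 diel genes into 4 clades; sizes 40/23/43/21; peak hours 0/18/12/6
common grid 6-22 h; 9582 edges at r > 0.5; 100% of ortholog pairs anti-correlated below -0.5
probes: 150 candidates -> 149 after cross-hyb -> 149 after redundancy -> 120 final (nifH probes kept: 6/6)
```

Reading these numbers: the simulated array plants 35% of genes above
background and 30% with a 24-h rhythm; detection recovers exactly the
planted expressed fraction (140/400), the permutation test finds 127 diel
genes (all 120 planted rhythms plus 7 false calls — a realized FDP of 0.06,
within the q < 0.25 target), the diel genes fall into four peak-phase
clades, and the 12-h phase shift planted between the two synthetic
organisms makes 100% of ortholog pairs anti-correlated below −0.5, so none
of them connect in the r > 0.5 network. The same chain runs as one call via
`run_diel_pipeline(diel_config(seed = 1))`, or `run_diel_demo(out_dir)` to
write all outputs at once.

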