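---
title: "Models and methods for diel transcription analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for diel transcription analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dieltx)
```

# The scientific setting

Marine cyanobacteria schedule their metabolism around the day/night cycle.
Free-living unicellular N~2~ fixers such as *Cyanothece* and *Crocosphaera*
fix nitrogen at night, when no photosynthetic O~2~ threatens the
oxygen-sensitive nitrogenase enzyme; the filamentous *Trichodesmium* and the
symbiotic, genome-reduced cyanobacterium UCYN-A instead fix N~2~ in the
daytime. Whole-genome expression arrays sampled over 36 h of light/dark
cycling are the standard instrument for characterizing these programs: a
minority of genes show a 24-h (diel) rhythm, genes cluster into a few
peak-phase clades, and cross-species comparison of ortholog rhythms shows
whether two organisms run their metabolism in phase or in antiphase.

`dieltx` implements that analysis chain as reusable, tested functions:
probe summarization and normalization, detection calls, Fourier-score
periodicity testing with a permutation null, peak-phase clustering,
cross-organism network comparison, and the oligonucleotide probe filter
cascade used when such arrays are designed. A synthetic-data generator with
planted ground truth makes every stage verifiable without external data.

# Time labels and the diel axis

Samples are labelled by phase and hour: `L6` is 6 h into the light period,
`D3` 3 h into darkness, and a `2` prefix marks the second day of a two-day
course. `parse_time_label()` places a label on a contiguous axis whose
origin is the first sunrise (first dark onset for dark-first regimes): under
the default 12 h/12 h photoperiod, light occupies hours 0–12 and dark 12–24
of each day, and the nominal within-day hour is taken modulo 24 so that an
end-of-dark label (`D12`, `2D12`) coincides with the sunrise it abuts.

Published label sequences are not always decodable label-by-label: a series
that begins in the dark can revisit the same phase-hour combination on day
two without the `2` prefix. The per-label arithmetic therefore defines only
a nominal hour, and `parse_time_series()` treats a declared-ordered sequence
as monotone, adding whole days whenever a later label fails to advance the
clock. The testable contract is ordering: each supported organism's
published sampling order parses to a strictly increasing hour vector, and
labels round-trip through `format_time_label()`.

# Preprocessing model

Probe intensities are floored at a small epsilon (default `1e-3` intensity
units, counted and reported) and log2-transformed. Chips are then
**quantile-normalized**: each chip's sorted values are replaced by the
across-chip mean of sorted values, which removes chip-wide affine intensity
drift while preserving within-chip ranks. Probe blocks are summarized to
one gene value per chip by **Tukey median polish**: the probes × chips
block is decomposed into `overall + probe effect + chip effect + residual`
by alternating row/column median sweeps, and the gene's chip value is
`overall + chip effect`. Medians make the summary robust to a single
aberrant probe, and the probe (row) effects absorb sequence-dependent
affinity differences.

Choices a user may care about:

* **Order of operations.** Normalization precedes summarization (the usual
  multichip convention, so that probe-level distributions are comparable
  when polished); `preprocess_probes(normalize_after = TRUE)` swaps the
  order for sensitivity analysis.
* **Polish convergence.** Sweeping stops when the reduction in the sum of
  absolute residuals falls below `tol` (default `1e-8`) or after `max_iter
  = 20` sweeps; medians of even-length vectors are midpoints. After the
  final column sweep the residual column medians are exactly zero; row
  medians are only approximately zero, which is inherent to the procedure.
* **Replicates** are averaged arithmetically on the log2 scale, after
  summarization, one column per time point.

# Detection calls

A gene is "transcribed at detectable levels" when its signal stands above
the chip background. The background of a chip is the mean of its lowest 5%
of signals; the signal-to-noise ratio of gene *i* on that chip is

$$\mathrm{SNR}_i = \frac{S_i - BG}{BG},$$

and a gene is detected when SNR ≥ 5 (default) on at least one chip. The
`any` rule maximizes sensitivity; `all` and `k_of_n` are available. SNR is
invariant to rescaling a chip by a constant, and the detected set shrinks
monotonically as the threshold rises — both properties are enforced by
tests. Detection runs on linear-scale values of the summarized,
*unaveraged* chips. A separate abundance/variability filter
(`abundance_iqr_filter()`: log2 value above a cutoff in ≥ 25% of samples
and log2 IQR ≥ 0.5) reproduces the filter style used on platforms without
a usable background estimate; its abundance cutoff must be given explicitly
because published descriptions of such filters mix linear and log2 units.

# Periodicity

The rhythm statistic is a single-frequency periodogram ("Fourier score").
With the series standardized to mean 0, sd 1, and evaluated at the true
sampling hours $t_j$ (irregular grids are used as-is, never resampled),

$$F = \frac{1}{n}\sqrt{\Big(\sum_j z_j \cos \omega t_j\Big)^2 +
 \Big(\sum_j z_j \sin \omega t_j\Big)^2},\qquad \omega = \frac{2\pi}{24\ \mathrm h}.$$

A constant series scores 0 by convention, and the score is invariant to
affine transforms of the series.

Significance comes from a **permutation null**: the assignment of values to
time points is permuted with a seeded generator and
$p = (1 + \#\{F_\pi \ge F\})/(n_\pi + 1)$, so the smallest attainable
p-value is $1/(n_\pi+1)$ ($n_\pi = 1999$ by default). One seeded
permutation set is drawn per call and applied to every gene: each gene's
values are independent of the (fixed) permutation set, so per-gene validity
is unchanged, while the computation vectorizes into two matrix products.
Genes are called diel at Benjamini–Hochberg `q < 0.25` (the conventional
screening threshold for diel transcriptome studies; exposed as `fdr`).
Among several possible null models for the Fourier score (Gaussian, AR(1),
permutation) the permutation null was chosen because it makes no
distributional assumption and is exactly testable.

The **peak hour** is estimated by least squares —
$x \approx a\cos\omega t + b\sin\omega t + c$, peak at
$\hat\phi = \mathrm{atan2}(b, a)/\omega$ — rather than by the raw
projection, because least squares remains unbiased on irregular grids where
$\sum_j \cos\omega t_j \ne 0$.

**Light/dark contrasts** use a per-gene Welch two-sample t-test between
light-phase and dark-phase chips with BH adjustment; the fold change is
$2^{|\Delta\bar x|}$. This is a deliberate simplification relative to
moderated (empirical-Bayes) microarray statistics: with ~12 chips it has
good power for sustained phase differences (planted 2-log2-unit shifts are
recovered at ≥ 95% in the test suite) but, unlike a rhythm test, it cannot
see genes peaking near dawn or dusk whose light and dark *means* coincide —
so the fraction of detected genes with significant light/dark differences
is substantially smaller than the fraction with a detectable rhythm, and
the two summaries should not be conflated.

# Peak-phase clades

Diel genes are standardized per gene across time points (mean 0, sd 1 with
the n−1 denominator; constant genes are excluded with a logged count).
Published figure legends in this literature are ambiguous between per-gene
and double (gene × sample) standardization; per-gene standardization was
chosen because it is what makes profiles comparable for correlation-based
clustering. The distance is $d = 1 - r$ (Pearson), clustered by
complete-linkage agglomeration and cut into `k = 4` clades by default (the
number of phase groups typically reported; `k` is a parameter and a
silhouette sweep over k = 2…8 is part of the tests). Cluster assignments
are deterministic given the input order; the test suite verifies agreement
with an exhaustive O(n³) agglomeration oracle and invariance of the
partition to gene order. Each clade is summarized by its mean standardized
course and the sampling hour at which that mean peaks.

# Cross-organism comparison

Different studies sample different grids, so courses are aligned onto a
common hourly grid before correlation. The grid spans the *intersection*
of the organisms' observed ranges (latest start to earliest end);
extrapolation and cyclic extension are refused — a conservative choice that
shortens the comparable window rather than inventing data.

Missing hours are interpolated with **Stineman's rational interpolation**,
implemented in-package: slopes at the knots are the tangents of the circle
through each consecutive point triple (chord slopes for collinear triples),
and within an interval the deviation from the secant is the rational
combination of the two tangent-line deviations. Two numerical safeguards
are applied to the slopes where both adjacent secants share a sign: the
slope keeps that sign, and its magnitude is capped at twice the smaller
adjacent secant magnitude. The cap is required for the method's
no-overshoot promise to hold exactly — circle tangents alone can overshoot
when knot spacings are extremely uneven — and it is inactive for linear
data (slope = secant), so exact reproduction of lines is preserved. The
contract enforced by tests: knots reproduce exactly, exactly linear data
reproduce exactly, and monotone knots yield a monotone interpolant on a
dense grid.

Orthologs between two gene sets are called by **reciprocal best hit** on
a user-supplied similarity matrix or on the built-in shared-k-mer score
(distinct shared 11-mers normalized by the shorter sequence's k-mer count)
— a desk-scale, swappable stand-in for alignment-based scoring. Ties for
best hit disqualify a gene rather than guessing.

The **co-expression network** connects genes whose courses on the common
grid correlate above a threshold (0.5 by default; 0.2 is the conventional
looser screen). Edges are defined by $r > \tau$, not $|r| > \tau$: the
figure convention in this literature connects positively co-expressed
genes, and anti-phase pairs are the interesting *absence* of an edge. An
`include_anticorrelated` flag provides the $|r|$ variant for exploration.
Edge sets are monotone decreasing in the threshold by construction.

# Probe filter cascade

Array design for an uncultivated organism tiles six 60-mers per gene and
then removes hazardous probes in three ordered stages: (1) **cross-
hybridization** — a probe is deleted when any window of an off-target
database matches it at ≥ 95% identity over 100% of its length; (2)
**redundancy** — greedy clustering in input order at 95% identity keeps one
representative per cluster; (3) **strain specificity** — probes matching
the sister strain's genes at ≥ 95% are deleted, except probes of
whitelisted, deliberately shared conserved genes (the *nifH* scenario),
which are retained with the evidence recorded.

Identity here is a gapless, full-length sliding-window scan over both
strands. This matches the hybridization rationale for 60-mer arrays — the
platform tolerates about 5% mismatches across the whole probe, a
full-length criterion — and makes the 95% boundary exact and testable
(57/60 matches are removed, 56/60 kept); gapped alignments are deliberately
out of scope. Probe placement uses even spacing along the gene (the
proprietary placement heuristics of array-design tools are not public), and
an annealing-temperature criterion is not implemented. Per-stage attrition
counts are reported and must sum to the total removed.

# The synthetic-data generator

The generator is the package's test bed and defines the study conditions;
its defaults are fixed, not tuning knobs. Per gene it plants one of three
classes — periodic (single-harmonic cosinor
$x(t) = M + A\cos(2\pi (t-\phi)/24) + \varepsilon$), expressed-but-flat, or
background — then builds probes (gene course + per-probe affinity offset +
probe noise), applies a per-chip affine distortion on the log2 scale, and
exponentiates to linear intensities.

Defaults and their rationale:

* **Design:** 8 time points spanning 36 h (`L6 … 2L12`) with duplicate
  chips at four of them — 12 chips — matching the two-day field-campaign
  structure such studies use; 6 probes per gene.
* **Class fractions:** 30% periodic, 65% background, 5% expressed-but-flat,
  realized exactly. This mirrors the reported structure of diel microarray
  data sets, where roughly a third of genes are detectable, most of those
  rhythmic, and the rest of the array sits at background.
* **Mesors:** expressed genes draw log2 mesors from a truncated normal
  centred at 6 (sd 1.5) on [4.5, 13.5] — detected genes in such data span
  roughly 2–13.5 log2 with a median near 6, and the lower truncation
  encodes that a detectable gene must clear the array's detection limit.
  Background genes sit at log2 3 (sd 0.3).
* **Rhythms:** amplitudes uniform on 0.8–2 log2 units (2- to 4-fold
  swings), phases uniform unless planted; gene-level noise sd 0.3 log2.
* **Distortions:** chip slopes ~ N(1, 0.02) and intercepts ~ N(0, 0.3) on
  the log2 scale — enough to make quantile normalization consequential
  without modelling scanner physics.

What the generator does **not** emulate: cross-hybridization between
related probes (the array-design module treats sequences, the expression
simulator does not), spatial chip artifacts, non-Gaussian noise,
multi-harmonic or asymmetric waveforms, and replicate-specific biology.
Passing the recovery tests therefore demonstrates that the analysis chain
is correct and well calibrated under its stated model — it does not certify
performance on real arrays whose noise violates these assumptions.

# Numerical conventions and problem sizes

Constant series: Fourier score 0, peak hour `NA` (flagged), excluded from
standardization. Permutation p-values use the add-one rule and a shared
seeded permutation matrix; permutation score ties are counted with a
`1e-12` guard. Zero/negative linear intensities are floored (default
`1e-3`) before log2. Quantile-normalization ties resolve in
first-occurrence order. Welch tests on two exactly constant groups return
p = 1 (equal means) or p = 0 (unequal), a degenerate case that arises only
in fixtures. All thresholds (SNR 5, FDR 0.25, network 0.5, identity 0.95,
k = 4) are configuration values echoed into the run metadata, never hidden
constants.

The shipped test suite and acceptance script run on deliberately compact
problems — 400-gene arrays with 12 chips, 1,000-gene null calibrations at
1,999 permutations, 100–120 ortholog pairs, 20–25 gene probe sets — sizes
at which every stage's behaviour (calibration, power, recovery) is already
measurable while a full run stays interactive on a single core.

# Known limitations

* The permutation null is shared across genes per call; p-values of
  different genes are computed against the same permutation set (valid
  per gene, slightly correlated jointly).
* The Welch light/dark contrast understates "difference" relative to
  moderated statistics and to rhythm detection (see above).
* RMA-style convolution background correction is not implemented; the
  chain starts at floored log2 intensities.
* The k-mer ortholog scorer is a stand-in: for real genomes, supply
  alignment-based score matrices to `reciprocal_best_hits()`.
* Cyclic extension of short series is refused rather than modelled, so a
  pair of organisms is compared only on their overlapping hours.
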