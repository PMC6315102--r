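#' Sample design emulating an 8-point, 36-h field time course
#'
#' Eight diel time points spanning 36 h with duplicate chips at four of them
#' (12 chips in total), the sampling structure typical of a two-day field
#' campaign where RNA yield allows replication at only some times.
#'
#' @param organism Organism tag.
#' @return Sample table from [diel_design()].
#' @export
samples_ucyna_like <- function(organism = "orgA") {
  diel_design(
    c(
      "L6", "L6", "L9", "L9", "D3", "D3", "D6",
      "2D12", "2L3", "2L9", "2L12", "2L12"
    ),
    organism = organism
  )
}

#' @rdname samples_ucyna_like
#' @export
samples_cyanothece_like <- function(organism = "orgB") {
  diel_design(c("L2", "L6", "L10", "D2", "D6", "D10"), organism = organism)
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  u <- stats::runif(
    n,
    stats::pnorm(lower, mean, sd),
    stats::pnorm(upper, mean, sd)
  )
  stats::qnorm(u, mean, sd)
}

#' Plant per-gene rhythm parameters for a synthetic diel data set
#'
#' Genes fall into three classes mirroring a typical diel microarray
#' experiment: periodic expressed genes (single-harmonic cosinor rhythm),
#' flat expressed genes, and background genes whose intensity sits at the
#' array's background level so that detection calls have true negatives.
#' Class fractions are realized exactly (by rounded counts).
#'
#' Defaults describe the emulated study conditions: 30% periodic genes and
#' 65% background genes; expressed mesors follow a truncated normal on the
#' log2 scale centred at 6 (range restricted to clear the detection limit),
#' amplitudes are uniform on 0.8-2 log2 units, phases uniform over the day
#' unless `phase_hours` plants them explicitly.
#'
#' @param n_genes Number of genes.
#' @param frac_periodic Fraction of genes with a planted 24-h rhythm.
#' @param frac_background Fraction of genes at background intensity.
#' @param mesor_mean,mesor_sd,mesor_range Truncated-normal parameters (log2)
#'   for expressed-gene mesors.
#' @param background_level,background_sd Log2 centre and between-gene sd of
#'   background intensities.
#' @param amplitude_range Uniform range (log2) of planted amplitudes.
#' @param noise_sd Per-sample biological/technical noise sd (log2) for
#'   expressed genes.
#' @param background_noise_sd Per-sample noise sd (log2) for background genes.
#' @param phase_hours Optional vector of peak hours recycled over the
#'   periodic genes (e.g. four planted phase clades); default uniform (0, 24).
#' @param period_hours Rhythm period (default 24).
#' @param seed Integer seed; identical seed and parameters give bit-identical
#'   truth tables.
#' @return Data frame (one row per gene): `gene_id`, `is_periodic`,
#'   `is_background`, `mesor`, `amplitude`, `phase_hour`, `noise_sd`, with
#'   `period_hours` and the generator parameters stored as attributes.
#' @export
simulate_truth <- function(n_genes = 400, frac_periodic = 0.30,
                           frac_background = 0.65,
                           mesor_mean = 6, mesor_sd = 1.5,
                           mesor_range = c(4.5, 13.5),
                           background_level = 3, background_sd = 0.3,
                           amplitude_range = c(0.8, 2),
                           noise_sd = 0.3, background_noise_sd = 0.2,
                           phase_hours = NULL, period_hours = 24, seed = 1) {
  stopifnot(
    n_genes >= 1, frac_periodic >= 0, frac_background >= 0,
    frac_periodic + frac_background <= 1, noise_sd >= 0
  )
  set.seed(seed)
  n_per <- round(frac_periodic * n_genes)
  n_bg <- round(frac_background * n_genes)
  n_flat <- n_genes - n_per - n_bg
  is_periodic <- c(rep(TRUE, n_per), rep(FALSE, n_flat + n_bg))
  is_background <- c(rep(FALSE, n_per + n_flat), rep(TRUE, n_bg))
  mesor <- numeric(n_genes)
  expressed <- !is_background
  mesor[expressed] <- rtrunc_norm(
    sum(expressed), mesor_mean, mesor_sd, mesor_range[1], mesor_range[2]
  )
  mesor[is_background] <- stats::rnorm(n_bg, background_level, background_sd)
  amplitude <- numeric(n_genes)
  amplitude[is_periodic] <- stats::runif(
    n_per, amplitude_range[1], amplitude_range[2]
  )
  phase_hour <- rep(NA_real_, n_genes)
  phase_hour[is_periodic] <- if (is.null(phase_hours)) {
    stats::runif(n_per, 0, period_hours)
  } else {
    rep_len(phase_hours, n_per)
  }
  truth <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    is_periodic = is_periodic,
    is_background = is_background,
    mesor = mesor,
    amplitude = amplitude,
    phase_hour = phase_hour,
    noise_sd = ifelse(is_background, background_noise_sd, noise_sd),
    stringsAsFactors = FALSE
  )
  attr(truth, "period_hours") <- period_hours
  attr(truth, "seed") <- seed
  truth
}

#' Simulate one gene's log2 time course under a cosinor model
#'
#' `x(t) = mesor + amplitude * cos(2*pi*(t - phase_hour)/period) + noise`,
#' with iid Gaussian noise; non-periodic genes have amplitude 0.
#'
#' @param mesor,amplitude,phase_hour Cosinor parameters (log2 units; hours).
#' @param noise_sd Gaussian noise sd (log2), must be >= 0.
#' @param hours Ordered absolute sampling hours.
#' @param period_hours Period (default 24).
#' @return Numeric vector of log2 values, one per hour.
#' @export
simulate_gene_course <- function(mesor, amplitude, phase_hour, noise_sd,
                                 hours, period_hours = 24) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  stopifnot(!is.unsorted(hours))
  phase_hour <- if (is.na(phase_hour)) 0 else phase_hour
  mesor + amplitude * cos(2 * pi * (hours - phase_hour) / period_hours) +
    stats::rnorm(length(hours), 0, noise_sd)
}

#' Simulate a probe-level intensity matrix with known truth
#'
#' Gene-level log2 courses are drawn from the planted cosinor model, each of
#' the `probes_per_gene` probes adds a fixed affinity offset plus probe-level
#' noise, a per-sample affine distortion (`scale * x + shift` on the log2
#' scale, emulating chip-to-chip intensity drift that quantile normalization
#' must undo) is applied, and values are exponentiated to linear intensities.
#'
#' @param truth Truth table from [simulate_truth()].
#' @param design Sample table, e.g. [samples_ucyna_like()].
#' @param probes_per_gene Number of probes per gene (>= 1).
#' @param affinity_sd Between-probe affinity offset sd (log2).
#' @param probe_noise_sd Probe-level measurement noise sd (log2).
#' @param scale_sd,shift_sd Per-sample affine distortion: slopes ~
#'   N(1, scale_sd), intercepts ~ N(0, shift_sd), both on the log2 scale.
#' @param seed Integer seed for the probe/sample-level randomness.
#' @return List with `probes` (linear-scale `expr_matrix`, probes x chips),
#'   `probe_map` (probe_id, gene_id), `gene_log2` (noise-free... the realized
#'   per-chip gene-level log2 courses before probe effects), `sample_truth`
#'   (per-chip scale/shift distortions) and `probe_truth` (affinity offsets).
#' @export
simulate_probe_matrix <- function(truth, design = samples_ucyna_like(),
                                  probes_per_gene = 6,
                                  affinity_sd = 0.5, probe_noise_sd = 0.25,
                                  scale_sd = 0.02, shift_sd = 0.3, seed = 1) {
  stopifnot(probes_per_gene >= 1)
  set.seed(seed + 1L)
  period <- attr(truth, "period_hours") %||% 24
  hours <- design$absolute_hour
  n_genes <- nrow(truth)
  n_samp <- nrow(design)
  gene_log2 <- t(vapply(
    seq_len(n_genes),
    function(i) {
      simulate_gene_course(
        truth$mesor[i], truth$amplitude[i], truth$phase_hour[i],
        truth$noise_sd[i], hours, period
      )
    },
    numeric(n_samp)
  ))
  dimnames(gene_log2) <- list(truth$gene_id, design$sample_id)
  probe_map <- data.frame(
    probe_id = paste0(
      rep(truth$gene_id, each = probes_per_gene), "_p",
      rep(seq_len(probes_per_gene), times = n_genes)
    ),
    gene_id = rep(truth$gene_id, each = probes_per_gene),
    stringsAsFactors = FALSE
  )
  affinity <- stats::rnorm(nrow(probe_map), 0, affinity_sd)
  scale_distortion <- stats::rnorm(n_samp, 1, scale_sd)
  shift_distortion <- stats::rnorm(n_samp, 0, shift_sd)
  probe_log2 <- gene_log2[probe_map$gene_id, , drop = FALSE] + affinity +
    stats::rnorm(nrow(probe_map) * n_samp, 0, probe_noise_sd)
  probe_log2 <- sweep(probe_log2, 2, scale_distortion, `*`)
  probe_log2 <- sweep(probe_log2, 2, shift_distortion, `+`)
  values <- 2^probe_log2
  dimnames(values) <- list(probe_map$probe_id, design$sample_id)
  list(
    probes = expression_matrix(values, design, "linear"),
    probe_map = probe_map,
    gene_log2 = gene_log2,
    sample_truth = data.frame(
      sample_id = design$sample_id,
      scale_distortion = scale_distortion,
      shift_distortion = shift_distortion,
      stringsAsFactors = FALSE
    ),
    probe_truth = data.frame(
      probe_id = probe_map$probe_id,
      affinity_offset = affinity,
      stringsAsFactors = FALSE
    )
  )
}

#' One-call synthetic data set under the default emulation preset
#'
#' Convenience wrapper: [simulate_truth()] with its defaults (30% periodic,
#' 65% background) on the 8-point/12-chip design of [samples_ucyna_like()],
#' then [simulate_probe_matrix()] with 6 probes per gene.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes.
#' @param ... Passed on to [simulate_truth()].
#' @return List as from [simulate_probe_matrix()], plus `truth` and `design`.
#' @export
simulate_ucyna_dataset <- function(seed = 1, n_genes = 400, ...) {
  truth <- simulate_truth(n_genes = n_genes, seed = seed, ...)
  design <- samples_ucyna_like()
  out <- simulate_probe_matrix(truth, design, seed = seed)
  out$truth <- truth
  out$design <- design
  out
}

#' Simulate two organisms with phase-shifted ortholog rhythms
#'
#' Organism B's orthologs reuse organism A's cosinor parameters with the peak
#' phase shifted by `phase_shift_hours` (12 h emulates a day-active organism
#' compared against a night-active one). The two organisms may be sampled on
#' different diel grids. All genes are periodic by default: the comparison
#' emulates the *diel* gene sets that enter a cross-species network. Returns
#' gene-level log2 matrices (probe effects are irrelevant at this stage).
#'
#' @param seed Integer seed.
#' @param phase_shift_hours Phase shift applied to organism B (hours).
#' @param n_genes Number of ortholog pairs.
#' @param design_a,design_b Sample tables for the two organisms.
#' @param amplitude_range,noise_sd,mesor_mean,mesor_sd As in
#'   [simulate_truth()]; all genes are expressed and periodic here.
#' @return List with `org_a`, `org_b` (log2 `expr_matrix`), `orthologs`
#'   (gene_a, gene_b, phase shift) and `truth` (organism-A parameters).
#' @export
simulate_two_organisms <- function(seed = 1, phase_shift_hours = 12,
                                   n_genes = 120,
                                   design_a = samples_ucyna_like("orgA"),
                                   design_b = samples_cyanothece_like("orgB"),
                                   amplitude_range = c(0.8, 2),
                                   noise_sd = 0.2,
                                   mesor_mean = 6, mesor_sd = 1.5) {
  set.seed(seed)
  truth <- data.frame(
    gene_id = sprintf("a%04d", seq_len(n_genes)),
    mesor = stats::rnorm(n_genes, mesor_mean, mesor_sd),
    amplitude = stats::runif(n_genes, amplitude_range[1], amplitude_range[2]),
    phase_hour = stats::runif(n_genes, 0, 24),
    stringsAsFactors = FALSE
  )
  course_set <- function(design, phases, prefix) {
    hours <- design$absolute_hour
    m <- t(vapply(
      seq_len(n_genes),
      function(i) {
        simulate_gene_course(
          truth$mesor[i], truth$amplitude[i], phases[i], noise_sd, hours
        )
      },
      numeric(nrow(design))
    ))
    dimnames(m) <- list(sub("^a", prefix, truth$gene_id), design$sample_id)
    expression_matrix(m, design, "log2")
  }
  org_a <- course_set(design_a, truth$phase_hour, "a")
  org_b <- course_set(design_b, (truth$phase_hour + phase_shift_hours) %% 24, "b")
  list(
    org_a = org_a,
    org_b = org_b,
    orthologs = data.frame(
      gene_a = rownames(org_a$values),
      gene_b = rownames(org_b$values),
      phase_shift_hours = phase_shift_hours,
      stringsAsFactors = FALSE
    ),
    truth = truth
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
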