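#' Chip background signal
#'
#' The background of a chip is the arithmetic mean of its lowest
#' `fraction` of signals (default: lowest 5%), computed over all entities on
#' the chip. With `n` signals, the `ceiling(fraction * n)` smallest values
#' are averaged.
#'
#' @param signals Linear-scale signal vector for one chip.
#' @param fraction Fraction of lowest signals to average, in (0, 1).
#' @return Background value (scalar).
#' @export
chip_background <- function(signals, fraction = 0.05) {
  if (length(signals) == 0L) stop("empty signal vector")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must lie in (0, 1)")
  }
  if (length(signals) * fraction < 1) {
    stop(
      "need at least ", ceiling(1 / fraction),
      " signals for fraction = ", fraction
    )
  }
  k <- ceiling(fraction * length(signals))
  mean(sort(signals)[seq_len(k)])
}

#' Signal-to-noise detection calls
#'
#' For each chip the background `BG` is the mean of the lowest 5% of all
#' signals ([chip_background()]); each gene's per-chip signal-to-noise ratio
#' is `SNR = (S - BG)/BG`. A gene is called detected when its SNR reaches
#' `threshold` (default 5) on chips according to `rule`: `"any"` (>= 1 chip,
#' the default), `"all"` (every chip), or `"k_of_n"` (at least `k` chips).
#'
#' SNR is invariant to rescaling a whole chip by a constant, and the detected
#' set can only shrink as `threshold` increases.
#'
#' @param em Linear-scale `expr_matrix` (gene level). Log2 input is refused.
#' @param threshold SNR detection cutoff (default 5).
#' @param rule Combination rule across chips.
#' @param k Number of chips required under `rule = "k_of_n"`.
#' @param bg_fraction Fraction for [chip_background()].
#' @return Data frame (class `detection_calls`): `gene_id`, `max_snr`,
#'   `n_above`, `detected`; the full SNR matrix and per-chip backgrounds are
#'   attached as attributes `snr` and `background`.
#' @export
snr_detect <- function(em, threshold = 5, rule = c("any", "all", "k_of_n"),
                       k = NULL, bg_fraction = 0.05) {
  stopifnot(inherits(em, "expr_matrix"))
  rule <- match.arg(rule)
  if (em$scale != "linear") {
    stop("snr_detect requires linear-scale signals; use delog2() first")
  }
  v <- em$values
  bg <- apply(v, 2L, chip_background, fraction = bg_fraction)
  snr <- sweep(sweep(v, 2L, bg), 2L, bg, `/`)
  above <- snr >= threshold
  n_above <- rowSums(above)
  detected <- switch(rule,
    any = n_above >= 1L,
    all = n_above == ncol(v),
    k_of_n = {
      if (is.null(k) || k < 1 || k > ncol(v)) {
        stop("rule 'k_of_n' needs k in 1..n_samples")
      }
      n_above >= k
    }
  )
  out <- data.frame(
    gene_id = rownames(v),
    max_snr = apply(snr, 1L, max),
    n_above = n_above,
    detected = detected,
    stringsAsFactors = FALSE
  )
  attr(out, "snr") <- snr
  attr(out, "background") <- bg
  attr(out, "threshold") <- threshold
  class(out) <- c("detection_calls", "data.frame")
  out
}

#' Abundance and variability gene filter
#'
#' A gene passes when (a) its log2 value exceeds `min_value` in at least
#' `min_fraction` of samples and (b) its interquartile range across all
#' samples on the log2 scale is at least `min_iqr_log2`. `min_value` has no
#' default and must be given explicitly on the log2 scale.
#'
#' @param em Log2-scale `expr_matrix`.
#' @param min_value Log2 abundance cutoff (required).
#' @param min_fraction Minimum fraction of samples above `min_value`
#'   (default 0.25), in (0, 1].
#' @param min_iqr_log2 Minimum IQR on the log2 scale (default 0.5).
#' @return Data frame: `gene_id`, `frac_above`, `iqr`, `pass_abundance`,
#'   `pass_iqr`, `pass`; the kept gene ids are attached as attribute `kept`.
#' @export
abundance_iqr_filter <- function(em, min_value, min_fraction = 0.25,
                                 min_iqr_log2 = 0.5) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$scale != "log2") stop("abundance_iqr_filter expects a log2-scale matrix")
  if (missing(min_value)) stop("min_value (log2 cutoff) must be supplied")
  if (min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must lie in (0, 1]")
  }
  v <- em$values
  frac_above <- rowMeans(v > min_value)
  iqr <- apply(v, 1L, stats::IQR)
  out <- data.frame(
    gene_id = rownames(v),
    frac_above = frac_above,
    iqr = iqr,
    pass_abundance = frac_above >= min_fraction,
    pass_iqr = iqr >= min_iqr_log2,
    stringsAsFactors = FALSE
  )
  out$pass <- out$pass_abundance & out$pass_iqr
  attr(out, "kept") <- out$gene_id[out$pass]
  out
}
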