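#' Single-frequency Fourier score of a time course
#'
#' Measures the strength of a fixed-period sinusoidal component: the series
#' is standardized to mean 0 / sd 1, projected onto `cos(2*pi*t/period)` and
#' `sin(2*pi*t/period)` at the true (possibly irregular) sampling hours, and
#' the score is the length of that projection divided by `n`:
#' `sqrt((sum z*cos)^2 + (sum z*sin)^2) / n`. A constant series scores 0 by
#' convention; the score is invariant to shifting or rescaling the series.
#'
#' @param x Numeric series (length >= 4).
#' @param t Absolute sampling hours, same length as `x`.
#' @param period Period in hours (default 24).
#' @return Non-negative scalar score.
#' @export
fourier_score <- function(x, t, period = 24) {
  if (length(x) != length(t)) stop("x and t must have the same length")
  if (length(x) < 4L) stop("need at least 4 time points")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    return(0)
  }
  z <- (x - mean(x)) / s
  w <- 2 * pi * t / period
  sqrt(sum(z * cos(w))^2 + sum(z * sin(w))^2) / length(x)
}

make_perm_matrix <- function(n, n_perm, seed) {
  set.seed(seed)
  vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
}

#' Permutation p-values for Fourier scores of many genes
#'
#' The null model permutes the assignment of values to time points with a
#' seeded generator; one seeded permutation set is drawn per call and applied
#' to every gene (each gene's values are independent of it, so per-gene
#' validity is unaffected, and the run is vectorized and reproducible).
#' P-values use the add-one rule `p = (1 + #{perm >= obs}) / (n_perm + 1)`,
#' so the smallest attainable p is `1/(n_perm + 1)`.
#'
#' @param x Matrix of series (genes x time points) or an `expr_matrix`
#'   (typically replicate-averaged).
#' @param t Absolute hours per column (taken from the sample table when `x`
#'   is an `expr_matrix`).
#' @param period Period in hours (default 24).
#' @param n_perm Number of permutations (default 1999; fewer than 99 draws a
#'   warning since the p resolution becomes too coarse).
#' @param seed Integer seed for the permutation generator.
#' @param fdr FDR threshold for the diel call (default 0.25).
#' @return Data frame (class `periodicity_result`): `gene_id`,
#'   `fourier_score`, `p_value`, `q_value` (Benjamini-Hochberg), `is_diel`
#'   (`q < fdr`), `peak_hour`.
#' @export
periodicity_test <- function(x, t = NULL, period = 24, n_perm = 1999,
                             seed = 1, fdr = 0.25) {
  if (inherits(x, "expr_matrix")) {
    if (is.null(t)) t <- x$samples$absolute_hour
    x <- x$values
  }
  stopifnot(is.matrix(x))
  if (is.null(t) || length(t) != ncol(x)) {
    stop("t must give one absolute hour per column")
  }
  if (ncol(x) < 4L) stop("need at least 4 time points")
  if (n_perm < 99) warning("n_perm < 99: permutation p-values are very coarse")
  n <- ncol(x)
  sds <- apply(x, 1L, stats::sd)
  z <- (x - rowMeans(x)) / ifelse(sds == 0, 1, sds)
  z[sds == 0, ] <- 0
  w <- 2 * pi * t / period
  cw <- cos(w)
  sw <- sin(w)
  obs <- sqrt((z %*% cw)^2 + (z %*% sw)^2)[, 1L] / n
  idx <- make_perm_matrix(n, n_perm, seed)
  cp <- matrix(cw[idx], nrow = n)
  sp <- matrix(sw[idx], nrow = n)
  perm <- sqrt((z %*% cp)^2 + (z %*% sp)^2) / n
  exceed <- rowSums(perm >= obs - 1e-12)
  p <- (1 + exceed) / (n_perm + 1)
  p[sds == 0] <- 1
  q <- fdr_adjust(p)
  peaks <- vapply(
    seq_len(nrow(x)),
    function(i) if (sds[i] == 0) NA_real_ else peak_hour(x[i, ], t, period),
    numeric(1)
  )
  out <- data.frame(
    gene_id = rownames(x) %||% sprintf("g%04d", seq_len(nrow(x))),
    fourier_score = obs,
    p_value = p,
    q_value = q,
    is_diel = q < fdr,
    peak_hour = peaks,
    stringsAsFactors = FALSE
  )
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "fdr") <- fdr
  class(out) <- c("periodicity_result", "data.frame")
  out
}

#' Permutation test for a single series
#'
#' Convenience wrapper around [periodicity_test()] for one gene.
#'
#' @inheritParams fourier_score
#' @param n_perm,seed As in [periodicity_test()].
#' @return List with `score` and `p_value`.
#' @export
permutation_test <- function(x, t, period = 24, n_perm = 1999, seed = 1) {
  res <- periodicity_test(matrix(x, nrow = 1L, dimnames = list("x", NULL)),
    t = t, period = period, n_perm = n_perm, seed = seed
  )
  list(score = res$fourier_score[1L], p_value = res$p_value[1L])
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; q-values are monotone in p.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of q-values.
#' @export
fdr_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Peak hour of the fitted daily component
#'
#' Least-squares fit of `a*cos(w t) + b*sin(w t) + c` at the true sampling
#' hours (robust to irregular grids); the peak hour is the phase of the
#' fitted cosine mapped to [0, period). Invariant to affine transforms of
#' `x`; undefined (NA, with a warning) for constant series.
#'
#' @inheritParams fourier_score
#' @return Peak hour in [0, period), or `NA` for a constant series.
#' @export
peak_hour <- function(x, t, period = 24) {
  if (length(x) != length(t)) stop("x and t must have the same length")
  if (length(x) < 4L) stop("need at least 4 time points")
  if (stats::sd(x) == 0) {
    warning("peak hour undefined for a constant series")
    return(NA_real_)
  }
  w <- 2 * pi * t / period
  fit <- stats::lm.fit(cbind(1, cos(w), sin(w)), x)
  a <- unname(fit$coefficients[2L])
  b <- unname(fit$coefficients[3L])
  (atan2(b, a) * period / (2 * pi)) %% period
}

#' Light-versus-dark differential transcription
#'
#' Welch two-sample t-test per gene comparing log2 values of light-phase and
#' dark-phase chips, with Benjamini-Hochberg adjustment. The fold change is
#' `2^|mean_light - mean_dark|` (always >= 1); `direction` is `"light_up"`
#' or `"dark_up"` when `q < alpha`, else `"flat"`.
#'
#' @param em Log2-scale `expr_matrix` with at least 2 light and 2 dark chips.
#' @param alpha Significance level on q for calling a direction (default 0.05).
#' @return Data frame: `gene_id`, `mean_light`, `mean_dark`,
#'   `log2_difference`, `fold_change`, `p_value`, `q_value`, `direction`.
#' @export
light_dark_contrast <- function(em, alpha = 0.05) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$scale != "log2") stop("light_dark_contrast expects log2 values")
  light <- em$samples$phase == "light"
  dark <- em$samples$phase == "dark"
  if (sum(light) < 2L || sum(dark) < 2L) {
    stop("need at least 2 light and 2 dark samples")
  }
  v <- em$values
  res <- t(vapply(
    seq_len(nrow(v)),
    function(i) {
      xl <- v[i, light]
      xd <- v[i, dark]
      ml <- mean(xl)
      md <- mean(xd)
      p <- if (stats::sd(xl) == 0 && stats::sd(xd) == 0) {
        if (isTRUE(all.equal(ml, md))) 1 else 0
      } else {
        stats::t.test(xl, xd)$p.value
      }
      c(ml, md, p)
    },
    numeric(3)
  ))
  p <- pmin(pmax(res[, 3L], .Machine$double.xmin), 1)
  q <- fdr_adjust(p)
  diff <- res[, 1L] - res[, 2L]
  direction <- ifelse(
    q < alpha,
    ifelse(diff > 0, "light_up", "dark_up"),
    "flat"
  )
  data.frame(
    gene_id = rownames(v),
    mean_light = res[, 1L],
    mean_dark = res[, 2L],
    log2_difference = diff,
    fold_change = 2^abs(diff),
    p_value = p,
    q_value = q,
    direction = direction,
    stringsAsFactors = FALSE
  )
}
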