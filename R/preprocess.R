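#' Tukey median polish of a two-way table
#'
#' Alternating row/column median sweeps decompose a matrix into
#' `overall + row_effect + column_effect + residual`. Used to summarize a
#' gene's probes-by-chips block into one robust value per chip: the
#' summarized chip value is `overall + column_effect`, which discounts both
#' probe-affinity differences (row effects) and outlying probes (medians, not
#' means). Sweeping stops when the reduction in the sum of absolute residuals
#' falls below `tol`, or after `max_iter` full sweeps.
#'
#' @param x Numeric matrix (or vector, treated as one row); all values finite.
#' @param max_iter Maximum number of full sweeps (default 20).
#' @param tol Absolute convergence tolerance on the sum of absolute
#'   residuals (default 1e-8).
#' @return Object of class `median_polish`: list with `overall`,
#'   `row_effects`, `col_effects`, `residuals`, `iterations`, `converged`.
#'   The decomposition reconstructs `x` up to floating-point error.
#' @export
median_polish <- function(x, max_iter = 20, tol = 1e-8) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  stopifnot(is.matrix(x), is.numeric(x))
  if (!all(is.finite(x))) stop("median_polish requires finite input")
  nr <- nrow(x)
  nc <- ncol(x)
  z <- x
  overall <- 0
  row_eff <- numeric(nr)
  col_eff <- numeric(nc)
  oldsum <- sum(abs(z))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter && !converged) {
    iter <- iter + 1L
    rdelta <- apply(z, 1L, stats::median)
    z <- z - rdelta
    row_eff <- row_eff + rdelta
    delta <- stats::median(col_eff)
    col_eff <- col_eff - delta
    overall <- overall + delta
    cdelta <- apply(z, 2L, stats::median)
    z <- sweep(z, 2L, cdelta)
    col_eff <- col_eff + cdelta
    delta <- stats::median(row_eff)
    row_eff <- row_eff - delta
    overall <- overall + delta
    newsum <- sum(abs(z))
    converged <- newsum == 0 || abs(oldsum - newsum) < tol
    oldsum <- newsum
  }
  structure(
    list(
      overall = overall, row_effects = row_eff, col_effects = col_eff,
      residuals = z, iterations = iter, converged = converged
    ),
    class = "median_polish"
  )
}

#' @export
print.median_polish <- function(x, ...) {
  cat(sprintf(
    "<median_polish> %d x %d, overall = %.4g, %d sweep(s), converged: %s\n",
    length(x$row_effects), length(x$col_effects), x$overall,
    x$iterations, x$converged
  ))
  invisible(x)
}

#' Quantile-normalize samples of an expression matrix
#'
#' Forces every sample (column) to share the across-sample mean distribution:
#' after normalization the sorted values of each column equal the mean of the
#' columns' sorted values, while within-column ranks are preserved (ties are
#' resolved in first-occurrence order). Applying the transform twice equals
#' applying it once.
#'
#' @param em An `expr_matrix` with at least 2 samples (any scale).
#' @return An `expr_matrix` on the same scale.
#' @export
quantile_normalize <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  v <- em$values
  if (ncol(v) < 2L) stop("quantile normalization needs >= 2 samples")
  target <- rowMeans(apply(v, 2L, sort))
  out <- v
  for (j in seq_len(ncol(v))) {
    out[order(v[, j]), j] <- target
  }
  expression_matrix(out, em$samples, em$scale)
}

#' Floor and log2-transform a linear-scale matrix
#'
#' Non-positive intensities (possible after background subtraction upstream)
#' are floored at `eps` before taking log2; the number of floored cells is
#' reported via a message and an attribute.
#'
#' @param em Linear-scale `expr_matrix`.
#' @param eps Small positive floor (default 1e-3 intensity units).
#' @return Log2-scale `expr_matrix` with attribute `n_floored`.
#' @export
log2_transform <- function(em, eps = 1e-3) {
  stopifnot(inherits(em, "expr_matrix"), eps > 0)
  if (em$scale != "linear") stop("log2_transform expects a linear-scale matrix")
  v <- em$values
  n_floored <- sum(v < eps)
  if (n_floored > 0) {
    message(n_floored, " intensity value(s) floored at ", eps, " before log2")
    v[v < eps] <- eps
  }
  out <- expression_matrix(log2(v), em$samples, "log2")
  attr(out, "n_floored") <- n_floored
  out
}

#' Undo the log2 transform
#'
#' @param em Log2-scale `expr_matrix`.
#' @return Linear-scale `expr_matrix` with values `2^x`.
#' @export
delog2 <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$scale != "log2") stop("delog2 expects a log2-scale matrix")
  expression_matrix(2^em$values, em$samples, "linear")
}

#' Summarize probe-level values to one gene value per chip
#'
#' Each gene's probes-by-chips block is decomposed by [median_polish()]; the
#' gene's chip value is `overall + column_effect`. Single-probe genes pass
#' through unchanged. Probes present in the matrix but absent from the map
#' are excluded with a warning (count kept as attribute `excluded_probes`);
#' probes named in the map but missing from the matrix are an error.
#'
#' @param probes Log2-scale probe-level `expr_matrix`.
#' @param probe_map Data frame with `probe_id`, `gene_id`.
#' @param max_iter,tol Passed to [median_polish()].
#' @return Gene-level log2 `expr_matrix` (genes in first-appearance order of
#'   the map).
#' @export
summarize_genes <- function(probes, probe_map, max_iter = 20, tol = 1e-8) {
  stopifnot(inherits(probes, "expr_matrix"))
  if (probes$scale != "log2") stop("summarize_genes expects log2-scale probes")
  validate_probe_map(probe_map)
  missing_probes <- setdiff(probe_map$probe_id, rownames(probes$values))
  if (length(missing_probes)) {
    stop(
      "probe(s) in map missing from matrix: ",
      paste(utils::head(missing_probes, 5L), collapse = ", ")
    )
  }
  unmapped <- setdiff(rownames(probes$values), probe_map$probe_id)
  if (length(unmapped)) {
    warning(length(unmapped), " probe(s) without gene mapping excluded")
  }
  genes <- unique(probe_map$gene_id)
  by_gene <- split(probe_map$probe_id, factor(probe_map$gene_id, levels = genes))
  vals <- probes$values
  out <- t(vapply(
    by_gene,
    function(pids) {
      block <- vals[pids, , drop = FALSE]
      if (nrow(block) == 1L) {
        return(block[1L, ])
      }
      mp <- median_polish(block, max_iter = max_iter, tol = tol)
      mp$overall + mp$col_effects
    },
    numeric(ncol(vals))
  ))
  dimnames(out) <- list(genes, colnames(vals))
  res <- expression_matrix(out, probes$samples, "log2")
  attr(res, "excluded_probes") <- length(unmapped)
  res
}

#' Average replicate chips per time point
#'
#' Arithmetic mean on the log2 scale across chips sharing a time label;
#' singleton time points pass through. The resulting sample ids are the time
#' labels themselves.
#'
#' @param em Log2-scale `expr_matrix`.
#' @return `expr_matrix` with one column per time point, in time order.
#' @export
average_replicates <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  s <- em$samples
  labels <- unique(s$label)
  out <- vapply(
    labels,
    function(l) rowMeans(em$values[, s$label == l, drop = FALSE]),
    numeric(nrow(em$values))
  )
  out <- matrix(out,
    nrow = nrow(em$values),
    dimnames = list(rownames(em$values), labels)
  )
  first <- match(labels, s$label)
  samples <- s[first, , drop = FALSE]
  samples$sample_id <- labels
  samples$replicate <- "1"
  rownames(samples) <- NULL
  expression_matrix(out, samples, em$scale)
}

#' Full probe-to-gene preprocessing chain
#'
#' Floors and log2-transforms linear probe intensities, quantile-normalizes
#' chips, and median-polish-summarizes probes to genes. Normalization
#' precedes summarization (the usual multichip convention); set
#' `quantile = FALSE` to skip it, or `normalize_after = TRUE` to run it after
#' summarization instead.
#'
#' @param probes Linear-scale probe-level `expr_matrix`.
#' @param probe_map Probe-to-gene map.
#' @param quantile Run quantile normalization (default TRUE).
#' @param normalize_after If TRUE, normalize the gene-level matrix instead of
#'   the probe-level one.
#' @param eps Floor for [log2_transform()].
#' @param max_iter,tol Median-polish controls.
#' @return Gene-level log2 `expr_matrix` (one column per chip, unaveraged).
#' @export
preprocess_probes <- function(probes, probe_map, quantile = TRUE,
                              normalize_after = FALSE, eps = 1e-3,
                              max_iter = 20, tol = 1e-8) {
  lg <- log2_transform(probes, eps = eps)
  if (quantile && !normalize_after) lg <- quantile_normalize(lg)
  genes <- summarize_genes(lg, probe_map, max_iter = max_iter, tol = tol)
  if (quantile && normalize_after) genes <- quantile_normalize(genes)
  genes
}
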