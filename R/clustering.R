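#' Standardize gene courses to z-scores
#'
#' Each gene's values are centred on its mean across time points and divided
#' by its standard deviation (denominator n-1), the standardization used for
#' relative diel profiles. Constant genes cannot be standardized and are
#' excluded (count in attribute `excluded_genes`, plus a message).
#'
#' @param em An `expr_matrix` (>= 2 time points) or a plain numeric matrix.
#' @return Numeric matrix of z-scores (rows: non-constant genes), with the
#'   sampling hours kept in attribute `hours` when available.
#' @export
standardize_courses <- function(em) {
  hours <- NULL
  if (inherits(em, "expr_matrix")) {
    hours <- em$samples$absolute_hour
    v <- em$values
  } else {
    v <- em
  }
  stopifnot(is.matrix(v), ncol(v) >= 2L)
  sds <- apply(v, 1L, stats::sd)
  constant <- sds == 0
  if (any(constant)) {
    message(sum(constant), " constant gene(s) excluded from standardization")
  }
  v <- v[!constant, , drop = FALSE]
  z <- (v - rowMeans(v)) / sds[!constant]
  attr(z, "excluded_genes") <- sum(constant)
  attr(z, "hours") <- hours
  z
}

#' Pearson-correlation distance matrix
#'
#' `d_ij = 1 - r_ij` with the sample (n-1) correlation between gene courses;
#' distances lie between 0 (identical profiles) and 2 (perfectly
#' anti-correlated profiles).
#'
#' @param z Matrix of (standardized) courses, genes in rows (>= 2 genes).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
pearson_distance <- function(z) {
  stopifnot(is.matrix(z), nrow(z) >= 2L)
  sds <- apply(z, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance course(s); exclude them (standardize_courses) first")
  }
  d <- 1 - stats::cor(t(z))
  d[d < 0] <- 0
  d[d > 2] <- 2
  diag(d) <- 0
  d
}

#' Complete-linkage phase clustering
#'
#' Agglomerative hierarchical clustering of the Pearson distance matrix with
#' complete linkage, cut into `k` groups. Cluster labels are contiguous
#' (1..k) in order of first appearance.
#'
#' @param d Symmetric distance matrix (e.g. from [pearson_distance()]).
#' @param k Number of clusters (default 4), 1 <= k <= n.
#' @return List of class `phase_clusters`: `assignment` (named integer
#'   vector), `k`, and the underlying `hclust` tree.
#' @export
phase_cluster <- function(d, k = 4) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (k < 1 || k > n) stop("k must lie in 1..n")
  tree <- stats::hclust(stats::as.dist(d), method = "complete")
  assignment <- stats::cutree(tree, k = k)
  structure(
    list(assignment = assignment, k = k, tree = tree),
    class = "phase_clusters"
  )
}

#' @export
print.phase_clusters <- function(x, ...) {
  cat(
    "<phase_clusters> k =", x$k, "; sizes:",
    paste(tabulate(x$assignment, x$k), collapse = ", "), "\n"
  )
  invisible(x)
}

#' Per-cluster mean course and peak hour
#'
#' Averages the standardized courses within each cluster and reports the
#' sampling hour at which the mean course is maximal, both on the absolute
#' 36-h axis and folded into the 24-h day.
#'
#' @param clusters A `phase_clusters` object (or a named assignment vector).
#' @param z Standardized course matrix (genes x time points).
#' @param hours Absolute sampling hours (defaults to `attr(z, "hours")`).
#' @return List with `summary` (data frame: cluster, size, peak_abs_hour,
#'   peak_hour) and `mean_courses` (clusters x time points matrix).
#' @export
cluster_summary <- function(clusters, z, hours = attr(z, "hours")) {
  assignment <- if (inherits(clusters, "phase_clusters")) {
    clusters$assignment
  } else {
    clusters
  }
  stopifnot(is.matrix(z), length(assignment) == nrow(z))
  if (is.null(hours)) stop("sampling hours required")
  ks <- sort(unique(assignment))
  mean_courses <- t(vapply(
    ks,
    function(k) colMeans(z[assignment == k, , drop = FALSE]),
    numeric(ncol(z))
  ))
  rownames(mean_courses) <- ks
  peak_abs <- hours[apply(mean_courses, 1L, which.max)]
  list(
    summary = data.frame(
      cluster = ks,
      size = as.integer(tabulate(match(assignment, ks))),
      peak_abs_hour = peak_abs,
      peak_hour = peak_abs %% 24,
      stringsAsFactors = FALSE
    ),
    mean_courses = mean_courses
  )
}
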