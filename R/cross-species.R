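#' Stineman monotone interpolation
#'
#' Rational interpolation after Stineman (1980): the interpolant passes
#' through every knot, reproduces exactly linear data exactly, and does not
#' overshoot -- a monotone knot sequence yields a monotone interpolant.
#' Slopes at the knots are the tangents of the circle through each
#' consecutive point triple (chord slopes for collinear triples; endpoint
#' slopes use the first/last triple), with a sign safeguard: where both
#' adjacent secants share a sign, the slope is clamped to that sign. Within
#' an interval the deviation from the secant line is the rational combination
#' of the two tangent-line deviations.
#'
#' @param t_known Strictly increasing knot positions (>= 2).
#' @param x_known Knot values.
#' @param t_query Query positions; must lie within `[min(t_known),
#'   max(t_known)]` (extrapolation is refused).
#' @return Interpolated values at `t_query`.
#' @export
stineman_interpolate <- function(t_known, x_known, t_query) {
  n <- length(t_known)
  stopifnot(length(x_known) == n)
  if (n < 2L) stop("need at least 2 knots")
  if (anyDuplicated(t_known) || is.unsorted(t_known, strictly = TRUE)) {
    stop("t_known must be strictly increasing without duplicates")
  }
  if (any(t_query < t_known[1L]) || any(t_query > t_known[n])) {
    stop("query point(s) outside the knot range; extrapolation refused")
  }
  yp <- stineman_slopes(t_known, x_known)
  s <- diff(x_known) / diff(t_known)
  i <- findInterval(t_query, t_known, rightmost.closed = TRUE)
  i[i >= n] <- n - 1L
  si <- s[i]
  yo <- x_known[i] + si * (t_query - t_known[i])
  dy1 <- (yp[i] - si) * (t_query - t_known[i])
  dy2 <- (yp[i + 1L] - si) * (t_query - t_known[i + 1L])
  prod <- dy1 * dy2
  out <- yo
  pos <- prod > 0
  out[pos] <- yo[pos] + prod[pos] / (dy1[pos] + dy2[pos])
  neg <- prod < 0
  out[neg] <- yo[neg] + prod[neg] *
    (2 * t_query[neg] - t_known[i[neg]] - t_known[i[neg] + 1L]) /
    ((dy1[neg] - dy2[neg]) * (t_known[i[neg] + 1L] - t_known[i[neg]]))
  out
}

circle_tangent_slope <- function(x, y, at) {
  # tangent slope at point `at` (1..3) of the circle through three points;
  # falls back to the chord across the triple when (nearly) collinear
  cr <- (x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1])
  scale <- max(abs(x[3] - x[1]), abs(y[3] - y[1]), 1)
  chord <- (y[3] - y[1]) / (x[3] - x[1])
  if (abs(cr) <= 1e-10 * scale^2) {
    return(chord)
  }
  q <- x^2 + y^2
  d <- 2 * cr
  a <- (q[1] * (y[2] - y[3]) + q[2] * (y[3] - y[1]) + q[3] * (y[1] - y[2])) / d
  b <- (q[1] * (x[3] - x[2]) + q[2] * (x[1] - x[3]) + q[3] * (x[2] - x[1])) / d
  if (y[at] == b) {
    return(chord)
  }
  -(x[at] - a) / (y[at] - b)
}

stineman_slopes <- function(x, y) {
  n <- length(x)
  s <- diff(y) / diff(x)
  if (n == 2L) {
    return(rep(s, 2L))
  }
  yp <- numeric(n)
  for (i in 2:(n - 1L)) {
    yp[i] <- circle_tangent_slope(x[(i - 1):(i + 1)], y[(i - 1):(i + 1)], 2L)
  }
  yp[1L] <- circle_tangent_slope(x[1:3], y[1:3], 1L)
  yp[n] <- circle_tangent_slope(x[(n - 2):n], y[(n - 2):n], 3L)
  # monotonicity safeguard: where both adjacent secants share a sign, the
  # slope keeps that sign and its magnitude stays within twice the smaller
  # secant magnitude (sufficient for the rational correction to preserve
  # monotone data; a no-op for linear data, where slope == secant)
  sec_left <- c(s[1L], s)
  sec_right <- c(s, s[n - 1L])
  up <- sec_left >= 0 & sec_right >= 0
  dn <- sec_left <= 0 & sec_right <= 0
  cap <- 2 * pmin(abs(sec_left), abs(sec_right))
  yp[up] <- pmin(pmax(yp[up], 0), cap[up])
  yp[dn] <- pmax(pmin(yp[dn], 0), -cap[dn])
  yp
}

#' Common hourly grid across organisms
#'
#' The grid spans the intersection of the organisms' observed time ranges
#' (from the latest series start to the earliest series end) so that no
#' series needs extrapolation.
#'
#' @param hour_sets List of absolute-hour vectors, one per organism.
#' @param step Grid step in hours (default 1).
#' @return Ordered numeric grid.
#' @export
common_grid <- function(hour_sets, step = 1) {
  stopifnot(is.list(hour_sets), length(hour_sets) >= 1L, step > 0)
  lo <- max(vapply(hour_sets, min, numeric(1)))
  hi <- min(vapply(hour_sets, max, numeric(1)))
  if (lo >= hi) stop("observed time ranges do not overlap")
  seq(lo, hi, by = step)
}

#' Align standardized gene courses onto a common time grid
#'
#' Standardizes each gene across its observed time points, then evaluates the
#' course on `grid_hours` by [stineman_interpolate()]. Genes observed at
#' fewer than `min_points` time points are excluded (count in attribute
#' `excluded_genes`). Values at observed time points pass through exactly.
#'
#' @param em Log2-scale `expr_matrix` (typically replicate-averaged).
#' @param grid_hours Common grid, within the observed hour range.
#' @param min_points Minimum observed time points per gene (default 4).
#' @return Matrix genes x grid hours (columns named by hour).
#' @export
align_to_grid <- function(em, grid_hours, min_points = 4) {
  stopifnot(inherits(em, "expr_matrix"))
  hours <- em$samples$absolute_hour
  if (min(grid_hours) < min(hours) || max(grid_hours) > max(hours)) {
    stop("grid extends outside the observed time range")
  }
  if (ncol(em$values) < min_points) {
    stop("fewer observed time points than min_points")
  }
  z <- standardize_courses(em)
  out <- t(apply(z, 1L, function(row) {
    stineman_interpolate(hours, row, grid_hours)
  }))
  colnames(out) <- format(grid_hours, trim = TRUE)
  attr(out, "hours") <- grid_hours
  attr(out, "excluded_genes") <- attr(z, "excluded_genes")
  out
}

#' Shared k-mer similarity between two sequence sets
#'
#' Desk-scale similarity scorer for reciprocal-best-hit ortholog calling:
#' the number of distinct k-mers shared by two sequences, normalized by the
#' number of k-mer positions in the shorter sequence. Intended as a
#' swappable stand-in for an alignment-based score table.
#'
#' @param seqs_a,seqs_b Named character vectors of DNA sequences.
#' @param k K-mer length (default 11).
#' @return Matrix of similarities, rows `seqs_a`, columns `seqs_b`.
#' @export
kmer_similarity <- function(seqs_a, seqs_b, k = 11) {
  stopifnot(k >= 1)
  kmers <- function(s) {
    L <- nchar(s)
    if (L < k) {
      return(character(0))
    }
    unique(substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L))
  }
  ka <- lapply(seqs_a, kmers)
  kb <- lapply(seqs_b, kmers)
  out <- matrix(0,
    nrow = length(seqs_a), ncol = length(seqs_b),
    dimnames = list(names(seqs_a), names(seqs_b))
  )
  for (i in seq_along(ka)) {
    for (j in seq_along(kb)) {
      denom <- min(nchar(seqs_a[[i]]), nchar(seqs_b[[j]])) - k + 1L
      if (denom >= 1L) {
        out[i, j] <- length(intersect(ka[[i]], kb[[j]])) / denom
      }
    }
  }
  out
}

#' Reciprocal-best-hit ortholog pairs
#'
#' A pair (a, b) is reported only when `b` is `a`'s unique best hit in
#' `scores_ab` and `a` is `b`'s unique best hit in `scores_ba`. Ties for
#' best hit disqualify the gene (counted in attribute `n_ties`).
#'
#' @param scores_ab Similarity matrix, rows = genes of A, columns = genes of B.
#' @param scores_ba Similarity matrix, rows = genes of B, columns = genes of A.
#' @return Data frame: `gene_a`, `gene_b`, `score_ab`, `score_ba`.
#' @export
reciprocal_best_hits <- function(scores_ab, scores_ba) {
  stopifnot(is.matrix(scores_ab), is.matrix(scores_ba))
  if (nrow(scores_ab) != ncol(scores_ba) || ncol(scores_ab) != nrow(scores_ba)) {
    stop("score matrix dimensions do not match (A x B vs B x A)")
  }
  best <- function(m) {
    apply(m, 1L, function(r) {
      top <- which(r == max(r))
      if (length(top) != 1L) NA_integer_ else top
    })
  }
  best_ab <- best(scores_ab)
  best_ba <- best(scores_ba)
  n_ties <- sum(is.na(best_ab)) + sum(is.na(best_ba))
  pairs <- which(!is.na(best_ab))
  keep <- pairs[vapply(
    pairs,
    function(i) {
      j <- best_ab[i]
      !is.na(best_ba[j]) && best_ba[j] == i
    },
    logical(1)
  )]
  out <- data.frame(
    gene_a = (rownames(scores_ab) %||% as.character(seq_len(nrow(scores_ab))))[keep],
    gene_b = (colnames(scores_ab) %||% as.character(seq_len(ncol(scores_ab))))[best_ab[keep]],
    score_ab = scores_ab[cbind(keep, best_ab[keep])],
    score_ba = scores_ba[cbind(best_ab[keep], keep)],
    stringsAsFactors = FALSE
  )
  attr(out, "n_ties") <- n_ties
  out
}

#' Co-expression network over a common time grid
#'
#' Pairwise Pearson correlations between gene courses evaluated on a shared
#' grid; genes are connected when the correlation exceeds the threshold
#' (only positive co-expression by default; `include_anticorrelated = TRUE`
#' connects on the absolute correlation).
#' Edge sets are monotone decreasing in the threshold.
#'
#' @param courses Matrix of courses on the common grid; row names are node
#'   ids (conventionally `organism:gene`).
#' @param threshold Correlation threshold (default 0.5).
#' @param nodes Optional data frame of node annotations (`node`, plus any
#'   columns); defaults to the row names.
#' @param include_anticorrelated Connect on `|r|` instead of `r`.
#' @return List of class `diel_network`: `nodes`, `edges` (node_a, node_b,
#'   r), `threshold`, `graph` (igraph), `components` (membership vector),
#'   `degree`.
#' @export
build_network <- function(courses, threshold = 0.5, nodes = NULL,
                          include_anticorrelated = FALSE) {
  stopifnot(is.matrix(courses), nrow(courses) >= 2L)
  sds <- apply(courses, 1L, stats::sd)
  if (any(sds == 0)) stop("zero-variance course(s) cannot enter the network")
  r <- stats::cor(t(courses))
  crit <- if (include_anticorrelated) abs(r) else r
  idx <- which(upper.tri(crit) & crit > threshold, arr.ind = TRUE)
  ids <- rownames(courses) %||% as.character(seq_len(nrow(courses)))
  edges <- data.frame(
    node_a = ids[idx[, 1L]],
    node_b = ids[idx[, 2L]],
    r = r[idx],
    stringsAsFactors = FALSE
  )
  if (is.null(nodes)) nodes <- data.frame(node = ids, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("node_a", "node_b")],
    directed = FALSE,
    vertices = nodes$node
  )
  comp <- igraph::components(g)
  structure(
    list(
      nodes = nodes,
      edges = edges,
      threshold = threshold,
      graph = g,
      components = comp$membership,
      degree = igraph::degree(g)
    ),
    class = "diel_network"
  )
}

#' @export
print.diel_network <- function(x, ...) {
  cat(sprintf(
    "<diel_network> %d nodes, %d edges at r > %g, %d component(s)\n",
    nrow(x$nodes), nrow(x$edges), x$threshold, max(x$components)
  ))
  invisible(x)
}

#' Correlations of ortholog pairs on a common grid
#'
#' @param courses_a,courses_b Course matrices on the same grid (rows named by
#'   gene).
#' @param pairs Data frame with `gene_a`, `gene_b`.
#' @return `pairs` with an added `r` column.
#' @export
ortholog_correlations <- function(courses_a, courses_b, pairs) {
  stopifnot(all(pairs$gene_a %in% rownames(courses_a)))
  stopifnot(all(pairs$gene_b %in% rownames(courses_b)))
  pairs$r <- vapply(
    seq_len(nrow(pairs)),
    function(i) {
      stats::cor(
        courses_a[pairs$gene_a[i], ],
        courses_b[pairs$gene_b[i], ]
      )
    },
    numeric(1)
  )
  pairs
}
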