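# Independent brute-force oracles used to cross-check the package's
# implementations. These are deliberately literal (loops, direct formulas)
# and share no code with the functions they verify.

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

oracle_fourier <- function(x, t, period = 24) {
  if (sd(x) == 0) {
    return(0)
  }
  z <- (x - mean(x)) / sd(x)
  re <- 0
  im <- 0
  for (j in seq_along(z)) {
    re <- re + z[j] * cos(2 * pi * t[j] / period)
    im <- im + z[j] * sin(2 * pi * t[j] / period)
  }
  sqrt(re^2 + im^2) / length(z)
}

# complete-linkage agglomeration by exhaustive search; ties broken by the
# lexicographically lowest cluster-index pair
oracle_complete_linkage <- function(d, k) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > k) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- max(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d - 1e-12) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  assignment <- integer(n)
  for (i in seq_along(clusters)) assignment[clusters[[i]]] <- i
  list(assignment = assignment, heights = heights)
}

oracle_rbh <- function(sab, sba) {
  pairs <- list()
  for (i in seq_len(nrow(sab))) {
    bi <- which(sab[i, ] == max(sab[i, ]))
    if (length(bi) != 1) next
    bj <- which(sba[bi, ] == max(sba[bi, ]))
    if (length(bj) == 1 && bj == i) {
      pairs[[length(pairs) + 1]] <- c(i, bi)
    }
  }
  if (!length(pairs)) {
    return(matrix(integer(0), ncol = 2))
  }
  do.call(rbind, pairs)
}

oracle_abundance_iqr <- function(v, min_value, min_fraction, min_iqr) {
  keep <- character(0)
  for (g in rownames(v)) {
    n_above <- 0
    for (j in seq_len(ncol(v))) {
      if (v[g, j] > min_value) n_above <- n_above + 1
    }
    if (n_above / ncol(v) >= min_fraction && IQR(v[g, ]) >= min_iqr) {
      keep <- c(keep, g)
    }
  }
  keep
}

# scalar reference evaluation of Stineman's published interpolation formulas
# (independent loop-based path through the same published equations)
oracle_stineman_point <- function(tk, xk, yp, tq) {
  n <- length(tk)
  i <- max(which(tk <= tq))
  if (i >= n) i <- n - 1
  s <- (xk[i + 1] - xk[i]) / (tk[i + 1] - tk[i])
  y0 <- xk[i] + s * (tq - tk[i])
  dy1 <- (yp[i] - s) * (tq - tk[i])
  dy2 <- (yp[i + 1] - s) * (tq - tk[i + 1])
  if (dy1 * dy2 > 0) {
    y0 + dy1 * dy2 / (dy1 + dy2)
  } else if (dy1 * dy2 < 0) {
    y0 + dy1 * dy2 * (2 * tq - tk[i] - tk[i + 1]) /
      ((dy1 - dy2) * (tk[i + 1] - tk[i]))
  } else {
    y0
  }
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

rand_expr_matrix <- function(n_genes, design = samples_ucyna_like(),
                             scale = "log2", fn = function(n) rnorm(n, 8, 2)) {
  v <- matrix(fn(n_genes * nrow(design)),
    nrow = n_genes,
    dimnames = list(sprintf("g%03d", seq_len(n_genes)), design$sample_id)
  )
  if (scale == "linear") v <- abs(v)
  expression_matrix(v, design, scale)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# plant a window in `host` that matches `probe` at exactly n_match/60 positions
mutate_probe <- function(probe, n_mismatch) {
  v <- strsplit(probe, "")[[1]]
  pos <- sample(seq_along(v), n_mismatch)
  for (p in pos) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  }
  paste(v, collapse = "")
}
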