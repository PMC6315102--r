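test_that("quantile normalization equalizes sample distributions", {
  design <- diel_design(c("L6", "D3"))
  v <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 2,
    dimnames = list(c("a", "b", "c"), design$sample_id)
  )
  em <- expression_matrix(v, design, "log2")
  out <- quantile_normalize(em)
  expect_equal(unname(out$values[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out$values[, 2]), c(2.5, 3.5, 4.5))
  # identical samples are unchanged
  v2 <- cbind(v[, 1], v[, 1])
  dimnames(v2) <- dimnames(v)
  em2 <- expression_matrix(v2, design, "log2")
  expect_equal(quantile_normalize(em2)$values, v2)
  # single sample refused
  expect_error(quantile_normalize(subset_matrix(em, sample_ids = "L6_1")),
    ">= 2 samples")
})

test_that("quantile normalization satisfies its definition and is idempotent", {
  set.seed(42)
  for (rep in 1:20) {
    em <- rand_expr_matrix(50, diel_design(c("L6", "L9", "D3", "D6")))
    out <- quantile_normalize(em)
    sorted <- apply(out$values, 2, sort)
    expect_lt(max(abs(sorted - rowMeans(sorted))), 1e-12)
    # ranks preserved within each sample
    for (j in 1:4) {
      expect_equal(order(out$values[, j]), order(em$values[, j]))
    }
    expect_equal(quantile_normalize(out)$values, out$values, tolerance = 1e-12)
  }
})

test_that("median polish decomposes additive and constant tables exactly", {
  r <- c(1, -2, 5)
  cc <- c(0.5, 3, -1, 2)
  x <- outer(r, cc, `+`)
  mp <- median_polish(x)
  expect_lt(max(abs(mp$residuals)), 1e-12)
  expect_true(mp$converged)
  mp_const <- median_polish(matrix(4.2, 3, 5))
  expect_equal(mp_const$overall, 4.2)
  expect_equal(mp_const$row_effects, rep(0, 3))
  expect_equal(mp_const$col_effects, rep(0, 5))
  expect_error(median_polish(matrix(c(1, NA, 2, 3), 2)), "finite")
})

test_that("median polish reconstruction identity holds for random tables", {
  set.seed(7)
  for (rep in 1:25) {
    x <- matrix(rnorm(6 * 8), 6, 8)
    mp <- median_polish(x, max_iter = 50)
    recon <- mp$overall + outer(mp$row_effects, mp$col_effects, `+`) +
      mp$residuals
    expect_lt(max(abs(recon - x)), 1e-10)
    # column medians vanish after the final column sweep, and the sweep has
    # converged: one further polish of the residuals reduces their absolute
    # sum only negligibly
    expect_lt(max(abs(apply(mp$residuals, 2, median))), 1e-10)
    again <- median_polish(mp$residuals, max_iter = 1)
    expect_lt(
      sum(abs(mp$residuals)) - sum(abs(again$residuals)),
      1e-6 * (1 + sum(abs(mp$residuals)))
    )
  }
})

test_that("gene summarization recovers planted courses and ignores probe order", {
  truth <- simulate_truth(n_genes = 12, frac_background = 0, seed = 31)
  sim <- simulate_probe_matrix(truth,
    probes_per_gene = 5, probe_noise_sd = 0,
    scale_sd = 0, shift_sd = 0, seed = 31
  )
  lg <- log2_transform(sim$probes)
  genes <- summarize_genes(lg, sim$probe_map)
  expect_equal(rownames(genes$values), truth$gene_id)
  # noise-free: summarized course equals the planted course up to a constant
  for (g in truth$gene_id[1:4]) {
    delta <- genes$values[g, ] - sim$gene_log2[g, ]
    expect_lt(diff(range(delta)), 1e-8)
  }
  # permutation invariance to probe row order
  perm <- sample(nrow(lg$values))
  lg_perm <- expression_matrix(lg$values[perm, ], lg$samples, "log2")
  genes_perm <- summarize_genes(lg_perm, sim$probe_map)
  expect_equal(genes_perm$values, genes$values)
  # identical probe rows summarize to themselves; single-probe genes pass through
  design <- diel_design(c("L6", "D3"))
  v <- rbind(p1 = c(2, 5), p2 = c(2, 5), p3 = c(2, 5), q1 = c(7, 1))
  colnames(v) <- design$sample_id
  em <- expression_matrix(v, design, "log2")
  pm <- data.frame(probe_id = c("p1", "p2", "p3", "q1"),
                   gene_id = c("gA", "gA", "gA", "gB"))
  out <- summarize_genes(em, pm)
  expect_equal(unname(out$values["gA", ]), c(2, 5))
  expect_equal(unname(out$values["gB", ]), c(7, 1))
})

test_that("unmapped and missing probes are handled as contracted", {
  design <- diel_design(c("L6", "D3"))
  v <- matrix(1:6, ncol = 2,
    dimnames = list(c("p1", "p2", "p3"), design$sample_id)
  )
  em <- expression_matrix(v + 0.0, design, "log2")
  pm <- data.frame(probe_id = c("p1", "p2"), gene_id = c("gA", "gA"))
  expect_warning(out <- summarize_genes(em, pm), "1 probe")
  expect_equal(attr(out, "excluded_probes"), 1L)
  pm_bad <- data.frame(probe_id = c("p1", "p9"), gene_id = c("gA", "gA"))
  expect_error(summarize_genes(em, pm_bad), "p9")
})

test_that("replicate averaging is the arithmetic log2 mean per time point", {
  design <- diel_design(c("L6", "L6", "D3"))
  v <- rbind(g1 = c(4, 6, 6), g2 = c(3, 5, 9))
  colnames(v) <- design$sample_id
  em <- expression_matrix(v, design, "log2")
  avg <- average_replicates(em)
  expect_equal(unname(avg$values["g1", ]), c(5, 6))
  expect_equal(avg$samples$label, c("L6", "D3"))
  # no replicates: identity
  em1 <- rand_expr_matrix(4, diel_design(c("L6", "L9", "D3")))
  expect_equal(average_replicates(em1)$values, em1$values,
    ignore_attr = TRUE)
  # averaging commutes with gene subsetting
  em2 <- rand_expr_matrix(10)
  sub_then_avg <- average_replicates(subset_matrix(em2, c("g003", "g007")))
  avg_then_sub <- subset_matrix(average_replicates(em2), c("g003", "g007"))
  expect_equal(sub_then_avg$values, avg_then_sub$values)
})

test_that("log2 transform floors non-positive intensities and is invertible", {
  design <- diel_design(c("L6", "D3"))
  v <- matrix(c(4, 0, 8, 16), 2, dimnames = list(c("a", "b"), design$sample_id))
  em <- expression_matrix(v, design, "linear")
  expect_message(lg <- log2_transform(em, eps = 0.5), "floored")
  expect_equal(attr(lg, "n_floored"), 1L)
  expect_equal(unname(lg$values["b", 1]), -1) # log2(0.5)
  back <- delog2(log2_transform(expression_matrix(
    matrix(c(4, 2, 8, 16), 2, dimnames = dimnames(v)), design, "linear"
  )))
  expect_equal(unname(back$values[1, 1]), 4)
})
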