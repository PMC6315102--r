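test_that("Stineman interpolation reproduces lines and passes through knots", {
  tk <- c(0, 1, 2.5, 4, 7, 11)
  xk <- 2 * tk + 1
  tq <- seq(0, 11, by = 0.37)
  expect_equal(stineman_interpolate(tk, xk, tq), 2 * tq + 1, tolerance = 1e-12)
  set.seed(9)
  xk2 <- rnorm(6)
  expect_equal(stineman_interpolate(tk, xk2, tk), xk2, tolerance = 1e-12)
  expect_error(stineman_interpolate(c(0, 0, 1), c(1, 2, 3), 0.5), "increasing")
  expect_error(stineman_interpolate(tk, xk, c(-0.5)), "extrapolation")
  expect_error(stineman_interpolate(tk, xk, c(11.5)), "extrapolation")
  expect_error(stineman_interpolate(1, 1, 1), "2 knots")
})

test_that("monotone knots yield monotone interpolants (no overshoot)", {
  set.seed(10)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    tk <- sort(runif(n, 0, 10))
    while (min(diff(tk)) < 1e-3) tk <- sort(runif(n, 0, 10))
    xk <- cumsum(abs(rnorm(n, 0, sample(c(0.1, 1, 10), 1))))
    if (rep %% 2 == 0) xk <- -xk # decreasing case
    tq <- seq(tk[1], tk[n], length.out = 400)
    y <- stineman_interpolate(tk, xk, tq)
    sign_dir <- sign(xk[n] - xk[1])
    expect_true(all(sign_dir * diff(y) >= -1e-9))
    # never leaves the knot envelope
    expect_true(all(y >= min(xk) - 1e-9 & y <= max(xk) + 1e-9))
  }
})

test_that("vectorized interpolation agrees with the scalar reference formulas", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(4:9, 1)
    tk <- sort(runif(n, 0, 10))
    while (min(diff(tk)) < 1e-3) tk <- sort(runif(n, 0, 10))
    xk <- rnorm(n)
    yp <- dieltx:::stineman_slopes(tk, xk)
    tq <- runif(25, tk[1], tk[n])
    mine <- stineman_interpolate(tk, xk, tq)
    ref <- vapply(tq, function(q) oracle_stineman_point(tk, xk, yp, q),
      numeric(1)
    )
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("grid alignment passes through observations and tracks a cosine", {
  hours <- parse_time_series(c("L2", "L6", "L10", "D2", "D6", "D10"))$absolute_hour
  x <- cos(2 * pi * (hours - 5) / 24)
  dense <- seq(2, 22, by = 0.25)
  interp <- stineman_interpolate(hours, x, dense)
  true_curve <- cos(2 * pi * (dense - 5) / 24)
  rms <- sqrt(mean((interp - true_curve)^2))
  expect_lt(rms, 0.05) # within 5% RMS of the unit-amplitude cosine
  # observed points pass through exactly
  expect_equal(stineman_interpolate(hours, x, hours), x, tolerance = 1e-12)

  em <- rand_expr_matrix(6, diel_design(c("L2", "L6", "L10", "D2", "D6", "D10")))
  grid <- common_grid(list(em$samples$absolute_hour), step = 1)
  z <- align_to_grid(em, grid)
  zs <- standardize_courses(em)
  on_grid <- match(em$samples$absolute_hour, grid)
  expect_equal(unname(z[, on_grid]), unname(zs[, ]), tolerance = 1e-10)
  expect_error(align_to_grid(em, seq(0, 36)), "outside")
})

test_that("common grids span the intersection of observed ranges", {
  g <- common_grid(list(c(6, 36), c(2, 22)), step = 1)
  expect_equal(range(g), c(6, 22))
  expect_equal(diff(g), rep(1, 16))
  expect_error(common_grid(list(c(0, 5), c(10, 20))), "overlap")
})

test_that("reciprocal best hits require agreement in both directions", {
  sab <- diag(3)
  dimnames(sab) <- list(paste0("a", 1:3), paste0("b", 1:3))
  sba <- t(sab)
  rbh <- reciprocal_best_hits(sab, sba)
  expect_equal(rbh$gene_a, paste0("a", 1:3))
  expect_equal(rbh$gene_b, paste0("b", 1:3))
  # one-way best only: no pair
  sab2 <- rbind(a1 = c(b1 = 1, b2 = 0.9), a2 = c(b1 = 0, b2 = 0.2))
  sba2 <- rbind(b1 = c(a1 = 1, a2 = 0.2), b2 = c(a1 = 0.9, a2 = 0.1))
  # a1's best is b1 and b1's best is a1 -> pair;
  # a2's best is b2 but b2's best is a1 -> no pair
  rbh2 <- reciprocal_best_hits(sab2, sba2)
  expect_equal(rbh2$gene_a, "a1")
  expect_error(reciprocal_best_hits(diag(3), diag(4)), "dimensions")
})

test_that("reciprocal best hits match the double-argmax oracle", {
  set.seed(13)
  for (rep in 1:100) {
    na <- sample(3:8, 1)
    nb <- sample(3:8, 1)
    sab <- matrix(runif(na * nb), na)
    sba <- matrix(runif(na * nb), nb)
    mine <- reciprocal_best_hits(sab, sba)
    oracle <- oracle_rbh(sab, sba)
    expect_equal(nrow(mine), nrow(oracle))
    if (nrow(oracle)) {
      expect_equal(as.integer(mine$gene_a), oracle[, 1])
      expect_equal(as.integer(mine$gene_b), oracle[, 2])
    }
  }
})

test_that("k-mer similarity behaves sensibly and ties are dropped", {
  set.seed(15)
  s <- random_dna(60)
  seqs <- c(x = s, y = s, z = random_dna(60))
  sim <- kmer_similarity(seqs["x"], seqs[c("y", "z")], k = 11)
  expect_equal(unname(sim[1, "y"]), 1)
  expect_lt(sim[1, "z"], 0.2)
  # exact ties for best hit disqualify a gene
  sab <- matrix(c(1, 1, 0, 1), 2, dimnames = list(c("a1", "a2"), c("b1", "b2")))
  sba <- matrix(c(1, 0, 1, 1), 2, dimnames = list(c("b1", "b2"), c("a1", "a2")))
  rbh <- reciprocal_best_hits(sab, sba)
  expect_false("a1" %in% rbh$gene_a) # a1 ties b1/b2
  expect_gte(attr(rbh, "n_ties"), 1L)
})

test_that("network edges follow the correlation threshold monotonically", {
  t <- seq(0, 23, by = 1)
  courses <- rbind(
    n1 = cos(2 * pi * t / 24),
    n2 = cos(2 * pi * t / 24),
    n3 = cos(2 * pi * (t - 12) / 24),
    n4 = cos(2 * pi * (t - 7) / 24)
  )
  net <- build_network(courses, threshold = 0.5)
  expect_s3_class(net, "diel_network")
  # identical courses connect with r = 1; antiphase courses never connect
  expect_true(any(net$edges$node_a == "n1" & net$edges$node_b == "n2"))
  expect_equal(net$edges$r[net$edges$node_a == "n1" &
    net$edges$node_b == "n2"], 1)
  expect_false(any(net$edges$node_a == "n1" & net$edges$node_b == "n3" |
    net$edges$node_a == "n3" & net$edges$node_b == "n1"))
  # threshold monotonicity: edges at 0.5 are a subset of edges at 0.2
  net02 <- build_network(courses, threshold = 0.2)
  key <- function(e) paste(e$node_a, e$node_b)
  expect_true(all(key(net$edges) %in% key(net02$edges)))
  # anticorrelated mode connects antiphase genes
  net_abs <- build_network(courses, threshold = 0.5, include_anticorrelated = TRUE)
  expect_true(any(key(net_abs$edges) == "n1 n3"))
  expect_error(build_network(rbind(courses, n5 = rep(1, 24))), "zero-variance")
})

test_that("ortholog phase shifts translate into network separation", {
  for (case in list(list(shift = 12, connected = 0, anti = 0.95),
                    list(shift = 0, connected = 0.95, anti = 0))) {
    two <- simulate_two_organisms(
      seed = 14, phase_shift_hours = case$shift,
      n_genes = 60, noise_sd = 0.2
    )
    grid <- common_grid(list(
      two$org_a$samples$absolute_hour,
      two$org_b$samples$absolute_hour
    ))
    za <- align_to_grid(average_replicates(two$org_a), grid)
    zb <- align_to_grid(average_replicates(two$org_b), grid)
    orth <- ortholog_correlations(za, zb, two$orthologs)
    if (case$connected == 0) {
      expect_equal(mean(orth$r > 0.5), 0)
      expect_gte(mean(orth$r < -0.5), case$anti)
    } else {
      expect_gte(mean(orth$r > 0.5), case$connected)
      expect_equal(mean(orth$r < -0.5), 0)
    }
  }
})
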