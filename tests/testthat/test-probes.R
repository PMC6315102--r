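test_that("candidate tiling spaces probes evenly and deterministically", {
  set.seed(20)
  gene <- random_dna(600)
  probes <- tile_candidates(gene, "gA")
  expect_equal(nrow(probes), 6L)
  expect_equal(probes$start[1], 0L)
  expect_equal(probes$start[6], 540L)
  expect_equal(unique(diff(probes$start)), 108L)
  expect_equal(nchar(probes$sequence), rep(60L, 6))
  expect_equal(probes$sequence[1], substr(gene, 1, 60))
  # identical on repeat
  expect_identical(tile_candidates(gene, "gA"), probes)
  # 60-nt gene: exactly one probe; shorter: none
  expect_equal(nrow(tile_candidates(random_dna(60), "gB")), 1L)
  expect_equal(nrow(tile_candidates(random_dna(59), "gC")), 0L)
  expect_error(tile_candidates("ACGTN", "gD"), "non-ACGT")
})

test_that("cross-hybridization removal follows the 95% full-length rule", {
  set.seed(21)
  gene <- random_dna(300)
  probes <- tile_candidates(gene, "gA", n_probes = 3)
  # off-target containing a 57/60 window of probe 1 (identity 0.95 -> removed)
  # and a 56/60 window of probe 2 (0.933 -> kept)
  hit57 <- mutate_probe(probes$sequence[1], 3)
  hit56 <- mutate_probe(probes$sequence[2], 4)
  db <- c(
    ot1 = paste0(random_dna(40), hit57, random_dna(40)),
    ot2 = paste0(random_dna(25), hit56, random_dna(25))
  )
  out <- cross_hyb_filter(probes, db)
  expect_equal(out$status, c("cross_hyb", "kept", "kept"))
  expect_match(out$evidence[1], "ot1.*0.950")
  # a probe matching only its own gene is untouched when the db excludes it
  expect_equal(cross_hyb_filter(probes, c(other = random_dna(200)))$status,
    rep("kept", 3))
  expect_error(cross_hyb_filter(probes, c(bad = "ACGTX")), "non-ACGT")
})

test_that("filtering is reverse-complement aware and symmetric", {
  set.seed(22)
  gene <- random_dna(240)
  probes <- tile_candidates(gene, "gA", n_probes = 2)
  hit <- mutate_probe(probes$sequence[1], 2) # 58/60 = 0.967
  db_fwd <- c(t1 = paste0(random_dna(30), hit, random_dna(30)))
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  db_rev <- c(t1 = rc(db_fwd[["t1"]]))
  out_fwd <- cross_hyb_filter(probes, db_fwd)
  out_rev <- cross_hyb_filter(probes, db_rev)
  expect_equal(out_fwd$status, out_rev$status)
  expect_equal(out_fwd$status[1], "cross_hyb")
})

test_that("redundancy clustering keeps one representative per 95% cluster", {
  set.seed(23)
  p1 <- random_dna(60)
  probes <- data.frame(
    probe_id = c("a", "b", "c", "d"),
    gene_id = "g",
    start = 0L,
    sequence = c(p1, p1, mutate_probe(p1, 2), random_dna(60)),
    status = "kept",
    evidence = "",
    stringsAsFactors = FALSE
  )
  out <- redundancy_cluster(probes)
  expect_equal(out$status, c("kept", "redundant", "redundant", "kept"))
  expect_match(out$evidence[2], "matches a")
  # all-distinct probes all survive
  distinct <- probes
  distinct$sequence <- vapply(1:4, function(i) random_dna(60), "")
  expect_equal(redundancy_cluster(distinct)$status, rep("kept", 4))
})

test_that("greedy clustering matches a brute-force oracle on small sets", {
  set.seed(24)
  for (rep in 1:10) {
    base <- replicate(6, random_dna(60))
    seqs <- c(base, vapply(
      sample(base, 10, replace = TRUE),
      function(s) mutate_probe(s, sample(0:6, 1)), ""
    ))
    probes <- data.frame(
      probe_id = sprintf("p%02d", seq_along(seqs)), gene_id = "g",
      start = 0L, sequence = seqs, status = "kept", evidence = "",
      stringsAsFactors = FALSE
    )
    out <- redundancy_cluster(probes, threshold = 0.95)
    # literal greedy re-implementation
    reps <- character(0)
    status <- character(length(seqs))
    for (i in seq_along(seqs)) {
      joined <- FALSE
      for (r in reps) {
        ident <- max(
          mean(strsplit(seqs[i], "")[[1]] == strsplit(r, "")[[1]]),
          mean(strsplit(seqs[i], "")[[1]] ==
            rev(chartr("ACGT", "TGCA", strsplit(r, "")[[1]])))
        )
        if (ident >= 0.95) {
          joined <- TRUE
          break
        }
      }
      if (joined) {
        status[i] <- "redundant"
      } else {
        status[i] <- "kept"
        reps <- c(reps, seqs[i])
      }
    }
    expect_equal(out$status, status)
  }
})

test_that("strain filter removes shared probes unless whitelisted", {
  set.seed(25)
  nifh_a <- random_dna(420)
  other_gene <- random_dna(420)
  probes <- rbind(
    tile_candidates(nifh_a, "nifH", n_probes = 2),
    tile_candidates(other_gene, "psbA", n_probes = 2)
  )
  # the other strain carries a near-identical nifH and a near-identical psbA
  other_strain <- c(
    nifH_b = mutate_probe(nifh_a, 8), # ~98% identity over any 60-mer window
    psbA_b = other_gene
  )
  plain <- strain_specificity_filter(probes, other_strain)
  expect_equal(plain$status, rep("strain_shared", 4))
  wl <- strain_specificity_filter(probes, other_strain, whitelist = "nifH")
  expect_equal(wl$status[wl$gene_id == "nifH"], rep("kept", 2))
  expect_match(wl$evidence[wl$gene_id == "nifH"][1], "retained despite")
  expect_equal(wl$status[wl$gene_id == "psbA"], rep("strain_shared", 2))
})

test_that("the cascade reports consistent per-stage attrition", {
  set.seed(26)
  genes <- c(gA = random_dna(360), gB = random_dna(360), nifH = random_dna(360))
  off_target <- c(env1 = paste0(
    random_dna(50), substr(genes[["gA"]], 1, 60), random_dna(50)
  ))
  other_strain <- c(nifH_b = genes[["nifH"]], gB_b = mutate_probe(genes[["gB"]], 5))
  res <- probe_filter_cascade(
    genes,
    off_target_db = off_target,
    other_strain_db = other_strain,
    whitelist = "nifH",
    n_probes = 4
  )
  att <- res$attrition
  expect_equal(att$stage, c("candidates", "cross_hyb", "redundancy",
                            "strain_specificity"))
  expect_equal(att$remaining[1], 12L)
  expect_equal(att$remaining[1] - sum(att$removed),
               sum(res$probes$status == "kept"))
  expect_true(all(diff(att$remaining) <= 0))
  # the planted off-target window removed gA's first probe
  expect_equal(res$probes$status[res$probes$probe_id == "gA_p1"], "cross_hyb")
  # whitelisted nifH probes survived the strain filter
  expect_true(all(res$probes$status[res$probes$gene_id == "nifH"] == "kept"))
  # gB probes matching the other strain were removed there
  expect_true(any(res$probes$status[res$probes$gene_id == "gB"] == "strain_shared"))
})

test_that("lowering the identity threshold never enlarges the kept set", {
  set.seed(27)
  gene <- random_dna(300)
  probes <- tile_candidates(gene, "g", n_probes = 4)
  db <- c(
    o1 = paste0(random_dna(20), mutate_probe(probes$sequence[1], 2), random_dna(20)),
    o2 = paste0(random_dna(20), mutate_probe(probes$sequence[2], 6), random_dna(20)),
    o3 = paste0(random_dna(20), mutate_probe(probes$sequence[3], 12), random_dna(20))
  )
  kept <- function(th) {
    out <- cross_hyb_filter(probes, db, min_identity = th)
    out$probe_id[out$status == "kept"]
  }
  for (pair in list(c(0.98, 0.9), c(0.9, 0.8), c(0.95, 0.75))) {
    expect_true(all(kept(pair[2]) %in% kept(pair[1])))
  }
})
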