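#' Read gene sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of upper-case DNA sequences.
#' @export
read_gene_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

check_dna <- function(seqs) {
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    nm <- names(seqs)[bad][1L] %||% as.character(which(bad)[1L])
    stop("non-ACGT character in sequence '", nm, "'")
  }
  invisible(seqs)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Tile evenly spaced probe candidates along a gene
#'
#' Up to `n_probes` windows of length `probe_length` at evenly spaced
#' offsets (deterministic; duplicated windows are dropped). A gene shorter
#' than the probe length yields zero candidates.
#'
#' @param gene_seq DNA sequence (A/C/G/T).
#' @param gene_id Gene identifier.
#' @param n_probes Target number of probes per gene (default 6).
#' @param probe_length Probe length in nt (default 60).
#' @return Data frame: `probe_id`, `gene_id`, `start` (0-based), `sequence`,
#'   `status` (`"kept"`), `evidence`.
#' @export
tile_candidates <- function(gene_seq, gene_id, n_probes = 6, probe_length = 60) {
  gene_seq <- toupper(gene_seq)
  check_dna(stats::setNames(gene_seq, gene_id))
  L <- nchar(gene_seq)
  if (L < probe_length) {
    return(data.frame(
      probe_id = character(0), gene_id = character(0), start = integer(0),
      sequence = character(0), status = character(0), evidence = character(0),
      stringsAsFactors = FALSE
    ))
  }
  n_slots <- min(n_probes, L - probe_length + 1L)
  starts <- unique(floor(seq(0L, L - probe_length, length.out = n_slots)))
  seqs <- substring(gene_seq, starts + 1L, starts + probe_length)
  dup <- duplicated(seqs)
  starts <- starts[!dup]
  seqs <- seqs[!dup]
  data.frame(
    probe_id = sprintf("%s_p%d", gene_id, seq_along(starts)),
    gene_id = gene_id,
    start = as.integer(starts),
    sequence = seqs,
    status = "kept",
    evidence = "",
    stringsAsFactors = FALSE
  )
}

#' @rdname tile_candidates
#' @param gene_seqs Named character vector of gene sequences.
#' @export
tile_candidates_all <- function(gene_seqs, n_probes = 6, probe_length = 60) {
  out <- do.call(rbind, lapply(
    names(gene_seqs),
    function(g) tile_candidates(gene_seqs[[g]], g, n_probes, probe_length)
  ))
  rownames(out) <- NULL
  out
}

# best gapless full-length identity of `probe` against all equal-length
# windows of `target`, forward strand only
best_window_identity_fwd <- function(probe, target) {
  L <- nchar(probe)
  n <- nchar(target)
  if (n < L) {
    return(list(identity = 0, offset = NA_integer_))
  }
  pi <- utf8ToInt(probe)
  ti <- utf8ToInt(target)
  n_off <- n - L + 1L
  matches <- integer(n_off)
  for (j in seq_len(L)) {
    matches <- matches + (ti[j:(j + n_off - 1L)] == pi[j])
  }
  best <- which.max(matches)
  list(identity = matches[best] / L, offset = best)
}

#' Best gapless window identity of a probe against target sequences
#'
#' Slides the probe along every target on both strands (the target's reverse
#' complement is scanned too) and reports the best full-length identity
#' (`matches / probe length`) together with the target it occurred on.
#'
#' @param probe Probe sequence.
#' @param targets Named character vector of target sequences.
#' @return List: `identity`, `target` (name of best target, NA if none),
#'   `strand` (`"+"`/`"-"`).
#' @export
probe_max_identity <- function(probe, targets) {
  best <- list(identity = 0, target = NA_character_, strand = "+")
  for (nm in names(targets)) {
    fwd <- best_window_identity_fwd(probe, targets[[nm]])
    if (fwd$identity > best$identity) {
      best <- list(identity = fwd$identity, target = nm, strand = "+")
    }
    rev <- best_window_identity_fwd(probe, revcomp(targets[[nm]]))
    if (rev$identity > best$identity) {
      best <- list(identity = rev$identity, target = nm, strand = "-")
    }
  }
  best
}

#' Cross-hybridization filter
#'
#' Removes every probe whose best gapless window identity against any
#' off-target sequence reaches `min_identity` over 100% of the probe length
#' (both strands scanned). The off-target set must not contain the probe's
#' own gene.
#'
#' @param probes Probe table from [tile_candidates_all()].
#' @param off_target_db Named character vector of off-target sequences.
#' @param min_identity Identity threshold in (0, 1] (default 0.95).
#' @return Probe table with removed probes marked `status = "cross_hyb"` and
#'   the offending target recorded in `evidence`.
#' @export
cross_hyb_filter <- function(probes, off_target_db, min_identity = 0.95) {
  off_target_db <- toupper(off_target_db)
  check_dna(off_target_db)
  check_dna(stats::setNames(probes$sequence, probes$probe_id))
  for (i in seq_len(nrow(probes))) {
    if (probes$status[i] != "kept") next
    hit <- probe_max_identity(probes$sequence[i], off_target_db)
    if (hit$identity >= min_identity) {
      probes$status[i] <- "cross_hyb"
      probes$evidence[i] <- sprintf(
        "%s (%s strand, identity %.3f)", hit$target, hit$strand, hit$identity
      )
    }
  }
  probes
}

pairwise_identity <- function(a, b) {
  # gapless identity between two probes; the shorter slides along the longer,
  # both strands, denominator = shorter length
  if (nchar(a) > nchar(b)) {
    tmp <- a
    a <- b
    b <- tmp
  }
  max(
    best_window_identity_fwd(a, b)$identity,
    best_window_identity_fwd(a, revcomp(b))$identity
  )
}

#' Redundancy clustering of probes
#'
#' Greedy clustering in input order: a probe joins the first existing cluster
#' whose representative it matches at `threshold` gapless identity or
#' better (both strands); otherwise it founds a new cluster. Only cluster
#' representatives are kept; other members are marked `"redundant"`.
#'
#' @param probes Probe table (only `status == "kept"` rows participate).
#' @param threshold Identity threshold (default 0.95).
#' @return Updated probe table.
#' @export
redundancy_cluster <- function(probes, threshold = 0.95) {
  reps <- integer(0)
  for (i in seq_len(nrow(probes))) {
    if (probes$status[i] != "kept") next
    joined <- FALSE
    for (r in reps) {
      if (pairwise_identity(probes$sequence[i], probes$sequence[r]) >= threshold) {
        probes$status[i] <- "redundant"
        probes$evidence[i] <- sprintf("matches %s", probes$probe_id[r])
        joined <- TRUE
        break
      }
    }
    if (!joined) reps <- c(reps, i)
  }
  probes
}

#' Cross-strain specificity filter
#'
#' Removes probes matching the other strain's genes at `threshold` identity
#' or better (same scan as [cross_hyb_filter()]), except probes of
#' whitelisted conserved genes, which are retained with the evidence
#' recorded.
#'
#' @param probes Probe table.
#' @param other_strain_db Named character vector of the other strain's genes.
#' @param threshold Identity threshold (default 0.95).
#' @param whitelist Gene ids whose probes survive despite cross-strain hits
#'   (highly conserved genes deliberately shared between strain arrays).
#' @return Updated probe table (`status = "strain_shared"` for removals).
#' @export
strain_specificity_filter <- function(probes, other_strain_db, threshold = 0.95,
                                      whitelist = character(0)) {
  other_strain_db <- toupper(other_strain_db)
  check_dna(other_strain_db)
  for (i in seq_len(nrow(probes))) {
    if (probes$status[i] != "kept") next
    hit <- probe_max_identity(probes$sequence[i], other_strain_db)
    if (hit$identity >= threshold) {
      if (probes$gene_id[i] %in% whitelist) {
        probes$evidence[i] <- sprintf(
          "retained despite %.3f identity to %s (conserved gene)",
          hit$identity, hit$target
        )
      } else {
        probes$status[i] <- "strain_shared"
        probes$evidence[i] <- sprintf(
          "%s (%s strand, identity %.3f)", hit$target, hit$strand, hit$identity
        )
      }
    }
  }
  probes
}

#' Full probe-selection cascade
#'
#' Candidate tiling, then -- in this order -- cross-hybridization deletion,
#' redundancy clustering, and cross-strain specificity filtering. Per-stage
#' attrition counts are returned alongside the final table.
#'
#' @param gene_seqs Named character vector of target genes.
#' @param off_target_db Off-target database for [cross_hyb_filter()].
#' @param other_strain_db Other strain's genes for
#'   [strain_specificity_filter()] (optional).
#' @param whitelist Conserved-gene whitelist for the strain filter.
#' @param n_probes,probe_length Tiling parameters.
#' @param min_identity Identity threshold used by all three filters.
#' @return List: `probes` (final table), `attrition` (data frame of per-stage
#'   removed/remaining counts).
#' @export
probe_filter_cascade <- function(gene_seqs, off_target_db = character(0),
                                 other_strain_db = character(0),
                                 whitelist = character(0),
                                 n_probes = 6, probe_length = 60,
                                 min_identity = 0.95) {
  probes <- tile_candidates_all(gene_seqs, n_probes, probe_length)
  n0 <- nrow(probes)
  if (length(off_target_db)) {
    probes <- cross_hyb_filter(probes, off_target_db, min_identity)
  }
  n1 <- sum(probes$status == "kept")
  probes <- redundancy_cluster(probes, min_identity)
  n2 <- sum(probes$status == "kept")
  if (length(other_strain_db)) {
    probes <- strain_specificity_filter(
      probes, other_strain_db, min_identity, whitelist
    )
  }
  n3 <- sum(probes$status == "kept")
  attrition <- data.frame(
    stage = c("candidates", "cross_hyb", "redundancy", "strain_specificity"),
    removed = c(0L, n0 - n1, n1 - n2, n2 - n3),
    remaining = c(n0, n1, n2, n3),
    stringsAsFactors = FALSE
  )
  list(probes = probes, attrition = attrition)
}
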