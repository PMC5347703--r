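#' Generate a synthetic normalized PSSM
#'
#' Each row is an independent draw from a symmetric Dirichlet with
#' concentration `conservation`: small values give peaked rows (strongly
#' conserved positions, most mass on one residue), large values approach
#' the uniform profile. Emulates the row-wise probability profiles that a
#' normalized PSI-BLAST PSSM provides, without any homology search. Fully
#' determined by the seed.
#'
#' @param L Sequence length (>= 2).
#' @param conservation Positive Dirichlet concentration (default 1).
#' @param seed Integer seed.
#' @param protein_id Identifier for the generated protein.
#' @return A normalized [pssm()].
#' @export
generate_pssm <- function(L, conservation = 1, seed = 1L,
                          protein_id = "synthetic") {
  if (L < 2L) stop_input("L must be >= 2")
  if (conservation <= 0) stop_input("conservation must be positive")
  m <- with_seed(seed, matrix(stats::rgamma(L * 20L, shape = conservation),
                              nrow = L, ncol = 20L))
  m[m < 1e-300] <- 1e-300
  m <- m / rowSums(m)
  pssm(m, protein_id = protein_id, normalized = TRUE)
}

#' Generate a synthetic raw (integer log-odds) PSSM
#'
#' Integer score matrices in the PSI-BLAST range, suitable for exercising
#' the ASCII writer/parser round trip losslessly (the native format stores
#' integers). Scores are drawn uniformly from `score_range`; the residue at
#' each position is the column with the highest score, so the derived
#' sequence matches the profile's argmax path.
#'
#' @param L Sequence length (>= 1).
#' @param score_range Inclusive integer score bounds (default -6..9).
#' @param seed Integer seed.
#' @param protein_id Identifier.
#' @return A raw [pssm()] with integer-valued entries and a `sequence`.
#' @export
generate_raw_pssm <- function(L, score_range = c(-6L, 9L), seed = 1L,
                              protein_id = "synthetic") {
  if (L < 1L) stop_input("L must be >= 1")
  m <- with_seed(seed, matrix(
    sample(seq(score_range[1], score_range[2]), L * 20L, replace = TRUE),
    nrow = L, ncol = 20L))
  storage.mode(m) <- "double"
  seqs <- paste(aa_alphabet()[max.col(m, ties.method = "first")],
                collapse = "")
  pssm(m, protein_id = protein_id, normalized = FALSE, sequence = seqs)
}

# Draw one positive/negative profile: a latent residue path from a
# first-order Markov chain over the 20 amino acids, each position then
# emitting a Dirichlet row peaked on its latent residue.
sample_profile <- function(L, trans, peak, base_conc) {
  states <- integer(L)
  states[1] <- sample.int(20L, 1L)
  for (i in 2:L) {
    states[i] <- sample.int(20L, 1L, prob = trans[states[i - 1L], ])
  }
  shape <- matrix(base_conc, nrow = L, ncol = 20L)
  shape[cbind(seq_len(L), states)] <- base_conc + peak
  m <- matrix(stats::rgamma(L * 20L, shape = shape), nrow = L)
  m[m < 1e-300] <- 1e-300
  list(matrix = m / rowSums(m), states = states)
}

#' Generate a labeled SIP-like dataset with planted transition enrichment
#'
#' Emulates a two-class self-interaction dataset at desk scale. Every
#' protein is a latent residue path from a first-order Markov chain whose
#' per-position profile rows are Dirichlet draws peaked on the path
#' (conserved-position behaviour). Negatives use a uniform transition
#' matrix; positives multiply the probability of each planted `(m, n)`
#' transition by `effect_size` before row renormalization, so the class
#' signal lives exactly in the adjacent-position transition mass that the
#' bi-gram features measure. Features are computed through the public
#' [bigram_features()]/[flatten_bigram()] path — the generator cannot drift
#' from the production featurization.
#'
#' @param n_pos,n_neg Class sizes (each >= 1, total >= 4).
#' @param enriched_transitions Two-column integer matrix of planted
#'   `(m, n)` index pairs in 1..20. The default plants the 20 symmetric
#'   pairs `(m, m + 10)` and `(m + 10, m)` for `m = 1..10` — a
#'   palindromic-motif-like signature touching 5% of the 400 transitions.
#'   Required non-trivial when `effect_size > 1`.
#' @param effect_size Multiplicative enrichment of planted transitions in
#'   positives (>= 1; 1 = null model, classes exchangeable).
#' @param length_range Inclusive integer bounds for sequence lengths
#'   (default 60..150).
#' @param peak Dirichlet concentration added on the latent residue
#'   (default 8, putting roughly 2/3 of a conserved row's mass on its
#'   residue; larger = more conserved rows).
#' @param base_conc Baseline symmetric Dirichlet concentration
#'   (default 0.25).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return List with `features` (n x 400 matrix, positives first),
#'   `labels` (1 = SIP-like, 0 = background), `ids`, and `lengths`.
#' @export
generate_sip_dataset <- function(n_pos, n_neg,
                                 enriched_transitions =
                                   rbind(cbind(1:10, 11:20),
                                         cbind(11:20, 1:10)),
                                 effect_size = 5,
                                 length_range = c(60L, 150L),
                                 peak = 8, base_conc = 0.25, seed = 1L) {
  if (n_pos < 1L || n_neg < 1L || n_pos + n_neg < 4L) {
    stop_input("need n_pos >= 1, n_neg >= 1 and n_pos + n_neg >= 4")
  }
  if (effect_size < 1) stop_input("effect_size must be >= 1")
  enriched_transitions <- as.matrix(enriched_transitions)
  if (effect_size > 1 && nrow(enriched_transitions) == 0L) {
    stop_input("enriched_transitions must be non-empty when effect_size > 1")
  }
  if (nrow(enriched_transitions) > 0L &&
      (any(enriched_transitions < 1) || any(enriched_transitions > 20))) {
    stop_input("enriched transition indices must lie in 1..20")
  }

  trans_neg <- matrix(1 / 20, 20L, 20L)
  trans_pos <- trans_neg
  if (nrow(enriched_transitions) > 0L) {
    trans_pos[enriched_transitions] <- trans_pos[enriched_transitions] *
      effect_size
  }
  trans_pos <- trans_pos / rowSums(trans_pos)

  n <- n_pos + n_neg
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))
  out <- with_seed(seed, {
    lengths <- sample(seq(length_range[1], length_range[2]), n,
                      replace = TRUE)
    feats <- matrix(NA_real_, nrow = n, ncol = 400L)
    for (i in seq_len(n)) {
      trans <- if (labels[i] == 1L) trans_pos else trans_neg
      prof <- sample_profile(lengths[i], trans, peak, base_conc)
      p <- pssm(prof$matrix, protein_id = sprintf("syn%04d", i),
                normalized = TRUE)
      feats[i, ] <- flatten_bigram(bigram_features(p))
    }
    list(lengths = lengths, feats = feats)
  })
  colnames(out$feats) <- names(flatten_bigram(
    matrix(0, 20, 20, dimnames = list(aa_alphabet(), aa_alphabet()))))
  ids <- sprintf("syn%04d", seq_len(n))
  rownames(out$feats) <- ids
  list(features = out$feats, labels = labels, ids = ids,
       lengths = out$lengths)
}

#' Generate a two-cluster Gaussian classification problem
#'
#' Two spherical unit-variance Gaussian clusters in d dimensions whose
#' centres are `separation` apart along the first axis; the standard
#' low-dimensional fixture for classifier unit tests (Bayes error is
#' `pnorm(-separation / 2)`).
#'
#' @param n Total points (even; half per class).
#' @param separation Distance between the cluster centres.
#' @param d Dimension (default 2).
#' @param seed Integer seed.
#' @return List with `x` (n x d matrix) and `labels` (`{0, 1}`).
#' @export
generate_blobs <- function(n, separation, d = 2L, seed = 1L) {
  if (n < 2L || n %% 2L != 0L) stop_input("n must be even and >= 2")
  if (d < 1L) stop_input("d must be >= 1")
  half <- n %/% 2L
  x <- with_seed(seed, {
    pts <- matrix(stats::rnorm(n * d), nrow = n, ncol = d)
    pts[seq_len(half), 1L] <- pts[seq_len(half), 1L] - separation / 2
    pts[half + seq_len(half), 1L] <- pts[half + seq_len(half), 1L] +
      separation / 2
    pts
  })
  list(x = x, labels = c(rep(0L, half), rep(1L, half)))
}

#' Write a synthetic PSSM collection to disk
#'
#' Writes `n` independent raw integer PSSMs in the PSI-BLAST ASCII dialect
#' (one file per protein, `<id>.pssm`) plus a matching multi-record FASTA of
#' each profile's argmax-path sequence, so parser and featurizer round-trip
#' tests can run on generated files.
#'
#' @param dir Output directory (created if missing).
#' @param n Number of proteins.
#' @param length_range Inclusive length bounds (default 20..60).
#' @param seed Integer seed.
#' @return List with `dir`, `pssm_files`, `fasta` and the in-memory `pssms`.
#' @export
write_synthetic_pssm_dir <- function(dir, n, length_range = c(20L, 60L),
                                     seed = 1L) {
  if (n < 1L) stop_input("n must be >= 1")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lens <- with_seed(seed,
                    sample(seq(length_range[1], length_range[2]), n,
                           replace = TRUE))
  pssms <- lapply(seq_len(n), function(i) {
    generate_raw_pssm(lens[i], seed = seed + i,
                      protein_id = sprintf("syn%03d", i))
  })
  files <- vapply(pssms, function(p) {
    f <- file.path(dir, paste0(p$protein_id, ".pssm"))
    write_pssm(p, f)
    f
  }, character(1))
  fasta <- file.path(dir, "sequences.fasta")
  writeLines(unlist(lapply(pssms, function(p) {
    c(paste0(">", p$protein_id), p$sequence)
  })), fasta)
  list(dir = dir, pssm_files = files, fasta = fasta, pssms = pssms)
}
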