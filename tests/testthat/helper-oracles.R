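# Shared fixtures and independent oracles for the test suite.

# literal triple-loop bi-gram computation, deliberately naive
bigram_oracle <- function(P) {
  L <- nrow(P)
  B <- matrix(0, 20, 20)
  for (m in 1:20) {
    for (n in 1:20) {
      acc <- 0
      for (i in 1:(L - 1)) acc <- acc + P[i, m] * P[i + 1, n]
      B[m, n] <- acc
    }
  }
  B
}

# AUC as concordance probability: concordant pairs + half ties over all
# positive-negative pairs
auc_pair_oracle <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

write_tmp_fasta <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fasta",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# a small random normalized PSSM via the package generator
random_pssm <- function(L, seed) generate_pssm(L, conservation = 1, seed = seed)
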