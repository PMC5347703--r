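#' Bi-gram transition features of a normalized PSSM
#'
#' For a row-normalized L x 20 profile P, the bi-gram occurrence matrix is
#' \deqn{B_{mn} = \sum_{i=1}^{L-1} P_{i,m} P_{i+1,n}, \quad 1 \le m, n \le 20,}
#' the expected number of adjacent-position transitions from amino acid m to
#' amino acid n under the per-position profiles. Because each row of P sums
#' to 1, the 400 entries of B sum to exactly L - 1 (one unit of transition
#' mass per adjacent pair) — a useful invariant for testing. Computed as the
#' cross product `t(P[1:(L-1), ]) %*% P[2:L, ]`.
#'
#' @param x A normalized `pssm` with at least 2 rows.
#' @return A 20 x 20 numeric matrix of class `bigram_matrix`, rows indexed by
#'   the source amino acid m and columns by the target n, in the PSSM's
#'   column order; `protein_id` carried as an attribute.
#' @export
#' @examples
#' p <- normalize_pssm(pssm(matrix(0, 5, 20)))  # uniform profile
#' bigram_features(p)[1, 1]                     # 4 * (1/20)^2 = 0.01
bigram_features <- function(x) {
  stopifnot(inherits(x, "pssm"))
  if (!x$normalized) {
    stop_input("bigram_features() requires a normalized PSSM; ",
               "call normalize_pssm() first")
  }
  L <- nrow(x$matrix)
  if (L < 2L) {
    stop_degenerate("bi-gram features need L >= 2 (no adjacent-position ",
                    "transition exists for L = ", L, ")")
  }
  B <- crossprod(x$matrix[-L, , drop = FALSE], x$matrix[-1L, , drop = FALSE])
  dimnames(B) <- list(x$column_order, x$column_order)
  structure(B, class = c("bigram_matrix", class(B)),
            protein_id = x$protein_id)
}

#' Flatten a bi-gram matrix to the 400-dimensional feature vector
#'
#' Row-major unrolling: positions 1..20 are row 1 (transitions from the
#' first amino acid to each of the 20), positions 21..40 row 2, and so on.
#' Element u (1-based) is `B[ceiling(u/20), ((u-1) %% 20) + 1]`.
#'
#' @param b A `bigram_matrix` (or any 20 x 20 numeric matrix).
#' @return Named numeric vector of length 400; names are `"A>R"`-style
#'   transition labels when dimnames are present.
#' @export
flatten_bigram <- function(b) {
  if (!is.matrix(b) || !all(dim(b) == c(20L, 20L))) {
    stop_input("expected a 20 x 20 bi-gram matrix")
  }
  v <- as.vector(t(b))
  if (!is.null(dimnames(b))) {
    names(v) <- as.vector(t(outer(rownames(b), colnames(b), paste, sep = ">")))
  }
  v
}

#' Full featurization of one PSSM
#'
#' Convenience composition `flatten_bigram(bigram_features(normalize_pssm(x)))`
#' (normalization skipped when `x` is already normalized).
#'
#' @param x A `pssm`, raw or normalized.
#' @param transform Passed to [normalize_pssm()] when `x` is raw.
#' @return Length-400 named feature vector.
#' @export
pssm_to_features <- function(x, transform = "logistic") {
  stopifnot(inherits(x, "pssm"))
  if (!x$normalized) x <- normalize_pssm(x, transform = transform)
  flatten_bigram(bigram_features(x))
}

#' Fit a PCA compression model on a feature table
#'
#' Mean-centered principal component analysis (no variance scaling) via
#' [stats::prcomp()], retaining the top `k` axes by explained variance. The
#' default `k = 350` compresses the 400 bi-gram features while keeping most
#' of the variance, discarding the low-variance directions that mostly carry
#' noise. Component signs are fixed so each component's largest-magnitude
#' loading is positive, making the model deterministic and serializable.
#'
#' @param x Numeric n x p feature matrix (or data frame of numerics), n >= 2.
#' @param k Number of components to retain; must satisfy
#'   `k <= min(p, n)`.
#' @return A list of class `pca_model` with elements `mean` (length p),
#'   `rotation` (p x k, orthonormal columns), `sdev` (all singular-value
#'   scaled sdevs), `k`, and `p`.
#' @export
fit_pca <- function(x, k = 350L) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop_input("feature table must be numeric")
  n <- nrow(x); p <- ncol(x)
  if (n < 2L) stop_input("PCA needs at least 2 samples, got ", n)
  if (k < 1L || k > min(p, n)) {
    stop_input("invalid component count k = ", k,
               ": must satisfy 1 <= k <= min(p = ", p, ", n = ", n, ")")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  # sign convention: largest-|loading| entry of each component positive
  flip <- vapply(seq_len(k), function(j) {
    i <- which.max(abs(rot[, j]))
    sign(rot[i, j])
  }, numeric(1))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2L, flip, `*`)
  structure(list(mean = pc$center, rotation = rot, sdev = pc$sdev,
                 k = as.integer(k), p = p),
            class = "pca_model")
}

#' Project a feature table through a fitted PCA model
#'
#' Computes `(x - mean) %*% rotation` using the training-fitted mean and
#' components only, so applying a model to held-out data leaks nothing from
#' the test fold.
#'
#' @param model A `pca_model` from [fit_pca()].
#' @param x Numeric m x p matrix with p matching the model.
#' @return m x k score matrix.
#' @export
apply_pca <- function(model, x) {
  stopifnot(inherits(model, "pca_model"))
  x <- as.matrix(x)
  if (ncol(x) != model$p) {
    stop_input("feature width ", ncol(x), " does not match the fitted model (",
               model$p, ")")
  }
  scores <- sweep(x, 2L, model$mean, `-`) %*% model$rotation
  colnames(scores) <- paste0("PC", seq_len(model$k))
  scores
}

# Scalar that rescales a training score matrix to unit total variance;
# a Gaussian kernel width is only meaningful relative to this scale.
score_scale_factor <- function(Z) {
  s <- sqrt(sum(apply(Z, 2L, stats::var)))
  if (!is.finite(s) || s <= 0) 1 else s
}

#' Write / read a protein feature table as CSV
#'
#' Plain CSV with a `protein_id` column followed by `f1..fp` feature columns.
#'
#' @param features Numeric matrix (rows = proteins) or data frame; row names
#'   or an existing `protein_id` column provide the ids.
#' @param path CSV path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a list with `ids` (character) and
#'   `features` (numeric matrix).
#' @export
write_feature_table <- function(features, path) {
  if (is.data.frame(features) && "protein_id" %in% names(features)) {
    ids <- as.character(features$protein_id)
    m <- as.matrix(features[setdiff(names(features), "protein_id")])
  } else {
    m <- as.matrix(features)
    ids <- rownames(m)
    if (is.null(ids)) ids <- paste0("prot", seq_len(nrow(m)))
  }
  df <- data.frame(protein_id = ids, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("protein_id", paste0("f", seq_len(ncol(m))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_input("feature table not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"protein_id" %in% names(df)) {
    stop_input("feature table lacks a protein_id column: ", path)
  }
  m <- as.matrix(df[setdiff(names(df), "protein_id")])
  if (!is.numeric(m)) stop_input("non-numeric feature values in ", path)
  rownames(m) <- df$protein_id
  list(ids = df$protein_id, features = m)
}
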