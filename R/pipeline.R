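#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end predictor with the published
#' settings as defaults: logistic PSSM normalization, PCA to 350
#' components, Gaussian kernel of width 2, uniform `alpha = 1/N`
#' initialization, and the five-repeat 1/6-holdout evaluation protocol.
#' Unknown keys are rejected; ranges are validated on construction.
#'
#' @param normalize PSSM normalization transform, `"logistic"` or
#'   `"softmax"`.
#' @param pca_k Retained PCA components (default 350).
#' @param kernel_width Gaussian kernel width (default 2).
#' @param scale Projected-score scaling before the kernel:
#'   `"total_variance"` (default; rescale the training PCA scores to unit
#'   total variance so the kernel width is scale-free) or `"none"`.
#' @param kernel_convention `"width2"` or `"half"`, see [gaussian_kernel()].
#' @param max_iter,tol,prune_threshold RVM training controls, see
#'   [rvm_control()].
#' @param threshold Decision threshold on the RVM score (default 0.5).
#' @param n_repeats,test_fraction,stratified Evaluation protocol, see
#'   [split_plan()].
#' @param min_len,max_len Sequence length filter bounds, see
#'   [length_filter()].
#' @param seed Integer seed for all pipeline randomness (splits).
#' @return Validated list of class `sip_config`.
#' @export
sip_config <- function(normalize = "logistic", pca_k = 350L,
                       kernel_width = 2, kernel_convention = "width2",
                       scale = "total_variance",
                       max_iter = 1000L, tol = 1e-3, prune_threshold = 1e9,
                       threshold = 0.5, n_repeats = 5L,
                       test_fraction = 1 / 6, stratified = TRUE,
                       min_len = 50L, max_len = 5000L, seed = 1L) {
  normalize <- match.arg(normalize, c("logistic", "softmax"))
  kernel_convention <- match.arg(kernel_convention, c("width2", "half"))
  scale <- match.arg(scale, c("total_variance", "none"))
  if (pca_k < 1L) stop_input("pca_k must be >= 1")
  if (kernel_width <= 0) stop_input("kernel_width must be positive")
  if (threshold < 0 || threshold > 1) {
    stop_input("threshold must lie in [0, 1]")
  }
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_input("test_fraction must be in (0, 1)")
  }
  if (min_len < 0 || min_len >= max_len) {
    stop_input("need 0 <= min_len < max_len")
  }
  structure(list(normalize = normalize, pca_k = as.integer(pca_k),
                 kernel_width = kernel_width,
                 kernel_convention = kernel_convention, scale = scale,
                 max_iter = as.integer(max_iter), tol = tol,
                 prune_threshold = prune_threshold, threshold = threshold,
                 n_repeats = as.integer(n_repeats),
                 test_fraction = test_fraction,
                 stratified = isTRUE(stratified),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 seed = as.integer(seed)),
            class = "sip_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys must match the arguments of [sip_config()]; unknown keys are an
#' error, so typos never silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return A validated `sip_config`.
#' @export
read_sip_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_input("the 'yaml' package is required to read config files")
  }
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(sip_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) {
    stop_input("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(sip_config, vals)
}

#' Featurize a directory of PSI-BLAST ASCII PSSM files
#'
#' Parses every file in `dir` (matching `pattern`), normalizes it, and
#' computes the 400 bi-gram features. Unparseable files are skipped with a
#' logged warning and counted, so one corrupt profile never aborts a batch;
#' zero parseable files is an error.
#'
#' @param dir Directory of PSSM files.
#' @param pattern Filename regexp (default `"\\.pssm$"`).
#' @param out Optional CSV path written via [write_feature_table()].
#' @param transform Normalization transform (default `"logistic"`).
#' @return n x 400 feature matrix with protein ids as row names; the number
#'   of skipped files is attached as attribute `n_skipped`.
#' @export
featurize_pssm_dir <- function(dir, pattern = "\\.pssm$", out = NULL,
                               transform = "logistic") {
  if (!dir.exists(dir)) stop_input("directory not found: ", dir)
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0L) {
    stop_input("no files matching '", pattern, "' in ", dir)
  }
  rows <- list()
  skipped <- 0L
  for (f in files) {
    feat <- tryCatch(
      pssm_to_features(parse_psiblast_pssm(f), transform = transform),
      error = function(e) {
        message("skipping '", basename(f), "': ", conditionMessage(e))
        NULL
      })
    if (is.null(feat)) skipped <- skipped + 1L
    else rows[[sub("\\.[^.]*$", "", basename(f))]] <- feat
  }
  if (length(rows) == 0L) {
    stop_input("no parseable PSSM files in ", dir, " (", skipped, " skipped)")
  }
  if (skipped > 0L) {
    message(skipped, " of ", length(files), " file(s) skipped")
  }
  m <- do.call(rbind, rows)
  attr(m, "n_skipped") <- skipped
  if (!is.null(out)) write_feature_table(m, out)
  m
}

#' Train the full SIP prediction model
#'
#' Fits PCA (k from the config, capped by the data) on the feature table,
#' rescales the projected scores per the config's `scale` setting, then
#' fits the RVM on them. Both sub-models plus the config
#' are bundled into one `sip_model`; with `model_dir` given, the bundle is
#' serialized as two deterministic JSON files (`pca.json`, `rvm.json`) and
#' a config record.
#'
#' @param features n x p numeric feature matrix (typically p = 400).
#' @param labels Length-n labels in `{0, 1}`, both classes present.
#' @param config A [sip_config()].
#' @param model_dir Optional output directory for the serialized archive.
#' @return List of class `sip_model` with `pca`, `rvm`, `config`.
#' @export
train_sip_model <- function(features, labels, config = sip_config(),
                            model_dir = NULL) {
  stopifnot(inherits(config, "sip_config"))
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L) {
    stop_degenerate("labels are single-class; cannot train")
  }
  pca <- fit_pca(features, k = config$pca_k)
  scores <- apply_pca(pca, features)
  s <- if (config$scale == "total_variance") score_scale_factor(scores)
       else 1
  model <- rvm_fit(scores / s, labels,
                   kernel = rvm_kernel(config$kernel_width,
                                       config$kernel_convention),
                   control = rvm_control(config$max_iter, config$tol,
                                         config$prune_threshold))
  fit <- structure(list(pca = pca, score_scale = s, rvm = model,
                        config = config),
                   class = "sip_model")
  if (!is.null(model_dir)) write_sip_model(fit, model_dir)
  fit
}

#' Serialize / load a trained SIP model
#'
#' Plain-text JSON archive in `dir`: `pca.json` (mean, rotation, k, format
#' tag), `rvm.json` (see [write_rvm_model()]) and `config.json`. Writing is
#' deterministic — training twice with the same inputs gives byte-identical
#' payloads.
#'
#' @param model A `sip_model`.
#' @param dir Archive directory (created if missing).
#' @return `write_sip_model()` returns `dir` invisibly; `read_sip_model()`
#'   the restored `sip_model`.
#' @export
write_sip_model <- function(model, dir) {
  stopifnot(inherits(model, "sip_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(format = "sipRVM/pca/1", mean = model$pca$mean,
         rotation = model$pca$rotation, sdev = model$pca$sdev,
         k = model$pca$k, p = model$pca$p,
         score_scale = model$score_scale),
    file.path(dir, "pca.json"), digits = I(17), auto_unbox = TRUE,
    matrix = "rowmajor")
  write_rvm_model(model$rvm, file.path(dir, "rvm.json"))
  jsonlite::write_json(unclass(model$config), file.path(dir, "config.json"),
                       digits = I(17), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_sip_model
#' @export
read_sip_model <- function(dir) {
  pf <- file.path(dir, "pca.json")
  if (!file.exists(pf)) stop_input("no model archive at ", dir)
  p <- jsonlite::read_json(pf, simplifyVector = TRUE)
  if (!identical(p$format, "sipRVM/pca/1")) {
    stop_input("unrecognized PCA format in ", pf)
  }
  rot <- p$rotation
  if (!is.matrix(rot)) rot <- matrix(rot, ncol = p$k)
  pca <- structure(list(mean = p$mean, rotation = rot, sdev = p$sdev,
                        k = as.integer(p$k), p = as.integer(p$p)),
                   class = "pca_model")
  cfgv <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  config <- do.call(sip_config, cfgv)
  structure(list(pca = pca,
                 score_scale = if (is.null(p$score_scale)) 1
                               else p$score_scale,
                 rvm = read_rvm_model(file.path(dir, "rvm.json")),
                 config = config),
            class = "sip_model")
}

#' Predict SIP scores and labels for new proteins
#'
#' Projects the 400-wide feature rows through the training-fitted PCA and
#' scores them with the RVM; labels are thresholded at the configured (or
#' overridden) decision threshold.
#'
#' @param model A `sip_model` (or an archive directory path).
#' @param features m x 400 feature matrix; width must match training.
#' @param threshold Optional override of `model$config$threshold`.
#' @param out Optional CSV path (`protein_id`, `score`, `label`).
#' @return Data frame with `protein_id`, `score`, `label`.
#' @export
predict_sip <- function(model, features, threshold = NULL, out = NULL) {
  if (is.character(model)) model <- read_sip_model(model)
  stopifnot(inherits(model, "sip_model"))
  features <- as.matrix(features)
  if (ncol(features) != model$pca$p) {
    stop_input("feature width ", ncol(features), " does not match the ",
               "model's expected width ", model$pca$p)
  }
  if (is.null(threshold)) threshold <- model$config$threshold
  sc <- predict(model$rvm, apply_pca(model$pca, features) / model$score_scale,
                type = "score")
  ids <- rownames(features)
  if (is.null(ids)) ids <- paste0("prot", seq_len(nrow(features)))
  res <- data.frame(protein_id = ids, score = sc,
                    label = as.integer(sc >= threshold),
                    stringsAsFactors = FALSE)
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  res
}

#' Evaluate the pipeline by repeated holdout
#'
#' Runs [repeated_holdout()] under the config's protocol (seeded splits,
#' PCA + RVM per training fold) and optionally writes the results table
#' ([write_holdout_csv()]) and the pooled test-fold ROC points.
#'
#' @param features n x p feature matrix.
#' @param labels Length-n `{0, 1}` labels.
#' @param config A [sip_config()].
#' @param out Optional metrics CSV path.
#' @param roc_out Optional ROC-points CSV path (FPR, TPR per threshold,
#'   computed on the pooled held-out scores of all repeats).
#' @return A `holdout_report` (see [repeated_holdout()]); when `roc_out`
#'   is requested the pooled ROC is attached as `$pooled_roc`.
#' @export
evaluate_sip <- function(features, labels, config = sip_config(),
                         out = NULL, roc_out = NULL) {
  stopifnot(inherits(config, "sip_config"))
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  plan <- split_plan(labels, n_repeats = config$n_repeats,
                     test_fraction = config$test_fraction,
                     stratified = config$stratified, seed = config$seed)
  report <- repeated_holdout(
    features, labels, plan = plan, pca_k = config$pca_k,
    kernel = rvm_kernel(config$kernel_width, config$kernel_convention),
    control = rvm_control(config$max_iter, config$tol,
                          config$prune_threshold),
    threshold = config$threshold, scale = config$scale,
    keep_scores = !is.null(roc_out))
  if (!is.null(roc_out)) {
    roc <- roc_curve(report$held_out$truth, report$held_out$score)
    utils::write.csv(roc$roc, roc_out, row.names = FALSE)
    report$pooled_roc <- roc
  }
  if (!is.null(out)) write_holdout_csv(report, out)
  report
}
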