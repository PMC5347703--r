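test_that("confusion counts follow the standard definitions", {
  c1 <- confusion_counts(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(unclass(c1)[c("TP", "FP", "TN", "FN")],
               list(TP = 2L, FP = 0L, TN = 2L, FN = 0L))
  c2 <- confusion_counts(c(1, 0), c(1, 1))
  expect_equal(c2$TP, 1L)
  expect_equal(c2$FP, 1L)

  # random pair against a naive counting loop
  y <- withr::with_seed(1, sample(0:1, 100, replace = TRUE))
  p <- withr::with_seed(2, sample(0:1, 100, replace = TRUE))
  cc <- confusion_counts(y, p)
  tally <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  for (i in 1:100) {
    key <- if (y[i] == 1 && p[i] == 1) "TP"
           else if (y[i] == 0 && p[i] == 1) "FP"
           else if (y[i] == 0 && p[i] == 0) "TN" else "FN"
    tally[key] <- tally[key] + 1
  }
  expect_equal(unlist(unclass(cc)[c("TP", "FP", "TN", "FN")]), tally)
  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)), "length")
})

test_that("metric arithmetic is exact on the reference counts", {
  met <- classification_metrics(list(TP = 9, FP = 1, TN = 89, FN = 1))
  expect_equal(met$Ac, 0.98)
  expect_equal(met$Sn, 0.9)
  expect_equal(met$Sp, 89 / 90)
  expect_equal(met$Pe, 0.9)
  expect_equal(met$Mcc, 800 / 900, tolerance = 1e-15)
})

test_that("metric edge cases use documented sentinels", {
  perfect <- classification_metrics(list(TP = 5, FP = 0, TN = 5, FN = 0))
  expect_equal(unlist(perfect[c("Ac", "Sn", "Sp", "Pe", "Mcc")]),
               c(Ac = 1, Sn = 1, Sp = 1, Pe = 1, Mcc = 1))

  expect_warning(
    nopos <- classification_metrics(list(TP = 0, FP = 0, TN = 8, FN = 2)),
    "zero-denominator")
  expect_equal(nopos$Pe, 0)
  expect_true("Pe" %in% nopos$undefined)

  expect_error(classification_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)),
               "empty")
})

test_that("ROC endpoints and oracle agreement hold", {
  y <- c(0, 0, 1, 1)
  expect_equal(roc_curve(y, c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(roc_curve(y, c(0.9, 0.8, 0.2, 0.1))$auc, 0)
  expect_error(roc_curve(c(1, 1), c(0.2, 0.3)), "single class")

  for (seed in 1:10) {
    y <- withr::with_seed(seed, sample(0:1, 50, replace = TRUE,
                                       prob = c(0.6, 0.4)))
    if (length(unique(y)) < 2) next
    s <- withr::with_seed(seed + 100,
                          round(stats::rnorm(50), 1))  # force ties
    r <- roc_curve(y, s)
    expect_equal(r$auc, auc_pair_oracle(y, s), tolerance = 1e-12)
    # invariance under a strictly monotone transform
    expect_equal(roc_curve(y, exp(3 * s))$auc, r$auc, tolerance = 1e-12)
    # curve is monotone in both coordinates
    expect_true(all(diff(r$roc$FPR) >= 0))
    expect_true(all(diff(r$roc$TPR) >= 0))
  }
})

test_that("ROC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  y <- withr::with_seed(5, sample(0:1, 80, replace = TRUE))
  s <- withr::with_seed(6, stats::rnorm(80))
  ours <- roc_curve(y, s)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(
    pROC::roc(y, s, levels = c(0, 1), direction = "<"))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("split plans are disjoint, exhaustive and reproducible", {
  labels <- rep(c(1, 0), c(100, 500))
  plan <- split_plan(labels, seed = 7)
  expect_length(plan$splits, 5L)
  for (sp in plan$splits) {
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_setequal(c(sp$train, sp$test), seq_along(labels))
    # test fold size n/6 = 100, stratified to the 1:5 class ratio
    expect_length(sp$test, 100L)
    expect_equal(sum(labels[sp$test] == 1), 17L)  # round(100/6)
  }
  plan2 <- split_plan(labels, seed = 7)
  expect_identical(plan, plan2)
  expect_false(identical(plan, split_plan(labels, seed = 8)))
})

test_that("repeated holdout is reproducible and beats chance on planted signal", {
  ds <- generate_sip_dataset(50, 50, effect_size = 5, seed = 17)
  plan <- split_plan(ds$labels, seed = 18)
  r1 <- suppressWarnings(
    repeated_holdout(ds$features, ds$labels, plan = plan, pca_k = 30))
  r2 <- suppressWarnings(
    repeated_holdout(ds$features, ds$labels, plan = plan, pca_k = 30))
  expect_identical(r1$per_repeat, r2$per_repeat)

  # above the no-information rate at the 95% binomial level
  n_test <- sum(r1$per_repeat$n_test)
  se <- sqrt(0.25 / n_test)
  expect_gt(mean(r1$per_repeat$Ac), 0.5 + 2 * se)
  expect_equal(r1$summary$metric, c("Ac", "Sn", "Sp", "Pe", "Mcc", "auc"))
  expect_true(all(is.finite(r1$summary$mean)))
})

test_that("a test fold without positives is flagged", {
  ds <- generate_sip_dataset(4, 36, effect_size = 5, seed = 19,
                             length_range = c(20L, 40L))
  # hand-built plan whose first test fold contains no positives
  neg <- which(ds$labels == 0)
  plan <- structure(
    list(seed = 1L, n_repeats = 1L, test_fraction = 0.25,
         stratified = FALSE, n = 40L,
         splits = list(list(train = setdiff(1:40, neg[1:10]),
                            test = neg[1:10]))),
    class = "split_plan")
  expect_warning(
    rep <- repeated_holdout(ds$features, ds$labels, plan = plan, pca_k = 10),
    "no positives")
  expect_match(rep$warnings, "Sn undefined", all = FALSE)
})

test_that("holdout CSV has one row per repeat plus the average row", {
  ds <- generate_sip_dataset(30, 30, effect_size = 5, seed = 23,
                             length_range = c(20L, 50L))
  rep <- suppressWarnings(
    repeated_holdout(ds$features, ds$labels,
                     plan = split_plan(ds$labels, seed = 24), pca_k = 20))
  f <- withr::local_tempfile(fileext = ".csv")
  write_holdout_csv(rep, f)
  lines <- readLines(f)
  expect_match(lines[1], "^# seed=24")
  tab <- utils::read.csv(f, comment.char = "#")
  expect_equal(nrow(tab), 6L)  # 5 repeats + average
  expect_equal(tab$testing_set[6], "Average")
  expect_match(tab$Ac[6], "\\+/-")
})
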