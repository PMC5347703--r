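test_that("gaussian kernel has the adopted functional form", {
  expect_equal(gaussian_kernel(c(1, 2), c(1, 2)), 1)
  # squared distance equal to width^2 forces exp(-1)
  expect_equal(gaussian_kernel(c(0, 0), c(2, 0), width = 2), exp(-1))
  x <- withr::with_seed(1, stats::rnorm(5))
  y <- withr::with_seed(2, stats::rnorm(5))
  expect_equal(gaussian_kernel(x, y, width = 1.7),
               exp(-sum((x - y)^2) / 1.7^2))
  expect_equal(gaussian_kernel(x, y, width = 1.7, convention = "half"),
               exp(-sum((x - y)^2) / (2 * 1.7^2)))
  expect_equal(gaussian_kernel(x, y), gaussian_kernel(y, x))
  expect_error(gaussian_kernel(c(1, 2), c(1, 2, 3)), "dimension")
  expect_error(gaussian_kernel(x, y, width = 0), "positive")
})

test_that("design matrix pairs a bias column with a symmetric kernel block", {
  X <- withr::with_seed(3, matrix(stats::rnorm(12), 6, 2))
  Phi <- rvm_design(X, X)
  expect_equal(dim(Phi), c(6L, 7L))
  expect_equal(unname(Phi[, 1]), rep(1, 6))
  K <- Phi[, -1]
  expect_equal(K, t(K), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(diag(K)), rep(1, 6))
})

test_that("posterior matches the identity-design closed form", {
  t <- c(1, 0, 1)
  post <- rvm_posterior(diag(3), t, alpha = rep(1, 3), sigma2 = 1)
  expect_equal(post$Sigma, diag(3) / 2, tolerance = 1e-12)
  expect_equal(post$mu, t / 2, tolerance = 1e-12)
})

test_that("posterior mean equals the ridge-regression oracle", {
  for (seed in 1:50) {
    prob <- withr::with_seed(seed, {
      N <- sample(4:12, 1); M <- sample(2:N, 1)
      list(Phi = matrix(stats::rnorm(N * M), N, M),
           t = sample(0:1, N, replace = TRUE),
           alpha = stats::rexp(M) + 0.1,
           sigma2 = stats::rexp(1) + 0.05)
    })
    post <- rvm_posterior(prob$Phi, prob$t, prob$alpha, prob$sigma2)
    ridge <- solve(crossprod(prob$Phi) + prob$sigma2 * diag(prob$alpha),
                   crossprod(prob$Phi, prob$t))
    expect_equal(post$mu, drop(ridge), tolerance = 1e-8)
  }
})

test_that("a huge prior precision pins its weight to zero", {
  Phi <- withr::with_seed(60, matrix(stats::rnorm(20), 10, 2))
  t <- rep(c(0, 1), 5)
  post <- rvm_posterior(Phi, t, alpha = c(1e12, 1), sigma2 = 0.5)
  expect_lt(abs(post$mu[1]), 1e-5)
})

test_that("hyperparameter update matches scalar hand arithmetic", {
  # single basis: Phi = (1, 2)', alpha = 0.5, sigma2 = 0.25
  Phi <- matrix(c(1, 2), 2, 1)
  t <- c(0, 1)
  alpha <- 0.5; sigma2 <- 0.25
  post <- rvm_posterior(Phi, t, alpha, sigma2)
  Sigma_hand <- 1 / (sum(Phi^2) / sigma2 + alpha)     # 1 / (20.5)
  mu_hand <- Sigma_hand * sum(Phi * t) / sigma2       # Sigma * 8
  expect_equal(post$Sigma[1, 1], Sigma_hand)
  expect_equal(post$mu, mu_hand)
  upd <- rvm_update(post$Sigma, post$mu, t, Phi, alpha)
  gamma_hand <- 1 - alpha * Sigma_hand
  expect_equal(upd$gamma, gamma_hand)
  expect_equal(upd$alpha, gamma_hand / mu_hand^2)
  expect_equal(upd$sigma2,
               sum((t - Phi %*% mu_hand)^2) / (2 - gamma_hand))
})

test_that("update guards degenerate regimes", {
  # more well-determined bases than observations: sum(gamma) > N
  Phi <- matrix(c(1, 0.5), 1, 2)
  Sigma <- diag(c(1e-12, 1e-12))
  mu <- c(0.1, 0.1)
  expect_error(rvm_update(Sigma, mu, t = 1, Phi, alpha = c(1, 1)),
               "degenerate")
  upd <- rvm_update(Sigma, mu, t = 1, Phi, alpha = c(1, 1), strict = FALSE)
  expect_true(is.na(upd$sigma2))

  # exactly well-determined basis (gamma -> 0) is flagged for pruning
  upd2 <- rvm_update(Sigma = matrix(2), mu = 0.5, t = c(0, 1),
                     Phi = matrix(c(1, 2), 2, 1), alpha = 0.5)
  expect_equal(upd2$gamma, 0)
  expect_gt(upd2$alpha, 1e9)

  # perfect fit: residual 0, sigma2 floored
  Phi3 <- matrix(c(1, 1), 2, 1)
  mu3 <- 1
  upd3 <- rvm_update(Sigma = matrix(0.5), mu = mu3, t = drop(Phi3 %*% mu3),
                     Phi = Phi3, alpha = 0.5)
  expect_equal(upd3$sigma2, 1e-12)

  # underflowing weight sends its alpha to the prune threshold
  upd4 <- rvm_update(Sigma = matrix(0.5), mu = 0, t = c(0, 1),
                     Phi = matrix(c(1, 2), 2, 1), alpha = 0.5)
  expect_gt(upd4$alpha, 1e9)
})

test_that("separable clusters are fit perfectly and sparsely", {
  b <- generate_blobs(20, separation = 8, d = 2, seed = 5)
  fit <- rvm_fit(b$x, b$labels)
  pred <- predict(fit, b$x, type = "label")
  expect_equal(pred, b$labels)
  expect_lt(nrow(fit$relevance_vectors), 20)
  # agreement with an independent nearest-centroid oracle
  centroids <- rbind(colMeans(b$x[b$labels == 0, ]),
                     colMeans(b$x[b$labels == 1, ]))
  nc <- apply(b$x, 1, function(p) {
    which.min(c(sum((p - centroids[1, ])^2), sum((p - centroids[2, ])^2))) - 1L
  })
  expect_equal(pred, nc)
})

test_that("duplicated training points do not change the learned classification", {
  # evidence maximization sees N through the alpha init and sigma2 refit,
  # so scores are not bit-invariant under duplication; the classification
  # and the ranking must still agree
  b <- generate_blobs(16, separation = 6, d = 2, seed = 9)
  probe <- withr::with_seed(10, matrix(stats::rnorm(60), 30, 2) * 3)
  f1 <- rvm_fit(b$x, b$labels)
  f2 <- rvm_fit(rbind(b$x, b$x), c(b$labels, b$labels))
  expect_identical(predict(f1, b$x, type = "label"),
                   predict(f2, b$x, type = "label"))
  s1 <- predict(f1, probe); s2 <- predict(f2, probe)
  expect_gt(stats::cor(s1, s2), 0.99)
  expect_gte(mean((s1 >= 0.5) == (s2 >= 0.5)), 0.9)
})

test_that("single-class labels are a degenerate model", {
  x <- matrix(stats::rnorm(20), 10, 2)
  expect_error(rvm_fit(x, rep(1, 10)), "single-class")
})

test_that("training is deterministic and permutation invariant", {
  b <- generate_blobs(40, separation = 5, d = 3, seed = 12)
  probe <- withr::with_seed(13, matrix(stats::rnorm(45), 15, 3))
  f1 <- rvm_fit(b$x, b$labels)
  f2 <- rvm_fit(b$x, b$labels)
  expect_identical(predict(f1, probe), predict(f2, probe))

  perm <- withr::with_seed(14, sample(40))
  f3 <- rvm_fit(b$x[perm, ], b$labels[perm])
  expect_lt(max(abs(predict(f1, probe) - predict(f3, probe))), 1e-8)
})

test_that("evidence is non-decreasing in almost all sweeps", {
  b <- generate_blobs(60, separation = 4, d = 2, seed = 21)
  fit <- rvm_fit(b$x, b$labels)
  ev <- fit$training_log$log_evidence
  ok <- diff(ev) >= -1e-6          # tolerate plateau float noise
  expect_gte(mean(ok, na.rm = TRUE), 0.95)
})

test_that("prediction follows the kernel expansion", {
  # hand-built model: one relevance vector, weight 1, no bias
  m <- structure(
    list(relevance_vectors = matrix(c(1, 2), 1, 2), weights = 1,
         has_bias = FALSE, rv_index = 1L, alpha = 1, sigma2 = 0.1,
         kernel = rvm_kernel(), converged = TRUE, n_train = 1,
         training_log = NULL),
    class = "rvm")
  expect_equal(predict(m, matrix(c(1, 2), 1, 2)), 1)
  expect_equal(predict(m, matrix(c(3, 2), 1, 2)), exp(-4 / 4))
  expect_identical(predict(m, matrix(numeric(0), 0, 2)), numeric(0))
  expect_error(predict(m, matrix(0, 1, 3)), "width")

  # fitted scores at training points reproduce the posterior fit
  b <- generate_blobs(24, separation = 5, d = 2, seed = 30)
  fit <- rvm_fit(b$x, b$labels)
  Phi <- rvm_design(b$x, b$x, fit$kernel)
  active <- c(if (fit$has_bias) 1L, fit$rv_index + 1L)
  post <- rvm_posterior(Phi[, active, drop = FALSE], b$labels,
                        fit$alpha, fit$sigma2)
  expect_equal(predict(fit, b$x),
               drop(Phi[, active, drop = FALSE] %*% post$mu),
               tolerance = 1e-8)
})

test_that("label thresholding is monotone with the documented boundary", {
  b <- generate_blobs(40, separation = 4, d = 2, seed = 31)
  fit <- rvm_fit(b$x, b$labels)
  sc <- predict(fit, b$x)
  expect_equal(predict(fit, b$x, type = "label", threshold = min(sc)),
               rep(1L, 40))  # boundary score counts as positive
  counts <- vapply(seq(0, 1, by = 0.1), function(th) {
    sum(predict(fit, b$x, type = "label", threshold = th))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a Bayes-separable blob problem generalizes", {
  b <- generate_blobs(200, separation = 8, d = 2, seed = 32)
  tr <- c(1:70, 101:170)
  fit <- rvm_fit(b$x[tr, ], b$labels[tr])
  acc <- mean(predict(fit, b$x[-tr, ], type = "label") == b$labels[-tr])
  expect_gt(acc, 0.9)
})

test_that("model serialization round-trips predictions exactly", {
  b <- generate_blobs(30, separation = 5, d = 2, seed = 33)
  fit <- rvm_fit(b$x, b$labels)
  f <- withr::local_tempfile(fileext = ".json")
  write_rvm_model(fit, f)
  back <- read_rvm_model(f)
  probe <- withr::with_seed(34, matrix(stats::rnorm(20), 10, 2))
  expect_equal(predict(fit, probe), predict(back, probe),
               tolerance = 1e-15)
})
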