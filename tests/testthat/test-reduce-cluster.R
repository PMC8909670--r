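test_that("fit_embedding matches the covariance eigendecomposition oracle", {
  set.seed(4)
  # 5 samples x 3 sites
  betas <- matrix(runif(15), nrow = 3)
  ages <- c(1, 5, 20, 40, 80)
  emb <- fit_embedding(betas, n_components = 3, ages = ages)
  ev_oracle <- sort(eigen(cov(t(betas)), symmetric = TRUE)$values,
                    decreasing = TRUE)
  expect_equal(emb$explained_variance, ev_oracle, tolerance = 1e-10)
  expect_true(all(diff(emb$explained_variance) <= 1e-12))
  # orthonormal basis
  expect_equal(crossprod(emb$basis), diag(3), tolerance = 1e-8)
})

test_that("rank-1 data put all variance on component 1; reconstruction is exact", {
  dir <- c(1, 2, -1) / sqrt(6)
  t_vals <- c(-2, -1, 0, 1.5, 3)
  betas <- 0.5 + t(outer(t_vals, dir) * 0.05)  # sites x samples on one line
  emb <- fit_embedding(betas, n_components = 1)
  total_var <- sum(diag(cov(t(betas))))
  expect_equal(emb$explained_variance[1], total_var, tolerance = 1e-12)
  expect_error(fit_embedding(betas, n_components = 2), "rank")

  # full-rank 4x4: projection then reconstruction reproduces the centered data
  set.seed(9)
  b4 <- matrix(runif(16), 4)
  emb4 <- fit_embedding(b4, n_components = 3)  # 4 samples allow 3 components
  Xc <- sweep(t(b4), 2, emb4$training_mean)
  sc <- predict(emb4, b4)
  expect_equal(sc %*% t(emb4$basis), Xc, tolerance = 1e-10)
})

test_that("embedding projection behaves like the training map", {
  cfg <- small_config(n_samples = 50, n_sites = 80, seed = 41)
  cohort <- simulate_cohort(cfg)
  emb <- fit_embedding(cohort$train$betas, 2, cohort$train$ages)
  # training mean maps to the origin
  mu <- matrix(emb$training_mean, ncol = 1,
               dimnames = list(cohort$train$probe_ids, "m"))
  expect_equal(unname(predict(emb, mu)), matrix(0, 1, 2), tolerance = 1e-12)
  # per-component training variance equals explained_variance
  sc <- predict(emb, cohort$train$betas)
  expect_equal(unname(apply(sc, 2, var)), emb$explained_variance,
               tolerance = 1e-10)
  # held-out sample equals the brute-force inner product with each loading
  x <- cohort$test$betas[, 1, drop = FALSE]
  manual <- as.numeric((x[, 1] - emb$training_mean) %*% emb$basis)
  expect_equal(as.numeric(predict(emb, x)), manual, tolerance = 1e-12)
  # components are oriented to correlate non-negatively with age
  expect_true(all(apply(sc, 2, cor, y = cohort$train$ages) >= 0))
  # permutation equivariance
  perm <- sample(ncol(cohort$train$betas))
  expect_equal(predict(emb, cohort$train$betas[, perm]), sc[perm, ],
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(predict(emb, cohort$train$betas[1:10, ]), "missing")
})

test_that("k = 1 mixture recovers the family-constrained MLE", {
  set.seed(10)
  X <- matrix(rnorm(200), ncol = 2)
  n <- nrow(X)
  fit <- fit_gmm(X, k = 1, family = "full-free")
  expect_equal(as.numeric(fit$means), colMeans(X), tolerance = 1e-8)
  expect_equal(fit$covariances[[1]], cov(X) * (n - 1) / n, tolerance = 1e-8)
  fit_sph <- fit_gmm(X, k = 1, family = "spherical-shared")
  expect_equal(fit_sph$covariances[[1]],
               diag(rep(mean(diag(cov(X) * (n - 1) / n)), 2)),
               tolerance = 1e-8)
  expect_equal(rowSums(fit$responsibilities), rep(1, n), tolerance = 1e-12)
})

test_that("well-separated 1-D clusters are recovered and BIC prefers k = 2", {
  set.seed(11)
  x <- matrix(c(rnorm(100, -10, 0.5), rnorm(100, 10, 0.5)), ncol = 1)
  fit <- fit_gmm(x, k = 2, family = "spherical-free", seed = 1)
  expect_equal(sort(as.numeric(fit$means)), c(-10, 10), tolerance = 0.3)
  fit1 <- fit_gmm(x, k = 1, family = "spherical-free", seed = 1)
  expect_lt(gmm_bic(fit), gmm_bic(fit1))
  expect_equal(rowSums(fit$responsibilities), rep(1, 200), tolerance = 1e-12)
})

test_that("BIC counts parameters per family and follows the formula", {
  set.seed(12)
  X <- matrix(rnorm(120), ncol = 2)
  fit <- fit_gmm(X, k = 1, family = "spherical-shared")
  expect_identical(fit$n_params, 3L)  # 2 means + 1 variance
  expect_equal(gmm_bic(fit), 3 * log(60) - 2 * fit$log_likelihood,
               tolerance = 1e-12)
  # doubling n with identical log-likelihood raises BIC by n_params * ln 2
  expect_equal(gmm_bic(fit, 120) - gmm_bic(fit, 60), 3 * log(2),
               tolerance = 1e-12)
  # k = 3, d = 2: (k - 1) weights + k * d means + covariance entries
  counts <- c("spherical-shared" = 9L, "spherical-free" = 11L,
              "diagonal-shared" = 10L, "diagonal-free" = 14L,
              "full-shared" = 11L, "full-free" = 17L)
  for (fam in names(counts)) {
    expect_identical(fit_gmm(X, k = 3, family = fam, seed = 2)$n_params,
                     counts[[fam]])
  }
})

test_that("EM log-likelihood is non-decreasing across many randomized fits", {
  set.seed(13)
  fams <- gmm_families()
  for (i in 1:30) {
    n <- sample(30:60, 1)
    X <- matrix(rnorm(2 * n, sd = sample(1:3, 1)), ncol = 2) +
      rep(sample(0:4, 1), 2 * n)
    fit <- fit_gmm(X, k = sample(1:3, 1), family = sample(fams, 1), seed = i)
    expect_true(all(diff(fit$loglik_trace) >= -1e-7))
  }
})

test_that("select_gmm is deterministic and honours k_range", {
  set.seed(14)
  X <- rbind(matrix(rnorm(100, -4, 0.4), ncol = 2),
             matrix(rnorm(100, 4, 0.4), ncol = 2))
  s1 <- select_gmm(X, k_range = 1:3, seed = 5)
  s2 <- select_gmm(X, k_range = 1:3, seed = 5)
  expect_identical(s1$k, s2$k)
  expect_identical(s1$family, s2$family)
  expect_equal(s1$log_likelihood, s2$log_likelihood, tolerance = 1e-12)
  expect_identical(s1$k, 2L)
  expect_identical(select_gmm(X, k_range = 1, seed = 5)$k, 1L)
})

test_that("BIC selection recovers k = 3 from a clean mixture in >= 9/10 seeds", {
  centers <- rbind(c(-6, 0), c(0, 5), c(6, 0))
  hits <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    X <- do.call(rbind, lapply(1:3, function(j) {
      matrix(rnorm(2 * 667, sd = 0.6), ncol = 2) +
        matrix(centers[j, ], 667, 2, byrow = TRUE)
    }))
    sel <- select_gmm(X, k_range = 1:5,
                      families = c("spherical-free", "full-free"), seed = s)
    if (sel$k == 3L) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
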