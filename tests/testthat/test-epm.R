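test_that("site update is per-site OLS; oracle-checked on noisy data", {
  s <- c(0, 10, 25, 40, 60)
  # exact linear site
  b_exact <- matrix(0.1 + 0.002 * s, nrow = 1)
  up <- epm_site_update(b_exact, s)
  expect_equal(unname(up$intercepts), 0.1, tolerance = 1e-12)
  expect_equal(unname(up$rates), 0.002, tolerance = 1e-12)

  # constant site: rate 0, intercept = site mean
  up0 <- epm_site_update(matrix(0.42, 1, 5), s)
  expect_equal(unname(up0$rates), 0)
  expect_equal(unname(up0$intercepts), 0.42)

  expect_error(epm_site_update(b_exact, rep(3, 5)), "zero variance")

  # 20-sample noisy site vs brute-force grid minimization of squared error
  set.seed(30)
  s20 <- runif(20, 0, 80)
  b20 <- matrix(0.3 + 0.004 * s20 + rnorm(20, 0, 0.02), nrow = 1)
  up20 <- epm_site_update(b20, s20)
  grid_r <- seq(0.002, 0.006, by = 1e-6)
  sse <- vapply(grid_r, function(r) {
    m0 <- mean(b20) - r * mean(s20)
    sum((b20 - m0 - r * s20)^2)
  }, numeric(1))
  expect_equal(unname(up20$rates), grid_r[which.min(sse)], tolerance = 1e-4)
})

test_that("state update is the exact per-sample minimizer", {
  # single site inverts the line
  m0 <- 0.2; r <- 0.003; s_true <- 37.5
  b <- matrix(m0 + r * s_true, 1, 1)
  expect_equal(unname(epm_state_update(b, m0, r)), s_true, tolerance = 1e-10)

  # two sites with rates r and -r and consistent data agree with either alone
  b2 <- matrix(c(0.2 + 0.003 * s_true, 0.8 - 0.003 * s_true), 2, 1)
  expect_equal(unname(epm_state_update(b2, c(0.2, 0.8), c(0.003, -0.003))),
               s_true, tolerance = 1e-10)

  expect_error(epm_state_update(b2, c(0.2, 0.8), c(0, 0)), "rates")

  # 50-site noisy sample vs 1-D golden-section minimization
  set.seed(31)
  m0v <- runif(50, 0.2, 0.8)
  rv <- runif(50, -0.01, 0.01)
  bj <- matrix(m0v + rv * 42 + rnorm(50, 0, 0.02), ncol = 1)
  s_hat <- unname(epm_state_update(bj, m0v, rv))
  oracle <- optimize(function(s) sum((bj - m0v - rv * s)^2),
                     interval = c(-200, 300), tol = 1e-10)$minimum
  expect_equal(s_hat, oracle, tolerance = 1e-6)
})

test_that("epm_fit reaches the noiseless fixed point and never increases RSS", {
  cfg <- sim_config(n_samples = 40, n_sites = 60, noise_sd = 0, seed = 33)
  cohort <- simulate_cohort(cfg)
  s_true <- cohort$truth$latent_states[cohort$train$sample_ids]
  fit0 <- epm_fit(cohort$train$betas, initial_states = s_true)
  expect_lt(fit0$rss_history[2], 1e-18)  # RSS 0 after the first site update
  expect_true(fit0$converged)

  # randomized fits: RSS non-increasing at every half-step
  set.seed(34)
  for (i in 1:20) {
    n <- sample(10:25, 1); p <- sample(5:40, 1)
    B <- matrix(runif(n * p), p, n)
    fit <- suppressWarnings(epm_fit(B, initial_states = runif(n, 0, 90),
                                    max_iter = 30))
    expect_true(all(diff(fit$rss_history) <= 1e-10))
  }
})

test_that("EPM recovers generating states on a blood-like cohort", {
  cfg <- sim_config(n_samples = 250, n_sites = 500, noise_sd = 0.02, seed = 35)
  cohort <- simulate_cohort(cfg)
  fit <- epm_fit(cohort$train)
  s_true <- cohort$truth$latent_states[cohort$train$sample_ids]
  expect_gt(cor(fit$states, s_true), 0.95)
  expect_true(any(fit$rates != 0))
})

test_that("age initialization pins the affine scale of the solution", {
  # the model is invariant under s -> alpha s + gamma with compensating site
  # parameters; starting from the generating scale must keep the fit there.
  # Clean data whose latent state IS the initialization: slope vs truth ~ 1.
  set.seed(81)
  ages <- runif(120, 0, 90)
  # rates scaled down so site means stay in [0, 1] over the 0-90 state range
  cfg <- sim_config(n_samples = 120, n_sites = 200, noise_sd = 0.01,
                    site_rate_range = c(0.002, 0.008), seed = 82)
  out <- simulate_betas(stats::setNames(ages, sprintf("S%04d", 1:120)), cfg)
  fit <- epm_fit(out$dataset$betas, initial_states = ages)
  slope <- coef(lm(fit$states ~ ages))[2]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)

  # explicit invariance: transforming site parameters compensates the state
  # transform at unchanged RSS
  m0 <- out$truth$site_intercepts; r <- out$truth$site_rates
  B <- out$dataset$betas
  rss1 <- sum((B - (outer(r, ages) + m0))^2)
  alpha <- 2.5; gamma <- -7
  rss2 <- sum((B - (outer(r / alpha, alpha * ages + gamma) +
                      (m0 - r * gamma / alpha)))^2)
  expect_equal(rss1, rss2, tolerance = 1e-8)
})

test_that("epm_predict freezes site parameters", {
  cfg <- small_config(n_samples = 60, n_sites = 100, seed = 36)
  cohort <- simulate_cohort(cfg)
  fit <- epm_fit(cohort$train)
  # training samples reproduce fitted states
  expect_equal(epm_predict(fit, cohort$train), fit$states, tolerance = 1e-10)
  # duplicated sample predicts identically
  dup <- cohort$test$betas[, c(2, 2)]
  colnames(dup) <- c("x", "y")
  pd <- epm_predict(fit, dup)
  expect_equal(unname(pd[1]), unname(pd[2]))
  # held-out noiseless sample from the generating model is recovered exactly
  cfg0 <- sim_config(n_samples = 30, n_sites = 80, noise_sd = 0, seed = 37)
  c0 <- simulate_cohort(cfg0)
  B0 <- cohort_matrix(c0)
  fit0 <- epm_fit(c0$train, initial_states =
                    c0$truth$latent_states[c0$train$sample_ids])
  held <- c0$test$betas[, 1, drop = FALSE]
  expect_equal(unname(epm_predict(fit0, held)),
               unname(c0$truth$latent_states[c0$test$sample_ids[1]]),
               tolerance = 1e-8)
  expect_error(epm_predict(fit, cohort$test$betas[-1, ]), "missing")
})

test_that("cross-validation covers each sample once and correlates with truth", {
  cfg <- sim_config(n_samples = 100, n_sites = 300, noise_sd = 0.02, seed = 38)
  cohort <- simulate_cohort(cfg)
  tr <- cohort$train
  cv <- epm_cross_validate(tr, n_folds = 5, seed = 7)
  expect_length(cv$states, ncol(tr$betas))
  expect_identical(sort(unique(cv$folds)), 1:5)
  s_true <- cohort$truth$latent_states[tr$sample_ids]
  expect_gt(cor(cv$states, s_true), 0.95)

  # identical seed, identical folds; leave-one-out covers every sample
  cv2 <- epm_cross_validate(tr, n_folds = 5, seed = 7)
  expect_identical(cv$folds, cv2$folds)
  small <- subset_dataset(tr, samples = 1:8)
  loo <- epm_cross_validate(small, n_folds = 8, seed = 1)
  expect_identical(sort(loo$folds), 1:8)
})

test_that("doubling noise does not flip well-determined rate signs", {
  base <- sim_config(n_samples = 150, n_sites = 200, noise_sd = 0.02, seed = 39)
  doubled <- sim_config(n_samples = 150, n_sites = 200, noise_sd = 0.04, seed = 39)
  c1 <- simulate_cohort(base)
  c2 <- simulate_cohort(doubled)
  f1 <- epm_fit(c1$train)
  f2 <- epm_fit(c2$train)
  r_true <- c1$truth$site_rates
  # rate-estimation standard error at the doubled noise level
  s <- c2$truth$latent_states[c2$train$sample_ids]
  se <- 0.04 / sqrt(sum((s - mean(s))^2))
  strong <- abs(r_true) > 3 * se
  expect_true(any(strong))
  expect_identical(sign(f1$rates[strong]), sign(r_true[strong]))
  expect_identical(sign(f2$rates[strong]), sign(r_true[strong]))
})
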