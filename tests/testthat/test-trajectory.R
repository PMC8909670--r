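test_that("MST matches brute-force spanning-tree enumeration", {
  # 3 collinear centers at 0, 1, 3: edges (1,2), (2,3), total weight 3
  g <- minimum_spanning_tree(cbind(c(0, 1, 3)))
  expect_equal(unname(g$edges), rbind(c(1L, 2L), c(2L, 3L)))
  expect_equal(sum(g$weights), 3)

  # k = 1: empty edge set
  expect_identical(nrow(minimum_spanning_tree(cbind(0))$edges), 0L)

  # 5 random centers vs enumeration of all 125 labeled spanning trees
  for (s in 1:5) {
    set.seed(200 + s)
    centers <- matrix(runif(10), 5, 2)
    g5 <- minimum_spanning_tree(centers)
    expect_equal(sum(g5$weights), brute_force_mst_weight(centers),
                 tolerance = 1e-12)
    expect_identical(nrow(g5$edges), 4L)
  }

  # duplicate centers are allowed via a zero-weight edge
  gd <- minimum_spanning_tree(rbind(c(0, 0), c(0, 0), c(1, 0)))
  expect_equal(min(gd$weights), 0)
})

test_that("start cluster is the minimum-mean-age cluster, ties to smaller index", {
  set.seed(21)
  coords <- rbind(matrix(rnorm(60, -5, 0.3), ncol = 2),
                  matrix(rnorm(60, 0, 0.3), ncol = 2),
                  matrix(rnorm(60, 5, 0.3), ncol = 2))
  ages <- c(rnorm(30, 5, 1), rnorm(30, 40, 1), rnorm(30, 70, 1))
  gmm <- fit_gmm(coords, 3, "spherical-free", seed = 1)
  start <- choose_start_cluster(gmm, coords, ages)
  # the chosen cluster's mean coordinate should sit near the young group
  expect_equal(as.numeric(gmm$means[start, ]), c(-5, -5), tolerance = 0.5)

  g1 <- fit_gmm(coords, 1, "full-free")
  expect_identical(choose_start_cluster(g1, coords, ages), 1L)

  # equal mean ages: smaller index wins
  two <- fit_gmm(rbind(matrix(rnorm(40, -3, 0.2), ncol = 2),
                       matrix(rnorm(40, 3, 0.2), ncol = 2)),
                 2, "spherical-free", seed = 2)
  expect_identical(choose_start_cluster(two, rbind(two$means), c(30, 30)),
                   1L)
})

test_that("initial_path orders the chain and rejects branching trees", {
  g <- minimum_spanning_tree(cbind(c(0, 1, 3)))
  g$start_cluster <- 1L
  expect_identical(initial_path(g), c(1L, 2L, 3L))
  g$start_cluster <- 3L
  expect_identical(initial_path(g), c(3L, 2L, 1L))

  g1 <- minimum_spanning_tree(cbind(0))
  g1$start_cluster <- 1L
  expect_identical(initial_path(g1), 1L)

  # star tree with 3 leaves: declared unsupported topology
  star <- minimum_spanning_tree(rbind(c(0, 0), c(1, 0), c(-0.5, 0.9),
                                      c(-0.5, -0.9)))
  star$start_cluster <- 2L
  expect_error(initial_path(star), "unsupported topology")
})

test_that("principal curve handles straight lines, arcs, and max_iter = 0", {
  # points exactly on a segment: converges to it with ~zero projection RSS
  set.seed(22)
  t_vals <- sort(runif(60, 0, 1))
  pts <- cbind(t_vals * 4, t_vals * 3)
  path <- rbind(c(0, 0), c(4, 3))
  curve <- fit_principal_curve(pts, path)
  expect_lte(utils::tail(curve$msd_trace, 1), 1e-10)
  # arc-length differences match the generating positions (the curve's zero
  # sits at the first data point, not the initial path endpoint)
  pt <- assign_pseudotime(curve, pts)
  expect_equal(pt - pt[1], (t_vals - t_vals[1]) * 5, tolerance = 1e-5)

  # noisy quarter circle: final projection MSD <= initial piecewise-path MSD
  theta <- sort(runif(150, 0, pi / 2))
  arc <- cbind(cos(theta), sin(theta)) + matrix(rnorm(300, 0, 0.03), ncol = 2)
  init <- rbind(c(1, 0), c(sqrt(0.5), sqrt(0.5)), c(0, 1))
  curve2 <- fit_principal_curve(arc, init)
  expect_lte(utils::tail(curve2$msd_trace, 1), curve2$msd_trace[1])

  # max_iter = 0: initial path returned unchanged
  curve0 <- fit_principal_curve(arc, init, max_iter = 0)
  expect_equal(curve0$control_points, init, ignore_attr = TRUE)

  expect_error(fit_principal_curve(matrix(1, 5, 2), init), "identical")
})

test_that("pseudotime assignment agrees with a dense-sampling oracle", {
  set.seed(23)
  theta <- seq(0, pi / 2, length.out = 40)
  curve <- fit_principal_curve(cbind(cos(theta), sin(theta)),
                               rbind(c(1, 0), c(0, 1)), max_iter = 0)
  P <- curve$control_points

  # start point maps to 0; a point beyond the end tangent clamps to the total
  expect_equal(assign_pseudotime(curve, P[1, , drop = FALSE]), 0)
  endpt <- P[nrow(P), ] + 5 * (P[nrow(P), ] - P[nrow(P) - 1, ])
  expect_equal(assign_pseudotime(curve, rbind(endpt)), curve$total_length)

  # dense polyline sampling at 1e5 points as the projection oracle
  cum <- curve$cumulative_arc_length
  s_dense <- seq(0, curve$total_length, length.out = 1e5)
  dense <- cbind(approx(cum, P[, 1], xout = s_dense)$y,
                 approx(cum, P[, 2], xout = s_dense)$y)
  pts <- matrix(runif(20, -0.2, 1.2), ncol = 2)
  pt <- assign_pseudotime(curve, pts)
  oracle <- vapply(seq_len(nrow(pts)), function(i) {
    d2 <- (dense[, 1] - pts[i, 1])^2 + (dense[, 2] - pts[i, 2])^2
    s_dense[which.min(d2)]
  }, numeric(1))
  expect_lt(max(abs(pt - oracle)), 1e-3 * curve$total_length)
})

test_that("pseudotime is rigid-motion equivariant and bounded", {
  set.seed(24)
  pts <- cbind(sort(runif(80, 0, 4)), rnorm(80, 0, 0.1))
  init <- rbind(c(0, 0), c(4, 0))
  curve <- fit_principal_curve(pts, init)
  pt <- assign_pseudotime(curve, pts)
  expect_true(all(pt >= 0 & pt <= curve$total_length))

  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  shift <- c(3, -2)
  ptsR <- sweep(pts %*% R, 2, -shift)
  curveR <- fit_principal_curve(ptsR, sweep(init %*% R, 2, -shift))
  expect_equal(assign_pseudotime(curveR, ptsR), pt, tolerance = 1e-8)
})

test_that("clean-data pseudotime is monotone in the latent state", {
  cfg <- sim_config(n_samples = 150, n_sites = 300, noise_sd = 0, seed = 51)
  cohort <- simulate_cohort(cfg)
  # noiseless betas are exactly linear in the state, so the centered matrix
  # has rank 1 and only one component exists
  model <- fit_trajectory(cohort$train, n_components = 1, seed = 1)
  pt <- model$pseudotime
  s_true <- cohort$truth$latent_states[names(pt)]
  keep <- !duplicated(s_true)
  expect_equal(cor(pt[keep], s_true[keep], method = "spearman"), 1,
               tolerance = 1e-12)
  # start-cluster samples sit earlier than end-cluster samples
  assign <- model$gmm$cluster
  path <- initial_path(model$graph)
  if (length(path) > 1) {
    expect_lt(median(pt[assign == path[1]]),
              median(pt[assign == path[length(path)]]))
  }
})

test_that("predict_pseudotime reuses the frozen model", {
  cfg <- small_config(n_samples = 90, n_sites = 150, seed = 61)
  cohort <- simulate_cohort(cfg)
  ref <- build_reference(cohort$train)
  train <- quantile_normalize(cohort$train, ref)
  sel <- select_sites(site_age_correlation(train), 0.4)
  train_sel <- subset_dataset(train, sites = sel$probe_ids)
  model <- fit_trajectory(train_sel, seed = 1)

  # training data through predict equals the fit-time assignment
  expect_equal(predict_pseudotime(model, train_sel), model$pseudotime,
               tolerance = 1e-10)

  # duplicated sample columns give identical values
  test_sel <- subset_dataset(quantile_normalize(cohort$test, ref),
                             sites = sel$probe_ids)
  dup <- test_sel$betas[, c(1, 1)]
  colnames(dup) <- c("a", "b")
  ptd <- predict_pseudotime(model, dup)
  expect_equal(unname(ptd[1]), unname(ptd[2]))

  # site mismatch errors, naming missing probes
  expect_error(predict_pseudotime(model, test_sel$betas[-1, ]),
               sel$probe_ids[1], fixed = TRUE)
})
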