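#' Minimum spanning tree over cluster centers
#'
#' Prim's algorithm under Euclidean distance with deterministic tie-breaking:
#' among equal-weight candidate edges the lexicographically smallest (i, j)
#' pair wins.  Duplicate centers are allowed (zero-weight edges).
#'
#' @param centers Numeric matrix of cluster centers (k x dimensions).
#' @return An object of class `cluster_graph`: `centers`, `edges` (m x 2
#'   matrix with i < j), `weights`, `start_cluster` (NA until chosen).
#' @export
minimum_spanning_tree <- function(centers) {
  centers <- as.matrix(centers)
  k <- nrow(centers)
  if (k < 1) stop("need at least one center", call. = FALSE)
  edges <- matrix(integer(0), 0, 2)
  weights <- numeric(0)
  if (k > 1) {
    D <- as.matrix(stats::dist(centers))
    in_tree <- c(TRUE, rep(FALSE, k - 1))
    for (step in seq_len(k - 1)) {
      best <- NULL
      for (i in which(in_tree)) {
        for (j in which(!in_tree)) {
          e <- c(min(i, j), max(i, j))
          w <- D[i, j]
          if (is.null(best) || w < best$w - 1e-15 ||
              (abs(w - best$w) <= 1e-15 &&
               (e[1] < best$e[1] || (e[1] == best$e[1] && e[2] < best$e[2])))) {
            best <- list(e = e, w = w, add = j)
          }
        }
      }
      edges <- rbind(edges, best$e)
      weights <- c(weights, best$w)
      in_tree[best$add] <- TRUE
    }
  }
  rownames(edges) <- NULL
  structure(list(centers = centers, edges = edges, weights = weights,
                 start_cluster = NA_integer_),
            class = "cluster_graph")
}

#' Choose the trajectory's start cluster
#'
#' Assigns every sample to its maximum-responsibility cluster and returns the
#' cluster with the minimum mean training age (ties broken by smaller index),
#' so that pseudotime increases with age.
#'
#' @param gmm A `gmm_model`.
#' @param coords Training coordinates (samples x dimensions).
#' @param ages Training ages.
#' @return Integer cluster index.
#' @export
choose_start_cluster <- function(gmm, coords, ages) {
  resp <- gmm_responsibilities(gmm, coords)
  assign <- max.col(resp, ties.method = "first")
  mean_age <- vapply(seq_len(gmm$k), function(j) {
    if (any(assign == j)) mean(ages[assign == j]) else Inf
  }, numeric(1))
  which.min(mean_age)  # which.min already prefers the smaller index on ties
}

#' Order cluster centers along the single lineage
#'
#' Walks the spanning tree from the start cluster to the opposite end.  The
#' tree must be a simple path with the start at an endpoint; anything else is
#' a branching (multi-lineage) topology, which this package deliberately does
#' not model, and raises an error.
#'
#' @param graph A `cluster_graph` with `start_cluster` set.
#' @return Integer vector of cluster indices from start to end.
#' @export
initial_path <- function(graph) {
  stopifnot(inherits(graph, "cluster_graph"))
  k <- nrow(graph$centers)
  start <- graph$start_cluster
  if (is.na(start)) stop("`start_cluster` is not set", call. = FALSE)
  if (k == 1L) return(1L)
  deg <- tabulate(as.integer(graph$edges), nbins = k)
  if (any(deg >= 3L) || deg[start] > 1L) {
    stop("unsupported topology: the cluster tree branches; only single-lineage trajectories are modelled",
         call. = FALSE)
  }
  adj <- lapply(seq_len(k), function(i) {
    c(graph$edges[graph$edges[, 1] == i, 2], graph$edges[graph$edges[, 2] == i, 1])
  })
  path <- start
  prev <- 0L
  while (TRUE) {
    nxt <- setdiff(adj[[path[length(path)]]], prev)
    if (!length(nxt)) break
    prev <- path[length(path)]
    path <- c(path, nxt[1])
  }
  as.integer(path)
}

# orthogonal projection of points onto a polyline: per-point arc-length
# position and squared distance; ties resolved toward the smaller segment
project_polyline <- function(P, coords) {
  n <- nrow(coords)
  m <- nrow(P) - 1L
  seg <- P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE]
  len2 <- rowSums(seg^2)
  cum <- c(0, cumsum(sqrt(len2)))
  best_d2 <- rep(Inf, n)
  best_arc <- numeric(n)
  for (j in seq_len(m)) {
    if (len2[j] == 0) next
    dp <- sweep(coords, 2, P[j, ])
    t <- pmin(pmax(as.numeric(dp %*% seg[j, ]) / len2[j], 0), 1)
    proj_d2 <- rowSums((dp - outer(t, seg[j, ]))^2)
    take <- proj_d2 < best_d2 - 1e-15
    best_d2[take] <- proj_d2[take]
    best_arc[take] <- cum[j] + t[take] * sqrt(len2[j])
  }
  list(lambda = best_arc, dist2 = best_d2, total_length = cum[length(cum)])
}

# locally-weighted linear smoother of each coordinate against arc position;
# local-linear (lowess, iter = 0) rather than a plain running mean so that
# exactly collinear data reproduce their line including the endpoints
smooth_against_arc <- function(lambda, coords, span) {
  ord <- order(lambda)
  sm <- coords
  for (d in seq_len(ncol(coords))) {
    fit <- stats::lowess(lambda[ord], coords[ord, d], f = span, iter = 0)
    sm[ord, d] <- fit$y
  }
  sm[ord, , drop = FALSE]
}

rediscretize <- function(points, n_control) {
  keep <- c(TRUE, rowSums((points[-1, , drop = FALSE] -
                           points[-nrow(points), , drop = FALSE])^2) > 0)
  points <- points[keep, , drop = FALSE]
  if (nrow(points) < 2L) return(points)
  d <- sqrt(rowSums((points[-1, , drop = FALSE] -
                     points[-nrow(points), , drop = FALSE])^2))
  cum <- c(0, cumsum(d))
  s <- seq(0, cum[length(cum)], length.out = n_control)
  out <- vapply(seq_len(ncol(points)), function(j) {
    stats::approx(cum, points[, j], xout = s, ties = "ordered")$y
  }, numeric(n_control))
  out <- matrix(out, n_control)
  out[c(TRUE, rowSums((out[-1, , drop = FALSE] -
                       out[-n_control, , drop = FALSE])^2) > 0), , drop = FALSE]
}

make_principal_curve <- function(P, msd_trace, converged, n_iterations) {
  d <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  structure(list(control_points = P, cumulative_arc_length = c(0, cumsum(d)),
                 total_length = sum(d), msd_trace = msd_trace,
                 converged = converged, n_iterations = n_iterations),
            class = "principal_curve_path")
}

#' Fit a principal curve through embedded samples
#'
#' Project-then-smooth iteration: samples are projected orthogonally onto the
#' current polyline, ordered by arc-length position, each coordinate is
#' smoothed against that position with a local-linear smoother (span 0.3),
#' and the smoothed sequence is re-discretized into equally spaced control
#' points.  Iteration stops when the mean squared projection distance changes
#' by less than `tol` (relative) or after `max_iter` rounds; `max_iter = 0`
#' returns the initial path unchanged.
#'
#' @param coords Samples x dimensions matrix (>= 2 distinct points).
#' @param path_centers Ordered cluster centers initializing the polyline; a
#'   single center falls back to the data's principal axis through it.
#' @param max_iter Maximum project/smooth rounds (default 50).
#' @param tol Relative convergence tolerance on mean squared projection
#'   distance (default 1e-6).
#' @param span Smoother span fraction (default 0.3).
#' @param n_control Number of control points after re-discretization
#'   (default 100).
#' @return An object of class `principal_curve_path`: `control_points`,
#'   `cumulative_arc_length`, `total_length`, `msd_trace` (per-iteration mean
#'   squared projection distance, iteration 0 first), `converged`.
#' @export
fit_principal_curve <- function(coords, path_centers, max_iter = 50L,
                                tol = 1e-6, span = 0.3, n_control = 100L) {
  coords <- as.matrix(coords)
  if (nrow(unique(coords)) < 2L) {
    stop("all coordinates are identical; no curve can be fitted", call. = FALSE)
  }
  P <- as.matrix(path_centers)
  if (nrow(P) < 2L) {
    # single cluster: seed with the principal axis of the point cloud
    ctr <- colMeans(coords)
    dir <- eigen(stats::cov(coords), symmetric = TRUE)$vectors[, 1]
    proj <- as.numeric(sweep(coords, 2, ctr) %*% dir)
    P <- rbind(ctr + min(proj) * dir, ctr + max(proj) * dir)
  }
  pr <- project_polyline(P, coords)
  msd_trace <- mean(pr$dist2)
  if (max_iter >= 1L) {
    for (it in seq_len(max_iter)) {
      sm <- smooth_against_arc(pr$lambda, coords, span)
      P_new <- rediscretize(sm, n_control)
      if (nrow(P_new) < 2L) break
      P <- P_new
      pr <- project_polyline(P, coords)
      msd_trace <- c(msd_trace, mean(pr$dist2))
      prev <- msd_trace[length(msd_trace) - 1]
      if (abs(prev - mean(pr$dist2)) < tol * max(prev, 1e-12)) break
    }
  }
  converged <- length(msd_trace) > 1 &&
    abs(diff(utils::tail(msd_trace, 2))) <
      tol * max(msd_trace[length(msd_trace) - 1], 1e-12)
  make_principal_curve(P, msd_trace, converged, length(msd_trace) - 1L)
}

#' Assign arc-length pseudotime along a curve
#'
#' Pseudotime is the arc length from the curve's start to the orthogonal
#' projection of the sample onto the polyline (nearest segment by Euclidean
#' distance, ties to the smaller segment index).  Points beyond the
#' endpoints are clamped to `[0, total_length]`.
#'
#' @param curve A `principal_curve_path`.
#' @param coords Samples x dimensions matrix.
#' @return Numeric vector of pseudotime values in `[0, total_length]`.
#' @export
assign_pseudotime <- function(curve, coords) {
  stopifnot(inherits(curve, "principal_curve_path"))
  project_polyline(curve$control_points, as.matrix(coords))$lambda
}

#' Fit a full single-lineage trajectory model
#'
#' Composes the trajectory stages on training data already restricted to the
#' selected sites and normalized: principal-component embedding, BIC-selected
#' Gaussian mixture clustering, minimum spanning tree over cluster centers,
#' start-cluster choice by minimum mean age, and principal-curve smoothing
#' with arc-length pseudotime.
#'
#' @param train A [methylation_dataset()] (selected sites, normalized).
#' @param n_components Embedding dimensions (default 2).
#' @param k_range,families Passed to [select_gmm()].
#' @param seed Integer seed for clustering initialization.
#' @param ... Passed on to [fit_principal_curve()].
#' @return An object of class `trajectory_model`: `embedding`, `gmm`,
#'   `graph`, `curve`, and `pseudotime` (training assignment).
#' @export
fit_trajectory <- function(train, n_components = 2, k_range = 1:5,
                           families = gmm_families(), seed = 0L, ...) {
  stopifnot(inherits(train, "methylation_dataset"))
  embedding <- fit_embedding(train$betas, n_components, ages = train$ages)
  coords <- predict(embedding, train$betas)
  gmm <- select_gmm(coords, k_range = k_range, families = families, seed = seed)
  graph <- minimum_spanning_tree(gmm$means)
  graph$start_cluster <- choose_start_cluster(gmm, coords, train$ages)
  path <- initial_path(graph)
  curve <- fit_principal_curve(coords, gmm$means[path, , drop = FALSE], ...)
  pt <- assign_pseudotime(curve, coords)
  # orient the curve so pseudotime increases with age
  if (stats::sd(train$ages) > 0 && stats::cor(pt, train$ages) < 0) {
    curve <- make_principal_curve(curve$control_points[nrow(curve$control_points):1, , drop = FALSE],
                                  curve$msd_trace, curve$converged, curve$n_iterations)
    pt <- assign_pseudotime(curve, coords)
  }
  structure(list(embedding = embedding, gmm = gmm, graph = graph,
                 curve = curve, pseudotime = stats::setNames(pt, train$sample_ids)),
            class = "trajectory_model")
}

#' Predict pseudotime for new samples
#'
#' Projects samples onto the training embedding and assigns arc-length
#' pseudotime along the fitted curve; no component is refitted.  Input must
#' be restricted to the model's selected sites and normalized with the
#' training reference.
#'
#' @param model A `trajectory_model`.
#' @param dataset A [methylation_dataset()] or sites x samples matrix
#'   covering the model's probes.
#' @return Named numeric vector of pseudotime values.
#' @export
predict_pseudotime <- function(model, dataset) {
  stopifnot(inherits(model, "trajectory_model"))
  ids <- if (inherits(dataset, "methylation_dataset")) dataset$sample_ids else colnames(dataset)
  coords <- predict(model$embedding, dataset)
  stats::setNames(assign_pseudotime(model$curve, coords), ids)
}

#' @export
print.trajectory_model <- function(x, ...) {
  cat(sprintf("<trajectory_model> %d sites -> %d PCs, k = %d (%s), curve length %.3f (%d control points)\n",
              length(x$embedding$training_mean), x$embedding$n_components,
              x$gmm$k, x$gmm$family, x$curve$total_length,
              nrow(x$curve$control_points)))
  invisible(x)
}
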