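#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis.  Either a simulation
#' config or paths to a cohort written by [write_cohort()] must be supplied.
#'
#' @param simulation Optional [sim_config()]; when given, the cohort is
#'   simulated.
#' @param input_dir Optional directory with `betas.tsv`, `metadata.tsv`,
#'   `probes.tsv` (ignored when `simulation` is given).
#' @param pcc_threshold Site-selection threshold on |PCC| (default 0.4,
#'   blood-like; 0.7 is brain-like).
#' @param n_components Embedding dimensions (default 2).
#' @param k_range,families Mixture-model search space.
#' @param curve_tol,curve_max_iter,curve_span Principal-curve controls.
#' @param epm_tol,epm_max_iter,epm_n_folds Epigenetic Pacemaker controls.
#' @param trend_forms Forms passed to [compare_forms()].
#' @param seed Global seed; all stage seeds derive from it.
#' @param out_dir Output directory for serialized stage results (optional).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, input_dir = NULL,
                            pcc_threshold = 0.4, n_components = 2,
                            k_range = 1:5, families = gmm_families(),
                            curve_tol = 1e-6, curve_max_iter = 50L,
                            curve_span = 0.3,
                            epm_tol = 1e-6, epm_max_iter = 100L,
                            epm_n_folds = 5L,
                            trend_forms = c("quadratic", "logarithmic",
                                            "square_root", "exponential",
                                            "double_exponential"),
                            seed = 1L, out_dir = NULL) {
  if (is.null(simulation) && is.null(input_dir)) {
    stop("either `simulation` or `input_dir` must be supplied", call. = FALSE)
  }
  stopifnot_scalar_number(pcc_threshold, "pcc_threshold", 0, 1)
  for (v in c(curve_tol, epm_tol)) stopifnot_scalar_number(v, "tolerance", lower = 0)
  structure(list(simulation = simulation, input_dir = input_dir,
                 pcc_threshold = pcc_threshold, n_components = n_components,
                 k_range = k_range, families = families,
                 curve_tol = curve_tol, curve_max_iter = curve_max_iter,
                 curve_span = curve_span, epm_tol = epm_tol,
                 epm_max_iter = epm_max_iter, epm_n_folds = epm_n_folds,
                 trend_forms = trend_forms, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

r_squared_rmse <- function(observed, predicted) {
  tss <- sum((observed - mean(observed))^2)
  rss <- sum((observed - predicted)^2)
  list(r_squared = if (tss > 0) 1 - rss / tss else 0,
       rmse = sqrt(rss / length(observed)))
}

#' Trajectory fit metrics on train and validation splits
#'
#' R-squared and RMSE of the model's predicted pseudotime against the
#' pseudotime assigned during curve fitting (train) and against the
#' projection-based assignment (validation).
#'
#' @param model A `trajectory_model`.
#' @param train,validation [methylation_dataset()]s restricted to the model
#'   sites and normalized with the training reference.
#' @return List with `train` and `validation`, each `(r_squared, rmse)`.
#' @export
validate_trajectory <- function(model, train, validation) {
  pred_train <- predict_pseudotime(model, train)
  coords_val <- predict(model$embedding, validation)
  assigned_val <- assign_pseudotime(model$curve, coords_val)
  pred_val <- predict_pseudotime(model, validation)
  list(train = r_squared_rmse(model$pseudotime, pred_train),
       validation = r_squared_rmse(assigned_val, pred_val))
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

write_pseudotime_tsv <- function(path, ids, pt, split, seed) {
  df <- data.frame(sample_id = ids, pseudotime = format_num(pt),
                   split = split, stringsAsFactors = FALSE)
  con <- file(path, "w")
  writeLines(sprintf("# seed: %d", seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
}

#' Run the full pseudotime + Epigenetic Pacemaker pipeline
#'
#' Simulate (or load) a cohort, quantile-normalize all splits against the
#' training reference, select age-associated sites on the training split,
#' fit the trajectory, assign/predict pseudotime for all splits, fit the
#' Epigenetic Pacemaker at the same sites, correlate test pseudotime with
#' predicted epigenetic state, and compare trend forms of age.  Reruns with
#' the same config are bit-identical (timings are kept only in the returned
#' object, never serialized).
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list: selection summary, trajectory metrics,
#'   pseudotime per split, EPM fit and cross-validation diagnostics,
#'   pseudotime-state correlation, trend table, doubling times, timings.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  cohort <- pipeline_stage("load", {
    if (!is.null(config$simulation)) {
      simulate_cohort(config$simulation)
    } else {
      read_cohort(config$input_dir)
    }
  })
  timings["load"] <- tic() - t0; t0 <- tic()

  norm <- pipeline_stage("normalize", {
    ref <- build_reference(cohort$train)
    list(ref = ref,
         train = quantile_normalize(cohort$train, ref),
         validation = quantile_normalize(cohort$validation, ref),
         test = quantile_normalize(cohort$test, ref))
  })
  timings["normalize"] <- tic() - t0; t0 <- tic()

  selection <- pipeline_stage("select_sites", {
    pcc <- site_age_correlation(norm$train)
    sel <- select_sites(pcc, config$pcc_threshold)
    if (length(sel$probe_ids) < config$n_components) {
      stop("too few sites pass |PCC| > ", config$pcc_threshold)
    }
    sel
  })
  timings["select_sites"] <- tic() - t0; t0 <- tic()

  sel_train <- subset_dataset(norm$train, sites = selection$probe_ids)
  sel_val <- subset_dataset(norm$validation, sites = selection$probe_ids)
  sel_test <- subset_dataset(norm$test, sites = selection$probe_ids)

  model <- pipeline_stage("trajectory", {
    fit_trajectory(sel_train, n_components = config$n_components,
                   k_range = config$k_range, families = config$families,
                   seed = derive_seed(config$seed, 1),
                   max_iter = config$curve_max_iter, tol = config$curve_tol,
                   span = config$curve_span)
  })
  timings["trajectory"] <- tic() - t0; t0 <- tic()

  pseudotime <- pipeline_stage("pseudotime", {
    list(train = model$pseudotime,
         validation = predict_pseudotime(model, sel_val),
         test = predict_pseudotime(model, sel_test))
  })
  traj_metrics <- validate_trajectory(model, sel_train, sel_val)
  timings["pseudotime"] <- tic() - t0; t0 <- tic()

  epm <- pipeline_stage("epm", {
    fit <- epm_fit(sel_train, tol = config$epm_tol,
                   max_iter = config$epm_max_iter)
    cv <- epm_cross_validate(sel_train, n_folds = config$epm_n_folds,
                             seed = derive_seed(config$seed, 2),
                             tol = config$epm_tol,
                             max_iter = config$epm_max_iter)
    list(fit = fit, cv = cv,
         test_states = epm_predict(fit, sel_test),
         validation_states = epm_predict(fit, sel_val))
  })
  timings["epm"] <- tic() - t0; t0 <- tic()

  correlation <- pipeline_stage("correlation", {
    pearson_with_p(pseudotime$test, epm$test_states)
  })

  trends <- pipeline_stage("trends", {
    tab <- compare_forms(sel_test$ages, pseudotime$test,
                         forms = config$trend_forms)
    fits <- attr(tab, "fits")
    dt <- list()
    if (!is.null(fits$exponential)) {
      dt$exponential_b <- doubling_time(fits$exponential$coefficients[["b"]])
    }
    if (!is.null(fits$double_exponential)) {
      cf <- fits$double_exponential$coefficients
      if (cf[["b"]] > 0) dt$double_exponential_b <- doubling_time(cf[["b"]])
      if (cf[["d"]] > 0) dt$double_exponential_d <- doubling_time(cf[["d"]])
    }
    list(table = tab, doubling_times = dt)
  })
  timings["trends"] <- tic() - t0

  report <- structure(
    list(seed = config$seed,
         n_sites_selected = length(selection$probe_ids),
         pcc_threshold = config$pcc_threshold,
         gmm = list(k = model$gmm$k, family = model$gmm$family),
         trajectory_metrics = traj_metrics,
         pseudotime = pseudotime,
         epm_rss = epm$fit$rss,
         pseudotime_state_pcc = correlation,
         trend_table = trends$table,
         doubling_times = trends$doubling_times,
         truth = cohort$truth,
         model = model, epm = epm, selection = selection,
         timings = timings),
    class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    pipeline_stage("serialize", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      write_cohort(cohort, file.path(config$out_dir, "cohort"))
      sel_df <- data.frame(probe_id = selection$probe_ids,
                           pcc = format_num(selection$pcc),
                           stringsAsFactors = FALSE)
      utils::write.table(sel_df, file.path(config$out_dir, "site_selection.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_trajectory_model(model, file.path(config$out_dir, "trajectory"))
      all_ids <- c(names(pseudotime$train), names(pseudotime$validation),
                   names(pseudotime$test))
      write_pseudotime_tsv(
        file.path(config$out_dir, "pseudotime.tsv"), all_ids,
        c(pseudotime$train, pseudotime$validation, pseudotime$test),
        rep(c("train", "validation", "test"),
            lengths(pseudotime[c("train", "validation", "test")])),
        config$seed)
      epm_df <- data.frame(probe_id = epm$fit$site_ids,
                           intercept = format_num(epm$fit$intercepts),
                           rate = format_num(epm$fit$rates),
                           stringsAsFactors = FALSE)
      utils::write.table(epm_df, file.path(config$out_dir, "epm_sites.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      st_df <- data.frame(sample_id = names(epm$test_states),
                          state = format_num(epm$test_states),
                          stringsAsFactors = FALSE)
      utils::write.table(st_df, file.path(config$out_dir, "epm_test_states.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(form = trends$table$form,
                   coefficients = trends$table$coefficients,
                   aic = format_num(trends$table$aic),
                   rmse = format_num(trends$table$rmse),
                   r_squared = format_num(trends$table$r_squared),
                   stringsAsFactors = FALSE),
        file.path(config$out_dir, "trend_table.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      write_report_text(report, file.path(config$out_dir, "report.txt"))
    })
  }
  report
}

write_report_text <- function(report, path) {
  lines <- c(
    sprintf("seed: %d", report$seed),
    sprintf("pcc_threshold: %s", format_num(report$pcc_threshold)),
    sprintf("n_sites_selected: %d", report$n_sites_selected),
    sprintf("gmm: k = %d, family = %s", report$gmm$k, report$gmm$family),
    sprintf("trajectory train R2/RMSE: %s / %s",
            format_num(report$trajectory_metrics$train$r_squared),
            format_num(report$trajectory_metrics$train$rmse)),
    sprintf("trajectory validation R2/RMSE: %s / %s",
            format_num(report$trajectory_metrics$validation$r_squared),
            format_num(report$trajectory_metrics$validation$rmse)),
    sprintf("epm RSS: %s", format_num(report$epm_rss)),
    sprintf("pseudotime-state PCC: %s (p %s)",
            format_num(report$pseudotime_state_pcc$r),
            report$pseudotime_state_pcc$p_label),
    sprintf("trend winner: %s", attr(report$trend_table, "winner")),
    vapply(names(report$doubling_times), function(nm) {
      sprintf("doubling time (%s): %s years", nm,
              format_num(report$doubling_times[[nm]]))
    }, character(1)))
  writeLines(lines, path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> seed %d | %d sites selected | k = %d (%s)\n",
              x$seed, x$n_sites_selected, x$gmm$k, x$gmm$family))
  cat(sprintf("  trajectory R2 (train/validation): %.4f / %.4f\n",
              x$trajectory_metrics$train$r_squared,
              x$trajectory_metrics$validation$r_squared))
  cat(sprintf("  test pseudotime vs EPM state: r = %.4f (p %s)\n",
              x$pseudotime_state_pcc$r, x$pseudotime_state_pcc$p_label))
  cat(sprintf("  trend winner by AIC: %s\n", attr(x$trend_table, "winner")))
  for (nm in names(x$doubling_times)) {
    cat(sprintf("  doubling time (%s): %.2f years\n", nm, x$doubling_times[[nm]]))
  }
  invisible(x)
}

## ---- trajectory model serialization ---------------------------------------

#' Serialize a trajectory model to a directory of TSV/text files
#'
#' @param model A `trajectory_model`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_trajectory_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  emb <- model$embedding
  emb_df <- data.frame(probe_id = emb$probe_ids,
                       mean = format_num(emb$training_mean),
                       apply(emb$basis, 2, format_num),
                       stringsAsFactors = FALSE, check.names = FALSE)
  names(emb_df)[-(1:2)] <- sprintf("PC%d", seq_len(emb$n_components))
  con <- file(file.path(dir, "embedding.tsv"), "w")
  writeLines(sprintf("# explained_variance: %s",
                     paste(format_num(emb$explained_variance), collapse = ",")), con)
  utils::write.table(emb_df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  g <- model$gmm
  lines <- c(sprintf("k: %d", g$k), sprintf("family: %s", g$family),
             sprintf("loglik: %s", format_num(g$log_likelihood)),
             sprintf("weights: %s", paste(format_num(g$weights), collapse = ",")))
  for (j in seq_len(g$k)) {
    lines <- c(lines,
               sprintf("mean_%d: %s", j, paste(format_num(g$means[j, ]), collapse = ",")),
               sprintf("cov_%d: %s", j,
                       paste(format_num(as.numeric(g$covariances[[j]])), collapse = ",")))
  }
  lines <- c(lines, sprintf("start_cluster: %d", model$graph$start_cluster))
  writeLines(lines, file.path(dir, "gmm.txt"))

  cp <- data.frame(apply(model$curve$control_points, 2, format_num))
  names(cp) <- sprintf("PC%d", seq_len(ncol(model$curve$control_points)))
  utils::write.table(cp, file.path(dir, "curve.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a trajectory model written by [write_trajectory_model()]
#'
#' Restores the pieces needed for out-of-sample pseudotime prediction
#' (embedding and curve; the mixture is restored for completeness).
#'
#' @param dir Directory written by [write_trajectory_model()].
#' @return A `trajectory_model`.
#' @export
read_trajectory_model <- function(dir) {
  emb_path <- file.path(dir, "embedding.tsv")
  hdr <- readLines(emb_path, n = 1)
  ev <- as.numeric(strsplit(sub("^# explained_variance: ", "", hdr), ",")[[1]])
  emb_df <- utils::read.delim(emb_path, comment.char = "#", check.names = FALSE)
  basis <- as.matrix(emb_df[, -(1:2), drop = FALSE])
  rownames(basis) <- emb_df$probe_id
  embedding <- structure(
    list(training_mean = stats::setNames(emb_df$mean, emb_df$probe_id),
         basis = basis, explained_variance = ev, n_components = ncol(basis),
         probe_ids = emb_df$probe_id),
    class = "pca_embedding")

  gl <- readLines(file.path(dir, "gmm.txt"))
  getv <- function(key) sub(paste0("^", key, ": "), "", gl[startsWith(gl, paste0(key, ":"))])
  k <- as.integer(getv("k"))
  d <- embedding$n_components
  means <- do.call(rbind, lapply(seq_len(k), function(j) {
    as.numeric(strsplit(getv(sprintf("mean_%d", j)), ",")[[1]])
  }))
  covs <- lapply(seq_len(k), function(j) {
    matrix(as.numeric(strsplit(getv(sprintf("cov_%d", j)), ",")[[1]]), d, d)
  })
  gmm <- structure(
    list(k = k, family = getv("family"), d = d,
         weights = as.numeric(strsplit(getv("weights"), ",")[[1]]),
         means = means, covariances = covs,
         log_likelihood = as.numeric(getv("loglik")),
         n_params = gmm_n_params(k, d, getv("family"))),
    class = "gmm_model")

  cp <- as.matrix(utils::read.delim(file.path(dir, "curve.tsv")))
  curve <- make_principal_curve(cp, numeric(0), TRUE, 0L)
  graph <- minimum_spanning_tree(means)
  graph$start_cluster <- as.integer(getv("start_cluster"))
  structure(list(embedding = embedding, gmm = gmm, graph = graph,
                 curve = curve, pseudotime = NULL),
            class = "trajectory_model")
}
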