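#' Methylation dataset container
#'
#' Bundles a beta-value matrix (CpG sites in rows, samples in columns) with
#' per-sample chronological ages and per-probe Illumina design types.  Beta
#' values are methylation fractions and must lie in \[0, 1\] with no missing
#' entries.
#'
#' @param betas Numeric matrix, sites x samples, values in \[0, 1\].
#' @param ages Numeric vector of per-sample ages in years (>= 0), one per
#'   column of `betas`.
#' @param probe_types Character vector of probe design types, `"I"` or `"II"`,
#'   one per row of `betas`.
#' @param sample_ids,probe_ids Optional identifiers; default to the dimnames
#'   of `betas`.
#' @return An object of class `methylation_dataset`: a list with elements
#'   `betas`, `ages`, `sample_ids`, `probe_ids`, `probe_types`.
#' @examples
#' b <- matrix(runif(6), 2, 3, dimnames = list(c("cg1", "cg2"), c("a", "b", "c")))
#' md <- methylation_dataset(b, ages = c(1, 40, 80), probe_types = c("I", "II"))
#' md
#' @export
methylation_dataset <- function(betas, ages, probe_types,
                                sample_ids = colnames(betas),
                                probe_ids = rownames(betas)) {
  if (!is.matrix(betas) || !is.numeric(betas)) {
    stop("`betas` must be a numeric matrix (sites x samples)", call. = FALSE)
  }
  if (anyNA(betas)) stop("`betas` must not contain missing values", call. = FALSE)
  if (any(betas < 0 | betas > 1)) {
    stop("`betas` must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(ncol(betas)))
  if (is.null(probe_ids)) probe_ids <- sprintf("cg%06d", seq_len(nrow(betas)))
  if (length(ages) != ncol(betas)) {
    stop("`ages` must have one entry per sample column", call. = FALSE)
  }
  if (any(!is.finite(ages)) || any(ages < 0)) {
    stop("`ages` must be finite and >= 0", call. = FALSE)
  }
  probe_types <- as.character(probe_types)
  if (length(probe_types) != nrow(betas)) {
    stop("`probe_types` must have one entry per probe row", call. = FALSE)
  }
  if (!all(probe_types %in% c("I", "II"))) {
    stop('`probe_types` must be "I" or "II"', call. = FALSE)
  }
  dimnames(betas) <- list(probe_ids, sample_ids)
  structure(
    list(betas = betas, ages = as.numeric(ages),
         sample_ids = as.character(sample_ids),
         probe_ids = as.character(probe_ids),
         probe_types = probe_types),
    class = "methylation_dataset")
}

#' @export
print.methylation_dataset <- function(x, ...) {
  cat(sprintf("<methylation_dataset> %d sites x %d samples, ages %.1f-%.1f, %d type-I / %d type-II probes\n",
              nrow(x$betas), ncol(x$betas), min(x$ages), max(x$ages),
              sum(x$probe_types == "I"), sum(x$probe_types == "II")))
  invisible(x)
}

#' @export
dim.methylation_dataset <- function(x) dim(x$betas)

#' Subset a methylation dataset
#'
#' @param x A [methylation_dataset()].
#' @param sites Probe ids or row indices to keep (default all).
#' @param samples Sample ids or column indices to keep (default all).
#' @return A `methylation_dataset` restricted to the requested rows/columns.
#' @export
subset_dataset <- function(x, sites = NULL, samples = NULL) {
  stopifnot(inherits(x, "methylation_dataset"))
  ri <- if (is.null(sites)) seq_len(nrow(x$betas)) else sites
  ci <- if (is.null(samples)) seq_len(ncol(x$betas)) else samples
  if (is.character(ri)) {
    idx <- match(ri, x$probe_ids)
    if (anyNA(idx)) {
      stop("unknown probe ids: ", paste(utils::head(ri[is.na(idx)], 5), collapse = ", "),
           call. = FALSE)
    }
    ri <- idx
  }
  if (is.character(ci)) {
    idx <- match(ci, x$sample_ids)
    if (anyNA(idx)) {
      stop("unknown sample ids: ", paste(utils::head(ci[is.na(idx)], 5), collapse = ", "),
           call. = FALSE)
    }
    ci <- idx
  }
  methylation_dataset(x$betas[ri, ci, drop = FALSE], x$ages[ci],
                      x$probe_types[ri], x$sample_ids[ci], x$probe_ids[ri])
}

## ---- TSV serialization -----------------------------------------------------
## All numeric fields are written with 10 significant digits so a write/read
## round trip is lossless at that precision.

#' Write a simulated or loaded cohort to TSV files
#'
#' Writes four plain-text tables under `dir`: `betas.tsv` (probe_id plus one
#' column per sample), `metadata.tsv` (sample_id, age, split),
#' `probes.tsv` (probe_id, design_type) and, when a truth object is present,
#' `truth_states.tsv` / `truth_sites.tsv` with the generating latent states
#' and site parameters.
#'
#' @param cohort A list with elements `train`, `validation`, `test`
#'   (each a [methylation_dataset()]) and optionally `truth`, as returned by
#'   [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(is.list(cohort), all(c("train", "validation", "test") %in% names(cohort)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  splits <- c("train", "validation", "test")
  betas <- do.call(cbind, lapply(splits, function(s) cohort[[s]]$betas))
  ages <- unlist(lapply(splits, function(s) cohort[[s]]$ages), use.names = FALSE)
  split_lab <- rep(splits, vapply(splits, function(s) ncol(cohort[[s]]$betas), 1L))
  tr <- cohort$train

  bt <- data.frame(probe_id = tr$probe_ids,
                   apply(betas, 2, format_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(bt, file.path(dir, "betas.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  md <- data.frame(sample_id = colnames(betas), age = format_num(ages),
                   split = split_lab, stringsAsFactors = FALSE)
  utils::write.table(md, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pr <- data.frame(probe_id = tr$probe_ids, design_type = tr$probe_types,
                   stringsAsFactors = FALSE)
  utils::write.table(pr, file.path(dir, "probes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$truth)) {
    tru <- cohort$truth
    st <- data.frame(sample_id = names(tru$latent_states),
                     latent_state = format_num(tru$latent_states),
                     stringsAsFactors = FALSE)
    utils::write.table(st, file.path(dir, "truth_states.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    si <- data.frame(probe_id = tr$probe_ids,
                     intercept = format_num(tru$site_intercepts),
                     rate = format_num(tru$site_rates),
                     stringsAsFactors = FALSE)
    utils::write.table(si, file.path(dir, "truth_sites.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `betas.tsv`, `metadata.tsv`, `probes.tsv`.
#' @return A list with `train`, `validation`, `test` datasets and `truth`
#'   (NULL when no truth tables are present).
#' @export
read_cohort <- function(dir) {
  paths <- file.path(dir, c("betas.tsv", "metadata.tsv", "probes.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("cohort file(s) not found: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  bt <- utils::read.delim(paths[1], check.names = FALSE, stringsAsFactors = FALSE)
  md <- utils::read.delim(paths[2], stringsAsFactors = FALSE)
  pr <- utils::read.delim(paths[3], stringsAsFactors = FALSE)
  betas <- as.matrix(bt[, -1, drop = FALSE])
  rownames(betas) <- bt$probe_id
  md <- md[match(colnames(betas), md$sample_id), ]
  out <- list()
  for (s in c("train", "validation", "test")) {
    keep <- which(md$split == s)
    out[[s]] <- methylation_dataset(betas[, keep, drop = FALSE], md$age[keep],
                                    pr$design_type, md$sample_id[keep],
                                    pr$probe_id)
  }
  truth <- NULL
  ts_path <- file.path(dir, "truth_states.tsv")
  if (file.exists(ts_path)) {
    st <- utils::read.delim(ts_path, stringsAsFactors = FALSE)
    si <- utils::read.delim(file.path(dir, "truth_sites.tsv"), stringsAsFactors = FALSE)
    truth <- structure(
      list(latent_states = stats::setNames(st$latent_state, st$sample_id),
           site_intercepts = stats::setNames(si$intercept, si$probe_id),
           site_rates = stats::setNames(si$rate, si$probe_id),
           seed_used = NA_integer_),
      class = "synthetic_truth")
  }
  out$truth <- truth
  out
}
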