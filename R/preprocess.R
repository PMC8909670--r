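#' Per-site Pearson correlation with age
#'
#' Computes the Pearson correlation coefficient between each site's beta
#' values and sample age.  Sites with zero variance get `NA` (undefined),
#' never a number.
#'
#' @param dataset A [methylation_dataset()] with at least 3 samples and
#'   non-constant ages.
#' @return Named numeric vector of per-site PCCs in \[-1, 1\] (or `NA`).
#' @export
site_age_correlation <- function(dataset) {
  stopifnot(inherits(dataset, "methylation_dataset"))
  if (ncol(dataset$betas) < 3L) {
    stop("at least 3 samples are required for site-age correlation", call. = FALSE)
  }
  ages <- dataset$ages
  if (stats::sd(ages) == 0) stop("ages are all identical", call. = FALSE)
  x <- dataset$betas
  xc <- x - rowMeans(x)
  ac <- ages - mean(ages)
  num <- as.numeric(xc %*% ac)
  den <- sqrt(rowSums(xc^2) * sum(ac^2))
  pcc <- ifelse(den > 0, num / den, NA_real_)
  pcc[rowSums(xc^2) == 0] <- NA_real_
  stats::setNames(pmin(pmax(pcc, -1), 1), dataset$probe_ids)
}

#' Select age-associated sites by absolute correlation
#'
#' Retains sites with `|PCC| > threshold` (strict inequality); sites with
#' undefined correlation are excluded.
#'
#' @param pcc Named numeric vector of per-site correlations (may contain `NA`).
#' @param threshold Numeric in \[0, 1).
#' @return An object of class `site_selection`: list with `probe_ids`, `pcc`
#'   (for retained sites) and `threshold`.
#' @export
select_sites <- function(pcc, threshold = 0.4) {
  stopifnot_scalar_number(threshold, "threshold", 0, 1)
  if (threshold >= 1) stop("`threshold` must be < 1", call. = FALSE)
  keep <- which(!is.na(pcc) & abs(pcc) > threshold)
  ids <- names(pcc)[keep] %||% as.character(keep)
  structure(list(probe_ids = ids,
                 pcc = stats::setNames(as.numeric(pcc[keep]), ids),
                 threshold = threshold),
            class = "site_selection")
}

#' @export
print.site_selection <- function(x, ...) {
  cat(sprintf("<site_selection> %d sites with |PCC| > %g\n",
              length(x$probe_ids), x$threshold))
  invisible(x)
}

#' Build a probe-type quantile-normalization reference
#'
#' For each probe design type present in the training data, sorts each
#' sample's values at that type's probes and takes the per-rank median across
#' training samples.  The resulting reference vectors are non-decreasing by
#' construction and serve as the target distribution for
#' [quantile_normalize()].
#'
#' @param train A [methylation_dataset()] of training samples.
#' @return An object of class `norm_reference`: list with `reference`
#'   (per-type sorted numeric vectors) and `probes` (per-type probe ids).
#' @export
build_reference <- function(train) {
  stopifnot(inherits(train, "methylation_dataset"))
  if (ncol(train$betas) < 1L) stop("training data is empty", call. = FALSE)
  types <- unique(train$probe_types)
  reference <- list()
  probes <- list()
  for (tp in types) {
    rows <- which(train$probe_types == tp)
    sorted <- apply(train$betas[rows, , drop = FALSE], 2, sort)
    sorted <- matrix(sorted, nrow = length(rows))
    reference[[tp]] <- apply(sorted, 1, stats::median)
    probes[[tp]] <- train$probe_ids[rows]
  }
  structure(list(reference = reference, probes = probes),
            class = "norm_reference")
}

# map one sample's values at a probe type onto the reference distribution:
# value of rank k goes to the reference quantile at the matching position
# (linear interpolation when lengths differ); tied values receive the mean of
# the reference values at the ranks they jointly occupy.
qnorm_vector <- function(x, ref) {
  m <- length(x); L <- length(ref)
  if (m == 1L) return(stats::median(ref))
  pos_of_rank <- function(k) 1 + (k - 1) * (L - 1) / (m - 1)
  ref_at <- function(pos) {
    lo <- floor(pos); hi <- ceiling(pos)
    w <- pos - lo
    (1 - w) * ref[lo] + w * ref[hi]
  }
  ord <- order(x)
  xs <- x[ord]
  mapped <- ref_at(pos_of_rank(seq_len(m)))
  # average over tie groups so the map is deterministic and ties stay tied
  grp <- cumsum(c(TRUE, diff(xs) != 0))
  mapped <- stats::ave(mapped, grp)
  out <- numeric(m)
  out[ord] <- mapped
  out
}

#' Quantile normalize a dataset against a training reference
#'
#' Within each sample and probe design type, replaces the value of rank k by
#' the reference value at the matching quantile.  Within a probe type the
#' output multiset equals the reference multiset (up to ties and length
#' interpolation), so rank order within a sample is preserved.
#'
#' @param dataset A [methylation_dataset()].
#' @param reference A `norm_reference` from [build_reference()].
#' @return A [methylation_dataset()] with normalized betas.
#' @export
quantile_normalize <- function(dataset, reference) {
  stopifnot(inherits(dataset, "methylation_dataset"),
            inherits(reference, "norm_reference"))
  missing_types <- setdiff(unique(dataset$probe_types), names(reference$reference))
  if (length(missing_types)) {
    stop("probe type(s) absent from reference: ",
         paste(missing_types, collapse = ", "), call. = FALSE)
  }
  out <- dataset$betas
  for (tp in unique(dataset$probe_types)) {
    rows <- which(dataset$probe_types == tp)
    ref <- reference$reference[[tp]]
    for (j in seq_len(ncol(out))) {
      out[rows, j] <- qnorm_vector(dataset$betas[rows, j], ref)
    }
  }
  methylation_dataset(out, dataset$ages, dataset$probe_types,
                      dataset$sample_ids, dataset$probe_ids)
}
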