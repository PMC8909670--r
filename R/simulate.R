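#' Simulation configuration for synthetic methylation cohorts
#'
#' Describes the generative world for a synthetic 450k-style cohort: sample
#' ages, a latent epigenetic state following a sum-of-two-exponentials trend
#' of age, and per-site linear responses to that state
#' (`beta_ij = m_i0 + r_i * s_j + noise`), clipped to the beta scale.
#'
#' Defaults describe a blood-like cohort: ages uniform on 0-99, latent trend
#' coefficients from the whole-blood double-exponential fit
#' (a = 14.487, b = 0.019, c = 0.307, d = 0.105), 2000 sites of which half
#' respond to the latent state, beta-scale noise sd 0.02, and a 0.3/0.1/0.6
#' train/validation/test split stratified by age.
#'
#' @param n_samples Number of samples (>= 2).
#' @param age_range Length-2 numeric, minimum and maximum age in years.
#' @param age_distribution `"uniform"` or `"right-skewed"` (adult-heavy).
#' @param n_sites Number of CpG sites (>= 2).
#' @param frac_age_associated Fraction of sites responding to the latent state.
#' @param latent_form_params Named or positional numeric `(a, b, c, d)` of the
#'   latent trend `a * (1 + c - exp(-b x) - c exp(-d x))`; requires
#'   `a, b, d > 0` and a non-negative trend over `age_range`.
#' @param site_intercept_range Admissible interval for baseline methylation
#'   `m_i0` (beta units).
#' @param site_rate_range Interval for the magnitude of per-site rates `r_i`
#'   (beta units per state unit); signs are drawn symmetrically.
#' @param noise_sd Gaussian beta-scale noise sd (>= 0).
#' @param state_noise_sd Gaussian noise sd added to the latent state itself
#'   (default 0: inter-individual variation enters through `noise_sd`).
#' @param probe_type_fraction Fraction of probes labelled design type II.
#' @param split_fractions Named numeric `(train, validation, test)` summing
#'   to 1.
#' @param seed Integer RNG seed; identical configs produce identical cohorts.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 1500,
                       age_range = c(0, 99),
                       age_distribution = c("uniform", "right-skewed"),
                       n_sites = 2000,
                       frac_age_associated = 0.5,
                       latent_form_params = c(a = 14.487, b = 0.019,
                                              c = 0.307, d = 0.105),
                       site_intercept_range = c(0.05, 0.95),
                       site_rate_range = c(0.015, 0.04),
                       noise_sd = 0.02,
                       state_noise_sd = 0,
                       probe_type_fraction = 0.5,
                       split_fractions = c(train = 0.3, validation = 0.1,
                                           test = 0.6),
                       seed = 1L) {
  age_distribution <- match.arg(age_distribution)
  stopifnot_scalar_number(n_samples, "n_samples", lower = 2)
  stopifnot_scalar_number(n_sites, "n_sites", lower = 2)
  stopifnot_scalar_number(frac_age_associated, "frac_age_associated", 0, 1)
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 0)
  stopifnot_scalar_number(state_noise_sd, "state_noise_sd", lower = 0)
  stopifnot_scalar_number(probe_type_fraction, "probe_type_fraction", 0, 1)
  if (length(age_range) != 2L || age_range[1] < 0 || diff(age_range) <= 0) {
    stop("`age_range` must be an increasing pair of non-negative ages", call. = FALSE)
  }
  p <- as.numeric(latent_form_params)
  if (length(p) != 4L) stop("`latent_form_params` must be (a, b, c, d)", call. = FALSE)
  names(p) <- c("a", "b", "c", "d")
  if (p["a"] <= 0 || p["b"] <= 0 || p["d"] <= 0) {
    stop("latent_form_params require a > 0, b > 0, d > 0", call. = FALSE)
  }
  grid <- seq(age_range[1], age_range[2], length.out = 512)
  if (any(double_exponential_value(grid, p["a"], p["b"], p["c"], p["d"]) < -1e-9)) {
    stop("latent trend is negative somewhere over `age_range`", call. = FALSE)
  }
  if (length(site_intercept_range) != 2L || diff(site_intercept_range) < 0 ||
      site_intercept_range[1] < 0 || site_intercept_range[2] > 1) {
    stop("`site_intercept_range` must be an interval within [0, 1]", call. = FALSE)
  }
  if (length(site_rate_range) != 2L || any(site_rate_range < 0) ||
      diff(site_rate_range) < 0) {
    stop("`site_rate_range` must be a non-negative increasing interval", call. = FALSE)
  }
  sf <- as.numeric(split_fractions)
  if (length(sf) != 3L || any(sf < 0) || abs(sum(sf) - 1) > 1e-8) {
    stop("`split_fractions` must be 3 non-negative fractions summing to 1", call. = FALSE)
  }
  structure(
    list(n_samples = as.integer(n_samples), age_range = as.numeric(age_range),
         age_distribution = age_distribution, n_sites = as.integer(n_sites),
         frac_age_associated = frac_age_associated, latent_form_params = p,
         site_intercept_range = as.numeric(site_intercept_range),
         site_rate_range = as.numeric(site_rate_range), noise_sd = noise_sd,
         state_noise_sd = state_noise_sd,
         probe_type_fraction = probe_type_fraction,
         split_fractions = stats::setNames(sf, c("train", "validation", "test")),
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate latent epigenetic states from ages
#'
#' Evaluates the sum-of-two-exponentials latent aging trend
#' `s = a * (1 + c - exp(-b * age) - c * exp(-d * age))` and adds Gaussian
#' noise.  At age 0 the noiseless state is exactly 0 for any coefficients.
#'
#' @param ages Numeric vector of ages (>= 0).
#' @param form_params Numeric `(a, b, c, d)` with `a, b, d > 0`.
#' @param state_noise_sd Gaussian noise sd (>= 0).
#' @param seed Optional integer seed; when given, output is deterministic.
#' @return Numeric vector of latent states, one per age.
#' @examples
#' simulate_states(c(0, 20, 80), c(14.487, 0.019, 0.307, 0.105))
#' @export
simulate_states <- function(ages, form_params, state_noise_sd = 0, seed = NULL) {
  if (any(!is.finite(ages)) || any(ages < 0)) {
    stop("`ages` must be finite and >= 0", call. = FALSE)
  }
  p <- as.numeric(form_params)
  if (length(p) != 4L || p[1] <= 0 || p[2] <= 0 || p[4] <= 0) {
    stop("`form_params` must be (a, b, c, d) with a, b, d > 0", call. = FALSE)
  }
  stopifnot_scalar_number(state_noise_sd, "state_noise_sd", lower = 0)
  mean_state <- double_exponential_value(ages, p[1], p[2], p[3], p[4])
  if (state_noise_sd == 0) return(mean_state)
  noise <- if (is.null(seed)) {
    stats::rnorm(length(ages), 0, state_noise_sd)
  } else {
    with_seed(seed, stats::rnorm(length(ages), 0, state_noise_sd))
  }
  mean_state + noise
}

# draw site parameters so that noiseless means stay inside [0, 1] whenever the
# configured ranges allow it; otherwise fall back to the raw intercept range
# and warn that clipping will distort the linear response.
draw_site_params <- function(config, state_lo, state_hi) {
  n <- config$n_sites
  n_assoc <- round(config$frac_age_associated * n)
  rates <- numeric(n)
  intercepts <- numeric(n)
  assoc <- rep(FALSE, n)
  if (n_assoc > 0) assoc[sample.int(n, n_assoc)] <- TRUE

  lo <- config$site_intercept_range[1]
  hi <- config$site_intercept_range[2]
  # non-responding sites: baselines away from the clip boundaries
  n_flat <- n - n_assoc
  intercepts[!assoc] <- stats::runif(n_flat, max(lo, 0.1), min(hi, 0.9))

  if (n_assoc > 0) {
    mag <- stats::runif(n_assoc, config$site_rate_range[1], config$site_rate_range[2])
    sgn <- sample(c(-1, 1), n_assoc, replace = TRUE)
    r <- sgn * mag
    span_hi <- r * state_hi
    span_lo <- r * state_lo
    m_lo <- pmax(lo, -pmin(span_lo, span_hi))
    m_hi <- pmin(hi, 1 - pmax(span_lo, span_hi))
    bad <- m_hi < m_lo
    if (any(bad)) {
      warning(sprintf(
        "%d site(s) cannot keep means inside [0, 1] at state extremes; values will be clipped",
        sum(bad)), call. = FALSE)
      m_lo[bad] <- lo
      m_hi[bad] <- hi
    }
    intercepts[assoc] <- stats::runif(n_assoc, m_lo, m_hi)
    rates[assoc] <- r
  }
  list(intercepts = intercepts, rates = rates)
}

simulate_betas_impl <- function(states, config, site_params = NULL) {
  n_samples <- length(states)
  if (is.null(site_params)) {
    site_params <- draw_site_params(config, min(states), max(states))
  }
  m0 <- site_params$intercepts
  r <- site_params$rates
  mu <- outer(r, states) + m0
  if (any(mu < 0) || any(mu > 1)) {
    warning("noiseless site means fall outside [0, 1]; values clipped", call. = FALSE)
  }
  betas <- mu
  if (config$noise_sd > 0) {
    betas <- betas + matrix(stats::rnorm(length(mu), 0, config$noise_sd),
                            nrow(mu), ncol(mu))
  }
  betas <- pmin(pmax(betas, 0), 1)
  n_type2 <- round(config$probe_type_fraction * config$n_sites)
  probe_types <- rep("I", config$n_sites)
  if (n_type2 > 0) probe_types[sample.int(config$n_sites, n_type2)] <- "II"
  probe_ids <- sprintf("cg%06d", seq_len(config$n_sites))
  sample_ids <- names(states) %||% sprintf("S%04d", seq_len(n_samples))
  ages <- attr(states, "ages") %||% rep(0, n_samples)
  dataset <- methylation_dataset(betas, ages, probe_types, sample_ids, probe_ids)
  truth <- structure(
    list(latent_states = stats::setNames(as.numeric(states), sample_ids),
         site_intercepts = stats::setNames(m0, probe_ids),
         site_rates = stats::setNames(r, probe_ids),
         seed_used = config$seed),
    class = "synthetic_truth")
  list(dataset = dataset, truth = truth)
}

#' Simulate beta values from latent states
#'
#' For age-associated sites, `beta_ij = clip(m_i0 + r_i * s_j + e_ij, 0, 1)`
#' with Gaussian noise; the remaining sites are constant-mean plus noise
#' (rate exactly 0).  The returned truth records all generating values
#' before clipping.
#'
#' @param states Numeric vector of latent states, length `config$n_samples`.
#' @param config A [sim_config()].
#' @param site_params Optional list with `intercepts` and `rates` vectors of
#'   length `config$n_sites`, overriding the random draw (useful for
#'   parameter-recovery tests).
#' @return A list with `dataset` (a [methylation_dataset()]) and `truth`
#'   (class `synthetic_truth`).
#' @export
simulate_betas <- function(states, config, site_params = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (length(states) != config$n_samples) {
    stop("`states` must have length config$n_samples", call. = FALSE)
  }
  with_seed(config$seed, simulate_betas_impl(states, config, site_params))
}

#' Age-stratified sample split
#'
#' Orders samples by age (random tie-breaking), then walks the ordered list
#' assigning each sample to the split with the largest proportional deficit,
#' capped at largest-remainder global targets.  Every age window therefore
#' receives close-to-nominal proportions, and split sizes are exact.
#'
#' @param ages Numeric vector of ages.
#' @param fractions Numeric length-3 `(train, validation, test)` summing to 1.
#' @return Character vector of split labels, parallel to `ages`.
#' @export
stratified_age_split <- function(ages, fractions = c(0.3, 0.1, 0.6)) {
  fr <- as.numeric(fractions)
  if (length(fr) != 3L || any(fr < 0) || abs(sum(fr) - 1) > 1e-8) {
    stop("`fractions` must be 3 non-negative values summing to 1", call. = FALSE)
  }
  n <- length(ages)
  labels <- c("train", "validation", "test")
  # largest-remainder global targets
  raw <- n * fr
  target <- floor(raw)
  rem <- n - sum(target)
  if (rem > 0) {
    target[order(raw - floor(raw), decreasing = TRUE)[seq_len(rem)]] <-
      target[order(raw - floor(raw), decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  ord <- order(ages, stats::runif(n))
  counts <- c(0L, 0L, 0L)
  out <- character(n)
  for (i in seq_len(n)) {
    deficit <- fr * i - counts
    deficit[counts >= target] <- -Inf
    k <- which.max(deficit)
    counts[k] <- counts[k] + 1L
    out[ord[i]] <- labels[k]
  }
  out
}

#' Simulate a full train/validation/test methylation cohort
#'
#' Draws ages from the configured distribution, evaluates the latent aging
#' trend, simulates site-level beta values, and splits samples into
#' train/validation/test stratified by age.  The whole cohort is a
#' deterministic function of the config (including its seed).
#'
#' @param config A [sim_config()].
#' @return A list with elements `train`, `validation`, `test`
#'   (each a [methylation_dataset()]), `truth` (a `synthetic_truth` covering
#'   all samples in cohort order), and `split` (per-sample labels).
#' @examples
#' cfg <- sim_config(n_samples = 30, n_sites = 50, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' cohort$train
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    lo <- config$age_range[1]; hi <- config$age_range[2]
    ages <- if (config$age_distribution == "uniform") {
      stats::runif(n, lo, hi)
    } else {
      # adult-heavy mixture: 25% uniform across the range, 75% skewed old
      mix <- stats::runif(n) < 0.25
      a <- numeric(n)
      a[mix] <- stats::runif(sum(mix), lo, hi)
      a[!mix] <- lo + (hi - lo) * stats::rbeta(sum(!mix), 3, 1.5)
      a
    }
    p <- config$latent_form_params
    states <- double_exponential_value(ages, p["a"], p["b"], p["c"], p["d"])
    if (config$state_noise_sd > 0) {
      states <- states + stats::rnorm(n, 0, config$state_noise_sd)
    }
    names(states) <- sprintf("S%04d", seq_len(n))
    attr(states, "ages") <- ages
    sim <- simulate_betas_impl(states, config)
    split <- stratified_age_split(ages, config$split_fractions)
    out <- list()
    for (s in c("train", "validation", "test")) {
      out[[s]] <- subset_dataset(sim$dataset, samples = which(split == s))
    }
    out$truth <- sim$truth
    out$split <- split
    out
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d samples, %d sites (%d age-associated), seed %s\n",
              length(x$latent_states), length(x$site_rates),
              sum(x$site_rates != 0), format(x$seed_used)))
  invisible(x)
}
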