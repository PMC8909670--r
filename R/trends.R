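#' Functional forms of age
#'
#' Registry of the candidate trend forms relating a value (pseudotime or
#' epigenetic state) to chronological age:
#' quadratic `a + b x + c x^2`, logarithmic `a + b log(x)`,
#' square root `a + b sqrt(x)`, exponential `a (1 - exp(-b x))`,
#' the sum of two exponentials `a (1 + c - exp(-b x) - c exp(-d x))`,
#' and linear `a + b x`.  The logarithmic form is undefined at age 0, so
#' ages are floored at 0.1 years for that form only.
#'
#' @return Character vector of form names.
#' @export
trend_forms <- function() {
  c("quadratic", "logarithmic", "square_root", "exponential",
    "double_exponential", "linear")
}

trend_n_coefficients <- function(form) {
  switch(form, quadratic = 3L, logarithmic = 2L, square_root = 2L,
         exponential = 2L, double_exponential = 4L, linear = 2L,
         stop("unknown trend form: ", form, call. = FALSE))
}

LOG_AGE_FLOOR <- 0.1

#' Evaluate a trend form
#'
#' @param form One of [trend_forms()].
#' @param coefficients Numeric coefficients in the form's `(a, b, ...)` order.
#' @param x Ages (years).
#' @return Predicted values.
#' @export
evaluate_trend <- function(form, coefficients, x) {
  cf <- as.numeric(coefficients)
  switch(form,
    quadratic = cf[1] + cf[2] * x + cf[3] * x^2,
    logarithmic = cf[1] + cf[2] * log(pmax(x, LOG_AGE_FLOOR)),
    square_root = cf[1] + cf[2] * sqrt(x),
    exponential = cf[1] * (1 - exp(-cf[2] * x)),
    double_exponential = double_exponential_value(x, cf[1], cf[2], cf[3], cf[4]),
    linear = cf[1] + cf[2] * x,
    stop("unknown trend form: ", form, call. = FALSE))
}

#' Gaussian maximum-likelihood AIC for a least-squares fit
#'
#' `AIC = n log(2 pi rss / n) + n + 2 (n_coefficients + 1)`, counting the
#' error variance as a fitted parameter — the convention of the standard
#' `AIC()` applied to Gaussian least-squares models.  A perfect fit
#' (`rss = 0`) yields `-Inf` rather than an error.
#'
#' @param rss Residual sum of squares, or a `trend_fit` object.
#' @param n Number of observations.
#' @param n_coefficients Number of mean-model coefficients.
#' @return The AIC value (possibly `-Inf`).
#' @export
trend_aic <- function(rss, n = NULL, n_coefficients = NULL) {
  if (inherits(rss, "trend_fit")) {
    n <- rss$n; n_coefficients <- length(rss$coefficients); rss <- rss$rss
  }
  if (rss <= 0) return(-Inf)
  n * log(2 * pi * rss / n) + n + 2 * (n_coefficients + 1)
}

new_trend_fit <- function(form, coefficients, x, y, converged = TRUE) {
  fitted <- evaluate_trend(form, coefficients, x)
  rss <- sum((y - fitted)^2)
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  structure(
    list(form = form,
         coefficients = stats::setNames(as.numeric(coefficients),
                                        letters[seq_along(coefficients)]),
         rss = rss, aic = trend_aic(rss, n, length(coefficients)),
         rmse = sqrt(rss / n),
         r_squared = if (tss > 0) 1 - rss / tss else 0,
         n = n, converged = converged),
    class = "trend_fit")
}

fit_linear_form <- function(x, y, form) {
  X <- switch(form,
    quadratic = cbind(1, x, x^2),
    logarithmic = cbind(1, log(pmax(x, LOG_AGE_FLOOR))),
    square_root = cbind(1, sqrt(x)),
    linear = cbind(1, x))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("singular design for form ", form, call. = FALSE)
  new_trend_fit(form, qr.coef(qx, y), x, y)
}

# profiled RSS for the exponential form: a is linear given b
exp_profile <- function(b, x, y) {
  g <- 1 - exp(-b * x)
  g2 <- sum(g^2)
  if (g2 < 1e-300) return(list(rss = Inf, a = 0))
  a <- sum(g * y) / g2
  list(rss = sum((y - a * g)^2), a = a)
}

fit_exponential <- function(x, y, rate_grid) {
  rss_g <- vapply(rate_grid, function(b) exp_profile(b, x, y)$rss, numeric(1))
  i <- which.min(rss_g)
  lo <- if (i > 1) rate_grid[i - 1] else rate_grid[1] / 5
  hi <- if (i < length(rate_grid)) rate_grid[i + 1] else rate_grid[i] * 5
  opt <- stats::optimize(function(b) exp_profile(b, x, y)$rss,
                         interval = c(lo, hi), tol = 1e-12)
  b <- if (opt$objective <= rss_g[i]) opt$minimum else rate_grid[i]
  pr <- exp_profile(b, x, y)
  new_trend_fit("exponential", c(pr$a, b), x, y,
                converged = is.finite(pr$rss))
}

# profiled RSS for the sum of two exponentials: with u = a, v = a c the model
# is y = u (1 - exp(-b x)) + v (1 - exp(-d x)), linear in (u, v) given (b, d)
dexp_profile <- function(b, d, x, y) {
  Xm <- cbind(1 - exp(-b * x), 1 - exp(-d * x))
  if (!all(is.finite(Xm))) return(list(rss = Inf, u = 0, v = 0))
  fit <- stats::lm.fit(Xm, y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  rss <- sum(fit$residuals^2)
  if (!is.finite(rss)) rss <- Inf
  list(rss = rss, u = cf[1], v = cf[2])
}

fit_double_exponential <- function(x, y, rate_grid) {
  pairs <- expand.grid(b = rate_grid, d = rate_grid)
  pairs <- pairs[pairs$b < pairs$d, ]
  rss_g <- mapply(function(b, d) dexp_profile(b, d, x, y)$rss, pairs$b, pairs$d)
  starts <- order(rss_g)[seq_len(min(3L, length(rss_g)))]
  best <- NULL
  for (s in starts) {
    obj <- function(th) {
      th <- pmin(pmax(th, -20), 6)  # keep rates finite under NM excursions
      dexp_profile(exp(th[1]), exp(th[2]), x, y)$rss
    }
    opt <- stats::optim(log(c(pairs$b[s], pairs$d[s])), obj,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  par <- pmin(pmax(best$par, -20), 6)
  b <- exp(par[1]); d <- exp(par[2])
  pr <- dexp_profile(b, d, x, y)
  # resolve the label-swap symmetry: report b <= d
  u <- pr$u; v <- pr$v
  if (b > d) { tmp <- b; b <- d; d <- tmp; tmp <- u; u <- v; v <- tmp }
  # degenerate amplitude: keep a representable (a, c) pair with a*c = v
  if (abs(u) < 1e-10) u <- if (u < 0) -1e-10 else 1e-10
  new_trend_fit("double_exponential", c(u, b, v / u, d), x, y,
                converged = best$convergence == 0)
}

#' Fit one functional form of age
#'
#' Quadratic, logarithmic, square-root and linear forms are solved by exact
#' linear least squares on transformed regressors.  The exponential and
#' double-exponential forms are fitted by variable projection: the amplitude
#' coefficients are profiled out in closed form and the rate parameter(s)
#' optimized from every point of a multi-start grid, keeping the minimum-RSS
#' solution.  For the double exponential the reported rates satisfy `b <= d`.
#'
#' @param x Ages in years (>= 0).
#' @param y Values (pseudotime or epigenetic state).
#' @param form One of [trend_forms()].
#' @param rate_grid Multi-start grid for nonlinear rate parameters.
#' @return An object of class `trend_fit` with `coefficients`, `rss`, `aic`,
#'   `rmse`, `r_squared`, `n`, `converged`.
#' @examples
#' x <- 0:99
#' fit_trend(x, 2 * sqrt(x), "square_root")
#' @export
fit_trend <- function(x, y, form,
                      rate_grid = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1, 2)) {
  form <- match.arg(form, trend_forms())
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (any(x < 0)) stop("ages must be >= 0", call. = FALSE)
  if (length(y) <= trend_n_coefficients(form)) {
    stop("need more observations than coefficients", call. = FALSE)
  }
  switch(form,
    exponential = fit_exponential(x, y, rate_grid),
    double_exponential = fit_double_exponential(x, y, rate_grid),
    fit_linear_form(x, y, form))
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s: %s | AIC %.2f, RMSE %.4f, R2 %.4f%s\n",
              x$form,
              paste(sprintf("%s = %.4g", names(x$coefficients), x$coefficients),
                    collapse = ", "),
              x$aic, x$rmse, x$r_squared,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Fit and rank all candidate forms of age
#'
#' Fits each requested form and returns a table sorted by AIC (ascending);
#' the first row is the winner.  Individual non-convergence is recorded
#' per row, never fatal.
#'
#' @param x Ages.
#' @param y Values.
#' @param forms Forms to fit (default: the five competitive forms, without
#'   plain linear).
#' @return A data.frame of class `trend_comparison` with columns `form`,
#'   `coefficients` (formatted), `n_coefficients`, `rss`, `aic`, `rmse`,
#'   `r_squared`, `converged`; the fitted objects are attached as
#'   `attr(, "fits")`.
#' @export
compare_forms <- function(x, y, forms = c("quadratic", "logarithmic",
                                          "square_root", "exponential",
                                          "double_exponential")) {
  if (length(y) <= 5) stop("need more than 5 observations", call. = FALSE)
  fits <- list()
  rows <- lapply(forms, function(f) {
    fit <- tryCatch(fit_trend(x, y, f), error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(form = f, coefficients = NA_character_,
                        n_coefficients = trend_n_coefficients(f),
                        rss = NA_real_, aic = NA_real_, rmse = NA_real_,
                        r_squared = NA_real_, converged = FALSE,
                        stringsAsFactors = FALSE))
    }
    fits[[f]] <<- fit
    data.frame(form = f,
               coefficients = paste(sprintf("%.4g", fit$coefficients),
                                    collapse = ", "),
               n_coefficients = length(fit$coefficients), rss = fit$rss,
               aic = fit$aic, rmse = fit$rmse, r_squared = fit$r_squared,
               converged = fit$converged, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$aic), ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  attr(tab, "winner") <- tab$form[1]
  class(tab) <- c("trend_comparison", "data.frame")
  tab
}

#' @export
print.trend_comparison <- function(x, ...) {
  cat(sprintf("Trend-form comparison (sorted by AIC; winner: %s)\n",
              attr(x, "winner") %||% "<unknown>"))
  print.data.frame(x, digits = 6)
  invisible(x)
}

#' Doubling time of an exponential rate
#'
#' `ln(2) / beta`: the time for a process growing at rate `beta` per year to
#' double, as used to compare trend rates with the Gompertz mortality
#' coefficient.
#'
#' @param beta Positive per-year rate.
#' @return Doubling time in years.
#' @examples
#' doubling_time(0.1)   # 6.93 years
#' doubling_time(0.04)  # 17.33 years
#' @export
doubling_time <- function(beta) {
  stopifnot_scalar_number(beta, "beta")
  if (beta <= 0) stop("`beta` must be > 0", call. = FALSE)
  log(2) / beta
}

#' Pearson correlation with a two-sided p-value
#'
#' Pearson r with the classical t-transform p-value on `n - 2` degrees of
#' freedom.  Values below the representable range are labelled
#' `"< 1e-300"`.
#'
#' @param a,b Numeric vectors of equal length (n >= 3), both non-constant.
#' @return List with `r`, `p` (numeric) and `p_label` (character).
#' @export
pearson_with_p <- function(a, b) {
  if (length(a) != length(b)) stop("inputs differ in length", call. = FALSE)
  n <- length(a)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("inputs must not be constant", call. = FALSE)
  }
  r <- stats::cor(a, b)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p,
       p_label = if (p < 1e-300) "< 1e-300" else format(p, digits = 4))
}
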