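# Threshold-activation population model and the analog/binary trade-off.
#
# A cell triggers a binary switch when its steady-state output y5* exceeds a
# threshold (default 10; the results are largely independent of the value as
# long as it is larger than the total noise).  The population-level observable
# is the fraction of activated cells as a function of the fold input R; its
# steepness is summarized by an apparent Hill coefficient (aHC), the inverse
# measure of the input range over which the population output can be
# controlled.

#' Specification of the binary activation model
#'
#' @param noise A [noise_spec()] for the per-cell rate multipliers.
#' @param threshold Activation threshold on the output `y5*` (default 10,
#'   above the basal output of 1).
#' @param r_grid Fold-input grid; default 30 points log-spaced over
#'   `[1, 100]`, bracketing the threshold symmetrically in log space.
#' @param n_cells Cells simulated per dose (default 5000, keeping the
#'   Monte-Carlo standard error on each fraction below ~0.7 points).
#' @return An object of class `"binary_model_spec"`.
#' @export
binary_model_spec <- function(noise, threshold = 10,
                              r_grid = exp(seq(log(1), log(100),
                                               length.out = 30L)),
                              n_cells = 5000L) {
  stopifnot(inherits(noise, "noise_spec"))
  if (threshold <= 1) stop("'threshold' must exceed the basal output of 1",
                           call. = FALSE)
  if (any(diff(r_grid) <= 0)) stop("'r_grid' must be strictly increasing",
                                   call. = FALSE)
  structure(list(noise = noise, threshold = threshold, r_grid = r_grid,
                 n_cells = as.integer(n_cells)),
            class = "binary_model_spec")
}

#' Fraction of activated cells at one dose
#'
#' Fraction of simulated cells whose steady-state output strictly exceeds the
#' threshold.  Exactly 0 or 1 when `cv = 0` and `R` differs from the
#' threshold; 0.5 up to Monte-Carlo error when `R` equals the threshold (the
#' log-output median equals the log threshold).
#'
#' @param spec A [binary_model_spec()].
#' @param R Fold-input stimulus.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_activated <- function(spec, R) {
  stopifnot(inherits(spec, "binary_model_spec"))
  pop <- simulate_population(R, spec$noise, spec$n_cells)
  mean(pop$outputs > spec$threshold)
}

#' Percent-activated dose-response curve
#'
#' Simulates [fraction_activated()] over the fold-input grid.  The curve is
#' monotone non-decreasing in `R` up to Monte-Carlo noise, and an exact step
#' at `R = threshold` when `cv = 0`.
#'
#' @param spec A [binary_model_spec()].
#' @return An object of class `"dose_response"`: data.frame with columns `R`
#'   and `fraction`, with `threshold` and `n_cells` attributes.
#' @export
dose_response <- function(spec) {
  stopifnot(inherits(spec, "binary_model_spec"))
  if (!is.null(spec$noise$seed)) set.seed(spec$noise$seed)
  noise_run <- spec$noise
  noise_run$seed <- NULL  # one stream across doses, seeded once above
  frac <- vapply(spec$r_grid, function(r) {
    pop <- simulate_population(r, noise_run, spec$n_cells)
    mean(pop$outputs > spec$threshold)
  }, numeric(1))
  structure(data.frame(R = spec$r_grid, fraction = frac),
            class = c("dose_response", "data.frame"),
            threshold = spec$threshold, n_cells = spec$n_cells)
}

#' Fit a Hill curve to a percent-activated dose-response
#'
#' Nonlinear least squares of `f(R) = R^h / (k^h + R^h)` against the observed
#' fractions, with `R` on its natural scale.  Points at exactly 0 or 1 are
#' retained (they carry steepness information).  Initial guesses: `k` at the
#' grid point nearest fraction 0.5, `h = 2`; bounds `h` in (0, 100].  If the
#' Levenberg-Marquardt fit fails to converge the coefficient is recovered by a
#' profile grid search over `h` (optimizing `k` at each candidate), which is
#' robust on near-step data.
#'
#' @param curve A `"dose_response"` or any data.frame with columns `R` and
#'   `fraction`.
#' @return An object of class `"hill_fit"`: list with `h`, `k_half`,
#'   `residual` (sum of squared residuals), and `method` (`"nls"` or
#'   `"profile"`).
#' @export
fit_hill <- function(curve) {
  d <- as.data.frame(curve)[, c("R", "fraction")]
  interior <- d$fraction > 0 & d$fraction < 1
  if (!any(interior))
    stop("step-like curve: no fractions strictly inside (0, 1); ",
         "h exceeds upper bound", call. = FALSE)
  if (sum(interior) < 4L)
    warning("fewer than 4 non-saturated points; fit may be poorly constrained")
  k0 <- d$R[which.min(abs(d$fraction - 0.5))]
  fit <- tryCatch(
    minpack.lm::nlsLM(fraction ~ R^h / (k^h + R^h), data = d,
                      start = list(h = 2, k = k0),
                      lower = c(h = 1e-6, k = min(d$R) / 10),
                      upper = c(h = 100, k = max(d$R) * 10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    res <- sum(stats::resid(fit)^2)
    return(structure(list(h = unname(cf["h"]), k_half = unname(cf["k"]),
                          residual = res, method = "nls"),
                     class = "hill_fit"))
  }
  # profile grid search fallback
  hgrid <- exp(seq(log(0.2), log(100), length.out = 400L))
  ssr_k <- function(h) {
    o <- stats::optimize(function(lk) {
      f <- d$R^h / (exp(lk * h) + d$R^h)
      sum((f - d$fraction)^2)
    }, interval = log(range(d$R)) + c(-2, 2))
    c(o$objective, exp(o$minimum))
  }
  prof <- vapply(hgrid, ssr_k, numeric(2))
  best <- which.min(prof[1L, ])
  structure(list(h = hgrid[best], k_half = prof[2L, best],
                 residual = prof[1L, best], method = "profile"),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("hill_fit: h = %.3f, k_half = %.3f (SSR %.4g, %s)\n",
              x$h, x$k_half, x$residual, x$method))
  invisible(x)
}

#' Analytic apparent Hill coefficient
#'
#' The steepness of the percent-activated curve scales inversely with the
#' total log-output noise: `aHC = beta / (cv * sqrt(N))`, diverging as the
#' noise vanishes (step response).
#'
#' @param cv Per-component coefficient of variation (must be positive).
#' @param n_components Number of independently varying components `N`.
#' @param beta Calibration constant (default 1.4).
#' @return The apparent Hill coefficient.
#' @examples
#' ahc_analytic(0.10, 10)  # 4.43
#' @export
ahc_analytic <- function(cv, n_components = 10, beta = 1.4) {
  if (any(cv <= 0))
    stop("'cv' must be positive: at cv = 0 the response is a step and the ",
         "apparent Hill coefficient is unbounded", call. = FALSE)
  beta / (cv * sqrt(n_components))
}

#' Total output CV with partially covarying components
#'
#' Standard error propagation for `N` components of which `n_cov` are
#' perfectly correlated (the rest independent): the correlated group adds
#' linearly and the rest in quadrature, giving
#' `cv * sqrt(N - n_cov + n_cov^2)`.  Reduces to `cv * sqrt(N)` at
#' `n_cov` 0 or 1 and to `cv * N` when all components covary.
#'
#' @param cv Per-component coefficient of variation.
#' @param n_components Number of components `N`.
#' @param n_cov Number of perfectly covarying components, `0 <= n_cov <= N`.
#' @return The effective total CV.
#' @export
effective_cv <- function(cv, n_components = 10, n_cov = 0) {
  if (any(n_cov < 0) || any(n_cov > n_components))
    stop("'n_cov' must be between 0 and 'n_components'", call. = FALSE)
  cv * sqrt(n_components - n_cov + n_cov^2)
}

#' Analog/binary co-dependency curve
#'
#' For each parameter combination, computes the effective total CV (via
#' [effective_cv()]), the analytic fold-input detection limit and the analytic
#' apparent Hill coefficient.  The product `log2(fIDL) * aHC` equals
#' `alpha * beta / log(2)` identically — independent of `cv`, `N` and
#' `n_cov` — expressing the hard trade-off between analog accuracy and binary
#' controllability.
#'
#' @param cv Vector of per-component CVs (all positive).
#' @param n_components Number of pathway components `N` (vectorized).
#' @param n_cov Number of covarying components (vectorized, default 0).
#' @param accuracy Detection accuracy for the fIDL (default 0.95).
#' @param beta aHC calibration constant (default 1.4).
#' @return A data.frame with columns `cv`, `n_components`, `n_cov`,
#'   `cv_total`, `fidl`, `log2_fidl`, `ahc`, `product`.
#' @export
tradeoff_curve <- function(cv, n_components = 10, n_cov = 0,
                           accuracy = 0.95, beta = 1.4) {
  if (any(cv <= 0)) stop("'cv' must be positive", call. = FALSE)
  d <- data.frame(cv = cv, n_components = n_components, n_cov = n_cov)
  d$cv_total <- effective_cv(d$cv, d$n_components, d$n_cov)
  alpha <- fidl_alpha(accuracy)
  d$fidl <- exp(alpha * d$cv_total)
  d$log2_fidl <- log2(d$fidl)
  d$ahc <- beta / d$cv_total
  d$product <- d$log2_fidl * d$ahc
  d
}
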