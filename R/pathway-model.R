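# Five-step linear signaling pathway with lognormal expression noise.
#
# The model: a receptor input R activates y1, whose active form y1* activates
# y2, and so on down to the fifth step whose active form A* (= y5*) is the
# analog output.  Each activation and deactivation rate carries a per-cell
# multiplicative factor eps_i (odd i activating, even i deactivating) drawn
# lognormally to represent cell-to-cell variation in the expression of the
# corresponding pathway component.  Inactive pools are held at 1 (active forms
# are a small fraction of the total), so the system is linear in the active
# species and its unique fixed point is available in closed form.

#' Noise specification for a simulated cell population
#'
#' Describes how the ten per-cell rate multipliers `eps_1..eps_10` are drawn.
#' Each multiplier is `exp(z * cv)` with `z` standard normal, so the standard
#' deviation of `log(eps)` equals `cv` exactly; for small `cv` this also equals
#' the coefficient of variation of `eps` to first order.
#'
#' @param cv Coefficient of variation applied per regulator (fraction, e.g.
#'   `0.10` for 10%).
#' @param mode One of `"independent"` (each regulator drawn independently),
#'   `"sign_grouped"` (all five activating regulators share one draw and all
#'   five deactivating regulators share another, the maximal-covariation case),
#'   or `"custom"` (arbitrary correlation between the `z` draws).
#' @param n_regulators Number of regulators `N` (default 10, i.e. five
#'   activation/deactivation pairs).
#' @param correlation Optional `N x N` correlation matrix (symmetric, positive
#'   semidefinite, unit diagonal); required when `mode = "custom"`.
#' @param seed Optional integer seed; when non-`NULL`, [draw_noise()] seeds the
#'   R random number generator before drawing so results are reproducible.
#'
#' @return An object of class `"noise_spec"`.
#' @seealso [draw_noise()], [simulate_population()]
#' @export
noise_spec <- function(cv, mode = c("independent", "sign_grouped", "custom"),
                       n_regulators = 10L, correlation = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(cv) || length(cv) != 1L || is.na(cv) || cv < 0)
    stop("'cv' must be a single non-negative number", call. = FALSE)
  n_regulators <- as.integer(n_regulators)
  if (n_regulators < 1L) stop("'n_regulators' must be >= 1", call. = FALSE)
  if (mode == "custom") {
    if (is.null(correlation))
      stop("custom mode requires a correlation matrix", call. = FALSE)
    check_correlation(correlation, n_regulators)
  } else if (!is.null(correlation)) {
    stop("'correlation' is only used in custom mode", call. = FALSE)
  }
  if (mode == "sign_grouped" && n_regulators %% 2L != 0L)
    stop("sign_grouped mode needs an even number of regulators", call. = FALSE)
  structure(list(cv = cv, mode = mode, n_regulators = n_regulators,
                 correlation = correlation, seed = seed),
            class = "noise_spec")
}

# PSD check with an eigenvalue tolerance; unit diagonal and symmetry exact.
check_correlation <- function(correlation, n) {
  if (!is.matrix(correlation) || nrow(correlation) != n || ncol(correlation) != n)
    stop("correlation matrix must be ", n, " x ", n, call. = FALSE)
  if (!isSymmetric(correlation, tol = 1e-12))
    stop("correlation matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(correlation) - 1) > 1e-12))
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("correlation matrix is not positive semidefinite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  invisible(TRUE)
}

#' Draw per-cell lognormal rate multipliers
#'
#' Draws an `n_cells x N` matrix of multipliers `eps = exp(z * cv)`.  In
#' `sign_grouped` mode the odd columns (activating regulators) are identical
#' within each row, as are the even columns (deactivating regulators).  In
#' `custom` mode the standard-normal vector underlying each row has the
#' correlation given in the spec (via Cholesky factorization, with a pivoted
#' fallback for semidefinite matrices).
#'
#' @param spec A [noise_spec()].
#' @param n_cells Number of rows (cells) to draw.
#' @return Numeric matrix of positive multipliers, columns `eps_1..eps_N`.
#' @examples
#' eps <- draw_noise(noise_spec(0.1, "sign_grouped", seed = 1), 4)
#' stopifnot(all(eps[, 1] == eps[, 3]))
#' @export
draw_noise <- function(spec, n_cells) {
  stopifnot(inherits(spec, "noise_spec"))
  n_cells <- as.integer(n_cells)
  if (n_cells < 1L) stop("'n_cells' must be >= 1", call. = FALSE)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_regulators
  z <- switch(spec$mode,
    independent = matrix(stats::rnorm(n_cells * n), nrow = n_cells, ncol = n),
    sign_grouped = {
      za <- stats::rnorm(n_cells)  # shared by activating (odd) regulators
      zb <- stats::rnorm(n_cells)  # shared by deactivating (even) regulators
      z <- matrix(0, n_cells, n)
      z[, seq(1L, n, by = 2L)] <- za
      z[, seq(2L, n, by = 2L)] <- zb
      z
    },
    custom = {
      l <- chol_psd(spec$correlation)
      matrix(stats::rnorm(n_cells * n), n_cells, n) %*% l
    })
  eps <- exp(z * spec$cv)
  colnames(eps) <- paste0("eps_", seq_len(n))
  eps
}

# Upper-triangular factor t(L) with correlation == t(factor) %*% factor, valid
# for semidefinite inputs (pivoted Cholesky, unpivoted afterwards).
chol_psd <- function(m) {
  r <- tryCatch(chol(m), error = function(e) NULL)
  if (!is.null(r)) return(r)
  r <- suppressWarnings(chol(m, pivot = TRUE))
  piv <- attr(r, "pivot")
  r[, order(piv), drop = FALSE]
}

#' Parameters of one pathway realization
#'
#' @param epsilon Vector of 10 positive rate multipliers (odd entries
#'   activating, even deactivating).
#' @param R Fold-input stimulus (`R = 1` is basal).
#' @param t_end Integration horizon for [simulate_trajectory()]; the default 15
#'   dimensionless time units is ample for equilibration of the unit-rate
#'   system.
#' @return An object of class `"pathway_params"`.
#' @export
pathway_params <- function(epsilon = rep(1, 10), R = 1, t_end = 15) {
  epsilon <- as.numeric(epsilon)
  if (length(epsilon) != 10L || any(!is.finite(epsilon)) || any(epsilon <= 0))
    stop("'epsilon' must be 10 positive finite numbers", call. = FALSE)
  if (!is.numeric(R) || length(R) != 1L || R <= 0)
    stop("'R' must be a single positive number", call. = FALSE)
  structure(list(epsilon = epsilon, R = R, t_end = t_end),
            class = "pathway_params")
}

#' Closed-form steady-state output of the five-step pathway
#'
#' With inactive pools fixed at 1 the fixed point of the cascade is
#' `A* = R * (eps1 eps3 eps5 eps7 eps9) / (eps2 eps4 eps6 eps8 eps10)`,
#' strictly increasing (and exactly linear) in `R`.
#'
#' @param params A [pathway_params()], or a matrix of epsilons
#'   (`n_cells x 10`) together with `R`.
#' @param R Fold input, used when `params` is an epsilon matrix.
#' @return Steady-state output `A*` (scalar, or one value per matrix row).
#' @export
steady_state_output <- function(params, R = NULL) {
  if (inherits(params, "pathway_params")) {
    eps <- matrix(params$epsilon, nrow = 1L)
    R <- params$R
  } else {
    eps <- as.matrix(params)
    if (ncol(eps) != 10L) stop("epsilon matrix must have 10 columns", call. = FALSE)
    if (is.null(R)) stop("'R' is required with an epsilon matrix", call. = FALSE)
  }
  odd <- seq(1L, 9L, by = 2L)
  even <- seq(2L, 10L, by = 2L)
  out <- R * exp(rowSums(log(eps[, odd, drop = FALSE])) -
                   rowSums(log(eps[, even, drop = FALSE])))
  if (length(out) == 1L) out[[1L]] else out
}

# Basal steady state (same epsilons, R = 1), used as the default initial
# condition: y1* = e1/e2, y2* = e3 y1*/e4, ... cascading products.
basal_state <- function(epsilon, R = 1) {
  y <- numeric(5L)
  drive <- R
  for (k in seq_len(5L)) {
    y[k] <- epsilon[2L * k - 1L] * drive / epsilon[2L * k]
    drive <- y[k]
  }
  names(y) <- paste0("y", 1:5)
  y
}

#' Integrate the pathway ODEs to equilibrium
#'
#' Integrates the five activation/deactivation balance equations
#' `dyk*/dt = eps_{2k-1} * (upstream drive) * 1 - eps_{2k} * yk*`
#' on `[0, t_end]` with an adaptive solver (rtol 1e-8, atol 1e-10).  The final
#' state is checked post-hoc against the closed-form fixed point.
#'
#' @param params A [pathway_params()].
#' @param initial Initial active-species concentrations `y1*..y5*`; default is
#'   the basal steady state of the same cell at `R = 1`.
#' @param times Output time grid; default 151 points on `[0, t_end]`.
#' @return A data.frame with columns `time`, `y1..y5` (`y5` is the output
#'   `A*`), with the relative deviation of the final state from the analytic
#'   steady state in attribute `"steady_state_error"`.
#' @export
simulate_trajectory <- function(params, initial = NULL, times = NULL) {
  stopifnot(inherits(params, "pathway_params"))
  eps <- params$epsilon
  if (is.null(initial)) initial <- basal_state(eps, R = 1)
  initial <- as.numeric(initial)
  if (length(initial) != 5L || any(initial < 0))
    stop("'initial' must be 5 non-negative values", call. = FALSE)
  if (is.null(times)) times <- seq(0, params$t_end, length.out = 151L)
  rhs <- function(t, y, p) {
    drive <- c(params$R, y[1:4])
    list(eps[c(1, 3, 5, 7, 9)] * drive - eps[c(2, 4, 6, 8, 10)] * y)
  }
  sol <- deSolve::ode(y = stats::setNames(initial, paste0("y", 1:5)),
                      times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1L] < 0)
    stop("ODE integration failed: ", paste(attr(sol, "istate"), collapse = " "),
         call. = FALSE)
  out <- as.data.frame(unclass(sol))
  ss <- basal_state(eps, R = params$R)  # analytic fixed point, per species
  final <- as.numeric(out[nrow(out), paste0("y", 1:5)])
  attr(out, "steady_state_error") <- max(abs(final - ss) / ss)
  out
}

#' Simulate a population of cells at one stimulus level
#'
#' Draws one epsilon vector per cell from the noise spec and returns the
#' steady-state output of each cell.  The linear cascade's fixed point is exact
#' (see [steady_state_output()]), so no per-cell integration is needed; the
#' trajectory integrator agrees with this value to integrator tolerance.
#' In independent mode `log(A*) ~ Normal(log R, cv * sqrt(N))` exactly.
#'
#' @param R Fold-input stimulus applied to every cell.
#' @param noise A [noise_spec()].
#' @param n_cells Number of cells (default 5000).
#' @param keep_eps Keep the epsilon matrix in the result (default `FALSE`).
#' @return An object of class `"population_output"`: list with `outputs`
#'   (length `n_cells`), `R`, `noise`, and optionally `eps`.
#' @export
simulate_population <- function(R, noise, n_cells = 5000L, keep_eps = FALSE) {
  stopifnot(inherits(noise, "noise_spec"))
  eps <- draw_noise(noise, n_cells)
  out <- steady_state_output(eps, R = R)
  res <- list(outputs = as.numeric(out), R = R, noise = noise)
  if (keep_eps) res$eps <- eps
  structure(res, class = "population_output")
}

#' @export
print.population_output <- function(x, ...) {
  cat(sprintf("population_output: %d cells at R = %g (cv = %g, %s)\n",
              length(x$outputs), x$R, x$noise$cv, x$noise$mode))
  cat(sprintf("  output quartiles: %s\n",
              paste(signif(stats::quantile(x$outputs, c(.25, .5, .75)), 4),
                    collapse = " / ")))
  invisible(x)
}

#' Convert a population to a per-cell data.frame
#'
#' Column layout `cell_id, R, eps_1..eps_10, output`, suitable for
#' `write.csv`.  Requires the population to have been simulated with
#' `keep_eps = TRUE` (otherwise the eps columns are omitted).
#'
#' @param pop A `"population_output"`.
#' @return A data.frame with one row per cell.
#' @export
as_population_df <- function(pop) {
  stopifnot(inherits(pop, "population_output"))
  base <- data.frame(cell_id = seq_along(pop$outputs), R = pop$R)
  if (!is.null(pop$eps)) base <- cbind(base, as.data.frame(pop$eps))
  base$output <- pop$outputs
  base
}
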