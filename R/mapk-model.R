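# Noisy MAPK (Raf -> MEK -> ERK) cascade with negative feedback.
#
# A Sturm-type three-tier cascade: RasGTP (the input, standing in for
# receptor/EGF stimulation) activates Raf; active Raf distributively doubly
# phosphorylates MEK; doubly phosphorylated MEK doubly phosphorylates ERK;
# four phosphatases reverse the steps; doubly phosphorylated ERK (pERK, the
# output) feeds back negatively on Raf activation.  The two ERK sites share
# one phosphatase that operates near saturation, which makes the ERK cycle
# bistable: terminal pERK jumps between a near-zero and a near-pool-sized
# state, so lognormal cell-to-cell variation in the MEK and ERK totals
# yields a bimodal pERK population at intermediate doses.  The switching
# threshold falls with either pool (more MEK drives more ppMEK; more ERK
# pre-saturates the shared phosphatase), so cells with more MEK or ERK
# activate at lower doses.  The packaged rate constants are a synthetic
# in-house calibration (see inst/extdata/mapk_cascade_synthetic.yaml).

#' Load the MAPK cascade configuration
#'
#' Reads rate constants, phosphatase levels, protein totals and defaults from
#' a YAML config (the packaged synthetic calibration unless a path is given).
#'
#' @param path Optional path to a YAML config with the same layout as the
#'   packaged `mapk_cascade_synthetic.yaml`.
#' @param input_dose Override the RasGTP input dose (model units).
#' @param t_end Override the integration horizon.
#' @return An object of class `"mapk_config"`.
#' @export
mapk_config <- function(path = NULL, input_dose = NULL, t_end = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "mapk_cascade_synthetic.yaml",
                        package = "pathvar", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  for (grp in c("rates", "phosphatases", "totals"))
    cfg[[grp]] <- unlist(cfg[[grp]])
  if (!is.null(input_dose)) cfg$input_dose <- input_dose
  if (!is.null(t_end)) cfg$t_end <- t_end
  if (any(cfg$rates < 0) || any(cfg$totals < 0) || any(cfg$phosphatases < 0))
    stop("rates, totals and phosphatase levels must be non-negative",
         call. = FALSE)
  structure(cfg, class = "mapk_config")
}

#' Noise specification for the MAPK cascade
#'
#' @param cv_mek_erk Lognormal CV applied to the MEK and ERK totals
#'   (default 0.15).
#' @param cv_input Lognormal CV applied to the RasGTP input (default 0.10).
#' @param covary If `TRUE`, one shared lognormal draw multiplies both MEK and
#'   ERK totals in each cell (perfect covariation); if `FALSE` the two draws
#'   are independent.
#' @return An object of class `"mapk_noise_spec"`.
#' @export
mapk_noise_spec <- function(cv_mek_erk = 0.15, cv_input = 0.10,
                            covary = FALSE) {
  if (cv_mek_erk < 0 || cv_input < 0)
    stop("CVs must be non-negative", call. = FALSE)
  structure(list(cv_mek_erk = cv_mek_erk, cv_input = cv_input,
                 covary = isTRUE(covary)),
            class = "mapk_noise_spec")
}

# Right-hand side of the cascade ODEs.  States: Raf, aRaf, MEK, pMEK, ppMEK,
# ERK, pERK, ppERK.  All free and modified forms are integrated explicitly so
# mass conservation is an integrator-level property, not an identity.
mapk_rhs <- function(t, y, p) {
  fb <- p[["Ki"]] / (p[["Ki"]] + y[["ppERK"]])
  v1  <- p[["kc1"]] * p[["RasGTP"]] * y[["Raf"]] / (p[["Km1"]] + y[["Raf"]]) * fb
  v2  <- p[["kc2"]] * p[["P1"]] * y[["aRaf"]] / (p[["Km2"]] + y[["aRaf"]])
  den3 <- p[["Km3"]] + y[["MEK"]] + y[["pMEK"]]  # competitive MEK substrates
  v3  <- p[["kc3"]] * y[["aRaf"]] * y[["MEK"]] / den3
  v3b <- p[["kc3"]] * y[["aRaf"]] * y[["pMEK"]] / den3
  v4  <- p[["kc4"]] * p[["P2a"]] * y[["ppMEK"]] / (p[["Km4"]] + y[["ppMEK"]])
  v4b <- p[["kc4b"]] * p[["P2b"]] * y[["pMEK"]] / (p[["Km4b"]] + y[["pMEK"]])
  v5  <- p[["kc5"]] * y[["ppMEK"]] * y[["ERK"]] / p[["Km5"]]
  v5b <- p[["kc5b"]] * y[["ppMEK"]] * y[["pERK"]] / p[["Km5"]]
  denp <- 1 + y[["pERK"]] / p[["Km7"]] + y[["ppERK"]] / p[["Km6"]]
  v6  <- p[["kc6"]] * p[["P3"]] * (y[["ppERK"]] / p[["Km6"]]) / denp
  v6b <- p[["kc7"]] * p[["P3"]] * (y[["pERK"]] / p[["Km7"]]) / denp
  list(c(Raf = -v1 + v2, aRaf = v1 - v2,
         MEK = -v3 + v4b, pMEK = v3 - v3b - v4b + v4, ppMEK = v3b - v4,
         ERK = -v5 + v6b, pERK = v5 - v5b - v6b + v6, ppERK = v5b - v6))
}

# Integrate one cell; returns the deSolve matrix.
mapk_integrate <- function(config, dose, mek_total, erk_total, times) {
  y0 <- c(Raf = unname(config$totals["Raf"]), aRaf = 0,
          MEK = unname(mek_total), pMEK = 0, ppMEK = 0,
          ERK = unname(erk_total), pERK = 0, ppERK = 0)
  p <- c(config$rates, config$phosphatases, RasGTP = dose)
  sol <- deSolve::ode(y = y0, times = times, func = mapk_rhs, parms = p,
                      method = "lsoda", rtol = 1e-6, atol = 1e-8)
  if (attr(sol, "istate")[1L] < 0)
    stop("MAPK ODE integration failed at dose ", dose, call. = FALSE)
  sol
}

#' Simulate one noisy MAPK cell
#'
#' Draws the cell's MEK/ERK totals and input dose from the noise spec (using
#' the current RNG state), integrates the cascade, and classifies the cell as
#' active or inactive by its terminal pERK against the threshold.
#'
#' @param config A [mapk_config()].
#' @param noise A [mapk_noise_spec()], or `NULL` for a noise-free cell.
#' @param n_times Number of saved time points in the trace (default 51).
#' @return An object of class `"mapk_cell"`: list with `perk_trace`
#'   (data.frame `time`, `pERK`), `terminal_perk`, `active`, `mek_level`,
#'   `erk_level`, `dose`.
#' @export
simulate_mapk_cell <- function(config, noise = NULL, n_times = 51L) {
  stopifnot(inherits(config, "mapk_config"))
  mek <- unname(config$totals["MEK"])
  erk <- unname(config$totals["ERK"])
  dose <- config$input_dose
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "mapk_noise_spec"))
    dose <- dose * exp(stats::rnorm(1) * noise$cv_input)
    z_mek <- stats::rnorm(1)
    z_erk <- if (noise$covary) z_mek else stats::rnorm(1)
    mek <- mek * exp(z_mek * noise$cv_mek_erk)
    erk <- erk * exp(z_erk * noise$cv_mek_erk)
  }
  times <- seq(0, config$t_end, length.out = n_times)
  sol <- mapk_integrate(config, dose, mek, erk, times)
  perk <- sol[, "ppERK"]
  structure(list(perk_trace = data.frame(time = sol[, "time"], pERK = perk),
                 terminal_perk = unname(perk[length(perk)]),
                 active = unname(perk[length(perk)]) > config$perk_threshold,
                 mek_level = mek, erk_level = erk, dose = dose),
            class = "mapk_cell")
}

#' Simulate a population of noisy MAPK cells
#'
#' Integrates `n_cells` cells at the configured dose (terminal state only)
#' and returns one row per cell.
#'
#' @param config A [mapk_config()].
#' @param noise A [mapk_noise_spec()].
#' @param n_cells Number of cells.
#' @param seed Optional RNG seed.
#' @return Data.frame with columns `cell_id`, `dose`, `mek_level`,
#'   `erk_level`, `terminal_perk`, `active`.
#' @export
simulate_mapk_population <- function(config, noise, n_cells = 200L,
                                     seed = NULL) {
  stopifnot(inherits(config, "mapk_config"), inherits(noise, "mapk_noise_spec"))
  if (!is.null(seed)) set.seed(seed)
  n_cells <- as.integer(n_cells)
  base_mek <- unname(config$totals["MEK"])
  base_erk <- unname(config$totals["ERK"])
  # dose and MEK draws first so they are shared between covary modes under a
  # common seed (paired comparisons)
  dose <- config$input_dose * exp(stats::rnorm(n_cells) * noise$cv_input)
  z_mek <- stats::rnorm(n_cells)
  z_erk <- if (noise$covary) z_mek else stats::rnorm(n_cells)
  mek <- base_mek * exp(z_mek * noise$cv_mek_erk)
  erk <- base_erk * exp(z_erk * noise$cv_mek_erk)
  times <- c(0, config$t_end)
  perk <- vapply(seq_len(n_cells), function(i) {
    sol <- mapk_integrate(config, dose[i], mek[i], erk[i], times)
    unname(sol[nrow(sol), "ppERK"])
  }, numeric(1))
  data.frame(cell_id = seq_len(n_cells), dose = dose,
             mek_level = mek, erk_level = erk,
             terminal_perk = perk, active = perk > config$perk_threshold)
}

#' Percent-activated dose-response of the MAPK cascade
#'
#' Runs [simulate_mapk_population()] at each dose of a log2-spaced grid and
#' returns the fraction of active cells per dose as a `"dose_response"`
#' object (so [fit_hill()] and [fold_error_at_fraction()] apply directly).
#'
#' @param config A [mapk_config()].
#' @param noise A [mapk_noise_spec()].
#' @param dose_grid RasGTP doses; default 24 points log2-spaced over
#'   `[2^9, 2^13]`, bracketing the activation transition.
#' @param n_cells Cells per dose (default 100).
#' @param seed Optional RNG seed.
#' @return A `"dose_response"` data.frame with columns `R` (dose) and
#'   `fraction`.
#' @export
mapk_dose_response <- function(config, noise,
                               dose_grid = 2^seq(9, 13, length.out = 24L),
                               n_cells = 100L, seed = NULL) {
  if (any(diff(dose_grid) <= 0))
    stop("'dose_grid' must be strictly increasing", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  frac <- vapply(dose_grid, function(d) {
    cfg <- config
    cfg$input_dose <- d
    mean(simulate_mapk_population(cfg, noise, n_cells)$active)
  }, numeric(1))
  structure(data.frame(R = dose_grid, fraction = frac),
            class = c("dose_response", "data.frame"),
            threshold = config$perk_threshold, n_cells = n_cells)
}

#' Fold-error in activated fraction under input error
#'
#' Locates the dose at which the curve crosses `target_fraction`
#' (monotone piecewise-linear interpolation in `(log2 dose, log10 fraction)`)
#' and returns the fold-change in the activated fraction produced by a
#' relative input error (default +10%).  A shallower curve gives a fold-error
#' closer to 1; for an exact Hill curve in the low-fraction limit the
#' fold-error approaches `(1 + input_error)^h`.
#'
#' @param curve A `"dose_response"` (or data.frame with `R`, `fraction`).
#' @param target_fraction Activated fraction at the operating point
#'   (default 0.01).
#' @param input_error Relative input error (default 0.10).
#' @return The fold-change `fraction(R* (1 + input_error)) / target_fraction`.
#' @export
fold_error_at_fraction <- function(curve, target_fraction = 0.01,
                                   input_error = 0.10) {
  d <- as.data.frame(curve)[, c("R", "fraction")]
  d <- d[d$fraction > 0, , drop = FALSE]
  if (nrow(d) < 2L)
    stop("curve must be strictly positive around the target fraction",
         call. = FALSE)
  lx <- log2(d$R)
  ly <- log10(cummax(d$fraction))  # enforce monotonicity against MC jitter
  if (target_fraction < min(d$fraction) || target_fraction > max(d$fraction))
    stop("target fraction ", target_fraction,
         " is outside the range of the curve", call. = FALSE)
  lx_star <- stats::approx(ly, lx, xout = log10(target_fraction),
                           ties = "ordered")$y
  ly_pert <- stats::approx(lx, ly, xout = lx_star + log2(1 + input_error),
                           rule = 2, ties = "ordered")$y
  10^ly_pert / target_fraction
}

#' Compare MEK/ERK levels between active and inactive cells
#'
#' Per-class summary (n, median, quartiles) of the noisy MEK and ERK totals,
#' plus rank-sum p-values for the active-vs-inactive difference.  At
#' intermediate doses the active class has higher median MEK and ERK: cells
#' with more kinase are the ones that cross the activation threshold.
#'
#' @param cells A data.frame from [simulate_mapk_population()] (columns
#'   `mek_level`, `erk_level`, `active`).
#' @return List with `summary` (data.frame, one row per class x protein) and
#'   `p_values` (named vector; `NA` with a message if only one class is
#'   present).
#' @export
stratify_by_activity <- function(cells) {
  stopifnot(all(c("mek_level", "erk_level", "active") %in% names(cells)))
  cls <- factor(ifelse(cells$active, "active", "inactive"),
                levels = c("active", "inactive"))
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  rows <- list()
  for (prot in c("mek_level", "erk_level"))
    for (lv in levels(cls)) {
      x <- cells[[prot]][cls == lv]
      if (length(x) == 0L) next
      q <- qs(x)
      rows[[length(rows) + 1L]] <- data.frame(
        protein = sub("_level", "", prot), class = lv, n = length(x),
        q1 = q[1L], median = q[2L], q3 = q[3L])
    }
  summ <- do.call(rbind, rows)
  if (length(unique(cls)) < 2L) {
    message("only one activity class present; no comparison performed")
    return(list(summary = summ,
                p_values = c(mek = NA_real_, erk = NA_real_)))
  }
  pv <- vapply(c("mek_level", "erk_level"), function(prot)
    stats::wilcox.test(cells[[prot]][cells$active],
                       cells[[prot]][!cells$active])$p.value, numeric(1))
  names(pv) <- c("mek", "erk")
  list(summary = summ, p_values = pv)
}
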