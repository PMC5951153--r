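# Synthetic data generators with known ground truth.
#
# Every statistic in the measurement pipeline is exercised on generated data
# whose parameters are known exactly: single-egg relative-abundance tables
# (lognormal biological variation with a planted correlation structure,
# cell-cycle profiles for cyclin-like proteins, per-sample calibration error,
# technical noise) and per-cell imaging tables (lognormal mass and target
# concentrations, 2N/4N DNA mixture, concentration-dependent activation,
# FRET timecourses per activation class).

#' Default protein panel for the egg generator
#'
#' Twenty-six proteins: a MEK/ERK pair and an MCM5/MCM7 pair (the planted
#' covariation targets), four cyclin-like cell-cycle-regulated proteins
#' (excluded from the correction reference set), and generic signaling and
#' control proteins.  Biological CVs default to the 5-15% range observed for
#' relative protein abundances, 7% unless overridden.
#'
#' @param biological_cv Per-protein biological CV (recycled; default 0.07).
#' @return Data.frame with columns `name`, `mean`, `cv`, `is_cycling`,
#'   `is_reference`.
#' @export
default_egg_proteins <- function(biological_cv = 0.07) {
  nm <- c("MEK", "ERK", "MCM5", "MCM7",
          "CyclinA", "CyclinB", "Cdc6", "Emi1",
          paste0("SIG", 1:12), paste0("CTRL", 1:6))
  cycling <- nm %in% c("CyclinA", "CyclinB", "Cdc6", "Emi1")
  # fixed spread of mean relative abundances (arbitrary units)
  means <- round(exp(seq(log(0.2), log(5), length.out = length(nm))), 3)
  data.frame(name = nm, mean = means,
             cv = rep_len(biological_cv, length(nm)),
             is_cycling = cycling,
             is_reference = !cycling)  # the 22 non-cycling peptides
}

#' Build a protein correlation matrix with planted pairs
#'
#' Identity correlation except for the named pairs.
#'
#' @param names Protein names.
#' @param pairs List of `list(a, b, r)` entries (or length-3 vectors
#'   `c(a, b, r)`).
#' @return A correlation matrix.
#' @export
plant_correlation <- function(names, pairs = list()) {
  m <- diag(length(names))
  dimnames(m) <- list(names, names)
  for (p in pairs) {
    a <- as.character(p[[1L]]); b <- as.character(p[[2L]])
    r <- as.numeric(p[[3L]])
    m[a, b] <- m[b, a] <- r
  }
  m
}

#' Configuration of the synthetic egg dataset
#'
#' The bundled designs mirror common single-egg experiments: `"egg25"` (5
#' eggs at each of 5 timepoints, one batch per timepoint), `"egg120"` (60
#' eggs at each of 2 timepoints, each split into 6 batches of 10), and
#' `"tech30"` (30 aliquots of one pooled lysate: biological CV zero, so only
#' calibration and technical noise remain).
#'
#' @param design One of `"egg25"`, `"egg120"`, `"tech30"`.
#' @param proteins Protein panel as from [default_egg_proteins()].
#' @param correlation Correlation matrix over proteins for the biological
#'   draws; default plants r = 0.7 for MEK-ERK and MCM5-MCM7.
#' @param calibration_cv Per-sample multiplicative lognormal calibration
#'   error (default 0.05).
#' @param technical_cv Per-measurement lognormal technical noise
#'   (default 0.02).
#' @param seed RNG seed used by [generate_egg_dataset()].
#' @return An object of class `"egg_config"`.
#' @export
egg_config <- function(design = c("egg25", "egg120", "tech30"),
                       proteins = default_egg_proteins(),
                       correlation = NULL,
                       calibration_cv = 0.05, technical_cv = 0.02,
                       seed = NULL) {
  design <- match.arg(design)
  layout <- switch(design,
    egg25 = data.frame(batch = paste0("b", rep(1:5, each = 5)),
                       timepoint = rep(c(0, 20, 40, 60, 80), each = 5)),
    egg120 = data.frame(batch = paste0("t", rep(rep(c(60, 80), each = 6),
                                                each = 10),
                                       "_b", rep(rep(1:6, each = 10), 2)),
                        timepoint = rep(c(60, 80), each = 60)),
    tech30 = data.frame(batch = rep("pooled", 30), timepoint = rep(60, 30)))
  if (design == "tech30") proteins$cv <- 0  # pooled lysate: no biological CV
  if (is.null(correlation))
    correlation <- plant_correlation(proteins$name,
                                     list(list("MEK", "ERK", 0.7),
                                          list("MCM5", "MCM7", 0.7)))
  check_correlation(correlation, nrow(proteins))
  if (calibration_cv < 0 || technical_cv < 0)
    stop("noise CVs must be non-negative", call. = FALSE)
  structure(list(design = design, layout = layout, proteins = proteins,
                 correlation = correlation, calibration_cv = calibration_cv,
                 technical_cv = technical_cv, seed = seed),
            class = "egg_config")
}

# abundance trajectory of a cyclin-like protein over the first cell cycle:
# accumulation to a mid-cycle peak, then degradation
cyclin_profile <- function(t) {
  stats::approx(c(0, 40, 80), c(1, 1.6, 0.5), xout = t, rule = 2)$y
}

#' Generate a synthetic egg abundance dataset
#'
#' Each measured value is
#' `mean_p * profile_p(t_s) * exp(b_sp) * calib_s * exp(tech_sp)`, with the
#' biological log-deviations `b` drawn row-wise from a multivariate normal
#' with per-protein standard deviations equal to the biological CVs and the
#' planted correlation structure; `calib_s = exp(z * calibration_cv)` is the
#' per-sample calibration error and `tech` the per-measurement technical
#' noise.  All draws are returned as ground truth.
#'
#' @param config An [egg_config()].
#' @return List with `table` (an [abundance_table()]) and `truth` (list with
#'   the biological log-deviations, calibration factors, technical draws and
#'   the config).
#' @export
generate_egg_dataset <- function(config) {
  stopifnot(inherits(config, "egg_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  pr <- config$proteins
  n_s <- nrow(config$layout)
  n_p <- nrow(pr)
  l <- chol_psd(config$correlation)
  b <- (matrix(stats::rnorm(n_s * n_p), n_s, n_p) %*% l) *
    matrix(pr$cv, n_s, n_p, byrow = TRUE)
  calib <- exp(stats::rnorm(n_s) * config$calibration_cv)
  tech <- matrix(stats::rnorm(n_s * n_p) * config$technical_cv, n_s, n_p)
  profile <- matrix(1, n_s, n_p)
  if (any(pr$is_cycling))
    profile[, pr$is_cycling] <- cyclin_profile(config$layout$timepoint)
  values <- matrix(pr$mean, n_s, n_p, byrow = TRUE) * profile *
    exp(b) * calib * exp(tech)
  dimnames(values) <- list(paste0("egg_", seq_len(n_s)), pr$name)
  tab <- abundance_table(values,
                         sample_meta = config$layout,
                         protein_meta = data.frame(
                           is_reference = pr$is_reference,
                           is_cell_cycle_regulated = pr$is_cycling,
                           row.names = pr$name))
  list(table = tab,
       truth = list(biological_log_dev = b, calibration = calib,
                    technical_log_dev = tech, config = config))
}

#' Configuration of the synthetic imaging cell dataset
#'
#' @param n_cells Number of cells (default 1000).
#' @param mass_cv Lognormal CV of the total-protein-mass stain (cell volume
#'   proxy; default 0.25).
#' @param dna_weights 2N/4N mixture weights (default `c(0.6, 0.4)`).
#' @param dna_means DNA-content centers of the two modes (default `c(2, 4)`).
#' @param dna_cv Per-mode DNA-measurement CV (default 0.05).
#' @param targets Data.frame of per-target concentration `name`, `mean`,
#'   `cv`; default MEK and ERK at 15% CV.
#' @param target_correlation Correlation matrix over targets (default plants
#'   MEK-ERK r = 0.7).
#' @param activation_slope,activation_center Logistic model of the
#'   probability of responding as a function of the summed log target
#'   concentrations (`plogis(slope * (sum(log conc) - center))`).
#' @param fret List of FRET kinetics: `baseline`, `plateau` (responder rise
#'   amplitude), `rise_tau`, `noise_sd`, `stim_time`, `t_end`, `dt`
#'   (2-minute sampling by default).
#' @param measurement_cv Multiplicative antibody measurement noise
#'   (default 0.05).
#' @param image_size Square field size in pixels (default 1080).
#' @param seed RNG seed used by [generate_cell_dataset()].
#' @return An object of class `"cell_config"`.
#' @export
cell_config <- function(n_cells = 1000L, mass_cv = 0.25,
                        dna_weights = c(0.6, 0.4), dna_means = c(2, 4),
                        dna_cv = 0.05,
                        targets = data.frame(name = c("MEK", "ERK"),
                                             mean = c(1, 1),
                                             cv = c(0.15, 0.15)),
                        target_correlation = NULL,
                        activation_slope = 8, activation_center = 0,
                        fret = list(baseline = 1, plateau = 0.6,
                                    rise_tau = 6, noise_sd = 0.02,
                                    stim_time = 10, t_end = 60, dt = 2),
                        measurement_cv = 0.05,
                        image_size = 1080, seed = NULL) {
  if (abs(sum(dna_weights) - 1) > 1e-8)
    stop("'dna_weights' must sum to 1", call. = FALSE)
  if (is.null(target_correlation))
    target_correlation <- plant_correlation(targets$name,
                                            if (all(c("MEK", "ERK") %in%
                                                    targets$name))
                                              list(list("MEK", "ERK", 0.7))
                                            else list())
  check_correlation(target_correlation, nrow(targets))
  structure(list(n_cells = as.integer(n_cells), mass_cv = mass_cv,
                 dna_weights = dna_weights, dna_means = dna_means,
                 dna_cv = dna_cv, targets = targets,
                 target_correlation = target_correlation,
                 activation_slope = activation_slope,
                 activation_center = activation_center,
                 fret = fret, measurement_cv = measurement_cv,
                 image_size = image_size, seed = seed),
            class = "cell_config")
}

#' Generate one synthetic FRET timecourse
#'
#' Responders rise saturating-exponentially from baseline after the stimulus
#' (`baseline + plateau * (1 - exp(-(t - stim)/tau))`); non-responders stay
#' at baseline.  Gaussian measurement noise is added pointwise.
#'
#' @param class `"responder"` or `"nonresponder"`.
#' @param kinetics List as in the `fret` element of [cell_config()].
#' @return Data.frame with columns `time` and `ratio`.
#' @export
generate_fret_trace <- function(class = c("responder", "nonresponder"),
                                kinetics = cell_config()$fret) {
  class <- match.arg(class)
  k <- kinetics
  t <- seq(0, k$t_end, by = k$dt)
  ratio <- rep(k$baseline, length(t))
  if (class == "responder") {
    post <- t >= k$stim_time
    ratio[post] <- k$baseline +
      k$plateau * (1 - exp(-(t[post] - k$stim_time) / k$rise_tau))
  }
  if (k$noise_sd > 0) ratio <- ratio + stats::rnorm(length(t), 0, k$noise_sd)
  data.frame(time = t, ratio = ratio)
}

#' Generate a synthetic imaging cell dataset
#'
#' Per cell: a position uniform over the square field, a DNA content from
#' the 2N/4N mixture, a mass-stain intensity, correlated lognormal target
#' concentrations, antibody intensities
#' `mass * concentration * exp(measurement noise)`, an activation label
#' drawn from the concentration-dependent logistic model, and a FRET
#' timecourse synthesized for the label.
#'
#' @param config A [cell_config()].
#' @param traces If `TRUE` (default), FRET traces are generated and returned
#'   as a cells x timepoints matrix.
#' @return List with `cells` (data.frame: `cell_id`, `x`, `y`, `dna`,
#'   `mass_stain`, one intensity column per target, `responder`),
#'   `fret_time` and `fret_traces` (when requested), and `truth` (the latent
#'   concentrations and the config).
#' @export
generate_cell_dataset <- function(config, traces = TRUE) {
  stopifnot(inherits(config, "cell_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_cells
  tg <- config$targets
  mode <- sample(seq_along(config$dna_weights), n, replace = TRUE,
                 prob = config$dna_weights)
  dna <- config$dna_means[mode] * exp(stats::rnorm(n) * config$dna_cv)
  mass <- exp(stats::rnorm(n) * config$mass_cv)
  l <- chol_psd(config$target_correlation)
  z <- matrix(stats::rnorm(n * nrow(tg)), n) %*% l
  conc <- exp(sweep(z, 2L, tg$cv, "*")) *
    matrix(tg$mean, n, nrow(tg), byrow = TRUE)
  colnames(conc) <- tg$name
  intens <- conc * mass * exp(matrix(stats::rnorm(n * nrow(tg)) *
                                       config$measurement_cv, n))
  p_act <- stats::plogis(config$activation_slope *
                           (rowSums(log(conc)) - config$activation_center))
  responder <- stats::runif(n) < p_act
  cells <- data.frame(cell_id = seq_len(n),
                      x = stats::runif(n, 0, config$image_size),
                      y = stats::runif(n, 0, config$image_size),
                      dna = dna, mass_stain = mass)
  cells <- cbind(cells, as.data.frame(intens))
  cells$responder <- responder
  out <- list(cells = cells,
              truth = list(concentration = conc, p_activation = p_act,
                           dna_mode = mode, config = config))
  if (traces) {
    k <- config$fret
    tvec <- seq(0, k$t_end, by = k$dt)
    tr <- matrix(NA_real_, n, length(tvec))
    for (i in seq_len(n))
      tr[i, ] <- generate_fret_trace(
        if (responder[i]) "responder" else "nonresponder", k)$ratio
    out$fret_time <- tvec
    out$fret_traces <- tr
  }
  out
}
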