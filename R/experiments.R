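# Experiment runners: named, seeded, reproducible bundles tying the model,
# metric and statistics modules together.  Each experiment computes the
# headline statistics of one analysis (fIDL values, fitted Hill coefficients,
# CV/correlation reports, ...), optionally writes CSV/JSON outputs plus a
# manifest (experiment name, seed, parameter hash, package version), and
# returns the summary as a list.

experiment_registry <- function() {
  c("fig1_fidl", "figEV1_mi", "fig5_hill", "fig7_covariation",
    "fig8_tradeoff", "egg_pipeline", "mapk_bimodal")
}

#' List the available experiments
#'
#' @return Character vector of experiment names accepted by
#'   [run_experiment()].
#' @export
list_experiments <- function() experiment_registry()

#' Run a named experiment
#'
#' Executes one of the registered analyses end to end with all randomness
#' driven by `seed`.  With an output directory, writes the per-experiment
#' tables (CSV), the summary (JSON) and a manifest recording the experiment
#' name, seed, parameter hash and package version; reruns with the same seed
#' and parameters reproduce the summary.
#'
#' @param name Experiment name, one of [list_experiments()].
#' @param parameters Named list of overrides; unknown names are an error.
#'   Defaults per experiment: `fig1_fidl` (`cvs = c(0.05, 0.10, 0.25)`,
#'   `n_cells = 1e5`), `figEV1_mi` (`cv = 0.10`, `n_samples = 10000`,
#'   `r_max = 1000`), `fig5_hill` (`cvs = c(0.05, 0.10, 0.20, 0.40)`,
#'   `n_cells = 5000`, `threshold = 10`), `fig7_covariation` (`cv = 0.10`,
#'   `n_cells = 5000`, `threshold = 10`), `fig8_tradeoff`
#'   (`cvs`, `n_components`, `n_cov` grids), `egg_pipeline`
#'   (`design = "egg120"`, `n_boot = 500`), `mapk_bimodal`
#'   (`n_cells = 150`).
#' @param seed Integer seed (recorded in every output).
#' @param out_dir Optional output directory (created if needed).
#' @return The summary list (invisibly when writing to `out_dir`).
#' @export
run_experiment <- function(name, parameters = list(), seed = 1L,
                           out_dir = NULL) {
  if (!name %in% experiment_registry())
    stop("unknown experiment '", name, "'; see list_experiments()",
         call. = FALSE)
  runner <- get(paste0("exp_", name), mode = "function")
  defaults <- attr(runner, "defaults")
  bad <- setdiff(names(parameters), names(defaults))
  if (length(bad))
    stop("unknown parameter(s) for ", name, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  params <- utils::modifyList(defaults, parameters)
  set.seed(seed)
  res <- runner(params)
  res$summary$experiment <- name
  res$summary$seed <- seed
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(res$tables))
      utils::write.csv(res$tables[[nm]],
                       file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(
      list(experiment = name, seed = seed,
           parameter_hash = hash_object(params),
           package_version = as.character(utils::packageVersion("pathvar"))),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
    return(invisible(res$summary))
  }
  res$summary
}

# md5 of the canonical JSON serialization (via a temp file; tools::md5sum
# operates on files)
hash_object <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

exp_fig1_fidl <- structure(function(p) {
  rows <- lapply(p$cvs, function(cv) {
    ns <- noise_spec(cv, "independent")
    data.frame(cv = cv,
               fidl_analytic = fidl_analytic(cv, 10),
               fidl_simulated = fidl_simulated(ns, n_cells = p$n_cells))
  })
  tab <- do.call(rbind, rows)
  list(tables = list(fidl = tab),
       summary = list(fidl_analytic = as.list(stats::setNames(
                        tab$fidl_analytic, paste0("cv_", tab$cv))),
                      fidl_simulated = as.list(stats::setNames(
                        tab$fidl_simulated, paste0("cv_", tab$cv)))))
}, defaults = list(cvs = c(0.05, 0.10, 0.25), n_cells = 1e5))

exp_figEV1_mi <- structure(function(p) {
  ns <- noise_spec(p$cv, "independent")
  cmp <- mi_saturation_comparison(ns, n_samples = p$n_samples,
                                  r_max = p$r_max)
  fs_lin <- fidl_simulated(ns, n_cells = p$n_samples)
  fs_sat <- fidl_simulated(ns, n_cells = p$n_samples,
                           output_fun = saturating_population_output)
  list(tables = list(),
       summary = list(mi_linear_bits = cmp$mi_linear,
                      mi_saturated_bits = cmp$mi_saturated,
                      fidl_linear = fs_lin, fidl_saturated = fs_sat,
                      fidl_analytic = cmp$fidl_analytic))
}, defaults = list(cv = 0.10, n_samples = 10000L, r_max = 1000))

exp_fig5_hill <- structure(function(p) {
  rows <- lapply(p$cvs, function(cv) {
    spec <- binary_model_spec(noise_spec(cv, "independent"),
                              threshold = p$threshold, n_cells = p$n_cells)
    dr <- dose_response(spec)
    fit <- fit_hill(dr)
    data.frame(cv = cv, h = fit$h, k_half = fit$k_half)
  })
  tab <- do.call(rbind, rows)
  list(tables = list(hill_fits = tab),
       summary = list(hill = as.list(stats::setNames(tab$h,
                                                     paste0("cv_", tab$cv)))))
}, defaults = list(cvs = c(0.05, 0.10, 0.20, 0.40), n_cells = 5000L,
                   threshold = 10))

exp_fig7_covariation <- structure(function(p) {
  fit_mode <- function(mode) {
    spec <- binary_model_spec(noise_spec(p$cv, mode),
                              threshold = p$threshold, n_cells = p$n_cells)
    fit_hill(dose_response(spec))$h
  }
  h_ind <- fit_mode("independent")
  h_cov <- fit_mode("sign_grouped")
  list(tables = list(),
       summary = list(h_independent = h_ind, h_covarying = h_cov))
}, defaults = list(cv = 0.10, n_cells = 5000L, threshold = 10))

exp_fig8_tradeoff <- structure(function(p) {
  grid <- expand.grid(cv = p$cvs, n_components = p$n_components,
                      n_cov = p$n_cov)
  tab <- tradeoff_curve(grid$cv, grid$n_components, grid$n_cov)
  list(tables = list(tradeoff = tab),
       summary = list(product_min = min(tab$product),
                      product_max = max(tab$product)))
}, defaults = list(cvs = c(0.05, 0.10, 0.25, 0.40),
                   n_components = c(5, 10, 20), n_cov = 0))

exp_egg_pipeline <- structure(function(p) {
  ds <- generate_egg_dataset(egg_config(p$design))
  corr <- correction_factors(ds$table)
  cvs <- batch_cv(corr$corrected, n_boot = p$n_boot)
  pc <- pairwise_correlations(corr$corrected)
  planted <- pc[(pc$protein_1 == "MEK" & pc$protein_2 == "ERK") |
                  (pc$protein_1 == "ERK" & pc$protein_2 == "MEK"), ]
  list(tables = list(batch_cvs = cvs, correlations = pc),
       summary = list(median_cv = stats::median(cvs$cv),
                      mek_erk_r = planted$r[1L],
                      mek_erk_significant = planted$significant[1L],
                      n_significant_pairs = sum(pc$significant)))
}, defaults = list(design = "egg120", n_boot = 500L))

exp_mapk_bimodal <- structure(function(p) {
  cfg <- mapk_config()
  cells <- simulate_mapk_population(cfg, mapk_noise_spec(), p$n_cells)
  strat <- stratify_by_activity(cells)
  list(tables = list(mapk_cells = cells),
       summary = list(fraction_active = mean(cells$active),
                      median_perk_active =
                        stats::median(cells$terminal_perk[cells$active]),
                      median_perk_inactive =
                        stats::median(cells$terminal_perk[!cells$active]),
                      p_mek = unname(strat$p_values["mek"]),
                      p_erk = unname(strat$p_values["erk"])))
}, defaults = list(n_cells = 150L))
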