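# Generators: exactness without noise, planted-parameter recovery, FRET traces.

test_that("noise-free egg tables are exact means times profiles", {
  pr <- default_egg_proteins(0)
  cfg <- egg_config("egg25", proteins = pr, calibration_cv = 0,
                    technical_cv = 0, seed = 1)
  ds <- generate_egg_dataset(cfg)
  v <- pathvar:::abundance_values(ds$table)
  flat <- !pr$is_cycling
  expected_flat <- matrix(pr$mean[flat], nrow(v), sum(flat), byrow = TRUE)
  expect_equal(unname(v[, flat]), expected_flat, tolerance = 1e-12)
  # cyclin-like proteins follow the cell-cycle profile
  tp <- SummarizedExperiment::colData(ds$table)$timepoint
  cyc <- which(pr$is_cycling)[1]
  expect_equal(unname(v[, cyc]),
               pr$mean[cyc] * pathvar:::cyclin_profile(tp), tolerance = 1e-12)
})

test_that("raw CVs combine biological and calibration noise; correction removes it", {
  pr <- default_egg_proteins(0.07)
  pr$is_cycling <- FALSE
  cfg <- egg_config("egg120", proteins = pr, calibration_cv = 0.05,
                    technical_cv = 0, seed = 2)
  ds <- generate_egg_dataset(cfg)
  pooled_cv <- function(se) {
    v <- pathvar:::abundance_values(se)
    median(apply(v, 2, function(x) sd(x) / mean(x)))
  }
  expect_equal(pooled_cv(ds$table), sqrt(0.07^2 + 0.05^2), tolerance = 0.03)
  corrected <- correction_factors(ds$table)$corrected
  expect_equal(pooled_cv(corrected), 0.07, tolerance = 0.03)
})

test_that("planted correlation appears in the latent draws", {
  # average the sampling noise of the correlation estimate over several seeds
  r_mek <- r_mcm <- numeric(6)
  for (s in 1:6) {
    cfg <- egg_config("egg120", seed = s)
    ds <- generate_egg_dataset(cfg)
    b <- ds$truth$biological_log_dev
    idx <- match(c("MEK", "ERK"), cfg$proteins$name)
    mm <- match(c("MCM5", "MCM7"), cfg$proteins$name)
    r_mek[s] <- cor(b[, idx[1]], b[, idx[2]])
    r_mcm[s] <- cor(b[, mm[1]], b[, mm[2]])
  }
  expect_equal(mean(r_mek), 0.7, tolerance = 0.06 / 0.7)
  expect_equal(mean(r_mcm), 0.7, tolerance = 0.06 / 0.7)
})

test_that("generated datasets are reproducible from the seed", {
  a <- generate_egg_dataset(egg_config("egg25", seed = 9))
  b <- generate_egg_dataset(egg_config("egg25", seed = 9))
  expect_identical(SummarizedExperiment::assay(a$table),
                   SummarizedExperiment::assay(b$table))
  k <- cell_config(n_cells = 5, seed = 9)$fret
  set.seed(9); t1 <- generate_fret_trace("responder", k)
  set.seed(9); t2 <- generate_fret_trace("responder", k)
  expect_identical(t1, t2)
})

test_that("fret traces have the stated limiting behaviour", {
  k <- list(baseline = 1, plateau = 0.6, rise_tau = 6, noise_sd = 0,
            stim_time = 10, t_end = 60, dt = 2)
  nr <- generate_fret_trace("nonresponder", k)
  expect_true(all(nr$ratio == 1))
  expect_equal(integrated_activity(nr$time, nr$ratio, 10), 1 * 50)
  rs <- generate_fret_trace("responder", k)
  # saturating rise approaches baseline + plateau
  expect_equal(rs$ratio[nrow(rs)], 1.6, tolerance = 0.001)
  expect_true(all(diff(rs$ratio[rs$time >= 10]) >= 0))
})

test_that("cell datasets support gating, scoring and extreme-group recovery", {
  cfg <- cell_config(n_cells = 600, dna_weights = c(1, 0), dna_cv = 0,
                     measurement_cv = 0, mass_cv = 0, seed = 4,
                     fret = list(baseline = 1, plateau = 0.6, rise_tau = 6,
                                 noise_sd = 0.02, stim_time = 10, t_end = 60,
                                 dt = 2))
  ds <- generate_cell_dataset(cfg)
  # single 2N mode, no noise: gate keeps everything
  expect_identical(nrow(gate_g1(ds$cells)), 600L)

  # activity scores split into two classes matching the labels
  auc <- vapply(seq_len(600), function(i)
    integrated_activity(ds$fret_time, ds$fret_traces[i, ], 10), numeric(1))
  thr <- activity_threshold(auc)
  acc <- mean((auc > thr) == ds$cells$responder)
  expect_gte(acc, 0.98)

  # responders are concentration-biased, so the top-AUC group is richer
  conc <- normalize_by_mass(ds$cells, c("MEK", "ERK"))
  res <- compare_extremes(auc, conc$MEK_conc)
  expect_gt(res$summary$median[res$summary$group == "top"],
            res$summary$median[res$summary$group == "bottom"])
})

test_that("pipeline recovers planted CVs and correlations across random configs", {
  set.seed(12)
  n_cfg <- 12
  cv_hits <- 0; cv_total <- 0; r_hits <- 0; r_est <- numeric(n_cfg)
  for (i in seq_len(n_cfg)) {
    cv_i <- runif(1, 0.05, 0.15)
    pr <- default_egg_proteins(cv_i)
    pr$is_cycling <- FALSE
    cfg <- egg_config("egg120", proteins = pr,
                      correlation = plant_correlation(pr$name,
                                                      list(list("MEK", "ERK", 0.7))),
                      calibration_cv = 0.05, technical_cv = 0,
                      seed = 1000 + i)
    ds <- generate_egg_dataset(cfg)
    corrected <- correction_factors(ds$table)$corrected
    v <- pathvar:::abundance_values(corrected)
    for (p in seq_len(ncol(v))) {
      ci <- bootstrap_cv(v[, p], 400)
      cv_total <- cv_total + 1
      cv_hits <- cv_hits + (ci[1] <= cv_i && cv_i <= ci[2])
    }
    ct <- cor.test(v[, "MEK"], v[, "ERK"])
    r_est[i] <- ct$estimate
    r_hits <- r_hits + (ct$conf.int[1] <= 0.7 && 0.7 <= ct$conf.int[2])
  }
  expect_gte(cv_hits / cv_total, 0.9)
  # median-based correction subtracts a per-sample median that includes the
  # correlated pair's own deviations, deflating corrected correlations by a
  # few hundredths; the CI-coverage of the planted value is reduced
  # accordingly, but the point estimates stay close to it
  expect_gte(r_hits / n_cfg, 0.7)
  # allow the ~0.04 correction-induced deflation plus sampling error of the
  # 12-config mean (se ~ 0.014)
  expect_lt(abs(mean(r_est) - 0.7), 0.08)
})
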