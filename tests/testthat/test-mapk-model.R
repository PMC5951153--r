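# Noisy MAPK cascade: conservation, bimodality, covariation, stratification.

test_that("config loads and deterministic cells respond monotonically to dose", {
  cfg <- mapk_config()
  expect_s3_class(cfg, "mapk_config")
  expect_identical(unname(cfg$totals["ERK"]), 100)

  low <- simulate_mapk_cell(mapk_config(input_dose = 2^9.5))
  high <- simulate_mapk_cell(mapk_config(input_dose = 2^13))
  expect_false(low$active)
  expect_true(high$active)
  expect_gt(high$terminal_perk, low$terminal_perk)
  # pERK can never exceed the ERK pool
  expect_true(all(high$perk_trace$pERK <= 100 + 1e-6))
})

test_that("protein totals are conserved along trajectories", {
  cfg <- mapk_config(input_dose = 2^11.5)
  sol <- pathvar:::mapk_integrate(cfg, cfg$input_dose, 120, 100,
                                  times = seq(0, cfg$t_end, length.out = 31))
  raf <- sol[, "Raf"] + sol[, "aRaf"]
  mek <- sol[, "MEK"] + sol[, "pMEK"] + sol[, "ppMEK"]
  erk <- sol[, "ERK"] + sol[, "pERK"] + sol[, "ppERK"]
  expect_lt(max(abs(raf - 100)) / 100, 1e-5)
  expect_lt(max(abs(mek - 120)) / 120, 1e-5)
  expect_lt(max(abs(erk - 100)) / 100, 1e-5)
})

test_that("covarying noise keeps the MEK/ERK ratio constant across cells", {
  cfg <- mapk_config()
  cells <- simulate_mapk_population(cfg, mapk_noise_spec(covary = TRUE),
                                    10, seed = 1)
  ratio <- cells$mek_level / cells$erk_level
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-12)
})

test_that("terminal pERK is bimodal at an intermediate dose", {
  cfg <- mapk_config()  # default dose is the intermediate stimulus
  cells <- simulate_mapk_population(cfg, mapk_noise_spec(), 200, seed = 5)
  pp <- cells$terminal_perk
  expect_gt(mean(pp < 5), 0.2)   # inactive mode populated
  expect_gt(mean(pp > 60), 0.2)  # active mode populated
  # valley: the band between the modes holds less than half the smaller
  # mode's mass
  expect_lt(mean(pp > 10 & pp < 50),
            0.5 * min(mean(pp < 5), mean(pp > 60)))
  # the classification threshold separates the modes
  expect_identical(cells$active, pp > cfg$perk_threshold)
})

test_that("dose-response rises monotonically and covariation flattens it", {
  cfg <- mapk_config()
  grid <- 2^seq(10.4, 12, length.out = 10)
  dr_ind <- mapk_dose_response(cfg, mapk_noise_spec(covary = FALSE),
                               grid, n_cells = 50, seed = 31)
  dr_cov <- mapk_dose_response(cfg, mapk_noise_spec(covary = TRUE),
                               grid, n_cells = 50, seed = 31)
  # monotone up to Monte-Carlo jitter
  expect_true(all(diff(dr_ind$fraction) > -0.12))
  expect_gt(dr_ind$fraction[10], 0.9)
  h_ind <- fit_hill(dr_ind)$h
  h_cov <- fit_hill(dr_cov)$h
  expect_lt(h_cov, h_ind)

  # a shallower curve tolerates input error better near low fractions
  dense <- exp(seq(log(min(grid)), log(max(grid)), length.out = 200))
  fe_ind <- fold_error_at_fraction(hill_curve(h_ind, fit_hill(dr_ind)$k_half,
                                              dense), 0.01)
  fe_cov <- fold_error_at_fraction(hill_curve(h_cov, fit_hill(dr_cov)$k_half,
                                              dense), 0.01)
  expect_lt(fe_cov, fe_ind)
})

test_that("fold-error interpolation matches closed forms", {
  r <- exp(seq(log(1), log(1000), length.out = 400))
  # flat curve: input error changes nothing
  flat <- data.frame(R = r, fraction = rep(0.01, length(r)))
  expect_equal(fold_error_at_fraction(flat, 0.01), 1, tolerance = 1e-6)
  # exact Hill curve in the low-fraction limit: fold error ~ 1.1^h
  fe <- fold_error_at_fraction(hill_curve(3, 500, r), 0.001)
  expect_equal(fe, 1.1^3, tolerance = 0.02)
  expect_error(fold_error_at_fraction(hill_curve(3, 500, r), 0.9999),
               "outside the range")
})

test_that("activity stratification reports exact class summaries", {
  # deterministic two-population input with known medians
  cells <- data.frame(mek_level = c(1, 2, 3, 10, 20, 30),
                      erk_level = c(4, 5, 6, 40, 50, 60),
                      active = rep(c(FALSE, TRUE), each = 3))
  s <- stratify_by_activity(cells)
  med <- s$summary$median[s$summary$class == "active"]
  expect_identical(med, c(20, 50))
  expect_identical(s$summary$median[s$summary$class == "inactive"], c(2, 5))

  # single class: reported, no comparison
  expect_message(s1 <- stratify_by_activity(cells[cells$active, ]),
                 "one activity class")
  expect_true(all(is.na(s1$p_values)))
})

test_that("activated cells carry more MEK and ERK at intermediate doses", {
  cfg <- mapk_config()
  cells <- simulate_mapk_population(cfg, mapk_noise_spec(), 150, seed = 7)
  s <- stratify_by_activity(cells)
  get_med <- function(prot, cls)
    s$summary$median[s$summary$protein == prot & s$summary$class == cls]
  expect_gt(get_med("mek", "active"), get_med("mek", "inactive"))
  expect_gt(get_med("erk", "active"), get_med("erk", "inactive"))
})
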