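# Measurement-statistics pipeline: correction factors, CVs, correlations,
# gating, normalization, activity scoring.

make_table <- function(values, ref = rep(TRUE, ncol(values))) {
  abundance_table(values,
                  sample_meta = data.frame(batch = rep("b1", nrow(values))),
                  protein_meta = data.frame(is_reference = ref))
}

test_that("correction factors recover planted per-sample scalings", {
  set.seed(1)
  base <- matrix(rep(c(1, 2, 4, 0.5), each = 5), nrow = 5)
  # scale sample 2 uniformly by 1.1
  v <- base
  v[2, ] <- v[2, ] * 1.1
  cf <- correction_factors(make_table(v))
  expect_equal(unname(cf$factors[2]), 1.1, tolerance = 1e-12)
  expect_equal(pathvar:::abundance_values(cf$corrected), base,
               tolerance = 1e-12, ignore_attr = TRUE)

  # identical samples: all factors exactly 1
  cf <- correction_factors(make_table(base))
  expect_true(all(cf$factors == 1))

  # 3x3 hand-computed example
  v3 <- rbind(c(1, 2, 4), c(1.2, 2.4, 4.8), c(0.9, 1.8, 3.6))
  cf3 <- correction_factors(make_table(v3))
  expect_equal(unname(cf3$factors), c(1, 1.2, 0.9), tolerance = 1e-12)
})

test_that("correction is idempotent against its reference anchor", {
  set.seed(2)
  v <- matrix(exp(rnorm(26 * 10, 0, 0.1)), nrow = 10) *
    exp(rnorm(10, 0, 0.1))  # row-wise calibration error
  first <- correction_factors(make_table(v))
  second <- correction_factors(first$corrected,
                               reference_medians = first$reference_medians)
  expect_lt(max(abs(second$factors - 1)), 1e-12)
  # recomputing the anchor from corrected data moves factors only marginally
  refit <- correction_factors(first$corrected)
  expect_lt(max(abs(refit$factors - 1)), 0.05)
})

test_that("per-batch CV is exact on closed-form columns and scale-invariant", {
  v <- cbind(a = c(9, 10, 11), b = c(5, 5, 5))
  cvs <- batch_cv(make_table(v))
  expect_equal(cvs$cv[cvs$protein == "a"], 0.1, tolerance = 1e-12)
  expect_identical(cvs$cv[cvs$protein == "b"], 0)
  # scaling a column leaves its CV unchanged exactly
  cvs2 <- batch_cv(make_table(v * 1000))
  expect_identical(cvs$cv, cvs2$cv)
})

test_that("undersized groups are dropped with a warning", {
  v <- matrix(runif(12, 1, 2), nrow = 4,
              dimnames = list(NULL, c("p1", "p2", "p3")))
  se <- abundance_table(v, sample_meta = data.frame(
    batch = c("b1", "b1", "b1", "b2")))
  expect_warning(cvs <- batch_cv(se), "fewer than 2")
  expect_identical(unique(cvs$group), "b1")
})

test_that("bootstrap CI behaves on degenerate and growing samples", {
  expect_identical(unname(bootstrap_cv(rep(3, 10), 200)), c(0, 0))
  set.seed(3)
  x60 <- exp(rnorm(60, 0, 0.09))
  set.seed(3)
  ci10 <- bootstrap_cv(x60[1:10], 1000)
  set.seed(3)
  ci60 <- bootstrap_cv(x60, 1000)
  expect_lt(diff(ci60), diff(ci10))
})

test_that("bootstrap CI covers the generating CV at the nominal rate", {
  set.seed(4)
  true_cv <- sqrt(exp(0.09^2) - 1)
  hits <- 0
  for (i in 1:100) {
    x <- exp(rnorm(60, 0, 0.09))
    ci <- bootstrap_cv(x, 500)
    hits <- hits + (ci[1] <= true_cv && true_cv <= ci[2])
  }
  expect_gte(hits, 88)
})

test_that("pairwise correlations match cor.test and the BH oracle", {
  set.seed(5)
  v <- matrix(exp(rnorm(20 * 4, 0, 0.2)), nrow = 20,
              dimnames = list(NULL, c("p1", "p2", "p3", "p4")))
  v[, "p2"] <- v[, "p1"]  # duplicated column
  pc <- pairwise_correlations(make_table(v))
  row12 <- pc[pc$protein_1 == "p1" & pc$protein_2 == "p2", ]
  expect_equal(row12$r, 1, tolerance = 1e-12)
  expect_lt(row12$p, 1e-12)
  # p-values equal cor.test's
  ct <- cor.test(v[, "p1"], v[, "p3"])
  row13 <- pc[pc$protein_1 == "p1" & pc$protein_2 == "p3", ]
  expect_equal(row13$p, ct$p.value, tolerance = 1e-12)
  # adjustment equals the literal step-up oracle
  expect_equal(pc$p_adj, bh_oracle(pc$p), tolerance = 1e-12)
})

test_that("BH adjustment equals the step-up oracle on random vectors", {
  set.seed(6)
  for (m in c(1, 4, 37, 1000)) {
    p <- runif(m)^2
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
  # worked example: four p-values all collapse to 0.04
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
})

test_that("correlation p-values agree with a permutation null", {
  set.seed(7)
  x <- rnorm(15)
  y <- 0.6 * x + rnorm(15, 0, 0.8)
  r_obs <- cor(x, y)
  perm <- replicate(10000, abs(cor(x, sample(y))) >= abs(r_obs))
  p_perm <- mean(perm)
  p_t <- cor.test(x, y)$p.value
  expect_equal(p_t, p_perm, tolerance = 3 * sqrt(p_perm * (1 - p_perm) / 10000) +
                 0.2 * p_perm + 1e-4)
})

test_that("a planted correlated pair is the one recovered at BH 0.05", {
  set.seed(8)
  proteins <- default_egg_proteins(0.08)
  proteins$is_cycling <- FALSE  # flat profiles: no cycling-induced correlation
  layout <- data.frame(batch = rep("b1", 120), timepoint = rep(60, 120))
  hits_planted <- 0
  false_pos <- 0
  n_rep <- 20
  for (i in seq_len(n_rep)) {
    cfg <- egg_config("egg120", proteins = proteins,
                      correlation = plant_correlation(proteins$name,
                                                      list(list("MEK", "ERK", 0.7))),
                      seed = 100 + i)
    ds <- generate_egg_dataset(cfg)
    pc <- pairwise_correlations(correction_factors(ds$table)$corrected)
    planted <- pc$protein_1 == "MEK" & pc$protein_2 == "ERK"
    hits_planted <- hits_planted + pc$significant[planted]
    false_pos <- false_pos + sum(pc$significant[!planted])
  }
  expect_identical(hits_planted, n_rep)          # r = 0.7 at n = 120: certain
  expect_lt(false_pos / n_rep, 2)                # BH keeps false hits rare
})

test_that("technical floor comparison flags indistinguishable proteins", {
  tech <- data.frame(protein = c("a", "b"), cv = c(0.05, 0.05),
                     ci_lo = c(0.04, 0.04), ci_hi = c(0.06, 0.06))
  bio_same <- tech
  cmp <- technical_vs_biological(tech, bio_same)
  expect_true(all(cmp$ratio == 1))
  expect_true(all(cmp$at_technical_floor))

  bio_hi <- data.frame(protein = c("a", "b"), cv = c(0.10, 0.12),
                       ci_lo = c(0.08, 0.10), ci_hi = c(0.12, 0.14))
  cmp2 <- technical_vs_biological(tech, bio_hi)
  expect_false(any(cmp2$at_technical_floor))
  expect_equal(cmp2$ratio, c(2, 2.4))
  expect_error(technical_vs_biological(tech, bio_hi[1, ]), "do not match")
})

test_that("2N gating keeps the lower DNA mode and applies the radius filter", {
  set.seed(9)
  n <- 2000
  mode <- sample(1:2, n, replace = TRUE)
  cells <- data.frame(dna = c(2, 4)[mode] * exp(rnorm(n, 0, 0.05)),
                      x = runif(n, 0, 1080), y = runif(n, 0, 1080))
  g <- gate_g1(cells)
  expect_equal(nrow(g) / n, mean(mode == 1), tolerance = 0.03)
  expect_true(all(g$dna < 3))
  expect_equal(attr(g, "dna_mode"), 2, tolerance = 0.05)

  # single tight mode: everything retained
  one <- data.frame(dna = rep(2, 50))
  expect_identical(nrow(gate_g1(one)), 50L)

  # corner cell dropped by the radius filter regardless of DNA
  corner <- data.frame(dna = rep(2, 3), x = c(540, 540, 1070),
                       y = c(540, 600, 1070))
  g2 <- gate_g1(corner, radius_limit = 350, image_center = c(540, 540))
  expect_identical(nrow(g2), 2L)
})

test_that("mass normalization removes the common volume factor", {
  cells <- data.frame(mass_stain = c(1, 2, 4), mek = c(2, 4, 8))
  out <- normalize_by_mass(cells, "mek")
  expect_true(all(out$mek_conc == 2))
  # doubling both channels leaves concentration unchanged
  cells2 <- transform(cells, mass_stain = mass_stain * 2, mek = mek * 2)
  expect_identical(normalize_by_mass(cells2, "mek")$mek_conc, out$mek_conc)
  expect_error(normalize_by_mass(data.frame(mek = 1), "mek"), "mass_stain")
})

test_that("integrated activity is the post-stimulus area under the curve", {
  t <- seq(0, 60, by = 2)
  expect_equal(integrated_activity(t, rep(1.5, length(t)), 10), 1.5 * 50)
  expect_error(integrated_activity(t, rep(1, length(t)), 60), "positive length")
  expect_error(integrated_activity(t, 1:5, 0), "equal length")
  # baseline subtraction removes the pre-stimulus mean
  ratio <- c(rep(1, 5), rep(2, 26))
  expect_equal(integrated_activity(t, ratio, 10, baseline_subtract = TRUE),
               1 * 50)
})

test_that("bimodal activity scores are thresholded between the modes", {
  set.seed(10)
  auc <- c(rnorm(150, 40, 4), rnorm(150, 90, 6))
  thr <- activity_threshold(auc)
  expect_gt(thr, 50)
  expect_lt(thr, 80)
  expect_error(activity_threshold(rnorm(200)), "unimodal")
})

test_that("extreme-group comparison splits exactly and detects differences", {
  # deterministic: fraction 0.5 on 10 sorted distinct values
  res <- compare_extremes(1:10, (1:10) * 2, fraction = 0.5)
  expect_identical(res$summary$n, c(5L, 5L))
  expect_identical(res$summary$median[res$summary$group == "top"], 16)
  expect_identical(res$summary$median[res$summary$group == "bottom"], 6)
  expect_equal(res$summary$notch,
               1.58 * (res$summary$q3 - res$summary$q1) / sqrt(5))

  # activity increasing with concentration: top group richer
  set.seed(11)
  conc <- exp(rnorm(400, 0, 0.2))
  score <- conc * exp(rnorm(400, 0, 0.1))
  res2 <- compare_extremes(score, conc)
  expect_gt(res2$summary$median[res2$summary$group == "top"],
            res2$summary$median[res2$summary$group == "bottom"])
  expect_lt(res2$p_value, 1e-6)
  expect_error(compare_extremes(1:5, 1:5, fraction = 0.1), "too few")
})
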