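test_that("a noise-free, BSV-free cohort reproduces the closed forms exactly", {
  coh <- generate_cohort(noiseless_config(n_pairs = 3), seed = 7)
  obs <- coh$observations
  tr <- coh$truth
  for (i in seq_len(nrow(tr))) {
    p <- kinetic_params(tr$k_mm[i], tr$V_m[i], tr$CL_mb[i], tr$CL_bo[i], tr$V_b[i])
    sub <- obs[obs$pair_id == tr$pair_id[i], ]
    expect_equal(sub$enrichment_mg_per_kg,
                 predict_enrichment(tr$dose_g[i], p, sub$time_days, sub$role),
                 tolerance = 1e-12)
  }
})

test_that("covariate distributions match their configured medians", {
  coh <- generate_cohort(cohort_config(n_pairs = 2000), seed = 11)
  expect_equal(median(coh$truth$MWT_kg), 57, tolerance = 0.02)
  expect_equal(median(coh$truth$BWT_start_kg), 6.3, tolerance = 0.04)
  # dose range honoured and tied to assay sensitivity
  expect_true(all(coh$truth$dose_g >= 6 & coh$truth$dose_g <= 60))
  expect_true(all(coh$truth$dose_g[coh$truth$assay == "IRMS"] < 30))
  expect_true(all(coh$truth$dose_g[coh$truth$assay == "FTIR"] >= 30))
})

test_that("the non-EBF fraction lands inside binomial 99% bounds", {
  n <- 1000
  coh <- generate_cohort(cohort_config(n_pairs = n, fraction_non_ebf = 0.33),
                         seed = 13)
  k <- sum(coh$truth$true_class == "non-EBF")
  bounds <- stats::qbinom(c(0.005, 0.995), n, 0.33)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("truth and observations agree on pairs, and labels on Rs", {
  coh <- generate_cohort(cohort_config(n_pairs = 50), seed = 3)
  expect_setequal(unique(coh$observations$pair_id), coh$truth$pair_id)
  expect_equal(coh$truth$true_class,
               ifelse(coh$truth$true_rs > 86.6, "non-EBF", "EBF"))
  # reproducible under the same seed
  coh2 <- generate_cohort(cohort_config(n_pairs = 50), seed = 3)
  expect_identical(coh$observations, coh2$observations)
})

test_that("missingness is MCAR with the requested day profile", {
  coh <- generate_cohort(cohort_config(n_pairs = 40), seed = 2)
  obs <- coh$observations
  expect_identical(apply_missingness(obs, 0, seed = 1), obs)
  days <- sort(unique(obs$time_days))
  p <- ifelse(days == 5, 1, 0)
  dropped <- apply_missingness(obs, p, seed = 1)
  expect_false(any(dropped$time_days == 5))
  expect_equal(nrow(dropped), nrow(obs) - sum(obs$time_days == 5))
  # 30% everywhere: retention within 99% binomial bounds
  kept <- apply_missingness(obs, 0.3, seed = 9)
  bounds <- stats::qbinom(c(0.005, 0.995), nrow(obs), 0.7)
  expect_gte(nrow(kept), bounds[1])
  expect_lte(nrow(kept), bounds[2])
  # reproducible pattern
  expect_identical(apply_missingness(obs, 0.3, seed = 9), kept)
  expect_error(apply_missingness(obs, 1.2, seed = 1), "\\[0, 1\\]")
})

test_that("the cohort split is a stratified partition with calibration exempt", {
  coh <- generate_cohort(cohort_config(n_pairs = 790), seed = 17)
  s <- split_cohort(coh$truth, fraction_holdout = 1 / 3, seed = 5)
  expect_setequal(c(s$model_building$pair_id, s$design_evaluation$pair_id),
                  coh$truth$pair_id)
  expect_length(intersect(s$model_building$pair_id,
                          s$design_evaluation$pair_id), 0)
  # calibration-country pairs never held out
  expect_false(any(s$design_evaluation$country == "Indonesia"))
  # sizes near the 565 / 225 field split (third of the non-calibration pairs)
  n_field <- sum(coh$truth$country != "Indonesia")
  expect_lt(abs(nrow(s$design_evaluation) - n_field / 3), 6)
  expect_lt(abs(nrow(s$design_evaluation) - 225), 25)
  expect_lt(abs(nrow(s$model_building) - 565), 25)
  # two pairs from one country, fraction 1/2: one each
  two <- coh$truth[coh$truth$country == "Kenya", ][1:2, ]
  s2 <- split_cohort(two, 0.5, seed = 1)
  expect_equal(nrow(s2$model_building), 1)
  expect_equal(nrow(s2$design_evaluation), 1)
  expect_error(split_cohort(coh$truth[1, ], 0.5), "at least 2")
  expect_error(split_cohort(coh$truth, 1.5), "strictly")
})

test_that("infeasible configurations are rejected up front", {
  expect_error(cohort_config(n_pairs = 0), "n_pairs")
  expect_error(cohort_config(fraction_non_ebf = 1.2), "fraction_non_ebf")
  expect_error(cohort_config(day_grid = c(3, 2)), "increasing")
  expect_error(cohort_config(p_missing = -0.1), "p_missing")
})

test_that("the alternative non-EBF mechanism inflates infant clearance", {
  cfg <- cohort_config(n_pairs = 200, non_ebf_mechanism = "clbo_inflate")
  coh <- generate_cohort(cfg, seed = 23)
  tr <- coh$truth
  expect_equal(tr$true_class, ifelse(tr$true_rs > 86.6, "non-EBF", "EBF"))
  expect_gt(mean(tr$CL_bo[tr$true_class == "non-EBF"]),
            mean(tr$CL_bo[tr$true_class == "EBF"]))
})
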