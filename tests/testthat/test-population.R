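test_that("covariate models vanish at the reference value and with code 0", {
  meta <- tibble::tibble(MWT_kg = c(70, 57), BWT_kg = c(5, 6), flag = c(0, 1))
  X <- ebfdtm:::design_matrix(
    "ln_V_m", list(ln_V_m = list(covariate = "MWT_kg", type = "continuous",
                                 median = 70)), meta)
  # at the median the covariate term contributes exactly zero
  expect_equal(unname(X[1, 2]), 0)
  expect_equal(unname(X[2, 2]), log(57 / 70))
  Xc <- ebfdtm:::design_matrix(
    "ln_CL_bo", list(ln_CL_bo = list(covariate = "flag", type = "categorical")),
    meta)
  # category coded 0 reduces the model to the intercept alone
  expect_equal(unname(Xc[1, 2]), 0)
  expect_equal(unname(Xc[2, 2]), 1)
})

test_that("population fit validates inputs", {
  coh <- generate_cohort(cohort_config(n_pairs = 4), seed = 2)
  one <- coh$observations[coh$observations$pair_id == "P0001", ]
  expect_error(fit_population(one), "at least 2")
  bad_cov <- list(ln_V_m = list(covariate = "SHOE_SIZE", type = "continuous",
                                median = 40))
  expect_error(fit_population(coh$observations, covariates = bad_cov),
               "SHOE_SIZE")
})

test_that("a hierarchical fit recovers population truths on a rich design", {
  coh <- generate_cohort(cohort_config(n_pairs = 80), seed = 61)
  pf <- fit_population(coh$observations, build_prior("low_information"),
                       n_chains = 2, n_warmup = 400, n_samples = 400, seed = 3)
  td <- tidy(pf)
  est <- function(nm) td[td$parameter == nm, ]
  # covariate slope on mother weight -> V_m: generating value inside the CI
  sl <- est("theta2_ln_V_m_MWT_kg")
  expect_gt(0.46, sl$conf.low - 0.25)
  expect_lt(sl$conf.low, 0.46)
  expect_gt(sl$conf.high, 0.46)
  # typical k_mm close to the generating -2.18
  expect_equal(est("theta1_ln_k_mm")$estimate, -2.18, tolerance = 0.05)
  # BSV SDs in the right range
  expect_equal(est("omega_ln_k_mm")$estimate, 0.18, tolerance = 0.35)
  # residual sigma1 per assay recovered roughly
  expect_equal(est("sigma1_g1")$estimate, 0.04, tolerance = 0.3)
  expect_equal(est("sigma1_g2")$estimate, 0.08, tolerance = 0.3)
})

test_that("per-pair posteriors extracted from a population fit classify like truth", {
  coh <- generate_cohort(cohort_config(n_pairs = 40), seed = 71)
  pf <- fit_population(coh$observations, build_prior("mixed"),
                       n_chains = 2, n_warmup = 600, n_samples = 600, seed = 5)
  fits <- as_pair_fits(pf)
  expect_s3_class(fits, "dtm_fits")
  expect_equal(length(fits$fits), 40)
  cls <- classify_pairs(fits, seed = 6)
  agree <- mean(cls$label == coh$truth$true_class)
  expect_gt(agree, 0.85)
  # glance/tidy plumbing
  g <- glance(pf)
  expect_equal(g$n_pairs, 40)
  expect_s3_class(tidy(fits$fits[[1]]), "tbl_df")
})
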