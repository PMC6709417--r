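test_that("rhat is ~1 for identical chains and flags separated ones", {
  x <- matrix(rnorm(2000), ncol = 2)
  x[, 2] <- x[, 1]  # identical draw sequences
  expect_equal(rhat(x), 1, tolerance = 1e-3)
  y <- cbind(rnorm(500), rnorm(500) + 10)
  expect_gt(rhat(y), 2)
  expect_equal(rhat(matrix(5, 100, 3)), 1)  # constant chains
  expect_error(rhat(matrix(1:10, ncol = 1)), "2 chains")
})

test_that("fit_pair validates its inputs", {
  coh <- generate_cohort(cohort_config(n_pairs = 2), seed = 1)
  po <- coh$observations[coh$observations$pair_id == "P0001", ]
  expect_error(fit_pair(po[0, ]), "zero post-dose")
  expect_error(fit_pair(po, n_chains = 1), "at least 2 chains")
  expect_error(fit_pair(coh$observations), "exactly one pair")
})

test_that("a rich noiseless design recovers the simulation truth", {
  coh <- generate_cohort(noiseless_config(n_pairs = 2), seed = 42)
  po <- coh$observations[coh$observations$pair_id == "P0001", ]
  tr <- coh$truth[1, ]
  f <- fit_pair(po, build_prior("low_information"),
                residual_model(sigma1 = 0.05, sigma2 = 1), seed = 7)
  expect_true(f$stable)
  est <- tidy(f)
  truth <- c(CL_bo = tr$CL_bo, CL_mb = tr$CL_mb, V_m = tr$V_m, k_mm = tr$k_mm)
  rel <- abs(est$estimate - truth[est$parameter]) / truth[est$parameter]
  expect_true(all(rel < 0.05))
})

test_that("fits are reproducible under a fixed seed", {
  coh <- generate_cohort(cohort_config(n_pairs = 1), seed = 3)
  po <- coh$observations
  f1 <- fit_pair(po, seed = 11, n_warmup = 200, n_samples = 200)
  f2 <- fit_pair(po, seed = 11, n_warmup = 200, n_samples = 200)
  expect_identical(f1$draws, f2$draws)
})

test_that("one paired sample leaves the clearances unresolved (unstable chains)", {
  coh <- generate_cohort(cohort_config(n_pairs = 1), seed = 5)
  po <- coh$observations[coh$observations$time_days == 5, ]
  unstable <- vapply(1:10, function(s) {
    !fit_pair(po, build_prior("mixed"), default_residual(),
              n_warmup = 400, n_samples = 400, seed = s)$stable
  }, logical(1))
  expect_gt(mean(unstable), 0.5)
})

test_that("with an uninformative observation the posterior returns the prior", {
  # a single observation drowned in noise contributes ~no information
  coh <- generate_cohort(cohort_config(n_pairs = 1), seed = 9)
  po <- coh$observations[1, ]
  pr <- build_prior("informative")
  f <- fit_pair(po, pr, residual_model(sigma1 = 0, sigma2 = 1e7),
                n_warmup = 2000, n_samples = 2000, seed = 2)
  ip <- individual_prior(pr)
  ln_draws <- log(as.matrix(f$draws[, c("k_mm", "V_m", "CL_mb", "CL_bo")]))
  expect_equal(unname(colMeans(ln_draws)), ip$mean, tolerance = 0.03)
  expect_equal(unname(apply(ln_draws, 2, sd)), ip$sd, tolerance = 0.12)
})

test_that("adding sampling days contracts the clearance posterior", {
  cfg <- noiseless_config(n_pairs = 1)
  wins <- vapply(1:5, function(s) {
    coh <- generate_cohort(cfg, seed = 100 + s)
    po <- coh$observations
    few <- po[po$time_days %in% c(5, 13), ]
    many <- po[po$time_days %in% c(2, 5, 9, 13), ]
    res <- residual_model(sigma1 = 0.05, sigma2 = 1)
    f_few <- fit_pair(few, build_prior("mixed"), res, seed = s)
    f_many <- fit_pair(many, build_prior("mixed"), res, seed = s)
    sd(log(f_many$draws$CL_bo)) <= sd(log(f_few$draws$CL_bo))
  }, logical(1))
  expect_gte(mean(wins), 0.6)
})

test_that("outlier filtering applies the strict 40%-of-body-weight rule", {
  pm <- tibble::tibble(
    pair_id = c("A", "B", "C"),
    k_mm = 0.11, V_m = 31, CL_mb = 0.8,
    CL_bo = c(0.41 * 6, 0.40 * 6, 0.30 * 6),
    V_b = 3.6, stable = TRUE
  )
  w <- tibble::tibble(pair_id = c("A", "B", "C"),
                      BWT_start_kg = 6, BWT_end_kg = 6)
  flt <- filter_outliers(pm, weights = w)
  expect_equal(flt$excluded$pair_id, "A")        # 0.41 > 0.40 excluded
  expect_setequal(flt$retained, c("B", "C"))     # boundary 0.40 retained
  # no violations: identity
  flt2 <- filter_outliers(pm[3, ], weights = w[3, ])
  expect_equal(flt2$retained, "C")
  expect_equal(nrow(flt2$excluded), 0)
})

test_that("iVPC bands are ordered, centred and degenerate without noise", {
  coh <- generate_cohort(cohort_config(n_pairs = 1), seed = 21)
  f <- fit_pair(coh$observations, n_warmup = 300, n_samples = 300, seed = 2)
  bands <- ivpc(f, time_grid = seq(0.5, 14, by = 0.5), n_sim = 400, seed = 3)
  expect_true(all(bands$q2.5 <= bands$median + 1e-9))
  expect_true(all(bands$median <= bands$q97.5 + 1e-9))
  # single repeated draw + zero noise: all three curves equal the prediction
  f1 <- f
  f1$draws <- f$draws[rep(1, 50), ]
  b0 <- ivpc(f1, residual = residual_model(sigma1 = 0, sigma2 = 0),
             time_grid = c(1, 5, 9), n_sim = 200, seed = 4)
  p <- kinetic_params(f$draws$k_mm[1], f$draws$V_m[1], f$draws$CL_mb[1],
                      f$draws$CL_bo[1], f$pair$V_b)
  pred <- predict_enrichment(f$pair$dose_g, p, b0$time_days, b0$role)
  expect_equal(b0$q2.5, pred, tolerance = 1e-10)
  expect_equal(b0$q97.5, pred, tolerance = 1e-10)
  expect_warning(ivpc(f, n_sim = 50, seed = 1), "n_sim")
})

test_that("iVPC bands cover held-out noisy observations at the nominal rate", {
  cfg <- cohort_config(n_pairs = 1, bsv = c(k_mm = 0, V_m = 0, CL_bo = 0))
  coh <- generate_cohort(cfg, seed = 31)
  tr <- coh$truth[1, ]
  f <- fit_pair(coh$observations, build_prior("mixed"), default_residual(),
                n_warmup = 500, n_samples = 500, seed = 6)
  bands <- ivpc(f, time_grid = c(1:9, 13, 14), n_sim = 2000, seed = 7)
  # simulate fresh replicate observations from the truth and count coverage
  set.seed(8)
  p <- kinetic_params(tr$k_mm, tr$V_m, tr$CL_mb, tr$CL_bo, tr$V_b)
  n_rep <- 200
  sig <- residual_sigmas(default_residual(), tr$assay)
  hits <- 0; total <- 0
  for (r in seq_len(n_rep)) {
    pred <- predict_enrichment(tr$dose_g, p, bands$time_days, bands$role)
    y <- pred + rnorm(length(pred), 0, sqrt(pred^2 * sig[1]^2 + sig[2]^2))
    hits <- hits + sum(y >= bands$q2.5 & y <= bands$q97.5)
    total <- total + length(y)
  }
  expect_gt(hits / total, 0.90)
  expect_lt(hits / total, 0.995)
})
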