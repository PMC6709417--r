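test_that("family-A enumeration counts match the combinatorics", {
  expect_equal(nrow(enumerate_designs("A", size_min = 1, size_max = 1)), 11)
  expect_equal(nrow(enumerate_designs("A", size_min = 2, size_max = 2)), 55)
  all3 <- enumerate_designs("A", size_min = 1, size_max = 3)
  expect_equal(nrow(all3), 11 + 55 + choose(11, 3))
  expect_false(any(duplicated(all3$design)))
  # deterministic order: sizes ascending, then lexicographic on days
  expect_identical(all3, enumerate_designs("A", size_min = 1, size_max = 3))
  expect_equal(all3$design[1:3], c("1", "2", "3"))
})

test_that("family-B designs respect span and latest-day constraints", {
  b3 <- enumerate_designs("B", size_min = 2, size_max = 2, max_span = 3,
                          last_day = 9)
  expect_true("5+7" %in% b3$design)    # span 7-5+1 = 3
  expect_false("5+9" %in% b3$design)   # span 5 > 3
  expect_true(all(vapply(b3$days, function(d) max(d) <= 9, logical(1))))
  expect_true(all(vapply(b3$days, function(d) max(d) - min(d) + 1 <= 3,
                         logical(1))))
  expect_error(enumerate_designs("B", size_min = 2, size_max = 2,
                                 max_span = 1, last_day = 2), "no design")
  expect_error(enumerate_designs("A", grid = numeric(0)), "empty")
})

make_fitted_cohort <- function(n_pairs = 3, seed = 19) {
  coh <- generate_cohort(noiseless_config(n_pairs = n_pairs), seed = seed)
  fits <- fit_pairs(coh$observations, build_prior("mixed"),
                    residual_model(sigma1 = 0.05, sigma2 = 1),
                    n_warmup = 400, n_samples = 400, seed = seed + 1)
  list(coh = coh, fits = fits)
}

test_that("imputation balances the table and reproduces the forward model", {
  fc <- make_fitted_cohort()
  obs <- fc$coh$observations
  # remove day 6 for one pair, day 13 for another
  thin <- obs[!(obs$pair_id == "P0001" & obs$time_days == 6) &
                !(obs$pair_id == "P0002" & obs$time_days == 13), ]
  imp <- impute_full(thin, fc$fits)
  # exact balance: every pair x 11 days x 2 roles
  counts <- dplyr::count(imp$data, .data$pair_id)
  expect_true(all(counts$n == 22))
  # measured records pass through bit-identical
  merged <- dplyr::inner_join(
    thin, imp$data,
    by = c("pair_id", "role", "time_days"), suffix = c("", ".imp"))
  expect_identical(merged$enrichment_mg_per_kg,
                   merged$enrichment_mg_per_kg.imp)
  expect_true(all(!merged$imputed))
  # imputed cells equal the closed-form prediction on noiseless data
  tr <- fc$coh$truth[fc$coh$truth$pair_id == "P0001", ]
  p <- kinetic_params(tr$k_mm, tr$V_m, tr$CL_mb, tr$CL_bo, tr$V_b)
  cells <- imp$data[imp$data$imputed & imp$data$pair_id == "P0001", ]
  expect_equal(cells$enrichment_mg_per_kg,
               predict_enrichment(tr$dose_g, p, cells$time_days, cells$role),
               tolerance = 0.02)
  # and match an independent recomputation of the posterior-mean prediction
  f1 <- fc$fits$fits[["P0001"]]
  for (i in seq_len(nrow(cells))) {
    preds <- vapply(seq_len(nrow(f1$draws)), function(j) {
      pj <- kinetic_params(f1$draws$k_mm[j], f1$draws$V_m[j],
                           f1$draws$CL_mb[j], f1$draws$CL_bo[j], f1$pair$V_b)
      predict_enrichment(f1$pair$dose_g, pj, cells$time_days[i], cells$role[i])
    }, numeric(1))
    expect_equal(cells$enrichment_mg_per_kg[i], mean(preds), tolerance = 1e-6)
  }
  # already-balanced input: identity with an all-measured mask
  imp2 <- impute_full(obs, fc$fits)
  expect_false(any(imp2$data$imputed))
  expect_error(impute_full(obs, list(fits = fc$fits$fits[-1])), "P0001")
})

test_that("bootstrap streamlining keeps only design days and tracks sources", {
  fc <- make_fitted_cohort()
  imp <- impute_full(fc$coh$observations, fc$fits)
  des <- enumerate_designs("A", size_min = 2, size_max = 2)
  d713 <- des[des$design == "7+13", ]
  boot <- bootstrap_streamlined(imp, d713, seed = 3)
  expect_setequal(unique(boot$time_days), c(7, 13))
  counts <- dplyr::count(boot, .data$pair_id, .data$role)
  expect_true(all(counts$n == 2))
  expect_equal(length(unique(boot$pair_id)), nrow(fc$coh$truth))
  expect_true(all(boot$source_pair_id %in% fc$coh$truth$pair_id))
  # identity mode round-trips the full imputed data
  full <- tibble::tibble(design = "full", family = "A", size = 11,
                         days = list(imp$grid))
  rt <- bootstrap_streamlined(imp, full, seed = 1, resample = FALSE)
  expect_equal(nrow(rt), nrow(imp$data))
  expect_equal(rt$enrichment_mg_per_kg, imp$data$enrichment_mg_per_kg)
  expect_error(bootstrap_streamlined(imp, list(days = list(c(7, 21))), seed = 1),
               "outside")
})

test_that("bootstrap resampling has the expected unique-pair fraction", {
  fc0 <- generate_cohort(cohort_config(n_pairs = 200), seed = 29)
  imp <- list(data = fc0$observations, grid = c(1:9, 13, 14))
  class(imp) <- "imputed_dataset"
  imp$data$imputed <- FALSE
  d <- tibble::tibble(design = "7+13", family = "A", size = 2,
                      days = list(c(7, 13)))
  fracs <- vapply(1:20, function(s) {
    b <- bootstrap_streamlined(imp, d, seed = s)
    length(unique(b$source_pair_id)) / 200
  }, numeric(1))
  # E[unique fraction] = 1 - (1 - 1/n)^n ~ 0.632
  expect_gt(mean(fracs), 0.632 - 3 * 0.034 / sqrt(20))
  expect_lt(mean(fracs), 0.632 + 3 * 0.034 / sqrt(20))
})

test_that("ranking joins contexts, computes diffs, and is antisymmetric", {
  best <- tibble::tibble(
    design = c("7+13", "9+14"), family = "A", size = 2,
    sensitivity = c(0.98, 0.99), specificity = c(0.96, 0.96),
    stable_fraction = 1, n_scored = 60, failed = FALSE
  )
  evaluation <- dplyr::mutate(best, sensitivity = c(0.98, 0.98),
                              specificity = c(0.94, 0.89))
  v <- rank_and_validate(best, evaluation)
  expect_equal(v$diff_specificity[v$design == "9+14"], -0.07)
  expect_equal(v$diff_sensitivity[v$design == "7+13"], 0)
  # identical contexts: all diffs zero
  v0 <- rank_and_validate(best, best)
  expect_true(all(v0$diff_sensitivity == 0 & v0$diff_specificity == 0))
  # swapping contexts negates every diff
  vs <- rank_and_validate(evaluation, best)
  expect_equal(vs$diff_sensitivity, -v$diff_sensitivity[match(vs$design, v$design)])
  expect_equal(vs$diff_specificity, -v$diff_specificity[match(vs$design, v$design)])
  expect_error(rank_and_validate(best, evaluation[1, ]), "share")
})
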