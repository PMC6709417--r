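make_fit_stub <- function(CL_mb, CL_bo, n = length(CL_mb)) {
  draws <- tibble::tibble(
    chain = 1L, draw = seq_len(n),
    k_mm = 0.113, V_m = 31, CL_mb = CL_mb, CL_bo = CL_bo
  )
  structure(
    list(draws = draws,
         diagnostics = tibble::tibble(parameter = c("k_mm", "V_m", "CL_mb", "CL_bo"),
                                      rhat = 1),
         stable = TRUE,
         pair = tibble::tibble(pair_id = "S1", dose_g = 30, MWT_kg = 57,
                               BWT_start_kg = 6.3, BWT_end_kg = 6.5,
                               assay = "FTIR", V_b = 3.84),
         accept_rate = 0.3, prior = "mixed", residual = residual_model(),
         n_chains = 1, n_warmup = 0, n_samples = n, seed = 1),
    class = "dtm_fit")
}

test_that("Rs draws inherit the mass balance and its linearity", {
  f <- make_fit_stub(CL_mb = rep(0.8, 400), CL_bo = rep(0.85, 400))
  cfg0 <- classifier_config(ra_cv = 0, rg_sd = 0)
  rs <- rs_draws(f, cfg0, seed = 5)
  # degenerate posterior + fixed ancillaries: all draws identical
  expect_equal(length(unique(round(rs, 10))), 1)
  # shifting CL_bo by delta shifts every Rs draw by exactly 1000 * delta
  delta <- 0.02
  f2 <- make_fit_stub(CL_mb = rep(0.8, 400), CL_bo = rep(0.85 + delta, 400))
  rs2 <- rs_draws(f2, cfg0, seed = 5)
  expect_equal(rs2 - rs, rep(1000 * delta, 400))
})

test_that("the Monte-Carlo Rs mean matches the analytic mean", {
  set.seed(2)
  n <- 4000
  f <- make_fit_stub(CL_mb = 0.8 * exp(rnorm(n, 0, 0.1)),
                     CL_bo = 0.9 * exp(rnorm(n, 0, 0.1)), n = n)
  cfg <- classifier_config()
  rs <- rs_draws(f, cfg, seed = 6)
  ra_mean <- cfg$ra_fraction * 1000 * cfg$turnover_per_kg_water * f$pair$V_b
  rg_mean <- cfg$rg_water_fraction * (6.5 - 6.3) / 14 * 1000
  analytic <- 1000 * (mean(f$draws$CL_bo) - mean(f$draws$CL_mb)) +
    rg_mean - ra_mean * exp(log(1 + cfg$ra_cv^2) / 2)  # log-normal mean shift
  se <- sd(rs) / sqrt(n)
  expect_lt(abs(mean(rs) - analytic), 3 * se + 1)
})

test_that("the classification rule applies the strict threshold", {
  cfg <- classifier_config()
  # all draws above the cutoff: certain non-EBF
  expect_equal(classify_pair(rep(200, 100), cfg)$label, "non-EBF")
  # Pr = 0.85 < 0.9: EBF
  rs_085 <- c(rep(200, 85), rep(0, 15))
  cls <- classify_pair(rs_085, cfg)
  expect_equal(cls$pr_non_ebf, 0.85)
  expect_equal(cls$label, "EBF")
  # Pr = 0.9 exactly: EBF under the default strict comparator
  rs_090 <- c(rep(200, 90), rep(0, 10))
  expect_equal(classify_pair(rs_090, cfg)$label, "EBF")
  # and non-EBF under the >= reading
  cfg_ge <- classifier_config(strict = FALSE)
  expect_equal(classify_pair(rs_090, cfg_ge)$label, "non-EBF")
  expect_error(classify_pair(numeric(0)), "no Rs draws")
  expect_error(classifier_config(prob_threshold = 1), "prob_threshold")
  expect_error(classifier_config(rs_cutoff = -5), "rs_cutoff")
})

test_that("raising the cutoff or threshold never adds non-EBF labels", {
  set.seed(4)
  rs <- rnorm(1000, 100, 40)
  cutoffs <- seq(40, 200, by = 20)
  prs <- vapply(cutoffs, function(co) {
    classify_pair(rs, classifier_config(rs_cutoff = co))$pr_non_ebf
  }, numeric(1))
  expect_true(all(diff(prs) <= 0))
  thresholds <- c(0.5, 0.7, 0.9, 0.99)
  n_labels <- vapply(thresholds, function(th) {
    sum(classify_pair(rs, classifier_config(prob_threshold = th))$label == "non-EBF")
  }, numeric(1))
  expect_true(all(diff(n_labels) <= 0))
})

test_that("confusion counts and rates follow the reference definitions", {
  ref <- tibble::tibble(
    pair_id = sprintf("P%02d", 1:30),
    label = c(rep("non-EBF", 10), rep("EBF", 20))
  )
  test <- ref
  perfect <- score_against_reference(test, ref)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$tp + perfect$tn + perfect$fp + perfect$fn, 30)
  # flip 1 of 10 positives and 2 of 20 negatives: 0.9 / 0.9
  flipped <- ref
  flipped$label[1] <- "EBF"
  flipped$label[c(11, 12)] <- "non-EBF"
  sc <- score_against_reference(flipped, ref)
  expect_equal(sc$sensitivity, 0.9)
  expect_equal(sc$specificity, 0.9)
  # degenerate reference: flagged NaN with a warning
  ref_all_ebf <- dplyr::mutate(ref, label = "EBF")
  expect_warning(sc2 <- score_against_reference(ref_all_ebf, ref_all_ebf),
                 "sensitivity undefined")
  expect_true(is.nan(sc2$sensitivity))
  expect_equal(sc2$specificity, 1)
  # mismatched pair sets are an error naming the missing ids
  expect_error(score_against_reference(test[-1, ], ref), "P01")
})
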