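test_that("mother curve has the right dose scaling, decay and limits", {
  p <- kinetic_params(k_mm = 0.113, V_m = 30, CL_mb = 0.9, CL_bo = 0.95, V_b = 3.8)
  expect_equal(mother_enrichment(30, p, 0), 1000)
  expect_equal(mother_enrichment(30, p, 1e6), 0, tolerance = 1e-12)
  t <- seq(0, 14, by = 0.5)
  y <- mother_enrichment(30, p, t)
  expect_true(all(diff(y) < 0))
})

test_that("closed forms match an adaptive ODE integration", {
  p <- kinetic_params(k_mm = 0.113, V_m = 31.5, CL_mb = 0.9, CL_bo = 0.95, V_b = 3.8)
  times <- c(1:9, 13, 14)
  ode <- ode_curves(30, p, times)
  expect_equal(mother_enrichment(30, p, 7), ode$mother[times == 7],
               tolerance = 1e-8)
  expect_equal(infant_enrichment(30, p, times), unname(ode$infant),
               tolerance = 1e-7)
})

test_that("infant curve is zero at dose time, non-negative, single-peaked", {
  p <- test_params()
  expect_equal(infant_enrichment(30, p, 0), 0)
  t <- seq(0, 30, by = 0.05)
  y <- infant_enrichment(30, p, t)
  expect_true(all(y >= 0))
  peak <- which.max(y)
  expect_true(all(diff(y[seq_len(peak)]) >= 0))
  expect_true(all(diff(y[peak:length(y)]) <= 0))
})

test_that("equal elimination rates hit the removable-singularity branch", {
  Vb <- 3.8
  k <- 0.2
  p_eq <- kinetic_params(k_mm = k, V_m = 31.5, CL_mb = 0.9, CL_bo = k * Vb, V_b = Vb)
  p_near <- kinetic_params(k_mm = k, V_m = 31.5, CL_mb = 0.9,
                           CL_bo = k * (1 + 1e-9) * Vb, V_b = Vb)
  t <- c(0.5, 2, 5, 10)
  expect_equal(infant_enrichment(30, p_eq, t), infant_enrichment(30, p_near, t),
               tolerance = 1e-6)
})

test_that("infant uptake balances breastmilk delivery from the mother", {
  # mass balance over [0, T]: amount in the infant pool plus amount the
  # infant eliminated equals CL_mb * integral of the mother concentration
  p <- test_params()
  T_end <- 10
  delivered <- p$CL_mb *
    stats::integrate(function(t) mother_enrichment(30, p, t), 0, T_end,
                     rel.tol = 1e-10)$value
  eliminated <- p$CL_bo *
    stats::integrate(function(t) infant_enrichment(30, p, t), 0, T_end,
                     rel.tol = 1e-10)$value
  in_pool <- p$V_b * infant_enrichment(30, p, T_end)
  expect_equal(in_pool + eliminated, delivered, tolerance = 1e-6)
})

test_that("Rs mass balance is exact and linear in its arguments", {
  p <- kinetic_params(0.113, 31.5, 0.80, 0.85, 3.8)
  expect_equal(compute_rs(p, ancillary_rates(R_a = 25, R_g = 20)), 45)
  # balanced budget
  p0 <- kinetic_params(0.113, 31.5, 0.85, 0.85, 3.8)
  expect_equal(compute_rs(p0, ancillary_rates(R_a = 20, R_g = 20)), 0)
  # raising CL_bo by delta raises Rs by exactly 1000 * delta
  delta <- 0.037
  p1 <- kinetic_params(0.113, 31.5, 0.80, 0.85 + delta, 3.8)
  anc <- ancillary_rates(R_a = 25, R_g = 20)
  expect_equal(compute_rs(p1, anc) - compute_rs(p, anc), 1000 * delta)
  # and is linear in R_g and R_a with unit coefficients
  expect_equal(compute_rs(p, ancillary_rates(R_a = 25, R_g = 21)) -
                 compute_rs(p, anc), 1)
  expect_equal(compute_rs(p, ancillary_rates(R_a = 26, R_g = 20)) -
                 compute_rs(p, anc), -1)
})

test_that("invalid kinetic inputs fail loudly naming the offending field", {
  expect_error(kinetic_params(-0.1, 30, 0.9, 0.95, 3.8), "k_mm")
  expect_error(kinetic_params(0.1, 30, 0.9, Inf, 3.8), "CL_bo")
  p <- test_params()
  expect_error(mother_enrichment(-5, p, 1), "dose")
  expect_error(infant_enrichment(30, p, -1), "non-negative")
  expect_error(ancillary_rates(R_a = -1, R_g = 0), "R_a")
})

test_that("default ancillary rates follow turnover and weight change", {
  anc <- default_ancillary(CL_bo = 1, bwt_start = 6.3, bwt_end = 6.58,
                           duration = 14)
  expect_equal(anc$R_a, 63)
  expect_equal(anc$R_g, 0.73 * 0.28 / 14 * 1000)
  # weight loss gives negative growth retention
  anc2 <- default_ancillary(1, 6.3, 6.0, 14)
  expect_lt(anc2$R_g, 0)
})
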