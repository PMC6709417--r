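# Shared fixtures, built in code.

default_residual <- function() {
  residual_model(sigma1 = c(0.04, 0.08), sigma2 = c(1.5, 3),
                 group = c("IRMS", "FTIR"))
}

# Deterministic parameter set used across forward-model tests.
test_params <- function() {
  kinetic_params(k_mm = 0.113, V_m = 31.5, CL_mb = 0.9, CL_bo = 0.95, V_b = 3.8)
}

# A noise-free, BSV-free cohort: observations equal the closed-form curves.
noiseless_config <- function(n_pairs = 4, ...) {
  cohort_config(
    n_pairs = n_pairs,
    bsv = c(k_mm = 0, V_m = 0, CL_bo = 0),
    sigma1 = c(IRMS = 0, FTIR = 0), sigma2 = c(IRMS = 0, FTIR = 0),
    rs_ebf_sd = 0, ...
  )
}

# Numerically integrate the linked two-compartment system with deSolve
# (adaptive LSODA): an independent oracle for the closed forms.
ode_curves <- function(dose, params, times) {
  k_bb <- params$CL_bo / params$V_b
  rhs <- function(t, y, p) {
    dAm <- -params$k_mm * y[1]
    dAb <- params$CL_mb * y[1] / params$V_m - k_bb * y[2]
    list(c(dAm, dAb))
  }
  out <- deSolve::lsoda(c(Am = dose * 1000, Ab = 0), c(0, times), rhs,
                        parms = NULL, rtol = 1e-11, atol = 1e-11)
  out <- out[-1, , drop = FALSE]
  list(mother = out[, "Am"] / params$V_m, infant = out[, "Ab"] / params$V_b)
}
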