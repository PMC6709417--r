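#' Default covariate structure for the population model
#'
#' Log-linear covariate models of the standard allometric form: a
#' continuous covariate enters as
#' `ln(theta_i) = ln(theta1) + theta2 ln(cov_i / cov_median)`
#' and a categorical (0/1) covariate as
#' `ln(theta_i) = ln(theta1) + cov_i ln(theta2)`.
#' The default ties mother weight to her volume of distribution and infant
#' weight to the infant's water clearance.
#'
#' The reference values default to this package's synthetic-population
#' medians (mother 57 kg, infant 6.4 kg). The intercept of each covariate
#' model is the typical value at the reference covariate, so when an
#' informative prior regime pins a typical value the reference must be the
#' population's own median for the prior and the data to cohere.
#'
#' @param vm_median,clbo_median Reference (median) covariate values.
#' @return Named list keyed by log-parameter; each entry a list with
#'   `covariate`, `type` (`"continuous"`/`"categorical"`) and `median`.
#' @export
default_covariates <- function(vm_median = 57, clbo_median = 6.4) {
  list(
    ln_V_m = list(covariate = "MWT_kg", type = "continuous", median = vm_median),
    ln_CL_bo = list(covariate = "BWT_kg", type = "continuous", median = clbo_median)
  )
}

## Per-pair data bundle used by the Gibbs sweeps.
prepare_pop_data <- function(observations, residual, water_fraction) {
  meta <- observations |>
    dplyr::distinct(.data$pair_id, .data$dose_g, .data$MWT_kg,
                    .data$BWT_start_kg, .data$BWT_end_kg, .data$assay) |>
    dplyr::mutate(
      BWT_kg = (.data$BWT_start_kg + .data$BWT_end_kg) / 2,
      V_b = infant_water_volume(.data$BWT_start_kg, .data$BWT_end_kg, water_fraction)
    )
  obs <- dplyr::arrange(observations,
                        match(.data$pair_id, meta$pair_id), .data$role,
                        .data$time_days)
  counts <- as.integer(table(factor(obs$pair_id, levels = meta$pair_id)))
  start <- c(0L, cumsum(counts)[-length(counts)])
  grp <- if (is.null(residual$group)) rep(1L, nrow(meta)) else
    match(meta$assay, residual$group)
  if (anyNA(grp)) stop("fit_population: assay groups missing from residual model",
                       call. = FALSE)
  list(meta = meta, obs = obs, start = start, len = counts, group = grp)
}

design_matrix <- function(param, covariates, meta) {
  cv <- covariates[[param]]
  X <- matrix(1, nrow(meta), 1)
  cn <- "intercept"
  if (!is.null(cv)) {
    if (!cv$covariate %in% names(meta)) {
      stop("fit_population: covariate column missing: ", cv$covariate, call. = FALSE)
    }
    col <- if (identical(cv$type, "categorical")) meta[[cv$covariate]] else
      log(meta[[cv$covariate]] / cv$median)
    X <- cbind(X, col)
    cn <- c(cn, cv$covariate)
  }
  colnames(X) <- cn
  X
}

#' Fit the population (hierarchical) kinetic model
#'
#' Hierarchical Bayesian fit of the linked one-compartment model across
#' pairs: individual log-parameters are normal about covariate-dependent
#' population means with between-subject SDs `omega`, and residual SDs may
#' be group-specific (e.g. per assay). Sampling is Metropolis-within-Gibbs:
#' adaptive random-walk block updates for each pair's four log-parameters
#' (compiled), conjugate normal draws for the covariate coefficients, and
#' log-scale Metropolis steps for the BSV and residual SDs.
#'
#' @param observations Long observation tibble (many pairs; covariate
#'   columns required by `covariates` must be present).
#' @param prior A [build_prior()] regime supplying typical-value and BSV
#'   priors.
#' @param residual A [residual_model()] supplying the residual-error kind,
#'   grouping, and initial SD values.
#' @param covariates Covariate structure, see [default_covariates()].
#' @param slope_prior_sd Normal prior SD for covariate slopes.
#' @param n_chains,n_warmup,n_samples Sampler settings.
#' @param estimate_sigma Update the residual SDs (otherwise fixed at the
#'   values in `residual`).
#' @param sweeps_per_iter Individual-parameter Metropolis sweeps per Gibbs
#'   iteration.
#' @param seed Integer seed.
#' @param water_fraction Infant body-water fraction.
#' @param bounds Physiological truncation of the individual-parameter
#'   support, see [param_bounds()].
#' @return An object of class `dtm_popfit` with elements `population`
#'   (tibble of chain/draw and population-level parameters), `eta` (array
#'   chains x draws x pairs x 4 of individual log-parameters), `meta`
#'   (per-pair covariates), `diagnostics` (population-parameter Rhat), and
#'   the sampler settings.
#' @export
fit_population <- function(observations, prior = build_prior("mixed"),
                           residual = residual_model(
                             sigma1 = c(0.04, 0.08), sigma2 = c(1.5, 3),
                             group = c("IRMS", "FTIR")),
                           covariates = default_covariates(),
                           slope_prior_sd = 2,
                           n_chains = 2, n_warmup = 500, n_samples = 500,
                           estimate_sigma = TRUE, sweeps_per_iter = 8,
                           seed = 1L, water_fraction = 0.60,
                           bounds = param_bounds()) {
  if (length(unique(observations$pair_id)) < 2) {
    stop("fit_population: need at least 2 pairs", call. = FALSE)
  }
  pd <- prepare_pop_data(observations, residual, water_fraction)
  n <- nrow(pd$meta)
  combined <- residual$kind == "combined"
  n_grp <- max(pd$group)
  X <- lapply(LOG_PARAM_NAMES, design_matrix, covariates = covariates,
              meta = pd$meta)
  names(X) <- LOG_PARAM_NAMES
  pm <- individual_prior(prior)

  ## priors: intercept from the regime's typical values, diffuse slopes,
  ## truncated-normal BSV from the regime's BSV entries, half-normal sigmas
  b0 <- lapply(seq_len(4), function(p) {
    k <- ncol(X[[p]])
    c(prior$tv_mean[p], rep(0, k - 1))
  })
  B0 <- lapply(seq_len(4), function(p) {
    k <- ncol(X[[p]])
    diag(c(prior$tv_sd[p]^2, rep(slope_prior_sd^2, k - 1)), nrow = k)
  })
  omega_prior_mean <- prior$bsv_mean
  omega_prior_sd <- prior$bsv_sd

  keep_names <- unlist(lapply(seq_len(4), function(p) {
    cn <- colnames(X[[p]])
    ifelse(cn == "intercept", paste0("theta1_", LOG_PARAM_NAMES[p]),
           paste0("theta2_", LOG_PARAM_NAMES[p], "_", cn))
  }))
  keep_names <- c(keep_names, paste0("omega_", LOG_PARAM_NAMES),
                  paste0("sigma1_g", seq_len(n_grp)),
                  paste0("sigma2_g", seq_len(n_grp)))

  set.seed(seed)
  pop_draws <- vector("list", n_chains)
  eta_draws <- array(NA_real_, c(n_chains, n_samples, n, 4))

  for (chain in seq_len(n_chains)) {
    ## initial values: jittered prior/heuristic means
    beta <- lapply(seq_len(4), function(p) {
      init <- b0[[p]]
      if (pm$sd[p] > 10) {  # diffuse: data-scale heuristic intercepts
        init[1] <- switch(LOG_PARAM_NAMES[p],
                          ln_k_mm = log(0.113), ln_V_m = log(31),
                          ln_CL_mb = log(0.9), ln_CL_bo = log(0.95))
      }
      init + stats::rnorm(length(init), 0, 0.1)
    })
    omega <- pmax(pmin(omega_prior_mean, 1), 0.1) *
      exp(stats::rnorm(4, 0, 0.1))
    s1 <- residual$sigma1[seq_len(n_grp)]
    s2 <- residual$sigma2[seq_len(n_grp)]
    mu <- vapply(seq_len(4), function(p) as.vector(X[[p]] %*% beta[[p]]),
                 numeric(n))
    eta <- mu + matrix(stats::rnorm(n * 4, 0, 0.2), n, 4)
    sig1_pair <- s1[pd$group]
    sig2_pair <- s2[pd$group]
    eta <- pmin(pmax(eta, rep(bounds$lower + 0.05, each = n)),
                rep(bounds$upper - 0.05, each = n))
    ll <- cpp_loglik_all(eta, pd$obs$time_days, pd$obs$enrichment_mg_per_kg,
                         as.integer(pd$obs$role == "infant"), pd$start, pd$len,
                         pd$meta$dose_g, pd$meta$V_b, sig1_pair, sig2_pair,
                         combined, bounds$lower, bounds$upper)
    scale <- rep(0.15, n)
    sigma_step <- matrix(0.15, 2, n_grp)
    recenter_step <- ifelse(pm$sd > 10, 0.05, pmin(pm$sd, 0.05))
    rescale_step <- rep(0.1, 4)
    acc_run <- rep(0, n)
    total <- n_warmup + n_samples
    pop_mat <- matrix(NA_real_, n_samples, length(keep_names))
    ## per-pair proposal Cholesky factors (row-major 4x4), adapted from the
    ## warmup trajectory so elongated individual posteriors mix too
    Lmat <- matrix(rep(as.vector(diag(4)), each = n), n, 16)
    hist_len <- 120L
    eta_hist <- array(NA_real_, c(hist_len, n, 4))
    hist_ptr <- 0L

    for (it in seq_len(total)) {
      for (s in seq_len(sweeps_per_iter)) {
        up <- cpp_update_etas(eta, mu, omega, pd$obs$time_days,
                              pd$obs$enrichment_mg_per_kg,
                              as.integer(pd$obs$role == "infant"),
                              pd$start, pd$len, pd$meta$dose_g, pd$meta$V_b,
                              sig1_pair, sig2_pair, combined, scale, ll,
                              bounds$lower, bounds$upper, Lmat)
        eta <- up$eta
        ll <- up$loglik
        acc_run <- acc_run + up$accepted
      }
      if (it <= n_warmup) {
        hist_ptr <- (hist_ptr %% hist_len) + 1L
        eta_hist[hist_ptr, , ] <- eta
        if (it %% 20 == 0) {
          rate <- acc_run / (20 * sweeps_per_iter)
          scale <- pmin(pmax(scale * exp(rate - 0.3), 1e-3), 5)
          acc_run <- rep(0, n)
        }
        if (it >= hist_len && it %% 50 == 0) {
          for (i in seq_len(n)) {
            S <- stats::cov(eta_hist[, i, ]) + diag(1e-8, 4)
            Lc <- tryCatch(t(chol(S)), error = function(e) NULL)
            if (!is.null(Lc)) {
              ## rescale so the average step size is preserved
              Lmat[i, ] <- as.vector(t(Lc)) / sqrt(mean(diag(S)) + 1e-12)
            }
          }
        }
      }

      ## conjugate update of the covariate coefficients per parameter
      for (p in seq_len(4)) {
        Xp <- X[[p]]
        prec <- crossprod(Xp) / omega[p]^2 + solve(B0[[p]])
        V <- solve(prec)
        mpost <- V %*% (crossprod(Xp, eta[, p]) / omega[p]^2 +
                          solve(B0[[p]]) %*% b0[[p]])
        beta[[p]] <- as.vector(mpost + t(chol(V)) %*% stats::rnorm(ncol(Xp)))
      }
      mu <- vapply(seq_len(4), function(p) as.vector(X[[p]] %*% beta[[p]]),
                   numeric(n))

      ## recentering move: shift an intercept and every pair's eta jointly,
      ## which decouples the slow typical-value / individual-parameter
      ## random walk on sparse designs
      for (p in seq_len(4)) {
        delta <- stats::rnorm(1, 0, recenter_step[p])
        eta_prop <- eta
        eta_prop[, p] <- eta_prop[, p] + delta
        ll_prop <- cpp_loglik_all(eta_prop, pd$obs$time_days,
                                  pd$obs$enrichment_mg_per_kg,
                                  as.integer(pd$obs$role == "infant"),
                                  pd$start, pd$len, pd$meta$dose_g,
                                  pd$meta$V_b, sig1_pair, sig2_pair, combined,
                                  bounds$lower, bounds$upper)
        a <- sum(ll_prop) - sum(ll) +
          stats::dnorm(beta[[p]][1] + delta, b0[[p]][1], sqrt(B0[[p]][1, 1]),
                       log = TRUE) -
          stats::dnorm(beta[[p]][1], b0[[p]][1], sqrt(B0[[p]][1, 1]),
                       log = TRUE)
        acc <- is.finite(a) && log(stats::runif(1)) < a
        if (acc) {
          eta <- eta_prop
          ll <- ll_prop
          beta[[p]][1] <- beta[[p]][1] + delta
          mu[, p] <- mu[, p] + delta
        }
        if (it <= n_warmup) {
          recenter_step[p] <- min(max(
            recenter_step[p] * exp((as.numeric(acc) - 0.35) / sqrt(it)),
            1e-4), 1)
        }
      }

      ## BSV SDs: log-scale Metropolis with truncated-normal prior
      for (p in seq_len(4)) {
        prop <- omega[p] * exp(stats::rnorm(1, 0, 0.1))
        r <- eta[, p] - mu[, p]
        logpost <- function(w) {
          sum(stats::dnorm(r, 0, w, log = TRUE)) +
            stats::dnorm(w, omega_prior_mean[p], omega_prior_sd[p], log = TRUE) +
            log(w)  # Jacobian of the log-scale proposal
        }
        if (log(stats::runif(1)) < logpost(prop) - logpost(omega[p])) {
          omega[p] <- prop
        }
      }

      ## rescaling move: scale a BSV SD and the individual deviations
      ## together, so chains can climb out of the omega -> 0 funnel that
      ## sparse designs create
      for (p in seq_len(4)) {
        cf <- exp(stats::rnorm(1, 0, rescale_step[p]))
        eta_prop <- eta
        eta_prop[, p] <- mu[, p] + cf * (eta[, p] - mu[, p])
        ll_prop <- cpp_loglik_all(eta_prop, pd$obs$time_days,
                                  pd$obs$enrichment_mg_per_kg,
                                  as.integer(pd$obs$role == "infant"),
                                  pd$start, pd$len, pd$meta$dose_g,
                                  pd$meta$V_b, sig1_pair, sig2_pair, combined,
                                  bounds$lower, bounds$upper)
        a <- sum(ll_prop) - sum(ll) +
          stats::dnorm(cf * omega[p], omega_prior_mean[p], omega_prior_sd[p],
                       log = TRUE) -
          stats::dnorm(omega[p], omega_prior_mean[p], omega_prior_sd[p],
                       log = TRUE) +
          log(cf)
        acc <- is.finite(a) && log(stats::runif(1)) < a
        if (acc) {
          eta <- eta_prop
          ll <- ll_prop
          omega[p] <- cf * omega[p]
        }
        if (it <= n_warmup) {
          rescale_step[p] <- min(max(
            rescale_step[p] * exp((as.numeric(acc) - 0.35) / sqrt(it)),
            1e-3), 1)
        }
      }

      ## residual SDs per group: adaptive log-scale Metropolis, several
      ## repeats per iteration because sigma1/sigma2 trade off slowly
      if (estimate_sigma) {
        for (rep_s in 1:3) {
          for (g in seq_len(n_grp)) {
            in_g <- pd$group == g
            for (comp in 1:2) {
              cur <- if (comp == 1) s1[g] else s2[g]
              step <- sigma_step[comp, g]
              prop <- cur * exp(stats::rnorm(1, 0, step))
              s1p <- s1; s2p <- s2
              if (comp == 1) s1p[g] <- prop else s2p[g] <- prop
              llp <- cpp_loglik_all(eta, pd$obs$time_days,
                                    pd$obs$enrichment_mg_per_kg,
                                    as.integer(pd$obs$role == "infant"),
                                    pd$start, pd$len, pd$meta$dose_g, pd$meta$V_b,
                                    s1p[pd$group], s2p[pd$group], combined,
                                    bounds$lower, bounds$upper)
              pr_scale <- if (comp == 1) 0.5 else 20
              a <- sum(llp[in_g]) - sum(ll[in_g]) +
                stats::dnorm(prop, 0, pr_scale, log = TRUE) -
                stats::dnorm(cur, 0, pr_scale, log = TRUE) +
                log(prop) - log(cur)
              acc <- is.finite(a) && log(stats::runif(1)) < a
              if (acc) {
                if (comp == 1) s1 <- s1p else s2 <- s2p
                ll[in_g] <- llp[in_g]
              }
              if (it <= n_warmup) {
                sigma_step[comp, g] <- min(max(
                  sigma_step[comp, g] *
                    exp((as.numeric(acc) - 0.4) / sqrt(it)), 0.01), 1)
              }
            }
          }
        }
        sig1_pair <- s1[pd$group]
        sig2_pair <- s2[pd$group]
      }

      if (it > n_warmup) {
        k <- it - n_warmup
        pop_mat[k, ] <- c(unlist(beta), omega, s1, s2)
        eta_draws[chain, k, , ] <- eta
      }
    }
    colnames(pop_mat) <- keep_names
    pop_draws[[chain]] <- tibble::tibble(chain = chain,
                                         draw = seq_len(n_samples),
                                         tibble::as_tibble(pop_mat))
  }

  population <- dplyr::bind_rows(pop_draws)
  diagnostics <- tibble::tibble(
    parameter = keep_names,
    rhat = vapply(keep_names, function(nm) {
      m <- matrix(population[[nm]], nrow = n_samples, ncol = n_chains)
      if (n_chains >= 2) rhat(m) else NA_real_
    }, numeric(1))
  )
  structure(
    list(population = population, eta = eta_draws, meta = pd$meta,
         diagnostics = diagnostics, covariates = covariates,
         prior = attr(prior, "name"), residual = residual,
         n_chains = n_chains, n_samples = n_samples, seed = seed),
    class = "dtm_popfit"
  )
}

#' @export
print.dtm_popfit <- function(x, ...) {
  cat(sprintf("<dtm_popfit> %d pairs, %d chains x %d draws, prior '%s'\n",
              nrow(x$meta), x$n_chains, x$n_samples, x$prior))
  print(glance(x))
  invisible(x)
}

#' Convert a population fit into per-pair fits
#'
#' Extracts each pair's individual posterior draws from a hierarchical fit
#' as a `dtm_fits` object, so classification and imputation can consume
#' population-informed posteriors interchangeably with independent ones.
#'
#' @param popfit A `dtm_popfit`.
#' @return A `dtm_fits` object.
#' @export
as_pair_fits <- function(popfit) {
  stopifnot(inherits(popfit, "dtm_popfit"))
  n <- nrow(popfit$meta)
  n_samples <- popfit$n_samples
  n_chains <- popfit$n_chains
  fits <- vector("list", n)
  names(fits) <- popfit$meta$pair_id
  for (i in seq_len(n)) {
    mats <- lapply(seq_len(4), function(p) {
      as.vector(t(popfit$eta[, , i, p]))  # chain-major order
    })
    draws <- tibble::tibble(
      chain = rep(seq_len(n_chains), each = n_samples),
      draw = rep(seq_len(n_samples), times = n_chains),
      k_mm = exp(mats[[1]]), V_m = exp(mats[[2]]),
      CL_mb = exp(mats[[3]]), CL_bo = exp(mats[[4]])
    )
    rhats <- vapply(seq_len(4), function(p) {
      rhat(matrix(popfit$eta[, , i, p], nrow = n_chains, ncol = n_samples,
                  byrow = FALSE) |> t())
    }, numeric(1))
    meta_i <- popfit$meta[i, ]
    fits[[i]] <- structure(
      list(draws = draws,
           diagnostics = tibble::tibble(parameter = PARAM_NAMES, rhat = rhats),
           stable = all(is.finite(rhats)) && all(rhats < RHAT_GATE),
           pair = tibble::tibble(pair_id = meta_i$pair_id,
                                 dose_g = meta_i$dose_g, MWT_kg = meta_i$MWT_kg,
                                 BWT_start_kg = meta_i$BWT_start_kg,
                                 BWT_end_kg = meta_i$BWT_end_kg,
                                 assay = meta_i$assay, V_b = meta_i$V_b),
           accept_rate = NA_real_, prior = popfit$prior,
           residual = popfit$residual, n_chains = n_chains,
           n_warmup = NA_integer_, n_samples = n_samples, seed = popfit$seed),
      class = "dtm_fit"
    )
  }
  diagnostics <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(pair_id = f$pair$pair_id, f$diagnostics, stable = f$stable)
  })
  structure(list(fits = fits, diagnostics = diagnostics), class = "dtm_fits")
}

#' Residual model estimated by a population fit
#'
#' Extracts the posterior-mean residual SDs per assay group from a
#' hierarchical fit, for reuse in downstream (e.g. streamlined) refits
#' where the error model is treated as known.
#'
#' @param popfit A `dtm_popfit`.
#' @return A [residual_model()] with the fitted group sigmas.
#' @export
estimated_residual <- function(popfit) {
  stopifnot(inherits(popfit, "dtm_popfit"))
  res <- popfit$residual
  n_grp <- if (is.null(res$group)) 1 else length(res$group)
  s1 <- vapply(seq_len(n_grp), function(g) {
    mean(popfit$population[[paste0("sigma1_g", g)]])
  }, numeric(1))
  s2 <- vapply(seq_len(n_grp), function(g) {
    mean(popfit$population[[paste0("sigma2_g", g)]])
  }, numeric(1))
  residual_model(res$kind, sigma1 = s1, sigma2 = s2, group = res$group)
}
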