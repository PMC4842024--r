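## The simulation-study engine: simulate under a truth grid, fit the null
## and alternative animal models, calibrate the DIC-difference critical
## value under the null, and aggregate power, misspecification and
## estimator diagnostics.

#' Truth grid for a study pair
#'
#' Builds the default variance grids with the variance-splitting constraint
#' built in: for the `"S1"` pair (M1 vs M2) the genetic variances satisfy
#' `sigma2_a + sigma2_m = 0.6` with `sigma2_e = 0.4`; for `"S2"` (M1 vs M3)
#' the individual variances satisfy `sigma2_e + sigma2_p = 0.4` with
#' `sigma2_a = 0.6`.  Total phenotypic variance is 1 at every grid point.
#'
#' @param pair `"S1"` or `"S2"`.
#' @param maternal_values grid of the maternal variance (the first value
#'   should be 0, the null point).
#' @return A data.frame with columns `model`, `sigma2_a`, `sigma2_m`,
#'   `sigma2_p`, `sigma2_e` (one row per grid point; row 1 is the null).
#' @export
truth_grid <- function(pair = c("S1", "S2"),
                       maternal_values = NULL) {
  pair <- match.arg(pair)
  if (pair == "S1") {
    v <- maternal_values %||% seq(0, 0.6, by = 0.1)
    stopifnot(all(v >= 0), all(v <= 0.6))
    data.frame(model = ifelse(v == 0, "M1", "M2"),
               sigma2_a = 0.6 - v, sigma2_m = v, sigma2_p = 0, sigma2_e = 0.4)
  } else {
    v <- maternal_values %||% seq(0, 0.4, by = 0.1)
    stopifnot(all(v >= 0), all(v <= 0.4))
    data.frame(model = ifelse(v == 0, "M1", "M3"),
               sigma2_a = 0.6, sigma2_m = 0, sigma2_p = v, sigma2_e = 0.4 - v)
  }
}

#' Study configuration
#'
#' @param pair `"S1"` (null M1 vs alternative M2) or `"S2"` (M1 vs M3).
#' @param S replicates per grid point.
#' @param alpha significance level for the critical value.
#' @param grid truth grid (see [truth_grid()]); row 1 must be the null
#'   point (maternal variance 0).
#' @param ped a [pedigree()] object, or `NULL` to generate one from
#'   `system_params`.
#' @param system_params [study_system_params()] used when `ped` is `NULL`.
#' @param settings [mcmc_settings()] used for every fit.
#' @param seed master seed; per-replicate seeds are derived from
#'   `(seed, grid index, replicate index)` so results do not depend on
#'   execution order.
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(pair = c("S1", "S2"), S = 1000L, alpha = 0.05,
                         grid = NULL, ped = NULL,
                         system_params = study_system_params(),
                         settings = mcmc_settings(), seed = 1L) {
  pair <- match.arg(pair)
  grid <- grid %||% truth_grid(pair)
  stopifnot(S >= 2L, alpha > 0, alpha < 1)
  mat <- if (pair == "S1") grid$sigma2_m else grid$sigma2_p
  if (mat[1L] != 0)
    stop("row 1 of the truth grid must be the null point (maternal variance 0)")
  if (pair == "S1" && any(abs(grid$sigma2_a + grid$sigma2_m - 0.6) > 1e-9))
    stop("S1 grid must satisfy sigma2_a + sigma2_m = 0.6")
  if (pair == "S2" && any(abs(grid$sigma2_e + grid$sigma2_p - 0.4) > 1e-9))
    stop("S2 grid must satisfy sigma2_e + sigma2_p = 0.4")
  structure(list(
    pair = pair,
    h0 = model_spec("M1"),
    h1 = model_spec(if (pair == "S1") "M2" else "M3"),
    S = as.integer(S), alpha = alpha, grid = grid,
    ped = ped, system_params = system_params,
    settings = settings, seed = as.integer(seed)
  ), class = "study_config")
}

#' Desk-scale study configuration
#'
#' Reduced preset for laptop runs: ~800-individual synthetic pedigree
#' (~240 phenotyped), `S = 100`, maternal grid `{0, 0.2, 0.3, 0.4}`, and
#' short two-chain MCMC.  The maternal-genetic block (pair S1) mixes more
#' slowly than the i.i.d. maternal block, so S1 gets longer chains than S2.
#'
#' @inheritParams study_config
#' @param ... passed on to [study_config()].
#' @export
desk_config <- function(pair = c("S1", "S2"), seed = 1L, S = 100L, ...) {
  pair <- match.arg(pair)
  vals <- c(0, 0.2, 0.3, 0.4)
  settings <- if (pair == "S1")
    mcmc_settings(iterations = 2500L, burnin = 500L, thin = 4L, chains = 2L)
  else
    mcmc_settings(iterations = 1500L, burnin = 500L, thin = 2L, chains = 2L)
  study_config(
    pair = pair, S = S, grid = truth_grid(pair, maternal_values = vals),
    system_params = desk_system_params(),
    settings = settings,
    seed = seed, ...
  )
}

#' Critical value of the DIC-difference test
#'
#' The `ceiling((1 - alpha) * S)`-th order statistic of the null
#' `DeltaDIC` sample (empirical quantile without interpolation).
#'
#' @param null_deltas numeric vector of `DeltaDIC = DIC(H0) - DIC(H1)`
#'   computed on data simulated under the null model.
#' @param alpha significance level.
#' @return The critical value `C`.
#' @export
critical_value <- function(null_deltas, alpha = 0.05) {
  if (!length(null_deltas)) stop("empty null DeltaDIC sample")
  stopifnot(alpha > 0, alpha < 1)
  s <- sort(null_deltas)
  s[ceiling((1 - alpha) * length(s))]
}

#' Power estimate from alternative-model DIC differences
#'
#' Fraction of `DeltaDIC` values strictly greater than the critical value
#' (ties do not reject), with its binomial Monte-Carlo standard error.
#'
#' @param alt_deltas numeric vector of `DeltaDIC` under the alternative.
#' @param c critical value from [critical_value()].
#' @return A list `power`, `se`, `n`.
#' @export
power_estimate <- function(alt_deltas, c) {
  if (!length(alt_deltas)) stop("empty DeltaDIC sample")
  p <- mean(alt_deltas > c)
  list(power = p, se = sqrt(p * (1 - p) / length(alt_deltas)),
       n = length(alt_deltas))
}

## Fit H0 and H1 to one simulated data set; returns a one-row data.frame.
fit_replicate <- function(data, config, prep, grid_i, rep_s, fit_h0 = TRUE,
                          fit_h1 = TRUE) {
  settings <- config$settings
  out <- list(grid = grid_i, rep = rep_s)
  for (side in c("h0", "h1")) {
    if ((side == "h0" && !fit_h0) || (side == "h1" && !fit_h1)) next
    sp <- config[[side]]
    st <- settings
    st$seed <- mix_seed(config$seed, grid_i * 1000L + rep_s,
                        if (side == "h0") 1L else 2L)
    fit <- fit_animal_model(data, sp, st, prep = prep)
    out[[paste0(side, "_dic")]] <- fit$dic$DIC
    out[[paste0(side, "_converged")]] <- fit$converged
    out[[paste0(side, "_max_constraint")]] <- fit$max_abs_constraint
    for (k in seq_len(nrow(fit$summary))) {
      pn <- fit$summary$parameter[k]
      out[[paste0(side, "_", pn, "_mean")]] <- fit$summary$mean[k]
      out[[paste0(side, "_", pn, "_lo")]] <- fit$summary$q2.5[k]
      out[[paste0(side, "_", pn, "_hi")]] <- fit$summary$q97.5[k]
    }
  }
  if (fit_h0 && fit_h1) out$delta_dic <- out$h0_dic - out$h1_dic
  as.data.frame(out)
}

#' Run a simulation study
#'
#' Executes the full protocol on one pedigree: for every truth-grid point,
#' simulates `S` phenotype data sets, fits the null and alternative models
#' to each, and aggregates (i) the null `DeltaDIC` distribution and its
#' critical value, (ii) power along the grid, (iii) the
#' omitted-effect (null-fit) estimate table and (iv) bias and coverage of
#' the alternative-fit estimators.  Non-converged replicates are excluded
#' from aggregates and counted, never re-run.
#'
#' @param config a [study_config()].
#' @param progress log per-grid-point progress to stderr.
#' @return A list of class `"study_result"`: `replicates` (data.frame, one
#'   row per replicate), `null_deltas`, `c_value`, `power` (data.frame),
#'   `misspecification`, `diagnostics`, `n_nonconverged`, `config`.
#' @export
run_study <- function(config, progress = TRUE) {
  stopifnot(inherits(config, "study_config"))
  ped <- config$ped %||%
    generate_pedigree(config$system_params, seed = mix_seed(config$seed, 0L))
  prep <- inference_prep(ped)
  F <- inbreeding_coefficients(ped)
  grid <- config$grid
  reps <- vector("list", nrow(grid) * config$S)
  k <- 0L
  for (g in seq_len(nrow(grid))) {
    truth <- trait_truth(grid$model[g], beta0 = 0,
                         sigma2_a = grid$sigma2_a[g],
                         sigma2_m = grid$sigma2_m[g],
                         sigma2_p = grid$sigma2_p[g],
                         sigma2_e = grid$sigma2_e[g])
    for (s in seq_len(config$S)) {
      data <- simulate_dataset(ped, truth,
                               seed = mix_seed(config$seed, g, s), F = F)
      k <- k + 1L
      row <- fit_replicate(data, config, prep, g, s)
      row$maternal_true <- if (config$pair == "S1") grid$sigma2_m[g]
                           else grid$sigma2_p[g]
      reps[[k]] <- row
    }
    if (progress)
      pp_log("info", "grid point ", g, "/", nrow(grid), " done (",
             config$S, " replicates)")
  }
  replicates <- do.call(rbind, reps)
  aggregate_study(replicates, config, ped)
}

## Aggregation of a replicate table into a study_result.
aggregate_study <- function(replicates, config, ped = NULL) {
  ok <- replicates$h0_converged & replicates$h1_converged
  n_bad <- sum(!ok)
  if (n_bad) pp_log("warn", n_bad, " non-converged replicate(s) excluded")
  used <- replicates[ok, , drop = FALSE]
  null_deltas <- used$delta_dic[used$grid == 1L]
  if (length(null_deltas)) {
    c_value <- critical_value(null_deltas, config$alpha)
  } else {
    pp_log("warn", "no converged null replicates; critical value unavailable")
    c_value <- NA_real_
  }
  grid <- config$grid
  power <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    d <- used$delta_dic[used$grid == g]
    pw <- if (length(d) && !is.na(c_value)) power_estimate(d, c_value)
          else list(power = NA_real_, se = NA_real_, n = length(d))
    data.frame(grid = g, maternal_true = unique(
                 replicates$maternal_true[replicates$grid == g]),
               power = pw$power, se = pw$se, n = pw$n)
  }))
  res <- structure(list(
    replicates = replicates,
    null_deltas = null_deltas,
    c_value = c_value,
    power = power,
    misspecification = NULL,
    diagnostics = NULL,
    n_nonconverged = n_bad,
    config = config,
    np = if (!is.null(ped)) ped$np else NA_integer_,
    nd = if (!is.null(ped)) ped$nd else NA_integer_
  ), class = "study_result")
  res$misspecification <- misspecification_summary(res)
  res$diagnostics <- estimator_diagnostics(res)
  res
}

#' Omitted-effect (misspecification) summary
#'
#' Mean and spread of the null-model (H0) posterior-mean variance estimates
#' at every truth-grid point, answering what the other variance components
#' absorb when the maternal effect is present but not modeled; includes
#' the conservation diagnostic (sum of mean estimates vs. sum of true
#' variances).
#'
#' @param result a [run_study()] result.
#' @return A data.frame, one row per grid point.
#' @export
misspecification_summary <- function(result) {
  stopifnot(inherits(result, "study_result"))
  reps <- result$replicates
  if (is.null(reps$h0_sigma2_a_mean))
    stop("study was run without H0 fits; misspecification summary unavailable")
  ok <- reps$h0_converged
  grid <- result$config$grid
  do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    r <- reps[ok & reps$grid == g, , drop = FALSE]
    true_tot <- grid$sigma2_a[g] + grid$sigma2_m[g] +
      grid$sigma2_p[g] + grid$sigma2_e[g]
    data.frame(
      grid = g,
      maternal_true = unique(reps$maternal_true[reps$grid == g]),
      n = nrow(r),
      sigma2_a_mean = mean(r$h0_sigma2_a_mean),
      sigma2_a_sd = stats::sd(r$h0_sigma2_a_mean),
      sigma2_e_mean = mean(r$h0_sigma2_e_mean),
      sigma2_e_sd = stats::sd(r$h0_sigma2_e_mean),
      total_estimated = mean(r$h0_sigma2_a_mean + r$h0_sigma2_e_mean),
      total_true = true_tot
    )
  }))
}

#' Bias and coverage of the alternative-model estimators
#'
#' For every truth-grid point and every variance of the alternative model:
#' bias of the posterior mean and empirical coverage of the central 95%
#' credible interval, with binomial standard errors.
#'
#' @param result a [run_study()] result.
#' @return A data.frame, one row per grid point x parameter.
#' @export
estimator_diagnostics <- function(result) {
  stopifnot(inherits(result, "study_result"))
  reps <- result$replicates
  h1pars <- grep("^h1_sigma2_[ampe]_mean$", names(reps), value = TRUE)
  if (!length(h1pars))
    stop("study was run without H1 fits (no credible-interval records)")
  pars <- sub("^h1_(.*)_mean$", "\\1", h1pars)
  ok <- reps$h1_converged
  grid <- result$config$grid
  do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    r <- reps[ok & reps$grid == g, , drop = FALSE]
    do.call(rbind, lapply(pars, function(p) {
      truth <- grid[[p]][g]
      est <- r[[paste0("h1_", p, "_mean")]]
      lo <- r[[paste0("h1_", p, "_lo")]]
      hi <- r[[paste0("h1_", p, "_hi")]]
      cov <- mean(lo <= truth & truth <= hi)
      data.frame(grid = g,
                 maternal_true = unique(reps$maternal_true[reps$grid == g]),
                 parameter = p, truth = truth, n = nrow(r),
                 mean_estimate = mean(est), bias = mean(est) - truth,
                 coverage = cov,
                 coverage_se = sqrt(cov * (1 - cov) / nrow(r)))
    }))
  }))
}

#' @export
print.study_result <- function(x, ...) {
  cat("simulation study", x$config$pair, ": S =", x$config$S,
      "per grid point, np =", x$np, ", nd =", x$nd, "\n")
  cat(sprintf("critical value C = %.2f (alpha = %.3f, %d null replicates)\n",
              x$c_value, x$config$alpha, length(x$null_deltas)))
  cat("power along the maternal-variance grid:\n")
  print(x$power, digits = 3)
  if (x$n_nonconverged)
    cat("non-converged replicates excluded:", x$n_nonconverged, "\n")
  invisible(x)
}
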