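## Bayesian animal-model inference by blocked Gibbs sampling.
##
## Each pedigree-structured effect u ~ N(0, s2 A) is reparameterized once
## per pedigree: with A = R'R (Cholesky) and the nd x np incidence Z of the
## effect on the observations, let W = Z R' and W'W = V L V' (symmetric
## eigendecomposition).  Writing u = R'V w turns the full conditional of w
## into an independent normal with diagonal precision 1/s2 + L/s2_e, so a
## sweep costs a few dense mat-vecs instead of a sparse factorization.
## The sum-to-zero constraint 1'u = 0 is imposed exactly by conditioning
## each block draw on s'w = 0 (s = V'R 1), i.e. conditioning by kriging on
## a diagonal precision, and the variance full conditionals use the
## constrained dimension np - 1 and quadratic form w'w = u'A^-1 u.

#' Animal-model specification
#'
#' @param model shorthand: `"M1"` = direct genetic only, `"M2"` = + maternal
#'   genetic, `"M3"` = + maternal individual, `"M4"` = both maternal
#'   effects, `"M0"` = intercept + residual only (degenerate, for testing).
#' @param direct,maternal_genetic,maternal_individual explicit flags;
#'   override `model` when any is non-`NULL`.
#' @return A list of class `"model_spec"` with logical flags `a`, `m`, `p`
#'   and a `label`.  The residual variance is always present; each included
#'   variance carries an InvGamma(0.5, 0.5) prior, the intercept an
#'   effectively flat prior, and the structured effects `a` and `m`
#'   sum-to-zero constraints.
#' @export
model_spec <- function(model = c("M1", "M2", "M3", "M4", "M0"),
                       direct = NULL, maternal_genetic = NULL,
                       maternal_individual = NULL) {
  model <- match.arg(model)
  fl <- switch(model,
    M0 = c(a = FALSE, m = FALSE, p = FALSE),
    M1 = c(a = TRUE, m = FALSE, p = FALSE),
    M2 = c(a = TRUE, m = TRUE, p = FALSE),
    M3 = c(a = TRUE, m = FALSE, p = TRUE),
    M4 = c(a = TRUE, m = TRUE, p = TRUE))
  if (!is.null(direct)) fl["a"] <- isTRUE(direct)
  if (!is.null(maternal_genetic)) fl["m"] <- isTRUE(maternal_genetic)
  if (!is.null(maternal_individual)) fl["p"] <- isTRUE(maternal_individual)
  label <- if (identical(unname(fl), c(TRUE, FALSE, FALSE))) "M1"
    else if (identical(unname(fl), c(TRUE, TRUE, FALSE))) "M2"
    else if (identical(unname(fl), c(TRUE, FALSE, TRUE))) "M3"
    else if (identical(unname(fl), c(TRUE, TRUE, TRUE))) "M4"
    else if (!any(fl)) "M0"
    else paste0("custom[", paste(names(fl)[fl], collapse = ","), "]")
  structure(list(a = unname(fl["a"]), m = unname(fl["m"]), p = unname(fl["p"]),
                 label = label, prior_shape = 0.5, prior_rate = 0.5,
                 beta0_prior_var = 1e8),
            class = "model_spec")
}

#' MCMC settings
#'
#' @param iterations total Gibbs sweeps per chain.
#' @param burnin discarded initial sweeps (`< iterations`).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param chains number of independent chains.
#' @param seed integer seed (chain c uses a seed derived from it).
#' @param rhat_limit convergence gate on the potential scale reduction of
#'   every sampled variance (split-chain when `chains == 1`).
#' @export
mcmc_settings <- function(iterations = 6000L, burnin = 1000L, thin = 5L,
                          chains = 2L, seed = NULL, rhat_limit = 1.1) {
  s <- list(iterations = as.integer(iterations), burnin = as.integer(burnin),
            thin = as.integer(thin), chains = as.integer(chains),
            seed = seed, rhat_limit = rhat_limit)
  stopifnot(s$burnin >= 0L, s$burnin < s$iterations, s$thin >= 1L,
            s$chains >= 1L)
  structure(s, class = "mcmc_settings")
}

## Eigenbasis of one structured effect for a fixed pedigree + incidence.
## obs_link: for each phenotyped individual (in pedigree order) the
## pedigree index its effect is read from (its own index for a, its
## mother's for m), or NA when there is no link.
effect_basis <- function(Rt, obs_link) {
  np <- ncol(Rt)
  nd <- length(obs_link)
  W <- matrix(0, nd, np)
  ok <- !is.na(obs_link)
  W[ok, ] <- Rt[obs_link[ok], , drop = FALSE]
  eig <- eigen(crossprod(W), symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  G <- Rt %*% eig$vectors        # u = G w, with w iid N(0, s2) a priori
  list(lambda = lambda,
       T = W %*% eig$vectors,    # contribution to observations: T w
       G = G,
       s = colSums(G))           # 1'u = s'w (sum-to-zero constraint)
}

#' Precompute per-pedigree inference structures
#'
#' Builds the Cholesky factor of `A` and the eigenbases used by
#' [fit_animal_model()] for the direct and maternal genetic blocks.
#' Expensive (two dense `np x np` eigendecompositions) but reusable across
#' every fit on the same pedigree, which is what [run_study()] does.
#'
#' @param ped a [pedigree()] object.
#' @return A list of class `"inference_prep"`.
#' @export
inference_prep <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  A <- additive_relationship(ped)
  Rt <- t(chol(A)) # lower triangular, A = Rt %*% t(Rt)
  obs <- which(ped$phenotyped)
  mom <- ped$dam[obs]
  mothers <- sort(unique(mom[!is.na(mom)]))
  structure(list(
    ped_np = ped$np,
    obs = obs,
    basis_a = effect_basis(Rt, obs),
    basis_m = effect_basis(Rt, mom),
    mom_index = match(mom, mothers), # NA when mother unknown
    n_mothers = length(mothers),
    mother_ids = ped$id[mothers]
  ), class = "inference_prep")
}

#' Fit a Bayesian animal model by Gibbs sampling
#'
#' Conjugate blocked Gibbs sampler for models M1-M4 (and the degenerate
#' intercept-only M0) on a [simulate_dataset()] result or any
#' `trait_dataset`.  Structured blocks are updated jointly in a per-pedigree
#' eigenbasis; sum-to-zero constraints on the direct and maternal genetic
#' effects hold exactly at every retained draw.  Variances get
#' InvGamma(0.5, 0.5) priors, the intercept a diffuse normal
#' (variance 1e8, effectively flat).
#'
#' The per-draw conditional deviance `-2 log N(y | eta, s2_e I)` (latent
#' effects in the likelihood) is recorded and DIC computed with the plug-in
#' at posterior means of the linear predictor and residual variance.
#'
#' @param data a `trait_dataset`.
#' @param spec a [model_spec()].
#' @param settings an [mcmc_settings()].
#' @param prep optional [inference_prep()] for `data$ped` (computed when
#'   missing; pass it when fitting many data sets on one pedigree).
#' @return A list of class `"fit_result"`: `draws` (matrix of retained
#'   draws: variances, `beta0`, `deviance`), `summary` (data.frame with
#'   posterior mean, sd, 2.5% / 97.5% quantiles per parameter), `latent`
#'   (posterior means of `a`, `m` over the whole pedigree and `p` per
#'   mother), `dic` (list `Dbar`, `Dhat`, `pD`, `DIC`,
#'   `negative_pD`), `diagnostics` (`rhat`, `ess`), `converged`,
#'   `max_abs_constraint`, plus echoes of `spec` and `settings`.
#' @export
fit_animal_model <- function(data, spec, settings = mcmc_settings(),
                             prep = NULL) {
  stopifnot(inherits(data, "trait_dataset"), inherits(spec, "model_spec"),
            inherits(settings, "mcmc_settings"))
  ped <- data$ped
  y <- data$y[data$observed]
  nd <- length(y)
  if (nd < 2L) stop("no observed phenotypes (need at least 2)")
  if (is.null(prep)) prep <- inference_prep(ped)
  if ((spec$m || spec$p) && prep$n_mothers == 0L)
    stop("model ", spec$label, " includes a maternal term but no ",
         "phenotyped individual has a known mother")
  np <- prep$ped_np
  nkeep <- (settings$iterations - settings$burnin) %/% settings$thin
  if (nkeep < 2L) stop("MCMC settings leave fewer than 2 retained draws")

  vnames <- c(if (spec$a) "sigma2_a", if (spec$m) "sigma2_m",
              if (spec$p) "sigma2_p", "sigma2_e")
  pars <- c(vnames, "beta0")

  mom_idx <- prep$mom_index
  nm <- prep$n_mothers
  b0_prec <- 1 / spec$beta0_prior_var
  sh <- spec$prior_shape; rt <- spec$prior_rate

  chains <- vector("list", settings$chains)
  mu_sum <- numeric(nd)
  a_sum <- numeric(np); m_sum <- numeric(np); p_sum <- numeric(max(nm, 1L))
  max_con <- 0
  empty <- matrix(0, 1L, 1L)

  for (ch in seq_len(settings$chains)) {
    ch_seed <- if (is.null(settings$seed)) NULL else mix_seed(settings$seed, ch)
    res <- with_seed(ch_seed, .gibbs_chain(
      y,
      spec$a, if (spec$a) prep$basis_a$T else empty,
      prep$basis_a$lambda, prep$basis_a$s,
      if (spec$a) prep$basis_a$G else empty,
      spec$m, if (spec$m) prep$basis_m$T else empty,
      prep$basis_m$lambda, prep$basis_m$s,
      if (spec$m) prep$basis_m$G else empty,
      spec$p, ifelse(is.na(mom_idx), 0L, mom_idx), nm,
      sh, rt, b0_prec,
      settings$iterations, settings$burnin, settings$thin
    ))
    colnames(res$draws) <- c(pars, "deviance")
    chains[[ch]] <- res$draws
    mu_sum <- mu_sum + res$mu_sum
    if (spec$a) a_sum <- a_sum + res$a_sum
    if (spec$m) m_sum <- m_sum + res$m_sum
    if (spec$p) p_sum <- p_sum + res$p_sum
    max_con <- max(max_con, res$max_con)
  }

  ntot <- nkeep * settings$chains
  draws <- do.call(rbind, chains)
  qs <- apply(draws[, pars, drop = FALSE], 2L, stats::quantile,
              probs = c(0.025, 0.975))
  summary <- data.frame(
    parameter = pars,
    mean = colMeans(draws[, pars, drop = FALSE]),
    sd = apply(draws[, pars, drop = FALSE], 2L, stats::sd),
    q2.5 = qs[1L, ], q97.5 = qs[2L, ],
    row.names = NULL
  )

  mu_bar <- mu_sum / ntot
  sig_e_bar <- mean(draws[, "sigma2_e"])
  Dbar <- mean(draws[, "deviance"])
  Dhat <- -2 * sum(stats::dnorm(y, mu_bar, sqrt(sig_e_bar), log = TRUE))

  diag_pars <- vnames
  rhat <- vapply(diag_pars, function(p)
    rhat_split(lapply(chains, function(d) d[, p])), numeric(1))
  ess <- vapply(diag_pars, function(p) sum(vapply(chains, function(d)
    ess_acf(d[, p]), numeric(1))), numeric(1))
  converged <- all(is.finite(rhat)) && all(rhat < settings$rhat_limit)
  if (!converged)
    pp_log("warn", "chain did not pass convergence gate (max rhat = ",
           sprintf("%.3f", suppressWarnings(max(rhat))), ")")

  fit <- structure(list(
    draws = draws,
    summary = summary,
    latent = list(a = a_sum / ntot, m = m_sum / ntot, p = p_sum / ntot,
                  mother_ids = prep$mother_ids),
    y = y, mu_bar = mu_bar, sig_e_bar = sig_e_bar,
    dic = NULL,
    diagnostics = list(rhat = rhat, ess = ess),
    converged = converged,
    max_abs_constraint = max_con,
    spec = spec, settings = settings
  ), class = "fit_result")
  fit$dic <- compute_dic(fit)
  fit
}

#' Deviance information criterion of a fit
#'
#' `Dbar` is the mean per-draw conditional deviance; `Dhat` the deviance at
#' the posterior means of the linear predictor (intercept + latent
#' effects) and residual variance; `pD = Dbar - Dhat`; `DIC = Dbar + pD`.
#' A negative `pD` (a known DIC pathology) is reported with a flag, never
#' raised.
#'
#' @param fit a [fit_animal_model()] result.
#' @return A list `Dbar`, `Dhat`, `pD`, `DIC`, `negative_pD`.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  Dbar <- mean(fit$draws[, "deviance"])
  Dhat <- -2 * sum(stats::dnorm(fit$y, fit$mu_bar, sqrt(fit$sig_e_bar),
                                log = TRUE))
  pD <- Dbar - Dhat
  if (pD < 0) pp_log("warn", "negative pD (", sprintf("%.2f", pD), ")")
  list(Dbar = Dbar, Dhat = Dhat, pD = pD, DIC = Dbar + pD,
       negative_pD = pD < 0)
}

## Split-chain potential scale reduction (Gelman-Rubin).  With one chain
## the chain is split in halves.
rhat_split <- function(chain_list) {
  if (length(chain_list) == 1L) {
    x <- chain_list[[1L]]
    h <- floor(length(x) / 2)
    chain_list <- list(x[seq_len(h)], x[h + seq_len(h)])
  }
  m <- length(chain_list)
  n <- min(lengths(chain_list))
  xs <- vapply(chain_list, function(x) x[seq_len(n)], numeric(n))
  mu <- colMeans(xs)
  B <- n * stats::var(mu)
  Wv <- mean(apply(xs, 2L, stats::var))
  if (Wv <= 0) return(1)
  sqrt(((n - 1) / n * Wv + B / n) / Wv)
}

## Effective sample size by initial positive autocorrelation sum.
ess_acf <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1L, 100L), plot = FALSE)$acf[-1L]
  pos <- which(ac < 0.05)
  k <- if (length(pos)) pos[1L] - 1L else length(ac)
  n / (1 + 2 * sum(ac[seq_len(k)]))
}

#' @export
print.fit_result <- function(x, ...) {
  cat("animal model", x$spec$label, "fit:",
      nrow(x$draws), "retained draws,",
      if (x$converged) "converged" else "NOT converged", "\n")
  print(x$summary, digits = 4)
  cat(sprintf("DIC = %.2f (Dbar = %.2f, pD = %.2f)\n",
              x$dic$DIC, x$dic$Dbar, x$dic$pD))
  invisible(x)
}
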