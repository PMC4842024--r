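## Brute-force grid-integration posterior oracle for tiny pedigrees.
##
## Integrates the latent effects and intercept out analytically (the
## marginal of y given the variances is multivariate normal), then
## integrates the variances on a log-spaced grid with trapezoid weights
## and InvGamma(0.5, 0.5) priors.  The sum-to-zero constraints enter
## through the constrained kernel A_c = A - A 1 1' A / (1' A 1), and the
## diffuse-normal intercept (variance 1e8) through a constant covariance
## offset -- exactly the model the Gibbs sampler targets, reached by an
## entirely different route.
##
## Vectorized over the residual-variance dimension: for each structured
## combo the fixed covariance part is eigendecomposed once and sigma2_e
## only shifts its eigenvalues.
oracle_grid_posterior <- function(ped, y, spec, n_grid = 48, lo = 0.02,
                                  hi = 200) {
  A <- additive_relationship(ped)
  one <- rep(1, ped$np)
  Ac <- A - (A %*% one) %*% t(A %*% one) / sum(A)
  obs <- which(ped$phenotyped)
  yo <- y[obs]
  n <- length(yo)
  Ka <- Ac[obs, obs]
  mom <- ped$dam[obs]
  ok <- !is.na(mom)
  Km <- matrix(0, n, n); Km[ok, ok] <- Ac[mom[ok], mom[ok]]
  Kp <- matrix(0, n, n); Kp[ok, ok] <- outer(mom[ok], mom[ok], "==") * 1
  gr <- exp(seq(log(lo), log(hi), length.out = n_grid))
  dgr <- (c(0, diff(gr)) + c(diff(gr), 0)) / 2
  lpr <- -1.5 * log(gr) - 0.5 / gr # InvGamma(0.5, 0.5) log-kernel
  svars <- c(if (spec$a) "sa", if (spec$m) "sm", if (spec$p) "sp")
  combos <- do.call(expand.grid,
                    setNames(rep(list(seq_len(n_grid)), length(svars)), svars))
  n_combo <- max(nrow(combos), 1L)
  bv <- 1e8
  ones <- matrix(1, n, n)
  lp <- matrix(NA_real_, n_combo, n_grid) # log posterior, combo x sigma2_e
  for (r in seq_len(n_combo)) {
    S0 <- bv * ones
    if (spec$a) S0 <- S0 + gr[combos$sa[r]] * Ka
    if (spec$m) S0 <- S0 + gr[combos$sm[r]] * Km
    if (spec$p) S0 <- S0 + gr[combos$sp[r]] * Kp
    eg <- eigen(S0, symmetric = TRUE)
    uy <- as.vector(crossprod(eg$vectors, yo))
    d <- pmax(eg$values, 0)
    ll <- vapply(gr, function(se)
      -0.5 * sum(log(d + se)) - 0.5 * sum(uy^2 / (d + se)), numeric(1))
    row <- ll + lpr
    for (v in svars) row <- row + lpr[combos[[v]][r]]
    lp[r, ] <- row
  }
  w <- exp(lp - max(lp))
  w <- sweep(w, 2L, dgr, "*")
  for (v in svars) w <- w * dgr[combos[[v]]]
  w <- w / sum(w)
  acc <- c(vapply(svars, function(v) sum(rowSums(w) * gr[combos[[v]]]),
                  numeric(1)),
           se = sum(colSums(w) * gr))
  names(acc) <- c(if (spec$a) "sigma2_a", if (spec$m) "sigma2_m",
                  if (spec$p) "sigma2_p", "sigma2_e")
  acc
}
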