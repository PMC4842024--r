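## Gene-drop simulation of pedigree-structured effects and of phenotypes
## under the nested animal models M1-M4.

#' True parameter set for a simulated trait
#'
#' @param model one of `"M1"` (direct genetic only), `"M2"` (+ maternal
#'   genetic), `"M3"` (+ maternal individual), `"M4"` (both maternal
#'   effects).
#' @param beta0 intercept, trait units.
#' @param sigma2_a,sigma2_m,sigma2_p,sigma2_e variances (trait units
#'   squared) of the direct genetic, maternal genetic, maternal individual
#'   and residual individual effects.  Variances not used by `model` must
#'   be zero (and default to it).
#' @return A list of class `"trait_truth"`.
#' @export
trait_truth <- function(model = c("M1", "M2", "M3", "M4"), beta0 = 0,
                        sigma2_a = 0.6, sigma2_m = 0, sigma2_p = 0,
                        sigma2_e = 0.4) {
  model <- match.arg(model)
  tr <- list(model = model, beta0 = beta0, sigma2_a = sigma2_a,
             sigma2_m = sigma2_m, sigma2_p = sigma2_p, sigma2_e = sigma2_e)
  vs <- unlist(tr[c("sigma2_a", "sigma2_m", "sigma2_p", "sigma2_e")])
  if (any(vs < 0)) stop("variances must be non-negative")
  uses_m <- model %in% c("M2", "M4")
  uses_p <- model %in% c("M3", "M4")
  if (!uses_m && sigma2_m != 0)
    stop("model ", model, " has no maternal genetic term; sigma2_m must be 0")
  if (!uses_p && sigma2_p != 0)
    stop("model ", model, " has no maternal individual term; sigma2_p must be 0")
  structure(tr, class = "trait_truth")
}

#' Gene-drop a pedigree-structured effect
#'
#' Simulates `n` independent vectors with distribution `N(0, variance * A)`
#' by gene dropping: founders are drawn independently, each non-founder is
#' the mean of its known parents' values plus a Mendelian deviation whose
#' variance (`0.5 - 0.25 (F_d + F_s)` of the total with both parents known,
#' `0.75 - 0.25 F_known` with one, `1` with none) makes the marginal law
#' exactly `N(0, variance * A)` under the lenient unknown-parent
#' convention (unknown parents behave like unrelated founders).
#'
#' @param ped a [pedigree()] object.
#' @param variance effect variance, `>= 0`.
#' @param n number of independent replicate vectors.
#' @param seed optional integer seed.
#' @param F optional precomputed inbreeding coefficients (performance).
#' @return A numeric vector of length `np` when `n = 1`, otherwise an
#'   `np x n` matrix.
#' @export
gene_drop <- function(ped, variance, n = 1L, seed = NULL, F = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (variance < 0) stop("variance must be non-negative")
  np <- ped$np
  out <- with_seed(seed, {
    if (variance == 0) {
      matrix(0, np, n)
    } else {
      v <- mendelian_variance(ped, F) * variance
      x <- matrix(0, np, n)
      dam <- ped$dam; sire <- ped$sire
      dev <- matrix(stats::rnorm(np * n), np, n) * sqrt(v)
      for (i in seq_len(np)) {
        pa <- numeric(n)
        if (!is.na(dam[i])) pa <- pa + 0.5 * x[dam[i], ]
        if (!is.na(sire[i])) pa <- pa + 0.5 * x[sire[i], ]
        x[i, ] <- pa + dev[i, ]
      }
      x
    }
  })
  if (n == 1L) drop(out) else out
}

#' Simulate a phenotype data set
#'
#' Draws `y_i = beta0 + a_i + m_{m(i)} + p_{m(i)} + e_i` on the phenotyped
#' individuals of `ped` and `NA` elsewhere.  `a` and `m` are independent
#' gene drops (`N(0, s2 A)` each); `p` holds one i.i.d. value per distinct
#' mother of a phenotyped individual; `e` is i.i.d. residual.  Phenotyped
#' individuals with an unknown mother receive no maternal contribution and
#' are flagged in `maternal_zero`.
#'
#' @param ped a [pedigree()] object.
#' @param truth a [trait_truth()] object.
#' @param seed optional integer seed.
#' @param F optional precomputed inbreeding coefficients.
#' @return A list of class `"trait_dataset"`: `y` (length `np`, `NA` when
#'   unobserved), `observed` (logical mask, `== ped$phenotyped`),
#'   `maternal_zero` (logical over phenotyped individuals), `truth`,
#'   `seed`, and `ped`.
#' @export
simulate_dataset <- function(ped, truth, seed = NULL, F = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(truth, "trait_truth"))
  needs_mat <- truth$sigma2_m > 0 || truth$sigma2_p > 0
  obs <- ped$phenotyped
  if (needs_mat && !any(!is.na(ped$dam[obs])))
    stop("no phenotyped individual has a known mother: ",
         "maternal effects are unobservable in this pedigree")
  y <- with_seed(seed, {
    a <- gene_drop(ped, truth$sigma2_a, F = F)
    m <- gene_drop(ped, truth$sigma2_m, F = F)
    mom <- ped$dam
    mom_obs <- unique(stats::na.omit(mom[obs]))
    p_vals <- stats::rnorm(length(mom_obs), 0, sqrt(truth$sigma2_p))
    pm <- numeric(ped$np)
    pm[!is.na(mom)] <- p_vals[match(mom[!is.na(mom)], mom_obs)]
    pm[is.na(pm)] <- 0 # mothers outside the phenotyped-mother set
    mm <- ifelse(is.na(mom), 0, m[ifelse(is.na(mom), 1L, mom)])
    eps <- stats::rnorm(ped$np, 0, sqrt(truth$sigma2_e))
    truth$beta0 + a + mm + pm + eps
  })
  y[!obs] <- NA_real_
  structure(list(
    y = y,
    observed = obs,
    maternal_zero = is.na(ped$dam)[obs],
    truth = truth,
    seed = seed,
    ped = ped
  ), class = "trait_dataset")
}

#' Write simulated phenotypes to CSV
#'
#' Emits `id,y,observed` in original input row order; unobserved phenotypes
#' are empty fields.
#' @param data a [simulate_dataset()] result.
#' @param path output path.
#' @export
write_phenotypes <- function(data, path) {
  stopifnot(inherits(data, "trait_dataset"))
  ped <- data$ped
  o <- order(ped$orig_order)
  df <- data.frame(id = ped$id[o],
                   y = ifelse(is.na(data$y[o]), "", format(data$y[o], digits = 12)),
                   observed = as.integer(data$observed[o]))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
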