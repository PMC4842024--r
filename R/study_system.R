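## Synthetic study-system generator.
##
## Emulates the gross structure of an insular passerine pedigree: a handful
## of island groups, discrete non-overlapping generations, females mating
## with (possibly repeated) males of the same group and generation,
## occasional immigrants, unknown parents, and a phenotyped subset
## concentrated in later cohorts.  Defaults are frozen so that a default
## draw lands near np ~ 3574 individuals with ~ 1025 phenotyped.

#' Parameters for the synthetic study system
#'
#' @param generations number of discrete generations including founders.
#' @param groups number of island-equivalent groups.
#' @param founders_per_group founder cohort size in each group.
#' @param offspring_mean mean per-female Poisson offspring (recruits) count
#'   at the stable sex ratio.  Reproduction is density-regulated: each
#'   group's cohort is Poisson with total mean
#'   `founders_per_group * offspring_mean / 2` split over its mothers, so
#'   cohort sizes stay near carrying capacity instead of drifting
#'   multiplicatively.
#' @param p_mate_switch probability (per offspring) that the father is
#'   redrawn from the male pool instead of the mother's social mate.
#'   Emulates multiple broods, mate change and extra-pair paternity over a
#'   female's lifetime, producing the maternal half-sib families that
#'   separate maternal effects from additive genetic covariance; with
#'   `0` every maternal sibship is a full-sib family and the two are
#'   nearly confounded.
#' @param p_dam_unknown,p_sire_unknown probability that the respective
#'   parent link is unrecorded (per offspring).
#' @param immigrants_per_group new unrelated founders joining each group
#'   every generation after the first.
#' @param phenotyped_target target proportion of the pedigree carrying a
#'   phenotype record (in expectation).
#' @param phenotype_weight_late relative sampling weight of the last three
#'   generations versus earlier ones (observation effort grows over time).
#' @param phenotype_mother_known if `TRUE` (default) only individuals with
#'   a recorded mother can be phenotyped: the trait is measured at the
#'   nest, so a phenotype record implies a known maternal link, and every
#'   phenotyped record carries its maternal term in the animal model.
#'   Set `FALSE` to let phenotypes fall on unknown-mother individuals too
#'   (their maternal contribution is then zero and flagged).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A list of class `"study_system_params"`.
#' @export
study_system_params <- function(generations = 7L,
                                groups = 6L,
                                founders_per_group = 80L,
                                offspring_mean = 2.05,
                                p_mate_switch = 0.35,
                                p_dam_unknown = 0.08,
                                p_sire_unknown = 0.15,
                                immigrants_per_group = 3L,
                                phenotyped_target = 0.287,
                                phenotype_weight_late = 2.5,
                                phenotype_mother_known = TRUE,
                                seed = NULL) {
  p <- list(generations = as.integer(generations), groups = as.integer(groups),
            founders_per_group = as.integer(founders_per_group),
            offspring_mean = offspring_mean, p_mate_switch = p_mate_switch,
            p_dam_unknown = p_dam_unknown, p_sire_unknown = p_sire_unknown,
            immigrants_per_group = as.integer(immigrants_per_group),
            phenotyped_target = phenotyped_target,
            phenotype_weight_late = phenotype_weight_late,
            phenotype_mother_known = isTRUE(phenotype_mother_known),
            seed = seed)
  stopifnot(p$generations >= 1L, p$groups >= 1L, p$founders_per_group >= 1L,
            p$offspring_mean >= 0, p$immigrants_per_group >= 0L,
            p$p_mate_switch >= 0, p$p_mate_switch <= 1,
            p$p_dam_unknown >= 0, p$p_dam_unknown <= 1,
            p$p_sire_unknown >= 0, p$p_sire_unknown <= 1,
            p$phenotyped_target >= 0, p$phenotyped_target <= 1)
  structure(p, class = "study_system_params")
}

#' Desk-scale study-system parameters
#'
#' Same structure as the full-size defaults but ~ 800 individuals with
#' ~ 240 phenotyped, for laptop-scale simulation studies.
#' @param seed optional seed stored in the params.
#' @export
desk_system_params <- function(seed = NULL) {
  study_system_params(founders_per_group = 18L, immigrants_per_group = 1L,
                      seed = seed)
}

#' Generate a synthetic pedigree
#'
#' Draws a pedigree under [study_system_params()]: founders per group, then
#' for each later generation every female of the previous generation in the
#' group mates a uniformly drawn male of that group/generation (males can be
#' drawn repeatedly, producing both full- and half-sib families) and bears a
#' Poisson number of offspring with even sex odds.  Parent links are
#' independently unrecorded with the configured probabilities, immigrants
#' enter as unrelated founders of later generations, and the phenotyped
#' mask is Bernoulli with extra weight on the last three generations,
#' scaled to hit `phenotyped_target` in expectation.
#'
#' @param params a [study_system_params()] object.
#' @param seed overrides `params$seed` when given.
#' @return A validated [pedigree()] object.
#' @export
generate_pedigree <- function(params = study_system_params(), seed = NULL) {
  stopifnot(inherits(params, "study_system_params"))
  seed <- seed %||% params$seed
  with_seed(seed, {
    id <- character(0); dam <- character(0); sire <- character(0)
    sex <- character(0); gen <- integer(0); grp <- integer(0)
    nid <- 0L
    new_id <- function(k) sprintf("i%05d", nid + seq_len(k))
    for (g in seq_len(params$groups)) {
      k <- params$founders_per_group
      ids <- new_id(k); nid <- nid + k
      id <- c(id, ids); dam <- c(dam, rep(NA, k)); sire <- c(sire, rep(NA, k))
      sex <- c(sex, sample(rep_len(c("F", "M"), k)))
      gen <- c(gen, rep(0L, k)); grp <- c(grp, rep(g, k))
    }
    for (t in seq_len(params$generations - 1L)) {
      born_any <- FALSE
      for (g in seq_len(params$groups)) {
        prev <- which(gen == t - 1L & grp == g)
        moms <- prev[sex[prev] == "F"]
        dads <- prev[sex[prev] == "M"]
        if (length(moms) && length(dads)) {
          born_any <- TRUE
          lam <- params$founders_per_group * params$offspring_mean /
            (2 * length(moms))
          noff <- stats::rpois(length(moms), lam)
          mom_of <- rep(moms, noff)
          mate <- dads[sample.int(length(dads), length(moms), replace = TRUE)]
          dad_of <- rep(mate, noff)
          k <- length(mom_of)
          ## lifetime mate heterogeneity -> maternal half-sibs
          sw <- stats::runif(k) < params$p_mate_switch
          if (any(sw))
            dad_of[sw] <- dads[sample.int(length(dads), sum(sw),
                                          replace = TRUE)]
          if (k) {
            ids <- new_id(k); nid <- nid + k
            dmiss <- stats::runif(k) < params$p_dam_unknown
            smiss <- stats::runif(k) < params$p_sire_unknown
            id <- c(id, ids)
            dam <- c(dam, ifelse(dmiss, NA, id[mom_of]))
            sire <- c(sire, ifelse(smiss, NA, id[dad_of]))
            sex <- c(sex, sample(rep_len(c("F", "M"), k)))
            gen <- c(gen, rep(t, k)); grp <- c(grp, rep(g, k))
          }
        }
        ni <- params$immigrants_per_group
        if (ni > 0L) {
          ids <- new_id(ni); nid <- nid + ni
          id <- c(id, ids); dam <- c(dam, rep(NA, ni)); sire <- c(sire, rep(NA, ni))
          sex <- c(sex, sample(rep_len(c("M", "F"), ni)))
          gen <- c(gen, rep(t, ni)); grp <- c(grp, rep(g, ni))
        }
      }
      if (!born_any)
        stop("study system went extinct at generation ", t,
             ": no group had both mothers and fathers available; ",
             "raise founders_per_group or offspring_mean")
    }
    ## Phenotype mask: Bernoulli, late generations over-sampled, scaled to
    ## the target overall proportion (of the whole pedigree); by default
    ## restricted to individuals whose mother is recorded.
    w <- ifelse(gen >= params$generations - 3L, params$phenotype_weight_late, 1)
    if (params$phenotype_mother_known) w[is.na(dam)] <- 0
    pr <- if (sum(w) > 0)
      pmin(params$phenotyped_target * length(w) * w / sum(w), 1)
    else rep(0, length(w))
    phen <- stats::runif(length(w)) < pr
    pedigree(id = id, dam = dam, sire = sire, sex = sex, phenotyped = phen)
  })
}

#' Summarize a pedigree
#'
#' @param ped a [pedigree()] object.
#' @param max_n passed to [inbreeding_coefficients()]; mean F is skipped
#'   (NA) for pedigrees above this size.
#' @return A list with `np`, `nd`, `generations`, `generation_sizes`,
#'   `prop_known_mother` (overall), `prop_phenotyped_known_mother`,
#'   `mean_maternal_sibship`, `mean_F`.
#' @export
pedigree_summary <- function(ped, max_n = 10000L) {
  stopifnot(inherits(ped, "pedigree"))
  known_mom <- !is.na(ped$dam)
  sib <- table(ped$dam[known_mom])
  meanF <- if (ped$np <= max_n) mean(inbreeding_coefficients(ped)) else NA_real_
  list(
    np = ped$np,
    nd = ped$nd,
    generations = max(ped$generation) + 1L,
    generation_sizes = as.integer(table(factor(ped$generation,
                                               levels = 0:max(ped$generation)))),
    prop_known_mother = mean(known_mom),
    prop_phenotyped_known_mother =
      if (ped$nd > 0) mean(known_mom[ped$phenotyped]) else NA_real_,
    mean_maternal_sibship = if (length(sib)) mean(sib) else 0,
    mean_F = meanF
  )
}
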