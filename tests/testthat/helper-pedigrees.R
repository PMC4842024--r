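## Shared fixtures and independent oracles for the test suite.

## --- fixtures ----------------------------------------------------------

trio_ped <- function() {
  pedigree(id = c("1", "2", "3"), dam = c(NA, NA, "1"), sire = c(NA, NA, "2"),
           sex = c("F", "M", "U"), phenotyped = c(1, 1, 1))
}

founders_ped <- function(n = 10L, phenotyped = TRUE) {
  pedigree(id = as.character(seq_len(n)), dam = rep(NA, n), sire = rep(NA, n),
           sex = rep_len(c("F", "M"), n), phenotyped = rep(phenotyped, n))
}

## 12-individual pedigree with four distinct mothers of phenotyped
## offspring; identifies all four variance components reasonably well.
maternal_ped <- function() {
  pedigree(
    id   = c("gm", "gs", "s1", "d1", "d2", "d3", "o1", "o2", "o3", "o4", "o5", "o6"),
    dam  = c(NA, NA, NA, "gm", "gm", "gm", "d1", "d1", "d2", "d2", "d3", "d3"),
    sire = c(NA, NA, NA, "gs", "gs", "gs", "s1", "s1", "s1", "s1", "s1", "s1"),
    sex  = c("F", "M", "M", "F", "F", "F", "F", "M", "F", "M", "F", "M"),
    phenotyped = c(0, 0, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1))
}

## Random pedigree generator independent of the study_system module:
## individuals arrive in order; each has known parents drawn from earlier
## individuals of the right sex with probability p_parent.
random_ped <- function(n, seed, p_parent = 0.8, phen_prob = 0.8) {
  set.seed(seed)
  sex <- sample(rep_len(c("F", "M"), n))
  dam <- sire <- rep(NA_character_, n)
  for (i in 3:n) {
    fem <- which(sex[seq_len(i - 1L)] == "F")
    mal <- which(sex[seq_len(i - 1L)] == "M")
    if (length(fem) && stats::runif(1) < p_parent)
      dam[i] <- as.character(fem[sample.int(length(fem), 1L)])
    if (length(mal) && stats::runif(1) < p_parent)
      sire[i] <- as.character(mal[sample.int(length(mal), 1L)])
  }
  pedigree(id = as.character(seq_len(n)), dam = dam, sire = sire, sex = sex,
           phenotyped = stats::runif(n) < phen_prob)
}

## small pedigree for fast sampler smoke tests (~60 individuals)
tiny_system <- function(seed = 1) {
  generate_pedigree(study_system_params(
    generations = 4L, groups = 2L, founders_per_group = 8L,
    immigrants_per_group = 1L, phenotyped_target = 0.6), seed = seed)
}

## --- recursive kinship oracle ------------------------------------------
## Classic recursion, memoized, completely independent of the tabular
## method: phi(i,i) = 0.5 (1 + phi(d_i, s_i)); for i < j (topological),
## phi(i,j) = 0.5 (phi(i, d_j) + phi(i, s_j)).
kinship_oracle <- function(ped) {
  n <- ped$np
  memo <- new.env(hash = TRUE, parent = emptyenv())
  phi <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    key <- paste(min(i, j), max(i, j))
    got <- get0(key, envir = memo)
    if (!is.null(got)) return(got)
    val <- if (i == j) {
      0.5 * (1 + phi(ifelse(is.na(ped$dam[i]), 0L, ped$dam[i]),
                     ifelse(is.na(ped$sire[i]), 0L, ped$sire[i])))
    } else {
      a <- min(i, j); b <- max(i, j) # b is the later individual
      0.5 * (phi(a, ifelse(is.na(ped$dam[b]), 0L, ped$dam[b])) +
             phi(a, ifelse(is.na(ped$sire[b]), 0L, ped$sire[b])))
    }
    assign(key, val, envir = memo)
    val
  }
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) K[i, j] <- K[j, i] <- phi(i, j)
  K
}
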