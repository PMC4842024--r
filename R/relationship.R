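## Additive relationship computations on a validated pedigree.
##
## A is built by the tabular method in topological order; its sparse inverse
## by Henderson's rules with inbreeding; inbreeding coefficients come off
## the diagonal (F_i = A_ii - 1 = kinship(dam_i, sire_i)).

#' Additive relationship matrix (tabular method)
#'
#' Computes the numerator relationship matrix `A` in the pedigree's
#' topological order: `A[i,j] = 0.5 * (A[i, dam_j] + A[i, sire_j])` for
#' `i < j` (unknown-parent terms contribute 0) and
#' `A[i,i] = 1 + 0.5 * A[dam_i, sire_i]`, i.e. `1 + F_i`.
#'
#' @param ped a [pedigree()] object.
#' @param max_n dense-memory guard; pedigrees larger than this raise an
#'   error suggesting to work with [a_inverse()] instead.
#' @return A dense symmetric `np x np` matrix with `dimnames = id`.
#' @export
additive_relationship <- function(ped, max_n = 10000L) {
  stopifnot(inherits(ped, "pedigree"))
  n <- ped$np
  if (n > max_n)
    stop("pedigree has ", n, " individuals; dense A needs ~",
         round(8 * n^2 / 2^20), " MiB. Use a_inverse() / sparse workflows ",
         "or raise max_n explicitly.")
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  dam <- ped$dam; sire <- ped$sire
  for (i in seq_len(n)) {
    d <- dam[i]; s <- sire[i]
    if (i > 1L) {
      jj <- seq_len(i - 1L)
      v <- numeric(i - 1L)
      if (!is.na(d)) v <- v + A[jj, d]
      if (!is.na(s)) v <- v + A[jj, s]
      v <- 0.5 * v
      A[jj, i] <- v
      A[i, jj] <- v
    }
    A[i, i] <- 1 + if (!is.na(d) && !is.na(s)) 0.5 * A[d, s] else 0
  }
  A
}

#' Inbreeding coefficients
#'
#' `F_i` is the kinship between individual `i`'s parents; 0 when either
#' parent is unknown.  Computed as `diag(A) - 1` from the tabular method.
#'
#' @inheritParams additive_relationship
#' @return Numeric vector of length `np`, named by individual id.
#' @export
inbreeding_coefficients <- function(ped, max_n = 10000L) {
  diag(additive_relationship(ped, max_n = max_n)) - 1
}

## Mendelian sampling variance (as a multiple of sigma^2) for each
## individual given parental knowledge and parental inbreeding:
## both known: 0.5 - 0.25 (F_d + F_s); one known: 0.75 - 0.25 F_known;
## none: 1.  Gene dropping with these variances reproduces N(0, s2 A)
## exactly, and they are the diagonal of Henderson's decomposition.
mendelian_variance <- function(ped, F = NULL) {
  if (is.null(F)) F <- inbreeding_coefficients(ped)
  dam <- ped$dam; sire <- ped$sire
  v <- rep(1, ped$np)
  bd <- !is.na(dam); bs <- !is.na(sire)
  both <- bd & bs
  v[both] <- 0.5 - 0.25 * (F[dam[both]] + F[sire[both]])
  only_d <- bd & !bs
  v[only_d] <- 0.75 - 0.25 * F[dam[only_d]]
  only_s <- bs & !bd
  v[only_s] <- 0.75 - 0.25 * F[sire[only_s]]
  if (any(v <= 0))
    stop("internal error: non-positive Mendelian sampling variance ",
         "(invalid inbreeding coefficients?)")
  v
}

#' Sparse inverse of the additive relationship matrix
#'
#' Henderson's rules with inbreeding: `A^-1 = T' D^-1 T` where `T` maps
#' each individual to itself minus half its known parents and `D` holds the
#' Mendelian sampling variances.  Nonzeros only arise between an
#' individual, its parents, and its parent pair.
#'
#' @inheritParams additive_relationship
#' @param F optional precomputed inbreeding coefficients.
#' @return A [Matrix::sparseMatrix()] (symmetric, `dsCMatrix`).
#' @export
a_inverse <- function(ped, F = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  n <- ped$np
  v <- mendelian_variance(ped, F)
  dam <- ped$dam; sire <- ped$sire
  ii <- seq_len(n)
  ri <- list(ii); ci <- list(ii); xx <- list(1 / v)
  add <- function(r, c, x) {
    ri[[length(ri) + 1L]] <<- r
    ci[[length(ci) + 1L]] <<- c
    xx[[length(xx) + 1L]] <<- x
  }
  for (pcol in list(dam, sire)) {
    k <- which(!is.na(pcol))
    if (length(k)) {
      add(k, pcol[k], -0.5 / v[k])
      add(pcol[k], k, -0.5 / v[k])
      add(pcol[k], pcol[k], 0.25 / v[k])
    }
  }
  both <- which(!is.na(dam) & !is.na(sire))
  if (length(both)) {
    add(dam[both], sire[both], 0.25 / v[both])
    add(sire[both], dam[both], 0.25 / v[both])
  }
  Ainv <- Matrix::sparseMatrix(
    i = unlist(ri), j = unlist(ci), x = unlist(xx),
    dims = c(n, n), dimnames = list(ped$id, ped$id)
  )
  Matrix::forceSymmetric((Ainv + Matrix::t(Ainv)) / 2)
}

#' Relationship structure bundle
#'
#' Convenience wrapper returning `A`, its sparse inverse and the inbreeding
#' coefficients together.
#'
#' @inheritParams additive_relationship
#' @return A list of class `"relationship_structure"` with elements
#'   `order` (np), `A`, `A_inv`, `F`.
#' @export
relationship_structure <- function(ped, max_n = 10000L) {
  A <- additive_relationship(ped, max_n = max_n)
  F <- diag(A) - 1
  structure(
    list(order = ped$np, A = A, A_inv = a_inverse(ped, F = F), F = F),
    class = "relationship_structure"
  )
}
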