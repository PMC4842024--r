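## Pedigree ingestion and validation.
##
## A pedigree is stored in a validated topological order (parents before
## offspring, stable tie-breaking by input order).  Identifiers are opaque
## strings; all matrix work downstream is positional.

#' Construct a pedigree object
#'
#' Builds a validated pedigree from parallel vectors.  Individuals are
#' reordered topologically (parents before offspring) with stable
#' tie-breaking by input order; the original input position is kept in
#' `orig_order` so files can be round-tripped unchanged.
#'
#' @param id character vector of unique individual identifiers.
#' @param dam,sire character vectors of parent identifiers; `NA` (or a code
#'   in `missing_codes`) marks an unknown parent.
#' @param sex optional character vector, values in `c("F", "M", "U")`.
#'   Defaults to `"U"`; individuals used as dams/sires must not have a
#'   contradictory sex.
#' @param phenotyped optional logical (or 0/1) vector flagging individuals
#'   that carry a phenotype record; defaults to all `TRUE`.
#' @param missing_codes character codes interpreted as "unknown parent" in
#'   addition to `NA`.
#' @param strict if `TRUE`, a parent identifier absent from `id` is an
#'   error; if `FALSE` (default, lenient mode) such parents are promoted to
#'   founders with a warning.
#'
#' @return An object of class `"pedigree"`: a list with components
#'   `id`, `dam`, `sire` (integer indices into `id`, `NA` = unknown),
#'   `sex`, `phenotyped`, `generation` (founder depth), `orig_order`,
#'   and counts `np` (pedigree size) and `nd` (number phenotyped).
#' @export
#' @examples
#' trio <- pedigree(id = c("1", "2", "3"), dam = c(NA, NA, "1"),
#'                  sire = c(NA, NA, "2"))
#' trio$np
pedigree <- function(id, dam, sire, sex = NULL, phenotyped = NULL,
                     missing_codes = c("0", "", "NA", "*", "."),
                     strict = FALSE) {
  id <- as.character(id)
  dam <- as.character(dam)
  sire <- as.character(sire)
  n0 <- length(id)
  stopifnot(length(dam) == n0, length(sire) == n0)
  if (anyDuplicated(id))
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  dam[dam %in% missing_codes] <- NA_character_
  sire[sire %in% missing_codes] <- NA_character_

  if (is.null(sex)) sex <- rep("U", n0)
  sex <- toupper(as.character(sex))
  sex[is.na(sex) | !sex %in% c("F", "M")] <- "U"
  if (is.null(phenotyped)) phenotyped <- rep(TRUE, n0)
  if (is.character(phenotyped))
    phenotyped <- phenotyped %in% c("1", "TRUE", "true", "T", "yes")
  phenotyped <- as.logical(phenotyped)
  phenotyped[is.na(phenotyped)] <- FALSE

  ## Lenient mode: promote parents missing from the file to founders.
  ghosts <- setdiff(stats::na.omit(c(dam, sire)), id)
  if (length(ghosts)) {
    if (strict)
      stop("parent id(s) not present in pedigree: ",
           paste(utils::head(ghosts, 5L), collapse = ", "),
           if (length(ghosts) > 5L) ", ...")
    pp_log("warn", length(ghosts),
           " parent id(s) absent from file; promoted to founders")
    gh_sex <- ifelse(ghosts %in% dam, "F", "M")
    id <- c(id, ghosts)
    dam <- c(dam, rep(NA_character_, length(ghosts)))
    sire <- c(sire, rep(NA_character_, length(ghosts)))
    sex <- c(sex, gh_sex)
    phenotyped <- c(phenotyped, rep(FALSE, length(ghosts)))
  }
  n <- length(id)
  di <- match(dam, id)
  si <- match(sire, id)

  bad <- which(!is.na(di) & !is.na(si) & di == si)
  if (length(bad))
    stop("dam and sire identical for individual(s): ",
         paste(id[utils::head(bad, 5L)], collapse = ", "))
  bad <- which(!is.na(di) & sex[di] == "M")
  if (length(bad))
    stop("individual(s) of sex M referenced as dam: ",
         paste(unique(id[di[bad]]), collapse = ", "))
  bad <- which(!is.na(si) & sex[si] == "F")
  if (length(bad))
    stop("individual(s) of sex F referenced as sire: ",
         paste(unique(id[si[bad]]), collapse = ", "))
  ## A known dam is female, a known sire male (resolves "U").
  sex[stats::na.omit(di)] <- "F"
  sex[stats::na.omit(si)] <- "M"

  ord <- topo_order(di, si, id)

  rank <- integer(n); rank[ord] <- seq_len(n)
  remap <- function(p) ifelse(is.na(p), NA_integer_, rank[p])
  structure(list(
    id = id[ord],
    dam = remap(di)[ord],
    sire = remap(si)[ord],
    sex = sex[ord],
    phenotyped = phenotyped[ord],
    generation = founder_depth(remap(di)[ord], remap(si)[ord]),
    orig_order = seq_len(n)[ord],
    np = n,
    nd = sum(phenotyped)
  ), class = "pedigree")
}

## Kahn's algorithm with stable tie-breaking by input order; reports a cycle
## when one exists (any self-ancestry shows up here).
topo_order <- function(di, si, id) {
  n <- length(id)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(di[i], si[i])) {
      if (!is.na(p)) {
        if (p == i) stop("cycle detected in pedigree: ", id[i],
                         " is its own ancestor (", id[i], " -> ", id[i], ")")
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  ord <- integer(0)
  avail <- which(indeg == 0L) # already in input order
  while (length(avail)) {
    v <- avail[1L]; avail <- avail[-1L]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) avail <- sort(c(avail, k))
    }
  }
  if (length(ord) < n) {
    stuck <- setdiff(seq_len(n), ord)
    cyc <- trace_cycle(di, si, stuck[1L])
    stop("cycle detected in pedigree: ",
         paste(id[cyc], collapse = " -> "))
  }
  ord
}

trace_cycle <- function(di, si, start) {
  seen <- integer(0)
  v <- start
  repeat {
    if (v %in% seen) {
      i <- match(v, seen)
      return(c(seen[i:length(seen)], v))
    }
    seen <- c(seen, v)
    nxt <- c(di[v], si[v])
    nxt <- nxt[!is.na(nxt)]
    if (!length(nxt)) return(seen) # not actually cyclic (defensive)
    v <- nxt[1L]
  }
}

## Generation = 1 + max parental generation; founders are generation 0.
founder_depth <- function(dam, sire, n = length(dam)) {
  g <- integer(n)
  for (i in seq_len(n)) {
    gp <- c(if (!is.na(dam[i])) g[dam[i]], if (!is.na(sire[i])) g[sire[i]])
    g[i] <- if (length(gp)) max(gp) + 1L else 0L
  }
  g
}

#' Read a pedigree file
#'
#' Reads a delimited text pedigree with header columns
#' `id,dam,sire[,sex][,phenotyped]`.  Unknown parents are coded `"0"`,
#' empty, or any code in `missing_codes`.  `sex` takes values `F`, `M`,
#' `U`; `phenotyped` is 0/1.  Missing optional columns default to
#' `sex = "U"` and `phenotyped = 1`.
#'
#' @param path file path.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @inheritParams pedigree
#' @return A validated [pedigree()] object.
#' @seealso [write_pedigree()] for the mirror writer.
#' @export
read_pedigree <- function(path, sep = ",",
                          missing_codes = c("0", "", "NA", "*", "."),
                          strict = FALSE) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", strip.white = TRUE)
  need <- c("id", "dam", "sire")
  if (!all(need %in% names(df)))
    stop("pedigree file must have header columns id, dam, sire (got: ",
         paste(names(df), collapse = ", "), ")")
  ped <- pedigree(
    id = df$id, dam = df$dam, sire = df$sire,
    sex = if ("sex" %in% names(df)) df$sex else NULL,
    phenotyped = if ("phenotyped" %in% names(df)) df$phenotyped else NULL,
    missing_codes = missing_codes, strict = strict
  )
  pp_log("info", "read pedigree: np=", ped$np, ", nd=", ped$nd)
  ped
}

#' Write a pedigree file
#'
#' Emits the same dialect [read_pedigree()] accepts
#' (`id,dam,sire,sex,phenotyped`, unknown parent = `0`), in the original
#' input row order so canonical files round-trip bit-exactly.
#'
#' @param ped a [pedigree()] object.
#' @param path output file path.
#' @param sep field separator.
#' @export
write_pedigree <- function(ped, path, sep = ",") {
  stopifnot(inherits(ped, "pedigree"))
  o <- order(ped$orig_order)
  df <- data.frame(
    id = ped$id[o],
    dam = ifelse(is.na(ped$dam[o]), "0", ped$id[ped$dam[o]]),
    sire = ifelse(is.na(ped$sire[o]), "0", ped$id[ped$sire[o]]),
    sex = ped$sex[o],
    phenotyped = as.integer(ped$phenotyped[o])
  )
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree: np =", x$np, ", nd =", x$nd,
      ", generations =", max(x$generation) + 1L, "\n")
  cat("founders:", sum(is.na(x$dam) & is.na(x$sire)),
      "; known mother:", sum(!is.na(x$dam)), "\n")
  invisible(x)
}
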