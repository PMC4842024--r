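## pedigree ingestion, validation, and relationship computations

test_that("minimal trio parses, orders, and round-trips through the file dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,dam,sire,sex,phenotyped",
               "3,1,2,U,1", "1,0,0,F,1", "2,0,0,M,0"), path)
  ped <- suppressMessages(read_pedigree(path))
  expect_s3_class(ped, "pedigree")
  expect_equal(ped$np, 3L)
  expect_equal(ped$nd, 2L)
  ## topological order: founders first, offspring last
  expect_equal(ped$id[3], "3")
  expect_setequal(ped$id[1:2], c("1", "2"))
  expect_true(is.na(ped$dam[1]) && is.na(ped$dam[2]))
  ## writer restores the original row order bit-exactly up to unknown codes
  out <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(ped, out)
  expect_identical(readLines(out),
                   c("id,dam,sire,sex,phenotyped",
                     "3,1,2,U,1", "1,0,0,F,1", "2,0,0,M,0"))
  ## canonical file written by us round-trips bit-exactly
  ped2 <- suppressMessages(read_pedigree(out))
  out2 <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(ped2, out2)
  expect_identical(readLines(out2), readLines(out))
})

test_that("invalid pedigrees are rejected with informative errors", {
  expect_error(pedigree(id = c("1", "1"), dam = c(NA, NA), sire = c(NA, NA)),
               "duplicate")
  ## self-ancestry
  expect_error(pedigree(id = c("5"), dam = c("5"), sire = c(NA)),
               "cycle")
  ## two-node cycle
  expect_error(pedigree(id = c("a", "b"), dam = c("b", "a"),
                        sire = c(NA, NA), sex = c("F", "F")),
               "cycle")
  ## dam == sire
  expect_error(pedigree(id = c("1", "2"), dam = c(NA, "1"), sire = c(NA, "1")),
               "dam and sire identical")
  ## sex conflicts
  expect_error(pedigree(id = c("1", "2"), dam = c(NA, "1"), sire = c(NA, NA),
                        sex = c("M", "U")),
               "referenced as dam")
  ## strict mode: unknown parent id
  expect_error(pedigree(id = c("1"), dam = c("99"), sire = NA, strict = TRUE),
               "not present")
  ## lenient mode promotes it to a founder
  ped <- suppressMessages(pedigree(id = c("1"), dam = c("99"), sire = NA))
  expect_equal(ped$np, 2L)
  expect_equal(ped$sex[ped$id == "99"], "F")
  expect_false(ped$phenotyped[ped$id == "99"])
})

test_that("inbreeding coefficients match closed forms and the kinship oracle", {
  expect_equal(inbreeding_coefficients(founders_ped(6)), rep(0, 6),
               ignore_attr = TRUE)
  ## offspring of full sibs: F = 0.25
  ped <- pedigree(
    id = c("p1", "p2", "s1", "s2", "x"),
    dam = c(NA, NA, "p1", "p1", "s1"),
    sire = c(NA, NA, "p2", "p2", "s2"),
    sex = c("F", "M", "F", "M", "U"))
  expect_equal(unname(inbreeding_coefficients(ped)["x"]), 0.25)
  ## random pedigree vs recursive kinship: F_i = 2 phi(i,i) - 1
  ped <- random_ped(50, seed = 4)
  K <- kinship_oracle(ped)
  expect_equal(unname(inbreeding_coefficients(ped)), 2 * diag(K) - 1,
               tolerance = 1e-12)
})

test_that("A carries the standard coefficients and founders give the identity", {
  expect_equal(additive_relationship(founders_ped(5)), diag(5),
               ignore_attr = TRUE)
  ped <- pedigree(
    id = c("d", "s", "c1", "c2", "s2", "h"),
    dam = c(NA, NA, "d", "d", NA, "d"),
    sire = c(NA, NA, "s", "s", NA, "s2"),
    sex = c("F", "M", "U", "U", "M", "U"))
  A <- additive_relationship(ped)
  expect_equal(A["d", "c1"], 0.5)   # parent-offspring
  expect_equal(A["c1", "c2"], 0.5)  # full sibs
  expect_equal(A["c1", "h"], 0.25)  # half sibs
  expect_equal(diag(A), rep(1, 6), ignore_attr = TRUE) # all non-inbred
})

test_that("A equals twice the recursive kinship oracle on random pedigrees", {
  for (cfg in list(c(n = 50, seed = 1), c(n = 120, seed = 2),
                   c(n = 200, seed = 3))) {
    ped <- random_ped(cfg[["n"]], seed = cfg[["seed"]])
    A <- additive_relationship(ped)
    expect_lt(max(abs(A - 2 * kinship_oracle(ped))), 1e-12)
    ## PSD within tolerance
    expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
              -1e-9)
  }
})

test_that("a_inverse inverts A and has the closed-form trio pattern", {
  expect_equal(as.matrix(a_inverse(founders_ped(4))), diag(4),
               ignore_attr = TRUE)
  trio <- trio_ped()
  Ainv <- as.matrix(a_inverse(trio))
  expect_equal(Ainv,
               matrix(c(1.5, 0.5, -1, 0.5, 1.5, -1, -1, -1, 2), 3, 3),
               ignore_attr = TRUE)
  for (seed in 1:3) {
    ped <- random_ped(80, seed = seed)
    A <- additive_relationship(ped)
    expect_lt(max(abs(A %*% as.matrix(a_inverse(ped)) - diag(ped$np))), 1e-8)
  }
})

test_that("permuting input rows permutes A consistently", {
  ped <- random_ped(60, seed = 9)
  A <- additive_relationship(ped)
  set.seed(10)
  perm <- sample(ped$np)
  o <- order(ped$orig_order) # back to "file" order
  ped2 <- pedigree(id = ped$id[o][perm],
                   dam = ifelse(is.na(ped$dam[o][perm]), NA,
                                ped$id[ped$dam[o][perm]]),
                   sire = ifelse(is.na(ped$sire[o][perm]), NA,
                                 ped$id[ped$sire[o][perm]]),
                   sex = ped$sex[o][perm],
                   phenotyped = ped$phenotyped[o][perm])
  A2 <- additive_relationship(ped2)
  expect_lt(max(abs(A2[ped$id, ped$id] - A)), 1e-12)
})

test_that("synthetic pedigrees round-trip through the writer unchanged", {
  ped <- tiny_system(seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(ped, path)
  ped2 <- suppressMessages(read_pedigree(path))
  expect_equal(ped2$np, ped$np)
  expect_identical(ped2$id, ped$id)
  expect_identical(ped2$dam, ped$dam)
  expect_identical(ped2$sire, ped$sire)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(ped2, path2)
  expect_identical(readLines(path2), readLines(path))
})
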