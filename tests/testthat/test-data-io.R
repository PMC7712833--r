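test_that("phenotype validation rejects bad rows with the row number", {
  expect_s4_class(tiny_data(), "DiallelData")
  expect_equal(nRecords(tiny_data()), 3)
  expect_error(tiny_data(tnb = c(8, 2, 10), sb = c(1, 3, 2)), "row 2")
  expect_error(tiny_data(cross = c("EE", "XX", "RT")), "row 2.*XX")
  expect_error(tiny_data(parity = c(1, 7, 1)), "row 2")
})

test_that("phenotype files round-trip through read/write", {
  d <- tiny_data()
  f <- withr::local_tempfile(fileext = ".tsv")
  writePhenotypes(d, f)
  d2 <- readPhenotypes(f)
  expect_equal(records(d2), records(d))
  f2 <- withr::local_tempfile(fileext = ".csv")
  writePhenotypes(d, f2, sep = ",")
  expect_equal(records(readPhenotypes(f2)), records(d))
  # single valid row
  writeLines("sow_id\tcross\tparity\tyear_season\ttnb\tsb\ns1\tEE\t1\ty1\t8\t1", f)
  expect_equal(nRecords(readPhenotypes(f)), 1)
  # invalid row is named
  writeLines("sow_id\tcross\tparity\tyear_season\ttnb\tsb\ns1\tEE\t1\ty1\t2\t3", f)
  expect_error(readPhenotypes(f), "row 1")
  writeLines("sow_id\tcross\tparity\tyear_season\ttnb\tsb\ns1\tEE\t1\ty1\tx\t0", f)
  expect_error(readPhenotypes(f), "non-integer tnb")
})

test_that("pedigree files round-trip and cycles are rejected", {
  ped <- pedigree(c("s", "d", "o"), c("0", "0", "s"), c("0", "0", "d"),
                  population = c("E", "R", NA))
  f <- withr::local_tempfile(fileext = ".txt")
  writePedigree(ped, f)
  ped2 <- readPedigree(f)
  expect_equal(ped2@id, ped@id)
  expect_equal(ped2@sire, ped@sire)
  expect_equal(ped2@population, c("E", "R", NA))
  expect_error(pedigree(c("a", "b"), c("b", "a"), c(0, 0)), "cyclic")
  # mixed founders/non-founders round-trip with correct parent alignment
  big <- simulatePedigree(simConfig(scale = 0.02))$pedigree
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writePedigree(big, f2)
  big2 <- readPedigree(f2)
  expect_equal(sort(big2@id), sort(big@id))
  o <- match(big@id, big2@id)
  pid <- function(p, idx) {
    out <- rep("0", length(idx))
    out[idx > 0] <- p@id[idx[idx > 0]]
    out
  }
  expect_equal(pid(big2, big2@sire[o]), pid(big, big@sire))
  expect_equal(pid(big2, big2@dam[o]), pid(big, big@dam))
  # out-of-order input is topologically sorted
  ped3 <- pedigree(c("o", "s", "d"), c("s", 0, 0), c("d", 0, 0))
  expect_true(match("o", ped3@id) > match("s", ped3@id))
})

test_that("relationship matrix reproduces textbook identities", {
  # unrelated founders
  rel0 <- buildRelationship(tiny_pedigree(c("x", "y")))
  expect_equal(rel0@A, diag(2), ignore_attr = TRUE)
  # sire-dam-offspring trio
  rel <- buildRelationship(pedigree(c("s", "d", "o"), c(0, 0, "s"), c(0, 0, "d")))
  expect_equal(rel@A["o", "s"], 0.5)
  expect_equal(rel@A["o", "o"], 1)
  # full sibs (a = 0.5) and their inbred offspring (F = 0.5 * 0.5 = 0.25)
  ped <- pedigree(c("s", "d", "f1", "f2", "k"),
                  c(0, 0, "s", "s", "f1"), c(0, 0, "d", "d", "f2"))
  rel <- buildRelationship(ped)
  expect_equal(rel@A["f1", "f2"], 0.5)
  expect_equal(rel@A["k", "k"], 1.25)
  expect_equal(unname(inbreeding(ped)["k"]), 0.25)
})

test_that("Henderson's inverse agrees with the tabular method on random pedigrees", {
  set.seed(11)
  for (rep in 1:5) {
    rp <- random_pedigree(50)
    ped <- pedigree(rp$id, ifelse(rp$sire == 0, "0", rp$id[pmax(rp$sire, 1)]),
                    ifelse(rp$dam == 0, "0", rp$id[pmax(rp$dam, 1)]))
    rel <- buildRelationship(ped)
    # package A equals the naive tabular oracle (same ordering by construction)
    ord <- match(ped@id, rp$id)
    A_oracle <- oracle_tabular_A(rp$sire, rp$dam)[ord, ord]
    expect_equal(unname(rel@A), A_oracle, tolerance = 1e-10)
    # Henderson's sparse inverse really inverts A
    expect_lt(max(abs(as.matrix(rel@Ainv %*% rel@A) - diag(50))), 1e-8)
    # positive definite
    expect_silent(chol(rel@A))
    expect_true(all(diag(rel@A) >= 1))
  }
})
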