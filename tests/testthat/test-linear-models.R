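test_that("model specs enforce the coefficient layout of models I-V", {
  expect_equal(length(modelSpec("I")@lambda1), 0)
  expect_equal(length(modelSpec("II")@lambda1), 1)
  expect_equal(length(modelSpec("III")@lambda2), 1)
  expect_equal(length(modelSpec("IV")@lambda1), 9)
  expect_equal(length(modelSpec("V")@lambda2), 9)
  expect_error(new("ModelSpec", modelId = "II", tBar = 1,
                   lambda1 = numeric(0), lambda2 = numeric(0)), "lambda1")
})

test_that("design matrices are one-hot with the documented rank convention", {
  d <- tiny_data()
  ped <- tiny_pedigree(c("a", "b"))
  ds <- buildDesigns(d, ped)
  # all 9 cross columns kept, first parity and first year-season dropped
  expect_equal(ncol(ds$X), 9 + 5 + 1)
  expect_equal(unname(rowSums(ds$X[, 1:9])), rep(1, 3))
  # record 1: parity 1 and ys level 1 are absorbed -> only the cross column
  expect_equal(sum(ds$X[1, ]), 1)
  # two records of the same sow share random-effect rows
  expect_equal(ds$sowPed[1], ds$sowPed[2])
  expect_equal(ds$sowPe[1], ds$sowPe[2])
  expect_error(buildDesigns(d, tiny_pedigree("a")), "absent from pedigree")
})

test_that("the design of a simulated dataset is full column rank", {
  sim <- simulateDiallel(simConfig(scale = 0.06), seed = 5)
  ds <- buildDesigns(sim$data, sim$pedigree)
  expect_gt(nrow(ds$X), 400)
  expect_equal(qr(ds$X)$rank, ncol(ds$X))
})

test_that("logit predictor implements the five recursion forms", {
  # shared slope: one extra piglet adds lambda1 logit units
  sp2 <- modelSpec("II", tBar = 8.46, lambda1 = 0.257)
  expect_equal(logitPhi(sp2, 0, 8.46 + 1, "EE"), 0.257)
  # model I ignores litter size entirely
  sp1 <- modelSpec("I")
  expect_equal(logitPhi(sp1, 1.5, c(2, 20), c("EE", "TT")), c(1.5, 1.5))
  # model V: only the record's own cross coefficients act
  l1 <- setNames(rep(0, 9), crossCodes()); l1["RT"] <- 0.3
  l2 <- setNames(rep(0, 9), crossCodes()); l2["RT"] <- -0.02
  l1["EE"] <- 99; l2["EE"] <- 99          # inert for an RT record
  sp5 <- modelSpec("V", tBar = 8, lambda1 = l1, lambda2 = l2)
  expect_equal(logitPhi(sp5, 0, 10, "RT"), 0.3 * 2 - 0.02 * 4)
  # affine in d with the specified derivative
  sp3 <- modelSpec("III", tBar = 8, lambda1 = 0.2, lambda2 = 0.05)
  d0 <- 1.7; h <- 1e-5
  slope <- (logitPhi(sp3, 0, 8 + d0 + h, "EE") -
            logitPhi(sp3, 0, 8 + d0 - h, "EE")) / (2 * h)
  expect_equal(slope, 0.2 + 2 * 0.05 * d0, tolerance = 1e-8)
  # model IV with equal per-cross slopes reproduces model II exactly
  sp4 <- modelSpec("IV", tBar = 8.46, lambda1 = rep(0.257, 9))
  tnbs <- c(3, 8, 15); crs <- c("EE", "RT", "TT")
  expect_equal(logitPhi(sp4, 0.4, tnbs, crs), logitPhi(sp2, 0.4, tnbs, crs))
  # unresolved tBar is an error for recursive models
  expect_error(logitPhi(modelSpec("II"), 0, 9, "EE"), "tBar")
})

test_that("Gaussian predictor is the incidence sum of its effects", {
  d <- tiny_data()
  ds <- buildDesigns(d, tiny_pedigree(c("a", "b")))
  eff0 <- list(b = numeric(ncol(ds$X)), u = c(0, 0), p = c(0, 0))
  expect_equal(linearPredictorT(eff0, ds), c(0, 0, 0))
  b <- numeric(ncol(ds$X)); b[1] <- 2.5       # cross EE effect
  eff <- list(b = b, u = c(0.3, 0), p = c(0, -0.1))
  # records 1-2 are EE of sow "a" (pedigree pos 1, sow pos 1)
  expect_equal(linearPredictorT(eff, ds)[1:2], c(2.5 + 0.3, 2.5 + 0.3),
               ignore_attr = TRUE)
})
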