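test_that("simulated pedigree honours the cross-code convention and counts", {
  cfg <- simConfig(scale = 0.05)
  set.seed(1)
  pd <- simulatePedigree(cfg)
  ped <- pd$pedigree
  # requested sow counts met exactly
  expect_equal(unname(table(pd$sows$cross)[crossCodes()]),
               unname(cfg$sowsPerCross), ignore_attr = TRUE)
  # an ER sow has an E sire and an R dam (sire variety first)
  er <- pd$sows$sow_id[pd$sows$cross == "ER"][1]
  i <- match(er, ped@id)
  expect_equal(ped@population[ped@sire[i]], "E")
  expect_equal(ped@population[ped@dam[i]], "R")
  # founders are unrelated: the founder block of A is the identity
  founders <- which(ped@sire == 0L & ped@dam == 0L)
  rel <- buildRelationship(ped)
  expect_equal(rel@A[founders, founders], diag(length(founders)),
               ignore_attr = TRUE)
})

test_that("the generator is reproducible from its seed", {
  cfg <- simConfig(scale = 0.03)
  s1 <- simulateDiallel(cfg)
  s2 <- simulateDiallel(cfg)
  expect_identical(records(s1$data), records(s2$data))
  expect_identical(s1$pedigree@id, s2$pedigree@id)
  s3 <- simulateDiallel(cfg, seed = 999)
  expect_false(identical(records(s1$data)$sb, records(s3$data)$sb))
})

test_that("with theta = 1 and no heterogeneity the counts are exactly binomial", {
  # constant phi across litters: per-event death frequency must match the
  # binomial/MBN success probability within Monte Carlo error
  cfg <- simConfig(scale = 3, theta = 1,
                   spec = modelSpec("I", tBar = 8.46),
                   crossEffL = setNames(rep(0, 9), crossCodes()),
                   parityEffL = rep(0, 6), ysSdL = 0,
                   G = diag(c(1e-10, 0.397)), P = diag(c(1e-10, 0.368)),
                   baseLogit = qlogis(0.03))
  sim <- simulateDiallel(cfg, seed = 3)
  rec <- records(sim$data)
  expect_gt(nrow(rec), 2e4)
  phat <- sum(rec$sb) / sum(rec$tnb)
  se <- sqrt(0.03 * 0.97 / sum(rec$tnb))
  expect_lt(abs(phat - 0.03), 4 * se)
  # conditional distribution is binomial: variance of sb among litters of a
  # common size matches n p (1 - p) within sampling error
  sizes <- as.integer(names(sort(table(rec$tnb), decreasing = TRUE)))[1:3]
  for (s in sizes) {
    v <- var(rec$sb[rec$tnb == s])
    n_s <- sum(rec$tnb == s)
    expect_equal(v, s * 0.03 * 0.97, tolerance = 6 / sqrt(n_s))
  }
})

test_that("gene dropping reproduces the A (x) G covariance", {
  ped <- pedigree(c("f1", "f2", "f3", "a", "b", "c", "k"),
                  c(0, 0, 0, "f1", "f1", "f3", "b"),
                  c(0, 0, 0, "f2", "f2", "a", "c"))
  G <- matrix(c(0.5, 0.2, 0.2, 1.0), 2)
  A <- buildRelationship(ped)@A
  K <- kronecker(A, G)
  set.seed(14)
  reps <- 3000
  M <- matrix(0, reps, 14)
  for (r in seq_len(reps)) {
    U <- mbnDiallel:::.gene_drop(ped, G)
    M[r, ] <- c(t(U))                        # interleaved (l, t) per individual
  }
  emp <- cov(M)
  tru <- matrix(0, 14, 14)
  for (i in 1:7) for (j in 1:7)
    tru[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)] <- A[i, j] * G
  expect_lt(max(abs(emp - tru)) / max(abs(tru)), 0.1)
})

test_that("a positive recursion raises mortality in large litters", {
  base <- simConfig(scale = 0.15, spec = modelSpec("II", tBar = 8.46, lambda1 = 0),
                    baseLogit = -2.2)
  pos <- simConfig(scale = 0.15, spec = modelSpec("II", tBar = 8.46, lambda1 = 0.5),
                   baseLogit = -2.2)
  ratio_gap <- function(sim) {
    rec <- records(sim$data)
    big <- rec$tnb > 10; small <- rec$tnb < 7
    sum(rec$sb[big]) / sum(rec$tnb[big]) -
      sum(rec$sb[small]) / sum(rec$tnb[small])
  }
  g0 <- ratio_gap(simulateDiallel(base, seed = 15))
  g1 <- ratio_gap(simulateDiallel(pos, seed = 15))
  expect_gt(g1, g0)
  expect_gt(g1, 0)
})

test_that("the default configuration matches the survey structure", {
  cfg <- simConfig()
  expect_equal(sum(cfg$sowsPerCross), 2110)
  expect_equal(unname(cfg$foundersSires + cfg$foundersDams), c(47, 80, 107))
  # record count within 10% of the survey's 10,255 and mean TNB near 8.46
  # (averaged over replicates: the cohort mean carries realisation noise of
  # about +-0.08 from the finite founder pool)
  tnb_means <- n_rec <- numeric(3)
  for (r in 1:3) {
    sim <- simulateDiallel(cfg, seed = r)
    tnb_means[r] <- mean(records(sim$data)$tnb)
    n_rec[r] <- nRecords(sim$data)
  }
  expect_lt(abs(mean(n_rec) - 10255) / 10255, 0.1)
  expect_lt(abs(mean(tnb_means) - 8.46), 0.1)
})
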