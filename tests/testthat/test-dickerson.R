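test_that("forward map reproduces the crossbreeding coefficient table", {
  z <- c(0, 0, 0)
  expect_equal(unname(dickersonForward(z, z, z)), rep(0, 9))
  expect_equal(unname(dickersonForward(c(1, 0, 0), z, z)),
               c(1, 0.5, 0.5, 0.5, 0, 0, 0.5, 0, 0))
  # maternal effect follows the dam variety (second letter of the code)
  expect_equal(dickersonForward(z, c(0, 1, 0), z)[c("ER", "TR", "RR")],
               c(ER = 1, TR = 1, RR = 1))
  # documented null vector: D = +1, M = -1, H = 0
  expect_equal(unname(dickersonForward(c(1, 1, 1), c(-1, -1, -1), z)),
               rep(0, 9))
})

test_that("solver has rank 8 and recovers estimable contrasts exactly", {
  s0 <- dickersonSolve(rep(0, 9))
  expect_equal(unname(s0$params), rep(0, 9))
  expect_equal(s0$rank, 8)
  b <- c(EE = 0.2, ER = 0.5, ET = 0, RE = 0.3, RR = 0.1,
         RT = 0, TE = 0, TR = 0, TT = 0)
  s <- dickersonSolve(b)
  expect_equal(unname(s$params["H_ER"]), (0.5 + 0.3 - 0.2 - 0.1) / 2,
               tolerance = 1e-12)
  set.seed(3)
  for (i in 1:100) {
    D <- rnorm(3); M <- rnorm(3); H <- rnorm(3)
    bb <- dickersonForward(D, M, H)
    s <- dickersonSolve(bb)
    # b in the row space: residual ~ 0
    expect_lt(s$residual, 1e-10)
    # heterosis and within-block differences are invariant
    expect_equal(unname(s$params[7:9]), H, tolerance = 1e-10)
    expect_equal(unname(diff(s$params[1:3])), diff(D), tolerance = 1e-10)
    expect_equal(unname(diff(s$params[4:6])), diff(M), tolerance = 1e-10)
    expect_equal(unname(s$params[7:9]), unname(heterosisContrasts(bb)),
                 tolerance = 1e-10)
  }
})

test_that("estimable contrasts ignore a constant shift of all cross effects", {
  set.seed(8)
  b <- rnorm(9)
  s1 <- dickersonSolve(b)
  s2 <- dickersonSolve(b + 3.7)
  expect_equal(s1$params[7:9], s2$params[7:9], tolerance = 1e-10)
  expect_equal(diff(s1$params[1:3]), diff(s2$params[1:3]), tolerance = 1e-10)
  expect_equal(diff(s1$params[4:6]), diff(s2$params[4:6]), tolerance = 1e-10)
  expect_equal(heterosisContrasts(b), heterosisContrasts(b + 3.7),
               tolerance = 1e-12)
})

test_that("sum-to-zero mode constrains blocks but keeps the contrasts", {
  set.seed(9)
  b <- dickersonForward(rnorm(3), rnorm(3), rnorm(3))
  s <- dickersonSolve(b, constraint = "sum-to-zero")
  expect_equal(sum(s$params[1:3]), 0, tolerance = 1e-10)
  expect_equal(sum(s$params[4:6]), 0, tolerance = 1e-10)
  smn <- dickersonSolve(b)
  expect_equal(s$params[7:9], smn$params[7:9], tolerance = 1e-8)
  expect_lt(s$residual, 1e-8)
})

test_that("chain transform summarises the posterior of the parameters", {
  b <- c(0.2, 0.5, 0, 0.3, 0.1, 0, 0, 0, 0)
  cols <- paste0("b_l.cross.", crossCodes())
  # constant draws: degenerate posterior
  m <- matrix(rep(b, each = 50), 50, 9, dimnames = list(NULL, cols))
  dt <- dickersonChain(fake_chain(m), trait = "l")
  expect_equal(dt$sd, rep(0, 9))
  expect_equal(dt$mean[dt$parameter == "H_ER"], 0.25, tolerance = 1e-10)
  expect_equal(dt$hpd_lo, dt$hpd_hi)
  # direct and maternal blocks reported as mean-zero deviations
  expect_equal(sum(dt$mean[1:3]), 0, tolerance = 1e-12)
  expect_equal(sum(dt$mean[4:6]), 0, tolerance = 1e-12)
  # sign probabilities: draws of H_ER ~ N(-0.2, 0.1^2) -> P(<0) ~ pnorm(2)
  set.seed(21)
  n <- 40000
  m <- matrix(0, n, 9, dimnames = list(NULL, cols))
  h <- rnorm(n, -0.2, 0.1)
  m[, 2] <- h; m[, 4] <- h                   # b_ER = b_RE = H_ER here
  dt <- dickersonChain(fake_chain(m), trait = "l")
  expect_equal(dt$p_neg[dt$parameter == "H_ER"], pnorm(2), tolerance = 0.01)
  # all-negative draws give probability exactly 1
  m[, 2] <- m[, 4] <- -abs(h)
  dt <- dickersonChain(fake_chain(m), trait = "l")
  expect_equal(dt$p_neg[dt$parameter == "H_ER"], 1)
  expect_error(dickersonChain(fake_chain(m[, -1, drop = FALSE])), "lacks")
})
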