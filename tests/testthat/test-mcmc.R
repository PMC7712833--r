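# Small toys for sampler correctness; heavier recovery checks live in
# test-acceptance.R.

toy_fit_config <- function(only, n_iter = 2000, burn_in = 500, seed = 1,
                           init = list(), ...) {
  blocks <- c("b_t", "b_l", "u_t", "u_l", "p_t", "p_l", "lambda",
              "G", "P", "sigma_e", "theta")
  upd <- as.list(setNames(blocks %in% only, blocks))
  mcmcConfig(n_iter = n_iter, burn_in = burn_in, thin = 1, seed = seed,
             update = upd, init = init, ...)
}

test_that("log joint is finite, additive in the data, and binomial at theta = 1", {
  ped <- tiny_pedigree(c("a", "b"))
  spec <- modelSpec("I")
  st <- list(b_t = numeric(15), b_l = numeric(15),
             u_t = c(0, 0), u_l = c(0, 0), p_t = c(0, 0), p_l = c(0, 0),
             lambda1 = numeric(0), lambda2 = numeric(0),
             G = c(0.1, 0.02, 0.4), P = c(0.4, 0, 0.4),
             sigma2_et = 4.5, theta = 0.8)
  d0 <- diallelData(character(0), character(0), integer(0), character(0),
                    integer(0), integer(0), ysLevels = c("y1", "y2"))
  lj0 <- logJoint(st, d0, ped, spec)
  expect_true(is.finite(lj0))
  d1 <- tiny_data()
  lj1 <- logJoint(st, d1, ped, spec)
  rec <- records(d1)
  d2 <- diallelData(rep(rec$sow_id, 2), rep(rec$cross, 2), rep(rec$parity, 2),
                    rep(rec$year_season, 2), rep(rec$tnb, 2), rep(rec$sb, 2))
  lj2 <- logJoint(st, d2, ped, spec)
  # likelihood terms double when the data are duplicated
  expect_equal(lj2 - lj0, 2 * (lj1 - lj0), tolerance = 1e-9)
  # theta = 1: MBN likelihood term reduces to the binomial
  st1 <- st; st1$theta <- 1
  lj_b <- logJoint(st1, d1, ped, spec)
  manual <- sum(dbinom(rec$sb, rec$tnb, 0.5, log = TRUE)) +
    sum(dnorm(rec$tnb, 0, sqrt(4.5), log = TRUE))
  expect_equal(lj_b - lj0, manual, tolerance = 1e-9)
  # non-PD G yields -Inf, not an error
  st_bad <- st; st_bad$G <- c(0.1, 0.5, 0.1)
  expect_identical(logJoint(st_bad, d1, ped, spec), -Inf)
  # out-of-bound theta yields -Inf
  st_bad2 <- st; st_bad2$theta <- 99
  expect_identical(logJoint(st_bad2, d1, ped, spec), -Inf)
})

test_that("chains are reproducible and an all-burn-in run is empty", {
  sim <- simulateDiallel(simConfig(scale = 0.03), seed = 2)
  cfg <- mcmcConfig(n_iter = 300, burn_in = 100, thin = 2, seed = 5)
  ch1 <- runChain(sim$data, sim$pedigree, modelSpec("II"), cfg)
  ch2 <- runChain(sim$data, sim$pedigree, modelSpec("II"), cfg)
  expect_identical(draws(ch1), draws(ch2))
  expect_identical(loglikMatrix(ch1), loglikMatrix(ch2))
  expect_equal(nrow(draws(ch1)), 100)
  ch3 <- runChain(sim$data, sim$pedigree, modelSpec("II"),
                  mcmcConfig(n_iter = 200, burn_in = 200, seed = 5))
  expect_equal(nrow(draws(ch3)), 0)
})

test_that("Gaussian-side conditional matches the GLS solution on a toy", {
  # 3 records of one EE sow, only the EE cross effect of TNB free:
  # flat prior => posterior b ~ N(mean(t), sigma2/3)
  d <- diallelData(rep("a", 3), rep("EE", 3), c(1, 1, 1), rep("y1", 3),
                   c(7, 9, 11), c(0, 0, 0))
  ped <- tiny_pedigree("a")
  cfg <- toy_fit_config("b_t", n_iter = 6000, burn_in = 1000, seed = 3,
                        init = list(sigma2_et = 4, theta = 1))
  ch <- runChain(d, ped, modelSpec("I"), cfg)
  b <- draws(ch)[, "b_t.cross.EE"]
  expect_equal(mean(b), 9, tolerance = 0.01)
  expect_equal(var(b), 4 / 3, tolerance = 0.15)
  # near-degenerate residual variance pins the effect at the datum
  d1 <- diallelData("a", "EE", 1, "y1", 10, 0)
  cfg2 <- toy_fit_config("b_t", n_iter = 500, burn_in = 100, seed = 4,
                         init = list(sigma2_et = 1e-6, theta = 1))
  ch2 <- runChain(d1, ped, modelSpec("I"), cfg2)
  expect_equal(mean(draws(ch2)[, "b_t.cross.EE"]), 10, tolerance = 0.01)
})

test_that("MH marginal matches grid integration on a two-record toy", {
  # 1 sow, 2 records, only b_l.cross.EE free; everything else fixed.
  d <- diallelData(rep("a", 2), rep("EE", 2), c(1, 1), rep("y1", 2),
                   c(10, 12), c(2, 1))
  ped <- tiny_pedigree("a")
  theta0 <- 0.85
  cfg <- toy_fit_config("b_l", n_iter = 52000, burn_in = 2000, seed = 6,
                        init = list(theta = theta0))
  ch <- runChain(d, ped, modelSpec("I"), cfg)
  bdraws <- draws(ch)[, "b_l.cross.EE"]
  expect_equal(length(bdraws), 50000)
  # brute-force posterior on a fine grid (flat prior on b)
  grid <- seq(-6, 2, by = 0.002)
  lp <- sapply(grid, function(b)
    sum(dmbn(c(2, 1), c(10, 12), plogis(b), theta0, log = TRUE)))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  cdf <- cumsum(w)
  emp <- ecdf(bdraws)
  ks <- max(abs(emp(grid) - cdf))
  expect_lt(ks, 0.05)
})

test_that("variance draws stay PD and degenerate sufficient statistics hit the bound", {
  sim <- simulateDiallel(simConfig(scale = 0.03), seed = 7)
  ch <- runChain(sim$data, sim$pedigree, modelSpec("II"),
                 mcmcConfig(n_iter = 600, burn_in = 100, thin = 1, seed = 8))
  dr <- draws(ch)
  expect_true(all(dr[, "G.ll"] * dr[, "G.tt"] - dr[, "G.lt"]^2 > 0))
  expect_true(all(dr[, "P.ll"] * dr[, "P.tt"] - dr[, "P.lt"]^2 > 0))
  expect_true(all(dr[, "sigma2_et"] > 0))
  # u frozen at zero: G scale matrix is ~0, draws collapse to the lower bound
  cfg0 <- toy_fit_config(c("G"), n_iter = 300, burn_in = 50, seed = 9,
                         var_lo = 0)
  ch0 <- runChain(sim$data, sim$pedigree, modelSpec("II"), cfg0)
  expect_lt(max(draws(ch0)[, "G.ll"]), 1e-8)
  expect_lt(max(draws(ch0)[, "G.tt"]), 1e-8)
})

test_that("theta moves are bounded and dispersion direction is recovered", {
  cfg_sim <- simConfig(scale = 0.1, theta = 0.8)
  sim <- simulateDiallel(cfg_sim, seed = 10)
  ch <- runChain(sim$data, sim$pedigree, modelSpec("II"),
                 mcmcConfig(n_iter = 8000, burn_in = 4000, thin = 5, seed = 11))
  th <- draws(ch)[, "theta"]
  expect_true(all(th > 1e-3 & th <= 5))
  expect_lt(mean(th), 1)                    # over-dispersion detected
  acc <- acceptanceRates(ch)
  expect_true(all(acc[c("b_l", "u_l", "p_l", "lambda", "theta")] > 0.2 &
                  acc[c("b_l", "u_l", "p_l", "lambda", "theta")] < 0.7))
})
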