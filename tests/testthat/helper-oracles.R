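# Independent oracles, deliberately naive: direct-summation arithmetic on the
# natural scale, no log-space tricks, no reuse of package internals.

# MBN pmf by direct enumeration of the unnormalised weights.
oracle_mbn_pmf <- function(size, phi, theta) {
  x <- 0:size
  w <- choose(size, x) * phi^x * (1 - phi)^(size - x) * theta^(x * (size - x))
  w / sum(w)
}

oracle_mbn_mean <- function(size, phi, theta) {
  sum((0:size) * oracle_mbn_pmf(size, phi, theta))
}

oracle_mbn_var <- function(size, phi, theta) {
  p <- oracle_mbn_pmf(size, phi, theta)
  m <- sum((0:size) * p)
  sum(((0:size) - m)^2 * p)
}

# Tabular-method numerator relationship matrix, straight textbook recursion.
oracle_tabular_A <- function(sire, dam) {
  n <- length(sire)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    if (i > 1) for (j in 1:(i - 1)) {
      a <- 0
      if (s > 0) a <- a + 0.5 * A[s, j]
      if (d > 0) a <- a + 0.5 * A[d, j]
      A[i, j] <- A[j, i] <- a
    }
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
  }
  A
}

# Random valid pedigree: founders first, then offspring with parents drawn
# among earlier individuals (possibly unknown).
random_pedigree <- function(n, n_founders = max(4, round(n / 5)), p_known = 0.8) {
  sire <- dam <- integer(n)
  for (i in (n_founders + 1):n) {
    if (runif(1) < p_known) sire[i] <- sample(i - 1, 1)
    if (runif(1) < p_known) dam[i] <- sample(i - 1, 1)
    if (sire[i] == dam[i]) dam[i] <- 0L   # no self-pairing of a single parent
  }
  list(id = paste0("I", seq_len(n)), sire = sire, dam = dam)
}

# Small phenotype fixture: one sow per id, simple valid records.
tiny_data <- function(sow = c("a", "a", "b"), cross = c("EE", "EE", "RT"),
                      parity = c(1, 2, 1), ys = c("y1", "y1", "y2"),
                      tnb = c(8, 9, 10), sb = c(1, 0, 2)) {
  diallelData(sow, cross, parity, ys, tnb, sb)
}

tiny_pedigree <- function(ids = c("a", "b")) {
  pedigree(ids, rep(0, length(ids)), rep(0, length(ids)))
}

# Wrap a draws matrix into a McmcChain (for transform/summary tests).
fake_chain <- function(draws_mat, model = "I") {
  base <- c("G.ll", "G.lt", "G.tt", "P.ll", "P.lt", "P.tt", "sigma2_et", "theta")
  missing <- setdiff(base, colnames(draws_mat))
  if (length(missing)) {
    extra <- matrix(rep(c(1, 0, 1, 1, 0, 1, 1, 1)[match(missing, base)],
                        each = nrow(draws_mat)),
                    nrow(draws_mat), length(missing),
                    dimnames = list(NULL, missing))
    draws_mat <- cbind(draws_mat, extra)
  }
  new("McmcChain", draws = draws_mat, loglik = matrix(0, 0, 0),
      spec = modelSpec(model), acceptance = numeric(0), config = list())
}
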