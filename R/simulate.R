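#' Configuration of the synthetic diallel generator
#'
#' Defaults emulate the structure of the motivating survey: 2110 sows with
#' about 10,000 farrowing records over the nine crosses of three varieties
#' (E, R, T), a three-generation pedigree descending from purebred founders,
#' mean litter size about 8.46, over-dispersed stillbirth counts
#' (theta < 1) and a positive linear recursion from litter size to the logit
#' of the stillbirth parameter (model II with lambda1 = 0.257).  Generating
#' variance components are set at the magnitudes typical of this trait
#' (additive and permanent environmental variances below 0.5 on both
#' scales, residual litter-size variance about 4.5).
#'
#' @param scale multiplies all sow and founder counts (e.g. `scale = 0.25`
#'   for a quarter-size population).
#' @param sowsPerCross named integer vector (EE...TT) of phenotyped sows.
#' @param recordRange inclusive range of records per sow (uniform).
#' @param foundersSires,foundersDams founder counts per variety (E, R, T).
#' @param nYs number of year-season levels.
#' @param spec generating [ModelSpec-class] (tBar is the centering constant
#'   used by the generator).
#' @param crossEffT,crossEffL cross effects (length 9) on the litter-size
#'   and logit scales; `crossEffL` is centred at `baseLogit`.
#' @param parityEffT,parityEffL parity effects (length 6).
#' @param ysSdT,ysSdL standard deviations of the centred year-season
#'   effects.
#' @param baseLogit baseline of the logit predictor at the average litter
#'   size; the default is calibrated so the per-event death probability is
#'   about 0.03.
#' @param G,P 2x2 generating covariance matrices (logit trait first).
#' @param sigma2Et residual variance of litter size.
#' @param theta generating MBN dispersion.
#' @param seed integer seed for the generator.
#' @return list of class `mbn_sim_config`.
#' @export
simConfig <- function(scale = 1,
                      sowsPerCross = c(EE = 100, ER = 527, ET = 177,
                                       RE = 196, RR = 175, RT = 488,
                                       TE = 36, TR = 343, TT = 68),
                      recordRange = c(3L, 6L),
                      foundersSires = c(E = 13, R = 18, T = 38),
                      foundersDams = c(E = 34, R = 62, T = 69),
                      nYs = 30L,
                      spec = modelSpec("II", tBar = 8.46, lambda1 = 0.257),
                      crossEffT = c(EE = 7.95, ER = 8.53, ET = 8.02,
                                    RE = 8.84, RR = 8.38, RT = 8.60,
                                    TE = 8.69, TR = 8.53, TT = 7.28),
                      crossEffL = c(EE = 0.237, ER = -0.135, ET = -0.143,
                                    RE = 0.025, RR = 0.025, RT = 0.025,
                                    TE = 0.136, TR = -0.196, TT = 0.026),
                      parityEffT = c(-0.30, 0.05, 0.15, 0.20, 0.10, -0.20),
                      parityEffL = c(0.15, -0.05, -0.05, 0.00, 0.00, 0.10),
                      ysSdT = 0.15, ysSdL = 0.10,
                      baseLogit = NULL,
                      G = matrix(c(0.050, 0.0286, 0.0286, 0.397), 2),
                      P = matrix(c(0.418, 0.0111, 0.0111, 0.368), 2),
                      sigma2Et = 4.497, theta = 0.816,
                      seed = 1234L) {
  sows <- pmax(1L, as.integer(round(sowsPerCross * scale)))
  names(sows) <- crossCodes()
  fs <- pmax(2L, as.integer(round(foundersSires * scale)))
  fd <- pmax(2L, as.integer(round(foundersDams * scale)))
  names(fs) <- names(fd) <- c("E", "R", "T")
  if (is.null(baseLogit)) {
    # Calibrate the baseline so the expected overall death rate
    # sum(sb) / sum(tnb) is about `target`: deterministic quadrature of
    # t * p_event over the generative mixture of litter size (discretised
    # Gaussian) and the remaining logit-scale noise (Gauss-Hermite).
    target <- 0.0296           # overall per-event death rate SB/TNB
    lam <- if (length(spec@lambda1)) mean(spec@lambda1) else 0
    var_t <- sigma2Et + G[2, 2] + P[2, 2] + ysSdT^2 + var(crossEffT)
    V <- G[1, 1] + P[1, 1] + ysSdL^2 + var(crossEffL)
    ts <- seq_len(ceiling(spec@tBar + 6 * sqrt(var_t)))
    wt <- stats::pnorm(ts + 0.5, spec@tBar, sqrt(var_t)) -
      stats::pnorm(ts - 0.5, spec@tBar, sqrt(var_t))
    wt[1] <- stats::pnorm(1.5, spec@tBar, sqrt(var_t))   # floor at tnb = 1
    wt <- wt / sum(wt)
    gh_z <- sqrt(2) * c(-2.3506, -1.3358, -0.4361, 0.4361, 1.3358, 2.3506)
    gh_w <- c(0.00453, 0.15707, 0.72463, 0.72463, 0.15707, 0.00453)
    gh_w <- gh_w / sum(gh_w)
    rate_at <- function(b0) {
      num <- den <- 0
      for (i in seq_along(ts)) {
        lg <- b0 + lam * (ts[i] - spec@tBar) + sqrt(V) * gh_z
        p <- mbnSuccessProb(ts[i], pmin(pmax(plogis(lg), 1e-12), 1 - 1e-12),
                            theta)
        num <- num + wt[i] * ts[i] * sum(gh_w * p)
        den <- den + wt[i] * ts[i]
      }
      num / den
    }
    baseLogit <- stats::uniroot(function(x) rate_at(x) - target,
                                c(-14, 0), tol = 1e-8)$root
  }
  stopifnot(all(eigen(G, symmetric = TRUE, only.values = TRUE)$values > 0),
            all(eigen(P, symmetric = TRUE, only.values = TRUE)$values > 0),
            sigma2Et > 0, theta > 0)
  structure(list(
    sowsPerCross = sows, recordRange = as.integer(recordRange),
    foundersSires = fs, foundersDams = fd, nYs = as.integer(nYs),
    spec = spec, crossEffT = crossEffT, crossEffL = crossEffL,
    parityEffT = parityEffT, parityEffL = parityEffL,
    ysSdT = ysSdT, ysSdL = ysSdL, baseLogit = baseLogit,
    G = G, P = P, sigma2Et = sigma2Et, theta = theta,
    seed = as.integer(seed)), class = "mbn_sim_config")
}

#' Simulate a three-generation diallel pedigree
#'
#' Founders per variety, a purebred intermediate generation bred within
#' variety, and the phenotyped sow cohort whose cross code is derived from
#' the sire variety (first letter) and dam variety (second letter).  The
#' requested sow counts per cross are met exactly.
#'
#' @param config an [simConfig()] list.
#' @return list with `pedigree` (a [Pedigree-class]) and `sows`
#'   (data.frame `sow_id`, `cross`).
#' @export
simulatePedigree <- function(config) {
  stopifnot(inherits(config, "mbn_sim_config"))
  pops <- c("E", "R", "T")
  id <- character(0); sire <- character(0); dam <- character(0)
  pop <- character(0)
  g0m <- g1m <- g1f <- list()
  for (v in pops) {
    sm <- paste0("F", v, "S", seq_len(config$foundersSires[[v]]))
    dm <- paste0("F", v, "D", seq_len(config$foundersDams[[v]]))
    id <- c(id, sm, dm)
    sire <- c(sire, rep("0", length(sm) + length(dm)))
    dam <- c(dam, rep("0", length(sm) + length(dm)))
    pop <- c(pop, rep(v, length(sm) + length(dm)))
    # purebred intermediate generation, random founder matings
    nm <- max(2L, config$foundersSires[[v]])
    nf <- max(2L, config$foundersDams[[v]])
    m1 <- paste0("G1", v, "M", seq_len(nm))
    f1 <- paste0("G1", v, "F", seq_len(nf))
    id <- c(id, m1, f1)
    sire <- c(sire, sample(sm, nm + nf, replace = TRUE))
    dam <- c(dam, sample(dm, nm + nf, replace = TRUE))
    pop <- c(pop, rep(v, nm + nf))
    g0m[[v]] <- sm; g1m[[v]] <- m1; g1f[[v]] <- f1
  }
  sow_id <- character(0); sow_cross <- character(0)
  for (k in crossCodes()) {
    sv <- substr(k, 1, 1); dv <- substr(k, 2, 2)
    nk <- config$sowsPerCross[[k]]
    ids <- paste0("S", k, seq_len(nk))
    sow_id <- c(sow_id, ids)
    sow_cross <- c(sow_cross, rep(k, nk))
    id <- c(id, ids)
    sire <- c(sire, sample(c(g0m[[sv]], g1m[[sv]]), nk, replace = TRUE))
    dam <- c(dam, sample(g1f[[dv]], nk, replace = TRUE))
    pop <- c(pop, rep(NA_character_, nk))
  }
  list(pedigree = pedigree(id, sire, dam, population = pop),
       sows = data.frame(sow_id = sow_id, cross = sow_cross,
                         stringsAsFactors = FALSE))
}

#' Simulate phenotypes under the generating model
#'
#' Draws bivariate additive genetic values by gene dropping through the
#' pedigree (founders `N(0, G)`, offspring receive the parent average plus
#' Mendelian sampling with inbreeding-adjusted variance — exactly
#' `N(0, A (x) G)`), sow permanent environmental values `N(0, P)`, then for
#' each farrowing litter size `tnb = max(1, round(N(eta_t, sigma2Et)))` and
#' the stillbirth count from the MBN with logit given by the generating
#' model's predictor evaluated at the realised litter size.
#'
#' @param ped a [Pedigree-class].
#' @param sows data.frame `sow_id`, `cross` (as from [simulatePedigree()]).
#' @param config an [simConfig()] list.
#' @return list with `data` (a [DiallelData-class]) and `truth` (the
#'   generating parameter values, including per-sow `u` and `p`).
#' @export
simulatePhenotypes <- function(ped, sows, config) {
  stopifnot(is(ped, "Pedigree"), inherits(config, "mbn_sim_config"))
  n_ind <- nIndividuals(ped)
  U <- .gene_drop(ped, config$G)               # n_ind x 2, columns (l, t)
  q <- nrow(sows)
  Lp <- chol(config$P)
  Pe <- matrix(rnorm(2 * q), q, 2) %*% Lp      # columns (l, t)

  sped <- match(sows$sow_id, ped@id)
  stopifnot(!anyNA(sped))
  nrec <- sample(seq(config$recordRange[1], config$recordRange[2]),
                 q, replace = TRUE)
  ridx <- rep(seq_len(q), nrec)
  parity <- unlist(lapply(nrec, function(k) pmin(seq_len(k), 6L)))
  ysLevels <- sprintf("YS%02d", seq_len(config$nYs))
  ys <- sample(ysLevels, length(ridx), replace = TRUE)
  ysEffT <- rnorm(config$nYs, 0, config$ysSdT); ysEffT <- ysEffT - mean(ysEffT)
  ysEffL <- rnorm(config$nYs, 0, config$ysSdL); ysEffL <- ysEffL - mean(ysEffL)
  names(ysEffT) <- names(ysEffL) <- ysLevels

  cross <- sows$cross[ridx]
  eta_t <- config$crossEffT[cross] + config$parityEffT[parity] +
    ysEffT[ys] + U[sped[ridx], 2] + Pe[ridx, 2]
  tnb <- pmax(1L, as.integer(round(rnorm(length(ridx), eta_t,
                                         sqrt(config$sigma2Et)))))
  base_l <- config$baseLogit + config$crossEffL[cross] +
    config$parityEffL[parity] + ysEffL[ys] + U[sped[ridx], 1] + Pe[ridx, 1]
  lgt <- logitPhi(config$spec, base_l, tnb, cross)
  phi <- pmin(pmax(plogis(lgt), 1e-12), 1 - 1e-12)
  sb <- rmbn(length(tnb), tnb, phi, config$theta)

  data <- diallelData(sows$sow_id[ridx], cross, parity, ys, tnb, sb,
                      ysLevels = ysLevels)
  truth <- list(spec = config$spec, G = config$G, P = config$P,
                sigma2Et = config$sigma2Et, theta = config$theta,
                baseLogit = config$baseLogit,
                crossEffT = config$crossEffT, crossEffL = config$crossEffL,
                ysEffT = ysEffT, ysEffL = ysEffL,
                u = U, p = Pe)
  list(data = data, truth = truth)
}

#' One-call synthetic diallel dataset
#'
#' Sets the generator seed from `config$seed`, simulates the pedigree and
#' the phenotypes, and returns data, pedigree and generating truth.
#'
#' @param config an [simConfig()] list.
#' @param seed optional override of `config$seed`.
#' @return list with `data`, `pedigree`, `sows`, `truth`.
#' @export
simulateDiallel <- function(config = simConfig(), seed = NULL) {
  set.seed(if (is.null(seed)) config$seed else seed)
  pd <- simulatePedigree(config)
  ph <- simulatePhenotypes(pd$pedigree, pd$sows, config)
  list(data = ph$data, pedigree = pd$pedigree, sows = pd$sows,
       truth = ph$truth)
}

# Gene dropping of bivariate (l, t) additive values: exact N(0, A (x) G).
.gene_drop <- function(ped, G) {
  n <- nIndividuals(ped)
  L <- chol(G)                      # upper: t(L) %*% L = G
  U <- matrix(0, n, 2)
  f <- ped@f
  for (i in seq_len(n)) {
    s <- ped@sire[i]; d <- ped@dam[i]
    mu <- c(0, 0)
    v <- 1
    if (s > 0L) { mu <- mu + 0.5 * U[s, ]; v <- v - 0.25 * (1 + f[s]) }
    if (d > 0L) { mu <- mu + 0.5 * U[d, ]; v <- v - 0.25 * (1 + f[d]) }
    U[i, ] <- mu + sqrt(v) * drop(rnorm(2) %*% L)
  }
  U
}
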