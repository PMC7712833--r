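#' Sampler control settings
#'
#' Returns the control list consumed by [runChain()].  Defaults give a
#' desk-scale chain (30,000 iterations, 5,000 burn-in, thinning 10); the
#' full-scale analysis (550,000 / 50,000) is obtained by raising `n_iter`
#' and `burn_in`.  Metropolis-Hastings proposal standard deviations are
#' adapted toward an acceptance rate of 0.44 during burn-in and frozen
#' afterwards.  All priors are flat within the stated bounds.
#'
#' @param n_iter,burn_in,thin chain length controls; stored draws number
#'   `(n_iter - burn_in) / thin`.
#' @param seed integer seed; every source of randomness in the run flows
#'   from it.
#' @param var_lo,var_hi prior bounds for all variance parameters.
#' @param theta_lo,theta_hi prior bounds for the MBN dispersion theta.
#' @param sd_b_l,sd_u_l,sd_p_l,sd_lambda,sd_log_theta initial proposal sds.
#' @param min_sd floor on adapted proposal sds (guards a frozen chain).
#' @param max_var_tries redraw budget for truncated variance draws before
#'   erroring with advice to widen the bounds.
#' @param update named overrides turning individual update blocks off, e.g.
#'   `list(theta = FALSE)`; blocks: b_t, b_l, u_t, u_l, p_t, p_l, lambda,
#'   G, P, sigma_e, theta.
#' @param store_loglik keep the per-record log-likelihood matrix (needed for
#'   CPO)?
#' @param store_effects also store the full draws of the random effects
#'   (`u_l.*`, `u_t.*`, `p_l.*`, `p_t.*` columns); intended for small
#'   problems — posterior means of the effects are always returned.
#' @param init named list of initial values overriding the data-driven
#'   defaults (`b_t`, `b_l`, `u_t`, `u_l`, `p_t`, `p_l`, `lambda1`,
#'   `lambda2`, `G`, `P`, `sigma2_et`, `theta`; `G`/`P` as length-3
#'   `(v_ll, cov, v_tt)`).
#' @return a list of class `mbn_mcmc_config`.
#' @export
mcmcConfig <- function(n_iter = 30000, burn_in = 5000, thin = 10, seed = 1L,
                       var_lo = 1e-6, var_hi = 100,
                       theta_lo = 1e-3, theta_hi = 5,
                       sd_b_l = 0.3, sd_u_l = 0.3, sd_p_l = 0.3,
                       sd_lambda = 0.05, sd_log_theta = 0.05,
                       min_sd = 1e-3, max_var_tries = 10000L,
                       update = list(), store_loglik = TRUE,
                       store_effects = FALSE, init = list()) {
  blocks <- c("b_t", "b_l", "u_t", "u_l", "p_t", "p_l", "lambda",
              "G", "P", "sigma_e", "theta")
  upd <- setNames(rep(TRUE, length(blocks)), blocks)
  if (length(update)) {
    bad <- setdiff(names(update), blocks)
    if (length(bad)) stop("unknown update block(s): ", paste(bad, collapse = ", "))
    upd[names(update)] <- vapply(update, isTRUE, logical(1))
  }
  structure(list(
    n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
    thin = as.integer(thin), seed = as.integer(seed),
    var_lo = var_lo, var_hi = var_hi,
    theta_lo = theta_lo, theta_hi = theta_hi,
    sd_b_l = sd_b_l, sd_u_l = sd_u_l, sd_p_l = sd_p_l,
    sd_lambda = sd_lambda, sd_log_theta = sd_log_theta,
    min_sd = min_sd, max_var_tries = as.integer(max_var_tries),
    update = upd, store_loglik = isTRUE(store_loglik),
    store_effects = isTRUE(store_effects), init = init),
    class = "mbn_mcmc_config")
}

#' Fit a recursive multiplicative-binomial model by MCMC
#'
#' Runs the Gibbs sampler with Metropolis-Hastings steps: exact conjugate
#' scalar updates for the Gaussian litter-size side (`b_t`, `u_t`, `p_t`),
#' adaptive single-site random-walk MH for the logit side (`b_l`, `u_l`,
#' `p_l`, recursion coefficients), inverse-Wishart draws for the 2x2 genetic
#' (`G`) and permanent environmental (`P`) covariance matrices truncated to
#' the prior bounds, a scaled inverse-chi-square draw for the residual
#' variance of litter size, and random-walk MH on log(theta) for the MBN
#' dispersion.  Per-record MBN log-likelihoods are stored at every thinned
#' draw for CPO model comparison.
#'
#' @param data a [DiallelData-class].
#' @param ped a [Pedigree-class] containing every sow.
#' @param spec a [ModelSpec-class]; an unresolved `tBar` is replaced by the
#'   unweighted mean of the observed TNB.
#' @param config a control list from [mcmcConfig()].
#' @return a [McmcChain-class].
#' @seealso [summarizeChain()], [cpoEstimate()], [dickersonChain()]
#' @export
runChain <- function(data, ped, spec = modelSpec("II"),
                     config = mcmcConfig()) {
  stopifnot(is(data, "DiallelData"), is(ped, "Pedigree"),
            is(spec, "ModelSpec"), inherits(config, "mbn_mcmc_config"))
  designs <- buildDesigns(data, ped)
  n <- length(designs$tnb)
  p <- ncol(designs$X)
  q_u <- nIndividuals(ped)
  q_p <- length(designs$sows)

  tBar <- if (is.na(spec@tBar)) mean(designs$tnb) else spec@tBar
  spec_res <- modelSpec(spec@modelId, tBar = tBar,
                        lambda1 = if (length(spec@lambda1)) spec@lambda1 else NULL,
                        lambda2 = if (length(spec@lambda2)) spec@lambda2 else NULL)

  rel <- buildRelationship(ped, keepA = FALSE)
  Ainv <- methods::as(rel@Ainv, "CsparseMatrix")

  # data-driven default initial values
  rate <- min(max(sum(designs$sb) / max(sum(designs$tnb), 1), 1e-4), 0.5)
  b_t0 <- numeric(p); b_t0[1:9] <- mean(designs$tnb)
  b_l0 <- numeric(p); b_l0[1:9] <- qlogis(rate)
  init <- list(
    b_t = b_t0, b_l = b_l0,
    u_t = numeric(q_u), u_l = numeric(q_u),
    p_t = numeric(q_p), p_l = numeric(q_p),
    lambda1 = if (length(spec@lambda1)) unname(spec@lambda1) else numeric(1),
    lambda2 = if (length(spec@lambda2)) unname(spec@lambda2) else numeric(1),
    G = c(0.1, 0, 0.4), P = c(0.4, 0, 0.4),
    sigma2_et = max(stats::var(designs$tnb), 0.5), theta = 1)
  if (length(config$init)) {
    bad <- setdiff(names(config$init), names(init))
    if (length(bad)) stop("unknown init value(s): ", paste(bad, collapse = ", "))
    init[names(config$init)] <- config$init
  }

  upd <- config$update
  ctrl <- list(
    n_iter = config$n_iter, burn_in = config$burn_in, thin = config$thin,
    var_lo = config$var_lo, var_hi = config$var_hi,
    theta_lo = config$theta_lo, theta_hi = config$theta_hi,
    min_sd = config$min_sd, max_var_tries = config$max_var_tries,
    sd_b_l = config$sd_b_l, sd_u_l = config$sd_u_l, sd_p_l = config$sd_p_l,
    sd_lambda = config$sd_lambda, sd_log_theta = config$sd_log_theta,
    update_b_t = upd[["b_t"]], update_b_l = upd[["b_l"]],
    update_u_t = upd[["u_t"]], update_u_l = upd[["u_l"]],
    update_p_t = upd[["p_t"]], update_p_l = upd[["p_l"]],
    update_lambda = upd[["lambda"]],
    update_G = upd[["G"]], update_P = upd[["P"]],
    update_sigma_e = upd[["sigma_e"]], update_theta = upd[["theta"]],
    store_loglik = config$store_loglik,
    store_effects = config$store_effects)

  set.seed(config$seed)
  out <- run_chain_cpp(
    y = as.integer(designs$sb), t = as.integer(designs$tnb),
    traw = as.numeric(designs$tnb), d = designs$tnb - tBar,
    cross = as.integer(designs$cross),
    sow_ped = as.integer(designs$sowPed), sow_pe = as.integer(designs$sowPe),
    X = designs$X,
    Ap = Ainv@p, Ai = Ainv@i, Ax = Ainv@x,
    q_u = q_u, q_p = q_p,
    model = match(spec@modelId, c("I", "II", "III", "IV", "V")),
    init = init, ctrl = ctrl)

  cn <- colnames(designs$X)
  lamnames <- character(0)
  if (out$n_g1 == 1) lamnames <- "lambda1"
  if (out$n_g1 == 9) lamnames <- paste0("lambda1.", crossCodes())
  if (out$n_g2 == 1) lamnames <- c(lamnames, "lambda2")
  if (out$n_g2 == 9) lamnames <- c(lamnames, paste0("lambda2.", crossCodes()))
  parnames <- c(paste0("b_t.", cn), paste0("b_l.", cn), lamnames,
                "G.ll", "G.lt", "G.tt", "P.ll", "P.lt", "P.tt",
                "sigma2_et", "theta")
  if (config$store_effects)
    parnames <- c(parnames,
                  paste0("u_l.", ped@id), paste0("u_t.", ped@id),
                  paste0("p_l.", designs$sows), paste0("p_t.", designs$sows))
  colnames(out$draws) <- parnames
  em <- out$effect_means
  effects <- list(
    u = data.frame(id = ped@id, l = em[seq_len(q_u), 1],
                   t = em[seq_len(q_u), 2], row.names = NULL),
    p = data.frame(id = designs$sows, l = em[q_u + seq_len(q_p), 1],
                   t = em[q_u + seq_len(q_p), 2], row.names = NULL))
  new("McmcChain", draws = out$draws, loglik = out$loglik, spec = spec_res,
      acceptance = setNames(as.numeric(out$acceptance), names(out$acceptance)),
      effects = effects, config = unclass(config))
}

#' Log joint density of the model at a given state
#'
#' Sums (i) the MBN log-likelihood of the stillbirth counts given litter
#' sizes, the logit predictor and theta; (ii) the Gaussian log-likelihood of
#' litter size; (iii) the `N(0, A (x) G)` log prior of the additive genetic
#' values; (iv) the `N(0, I (x) P)` log prior of the permanent environmental
#' values.  Flat priors contribute 0 inside their bounds and `-Inf` outside;
#' a non-positive-definite `G` or `P` yields `-Inf` rather than an error.
#'
#' @param state list with `b_t`, `b_l`, `u_t`, `u_l`, `p_t`, `p_l`,
#'   `lambda1`, `lambda2` (as required by the model), `G`, `P` (length-3
#'   `(v_ll, cov, v_tt)`), `sigma2_et`, `theta`.
#' @param data a [DiallelData-class] (may have zero rows).
#' @param ped a [Pedigree-class].
#' @param spec a [ModelSpec-class] with `tBar` resolved.
#' @param config an [mcmcConfig()] list supplying the prior bounds.
#' @return the log joint density (a finite number or `-Inf`).
#' @export
logJoint <- function(state, data, ped, spec, config = mcmcConfig()) {
  G <- state$G; P <- state$P
  detG <- G[1] * G[3] - G[2]^2
  detP <- P[1] * P[3] - P[2]^2
  if (!(detG > 0 && G[1] > 0) || !(detP > 0 && P[1] > 0)) return(-Inf)
  inb <- function(v) v > config$var_lo & v < config$var_hi
  if (!all(inb(c(G[1], G[3], P[1], P[3], state$sigma2_et)))) return(-Inf)
  if (state$theta <= config$theta_lo || state$theta > config$theta_hi) return(-Inf)

  q_u <- nIndividuals(ped)
  rel <- buildRelationship(ped, keepA = FALSE)
  Ainv <- rel@Ainv
  U <- cbind(state$u_l, state$u_t)
  Su <- t(U) %*% (Ainv %*% U)
  ldetAinv <- as.numeric(Matrix::determinant(Ainv, logarithm = TRUE)$modulus)
  Ginv <- matrix(c(G[3], -G[2], -G[2], G[1]), 2) / detG
  lp_u <- -0.5 * (q_u * log(detG) - ldetAinv + sum(Ginv * as.matrix(Su))) -
    q_u * log(2 * pi)

  Pm <- matrix(c(P[1], P[2], P[2], P[3]), 2)
  Pinv <- solve(Pm)
  Pp <- cbind(state$p_l, state$p_t)
  q_p <- nrow(Pp)
  lp_p <- -0.5 * (q_p * log(detP) + sum(Pinv * (t(Pp) %*% Pp))) -
    q_p * log(2 * pi)

  lik <- 0
  if (nRecords(data) > 0) {
    designs <- buildDesigns(data, ped)
    effects_t <- list(b = state$b_t, u = state$u_t, p = state$p_t)
    effects_l <- list(b = state$b_l, u = state$u_l, p = state$p_l)
    eta_t <- linearPredictorT(effects_t, designs)
    base_l <- linearPredictorT(effects_l, designs)
    sp <- spec
    if (length(state$lambda1) || length(state$lambda2))
      sp <- modelSpec(spec@modelId, tBar = spec@tBar,
                      lambda1 = state$lambda1, lambda2 = state$lambda2)
    lgt <- logitPhi(sp, base_l, designs$tnb, designs$cross)
    lik <- sum(dmbn(designs$sb, designs$tnb, plogis(lgt), state$theta, log = TRUE)) +
      sum(dnorm(designs$tnb, eta_t, sqrt(state$sigma2_et), log = TRUE))
  }
  lik + lp_u + lp_p
}
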