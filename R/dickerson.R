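#' Dickerson decomposition of diallel cross effects
#'
#' The nine cross effects `b` (order EE, ER, ET, RE, RR, RT, TE, TR, TT;
#' sire variety first) are modelled as direct-line effects `D = (D_E, D_R,
#' D_T)`, maternal effects `M = (M_E, M_R, M_T)` and heterosis effects
#' `H = (H_ER, H_ET, H_RT)`:
#' purebred `b_XX = D_X + M_X`; cross `b_XY = 0.5 D_X + 0.5 D_Y + M_Y +
#' H_XY` (dam variety `Y` supplies the maternal effect).
#'
#' The 9x9 coefficient matrix is singular: the vector `D = +1, M = -1,
#' H = 0` annihilates every row, so the system has numerical rank 8 and only
#' contrasts (heterosis effects, within-block differences of `D` and of `M`)
#' are identified by the data.  `dickersonSolve` therefore returns the
#' minimum-norm least-squares solution (with rank and residual-norm
#' metadata), or a solution constrained to `sum(D) = 0` and `sum(M) = 0`
#' after absorbing a common intercept.
#'
#' @return `dickersonMatrix`: the 9x9 coefficient matrix mapping
#'   `(D, M, H)` to `b`.
#' @export
dickersonMatrix <- function() {
  par <- c("D_E", "D_R", "D_T", "M_E", "M_R", "M_T", "H_ER", "H_ET", "H_RT")
  M <- matrix(0, 9, 9, dimnames = list(crossCodes(), par))
  M["EE", ] <- c(1,   0,   0,   1, 0, 0, 0, 0, 0)
  M["ER", ] <- c(0.5, 0.5, 0,   0, 1, 0, 1, 0, 0)
  M["ET", ] <- c(0.5, 0,   0.5, 0, 0, 1, 0, 1, 0)
  M["RE", ] <- c(0.5, 0.5, 0,   1, 0, 0, 1, 0, 0)
  M["RR", ] <- c(0,   1,   0,   0, 1, 0, 0, 0, 0)
  M["RT", ] <- c(0,   0.5, 0.5, 0, 0, 1, 0, 0, 1)
  M["TE", ] <- c(0.5, 0,   0.5, 1, 0, 0, 0, 1, 0)
  M["TR", ] <- c(0,   0.5, 0.5, 0, 1, 0, 0, 0, 1)
  M["TT", ] <- c(0,   0,   1,   0, 0, 1, 0, 0, 0)
  M
}

#' @rdname dickersonMatrix
#' @param D,M,H numeric length-3 vectors of direct (E, R, T), maternal
#'   (E, R, T) and heterosis (ER, ET, RT) effects.
#' @return `dickersonForward`: the nine cross effects implied by the
#'   parameters, named by cross code.
#' @examples
#' dickersonForward(D = c(1, 0, 0), M = c(0, 0, 0), H = c(0, 0, 0))
#' @export
dickersonForward <- function(D, M, H) {
  stopifnot(length(D) == 3, length(M) == 3, length(H) == 3)
  drop(dickersonMatrix() %*% c(D, M, H))
}

#' @rdname dickersonMatrix
#' @param b numeric length-9 vector of cross effects in [crossCodes()] order.
#' @param constraint `"minimum-norm"` (pseudo-inverse solve) or
#'   `"sum-to-zero"` (absorb a common intercept `mu` with `sum(D) = 0`,
#'   `sum(M) = 0`; the intercept is returned as `mu`).
#' @return `dickersonSolve`: list with `params` (named length-9 vector),
#'   `rank`, `residual` (norm of `M params - b`), `constraint` and, for the
#'   sum-to-zero mode, `mu`.
#' @export
dickersonSolve <- function(b, constraint = c("minimum-norm", "sum-to-zero")) {
  constraint <- match.arg(constraint)
  stopifnot(length(b) == 9, is.numeric(b))
  b <- as.numeric(b)
  M <- dickersonMatrix()
  if (constraint == "minimum-norm") {
    sv <- svd(M)
    tol <- max(dim(M)) * .Machine$double.eps * sv$d[1]
    pos <- sv$d > tol
    x <- sv$v[, pos] %*% ((t(sv$u[, pos]) %*% b) / sv$d[pos])
    params <- setNames(drop(x), colnames(M))
    resid <- sqrt(sum((M %*% params - b)^2))
    list(params = params, rank = sum(pos), residual = resid,
         constraint = constraint)
  } else {
    # augment with an intercept column and impose sum(D) = sum(M) = 0 by
    # Lagrange multipliers (exact KKT solve)
    A <- cbind(M, mu = 1)
    C <- rbind(c(rep(1, 3), rep(0, 7)), c(rep(0, 3), rep(1, 3), rep(0, 4)))
    K <- rbind(cbind(crossprod(A), t(C)), cbind(C, matrix(0, 2, 2)))
    rhs <- c(crossprod(A, b), 0, 0)
    sol <- solve(K, rhs)
    params <- setNames(sol[1:9], colnames(M))
    mu <- sol[10]
    resid <- sqrt(sum((A %*% sol[1:10] - b)^2))
    list(params = params, rank = 8L, residual = resid,
         constraint = constraint, mu = mu)
  }
}

#' Heterosis effects as closed-form contrasts of cross effects
#'
#' `H_XY = (b_XY + b_YX - b_XX - b_YY) / 2`; these contrasts are estimable
#' regardless of the identifiability convention.
#'
#' @param b numeric length-9 vector in [crossCodes()] order.
#' @return named length-3 vector `(H_ER, H_ET, H_RT)`.
#' @export
heterosisContrasts <- function(b) {
  stopifnot(length(b) == 9)
  b <- setNames(as.numeric(b), crossCodes())
  c(H_ER = (b[["ER"]] + b[["RE"]] - b[["EE"]] - b[["RR"]]) / 2,
    H_ET = (b[["ET"]] + b[["TE"]] - b[["EE"]] - b[["TT"]]) / 2,
    H_RT = (b[["RT"]] + b[["TR"]] - b[["RR"]] - b[["TT"]]) / 2)
}

#' Posterior summaries of the Dickerson parameters from an MCMC chain
#'
#' Applies [dickersonSolve()] to the nine cross-effect samples of the chosen
#' trait at every stored draw (the posterior of a linear transformation of
#' the cross effects) and summarises each parameter by its posterior mean,
#' SD, shortest 95% highest-posterior-density interval and posterior
#' probability of being negative.  Direct and maternal effects are reported
#' as deviations from their within-block mean (the estimable part);
#' heterosis effects are estimable as is.
#'
#' @param chain a [McmcChain-class].
#' @param trait `"t"` (litter size) or `"l"` (logit of the MBN phi).
#' @param prob mass of the HPD interval.
#' @return data.frame with one row per parameter.
#' @export
dickersonChain <- function(chain, trait = c("t", "l"), prob = 0.95) {
  trait <- match.arg(trait)
  dr <- draws(chain)
  cols <- paste0("b_", trait, ".cross.", crossCodes())
  if (!all(cols %in% colnames(dr)))
    stop("chain lacks cross-effect draws for trait ", trait)
  B <- dr[, cols, drop = FALSE]
  sv <- svd(dickersonMatrix())
  pos <- sv$d > max(9) * .Machine$double.eps * sv$d[1]
  pinv <- sv$v[, pos] %*% (t(sv$u[, pos]) / sv$d[pos])
  S <- B %*% t(pinv)                      # draws x 9 parameter samples
  colnames(S) <- colnames(dickersonMatrix())
  # estimable presentation: within-block deviations for D and M
  S[, 1:3] <- S[, 1:3] - rowMeans(S[, 1:3])
  S[, 4:6] <- S[, 4:6] - rowMeans(S[, 4:6])
  summ <- function(x) {
    h <- hpdInterval(x, prob)
    c(mean = mean(x), sd = sd(x), hpd_lo = h[1], hpd_hi = h[2],
      p_neg = mean(x < 0))
  }
  out <- t(apply(S, 2, summ))
  data.frame(parameter = rownames(out), trait = trait, out,
             row.names = NULL, check.names = FALSE)
}
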