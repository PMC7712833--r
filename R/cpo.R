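#' Conditional predictive ordinate from MCMC draws
#'
#' Harmonic-mean Monte Carlo estimator of the leave-one-out predictive
#' density of each record:
#' \deqn{\hat p(y_i | y_{-i}) = N_m \left[\sum_j 1 / p(y_i |
#'   \theta^{(j)})\right]^{-1},}
#' where the sum runs over the `Nm` stored post-burn-in draws.  The sum of
#' reciprocals is accumulated by log-sum-exp of the negated log-likelihoods
#' so it cannot overflow.  The summed log CPO (`LogCPO`) is the pseudo
#' log-marginal probability of the data; larger is better.
#'
#' @param loglik matrix of per-record log-likelihoods, records x draws, as
#'   stored by [runChain()] (see [loglikMatrix()]), or a [McmcChain-class].
#' @return a [CpoResult-class].
#' @examples
#' ll <- log(matrix(c(0.1, 0.3), 1, 2))   # two draws, one record
#' logCpo(cpoEstimate(ll))                # log(0.15)
#' @export
cpoEstimate <- function(loglik) {
  if (is(loglik, "McmcChain")) loglik <- loglikMatrix(loglik)
  stopifnot(is.matrix(loglik))
  if (ncol(loglik) < 2) stop("need at least 2 draws to estimate the CPO")
  if (any(is.nan(loglik)) || any(loglik == Inf))
    stop("log-likelihood matrix has non-finite entries")
  nm <- ncol(loglik)
  neg <- -loglik
  mx <- apply(neg, 1, max)                     # rows with -Inf ll -> mx = Inf
  fin <- is.finite(mx)
  lse <- rep(Inf, nrow(neg))
  if (any(fin))
    lse[fin] <- mx[fin] +
      log(rowSums(exp(neg[fin, , drop = FALSE] - mx[fin])))
  logcpo <- log(nm) - lse
  inf_rows <- which(!fin)
  if (length(inf_rows)) {
    warning("records with zero likelihood at some draw (CPO = 0): ",
            paste(utils::head(inf_rows, 10), collapse = ", "))
    logcpo[inf_rows] <- -Inf
  }
  new("CpoResult", perRecordCpo = exp(pmin(logcpo, 0)),
      logCpoSum = sum(logcpo), nDraws = as.integer(nm))
}

#' Rank models by their summed log CPO
#'
#' @param results named list of [CpoResult-class] objects computed on the
#'   identical set of records.
#' @return data.frame with `model`, `logCPO`, and `delta` (difference from
#'   the best model; the best model has 0, all others are negative), sorted
#'   best first.
#' @export
compareModels <- function(results) {
  stopifnot(length(results) >= 1, all(vapply(results, is, logical(1), "CpoResult")))
  if (is.null(names(results)) || any(names(results) == ""))
    names(results) <- paste0("model", seq_along(results))
  nrec <- vapply(results, function(r) length(r@perRecordCpo), integer(1))
  if (length(unique(nrec)) != 1)
    stop("all models must be scored on the same records (record counts: ",
         paste(nrec, collapse = ", "), ")")
  lc <- vapply(results, logCpo, numeric(1))
  out <- data.frame(model = names(results), logCPO = lc,
                    delta = lc - max(lc), row.names = NULL)
  out[order(-out$logCPO), ]
}
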