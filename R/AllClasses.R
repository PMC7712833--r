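#' @include mbnDiallel-package.R
NULL

#' The nine sow cross codes of a three-variety diallel
#'
#' Sire variety first letter, dam variety second letter; E, R and T denote
#' the three varieties (e.g. Entrepelado, Retinto, Torbiscal).
#'
#' @export
crossCodes <- function() {
  c("EE", "ER", "ET", "RE", "RR", "RT", "TE", "TR", "TT")
}

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Phenotype table of a diallel cross
#'
#' One row per farrowing: sow identifier, cross code, parity class (1-6, 6
#' meaning sixth and beyond), year-season level, total number born (tnb) and
#' number stillborn (sb).  Level sets for cross, parity and year-season are
#' frozen at construction.
#'
#' @slot records data.frame with columns sow_id, cross, parity, year_season,
#'   tnb, sb.
#' @slot ysLevels character vector of year-season levels.
#' @export
setClass("DiallelData", representation(
  records = "data.frame",
  ysLevels = "character"
))

setValidity("DiallelData", function(object) {
  rec <- object@records
  need <- c("sow_id", "cross", "parity", "year_season", "tnb", "sb")
  if (!all(need %in% names(rec)))
    return(paste("missing columns:", paste(setdiff(need, names(rec)), collapse = ", ")))
  bad <- which(rec$sb < 0 | rec$sb > rec$tnb)
  if (length(bad))
    return(paste0("sb outside [0, tnb] at row(s) ", paste(utils::head(bad, 5), collapse = ", ")))
  if (!all(rec$cross %in% crossCodes()))
    return("unknown cross codes present")
  if (!all(rec$parity %in% 1:6))
    return("parity outside 1..6")
  if (!all(rec$year_season %in% object@ysLevels))
    return("year_season level not in declared level set")
  TRUE
})

#' Pedigree with inbreeding coefficients
#'
#' Individuals are ordered so parents precede offspring; sire/dam 0 means
#' unknown (treated as unrelated founder of the declared population).
#'
#' @slot id character identifiers.
#' @slot sire,dam integer positional indices (0 = unknown).
#' @slot population character population label per individual (may be NA).
#' @slot f numeric inbreeding coefficients (Meuwissen-Luo).
#' @export
setClass("Pedigree", representation(
  id = "character",
  sire = "integer",
  dam = "integer",
  population = "character",
  f = "numeric"
))

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  if (length(object@sire) != n || length(object@dam) != n)
    return("id, sire, dam must have equal length")
  if (anyDuplicated(object@id)) return("duplicated individual ids")
  idx <- seq_len(n)
  if (any(object@sire >= idx) || any(object@dam >= idx))
    return("parents must precede offspring in the ordering")
  if (any(object@sire < 0) || any(object@dam < 0))
    return("negative parent index")
  TRUE
})

#' Numerator relationship matrix and its sparse inverse
#'
#' @slot A dense numerator relationship matrix (NULL if not materialised).
#' @slot Ainv sparse inverse (Henderson's rules with inbreeding).
#' @slot f inbreeding coefficients.
#' @export
setClass("RelationshipMatrix", representation(
  A = "matrixOrNULL",
  Ainv = "Matrix",
  f = "numeric"
))

#' Specification of the logit predictor (models I-V)
#'
#' Model I: no recursion.  Model II: shared linear coefficient lambda1 on the
#' litter-size deviation d = tnb - tBar.  Model III: shared linear and
#' quadratic (lambda1, lambda2).  Model IV: cross-specific linear
#' coefficients.  Model V: cross-specific linear and quadratic coefficients.
#'
#' @slot modelId one of "I".."V".
#' @slot tBar centering constant (average litter size); NA means "compute
#'   from the data at fit time".
#' @slot lambda1,lambda2 numeric; length 1 for shared models, 9 (named by
#'   cross) for cross-specific ones; length 0 when unused.
#' @export
setClass("ModelSpec", representation(
  modelId = "character",
  tBar = "numeric",
  lambda1 = "numeric",
  lambda2 = "numeric"
))

setValidity("ModelSpec", function(object) {
  if (!object@modelId %in% c("I", "II", "III", "IV", "V"))
    return("modelId must be one of I, II, III, IV, V")
  n1 <- switch(object@modelId, I = 0L, II = 1L, III = 1L, IV = 9L, V = 9L)
  n2 <- switch(object@modelId, I = 0L, II = 0L, III = 1L, IV = 0L, V = 9L)
  if (length(object@lambda1) != n1)
    return(sprintf("model %s needs lambda1 of length %d", object@modelId, n1))
  if (length(object@lambda2) != n2)
    return(sprintf("model %s needs lambda2 of length %d", object@modelId, n2))
  TRUE
})

#' Posterior sample from the Gibbs/Metropolis-Hastings sampler
#'
#' @slot draws matrix of thinned posterior draws (one named column per scalar
#'   parameter).
#' @slot loglik matrix (records x draws) of per-record MBN log-likelihoods,
#'   the input of [cpoEstimate()].
#' @slot spec the [ModelSpec-class] that was fitted (tBar resolved).
#' @slot acceptance named Metropolis-Hastings acceptance rates
#'   (post-adaptation).
#' @slot effects posterior means of the random effects: data.frames `u`
#'   (additive genetic, per pedigree individual) and `p` (permanent
#'   environmental, per sow), each with columns `l` and `t`.
#' @slot config the control list used for the run.
#' @export
setClass("McmcChain", representation(
  draws = "matrix",
  loglik = "matrix",
  spec = "ModelSpec",
  acceptance = "numeric",
  effects = "list",
  config = "list"
))

#' Conditional predictive ordinate estimate
#'
#' @slot perRecordCpo estimated p(y_i | y_-i) per record.
#' @slot logCpoSum pseudo log-marginal: sum of log CPO over records.
#' @slot nDraws number of MCMC draws used.
#' @export
setClass("CpoResult", representation(
  perRecordCpo = "numeric",
  logCpoSum = "numeric",
  nDraws = "integer"
))

setValidity("CpoResult", function(object) {
  if (any(object@perRecordCpo < 0 | object@perRecordCpo > 1, na.rm = TRUE))
    return("per-record CPO values must lie in [0, 1]")
  TRUE
})

# ---- show methods ----------------------------------------------------------

setMethod("show", "DiallelData", function(object) {
  rec <- object@records
  cat("DiallelData:", nrow(rec), "farrowing records,",
      length(unique(rec$sow_id)), "sows\n")
  cat("  crosses:", paste(names(table(rec$cross)), collapse = " "), "\n")
  cat("  mean TNB:", round(mean(rec$tnb), 2),
      " mean SB:", round(mean(rec$sb), 2), "\n")
})

setMethod("show", "Pedigree", function(object) {
  cat("Pedigree:", length(object@id), "individuals,",
      sum(object@sire == 0L & object@dam == 0L), "founders, mean F =",
      signif(mean(object@f), 3), "\n")
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec: model", object@modelId,
      if (!is.na(object@tBar)) paste0("(tBar = ", round(object@tBar, 3), ")")
      else "(tBar from data)", "\n")
  if (length(object@lambda1))
    cat("  lambda1:", paste(signif(object@lambda1, 3), collapse = " "), "\n")
  if (length(object@lambda2))
    cat("  lambda2:", paste(signif(object@lambda2, 3), collapse = " "), "\n")
})

setMethod("show", "McmcChain", function(object) {
  cat("McmcChain: model", object@spec@modelId, "-", nrow(object@draws),
      "stored draws of", ncol(object@draws), "parameters\n")
  if (length(object@acceptance))
    cat("  MH acceptance:",
        paste(names(object@acceptance),
              sprintf("%.2f", object@acceptance), collapse = ", "), "\n")
})

setMethod("show", "CpoResult", function(object) {
  cat("CpoResult:", length(object@perRecordCpo), "records,",
      object@nDraws, "draws; LogCPO =", round(object@logCpoSum, 2), "\n")
})

# ---- accessors -------------------------------------------------------------

#' @describeIn DiallelData-class the record table
#' @param x,object a `DiallelData`
#' @export
records <- function(x) {
  stopifnot(is(x, "DiallelData"))
  x@records
}

#' @describeIn DiallelData-class number of farrowing records
#' @export
nRecords <- function(x) nrow(records(x))

#' @describeIn McmcChain-class matrix of posterior draws
#' @param chain a `McmcChain`
#' @export
draws <- function(chain) {
  stopifnot(is(chain, "McmcChain"))
  chain@draws
}

#' @describeIn McmcChain-class records x draws log-likelihood matrix
#' @export
loglikMatrix <- function(chain) {
  stopifnot(is(chain, "McmcChain"))
  chain@loglik
}

#' @describeIn McmcChain-class named MH acceptance rates
#' @export
acceptanceRates <- function(chain) {
  stopifnot(is(chain, "McmcChain"))
  chain@acceptance
}

#' @describeIn McmcChain-class posterior means of the random effects
#'   (`$u`: additive genetic values per pedigree individual; `$p`:
#'   permanent environmental values per sow; columns `l`, `t`)
#' @export
effectMeans <- function(chain) {
  stopifnot(is(chain, "McmcChain"))
  chain@effects
}

#' @describeIn CpoResult-class the summed log conditional predictive ordinate
#' @param x a `CpoResult`
#' @export
logCpo <- function(x) {
  stopifnot(is(x, "CpoResult"))
  x@logCpoSum
}
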