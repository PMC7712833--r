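#' Model specification for the logit predictor
#'
#' @param model one of `"I"`, `"II"`, `"III"`, `"IV"`, `"V"`.
#' @param tBar centering constant for the litter-size deviation
#'   `d = tnb - tBar`; `NA` (default) means "use the unweighted mean of the
#'   observed TNB at fit time", after which the fitted value is stored so
#'   the model is reusable on new data.
#' @param lambda1 shared (length 1, models II/III) or per-cross (length 9,
#'   models IV/V) linear recursion coefficient.
#' @param lambda2 shared (model III) or per-cross (model V) quadratic
#'   recursion coefficient.
#' @return a [ModelSpec-class].
#' @examples
#' modelSpec("II", lambda1 = 0.257)
#' @export
modelSpec <- function(model = "II", tBar = NA_real_,
                      lambda1 = NULL, lambda2 = NULL) {
  model <- match.arg(model, c("I", "II", "III", "IV", "V"))
  n1 <- switch(model, I = 0L, II = 1L, III = 1L, IV = 9L, V = 9L)
  n2 <- switch(model, I = 0L, II = 0L, III = 1L, IV = 0L, V = 9L)
  if (is.null(lambda1)) lambda1 <- numeric(n1) else lambda1 <- rep_len(as.numeric(lambda1), n1)
  if (is.null(lambda2)) lambda2 <- numeric(n2) else lambda2 <- rep_len(as.numeric(lambda2), n2)
  if (n1 == 9L) names(lambda1) <- crossCodes()
  if (n2 == 9L) names(lambda2) <- crossCodes()
  new("ModelSpec", modelId = model, tBar = as.numeric(tBar),
      lambda1 = lambda1, lambda2 = lambda2)
}

#' Incidence matrices for the diallel animal model
#'
#' Builds the fixed-effect incidence matrix `X` (all 9 cross levels are kept;
#' the first parity and first year-season level are dropped so `X` is full
#' column rank without a global intercept) plus the record-to-sow maps for
#' the additive genetic (`sowPed`, position in the pedigree) and permanent
#' environmental (`sowPe`, position among sows) random effects.
#'
#' @param data a [DiallelData-class].
#' @param ped a [Pedigree-class]; every `sow_id` must appear in it.
#' @return list with `X`, `levelMap` (retained column labels per factor),
#'   `sowPed`, `sowPe`, `sows` (sow ids in `sowPe` order), `tnb`, `sb`,
#'   `cross` (integer 1-9 per record).
#' @export
buildDesigns <- function(data, ped) {
  stopifnot(is(data, "DiallelData"), is(ped, "Pedigree"))
  rec <- records(data)
  n <- nrow(rec)
  sowPed <- match(rec$sow_id, ped@id)
  if (anyNA(sowPed))
    stop("sow(s) absent from pedigree: ",
         paste(utils::head(unique(rec$sow_id[is.na(sowPed)]), 5), collapse = ", "))
  sows <- unique(rec$sow_id)
  sowPe <- match(rec$sow_id, sows)

  crossLev <- crossCodes()
  parLev <- 2:6                       # first parity absorbed
  ysLev <- data@ysLevels
  ysKeep <- if (length(ysLev) > 1) ysLev[-1] else character(0)

  p <- length(crossLev) + length(parLev) + length(ysKeep)
  X <- matrix(0, n, p)
  cn <- c(paste0("cross.", crossLev), paste0("parity.", parLev),
          if (length(ysKeep)) paste0("ys.", ysKeep))
  colnames(X) <- cn
  ci <- match(rec$cross, crossLev)
  X[cbind(seq_len(n), ci)] <- 1
  pi <- match(rec$parity, parLev)
  ok <- !is.na(pi)
  X[cbind(which(ok), 9L + pi[ok])] <- 1
  if (length(ysKeep)) {
    yi <- match(rec$year_season, ysKeep)
    ok <- !is.na(yi)
    X[cbind(which(ok), 14L + yi[ok])] <- 1
  }

  list(X = X,
       levelMap = list(cross = crossLev, parity = parLev, ys = ysKeep,
                       dropped = list(parity = 1L,
                                      ys = if (length(ysLev)) ysLev[1] else NULL)),
       sowPed = sowPed, sowPe = sowPe, sows = sows,
       tnb = rec$tnb, sb = rec$sb, cross = ci)
}

#' Linear predictors of the two-trait recursive model
#'
#' `linearPredictorT` evaluates the Gaussian mean of litter size,
#' `X b + Z u + Z p`; `logitPhi` adds the model-specific recursion terms in
#' the litter-size deviation `d = tnb - tBar` to a baseline predictor and
#' returns the logit of the MBN location parameter:
#' 0 (model I), `lambda1 d` (II), `lambda1 d + lambda2 d^2` (III),
#' `lambda1[k] d` for the record's cross k (IV), `lambda1[k] d +
#' lambda2[k] d^2` (V).
#'
#' @param effects list with `b` (fixed effects, in `X` column order),
#'   `u` (additive genetic values over the pedigree), `p` (permanent
#'   environmental values over sows).
#' @param designs output of [buildDesigns()].
#' @return numeric vector, one value per record.
#' @export
linearPredictorT <- function(effects, designs) {
  drop(designs$X %*% effects$b) + effects$u[designs$sowPed] +
    effects$p[designs$sowPe]
}

#' @rdname linearPredictorT
#' @param spec a [ModelSpec-class]; `tBar` must be resolved (not NA).
#' @param baseline numeric vector: the non-recursive part
#'   `X b_l + Z u_l + Z p_l` per record.
#' @param tnb integer litter sizes per record.
#' @param cross cross codes (character) or integer indices 1-9 per record.
#' @export
logitPhi <- function(spec, baseline, tnb, cross) {
  stopifnot(is(spec, "ModelSpec"))
  n <- max(length(baseline), length(tnb), length(cross))
  baseline <- rep_len(baseline, n)
  if (spec@modelId == "I") return(baseline)
  if (is.na(spec@tBar))
    stop("tBar is unresolved; set it in the ModelSpec or fit the model first")
  d <- rep_len(tnb, n) - spec@tBar
  cross <- rep_len(cross, n)
  if (is.character(cross)) cross <- match(cross, crossCodes())
  l1 <- unname(spec@lambda1)
  l2 <- unname(spec@lambda2)
  baseline + switch(spec@modelId,
    II = l1 * d,
    III = l1 * d + l2 * d^2,
    IV = l1[cross] * d,
    V = l1[cross] * d + l2[cross] * d^2)
}
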