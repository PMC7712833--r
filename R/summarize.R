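#' Shortest highest-posterior-density interval
#'
#' The narrowest contiguous interval containing a fraction `prob` of the
#' sorted draws.
#'
#' @param x numeric vector of posterior draws.
#' @param prob interval mass (default 0.95).
#' @return length-2 numeric `(lower, upper)`.
#' @export
hpdInterval <- function(x, prob = 0.95) {
  stopifnot(length(x) >= 1, prob > 0, prob <= 1)
  xs <- sort(x)
  n <- length(xs)
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(xs[1], xs[n]))
  width <- xs[(k + 1):n] - xs[1:(n - k)]
  i <- which.min(width)
  c(xs[i], xs[i + k])
}

#' Posterior summary of a fitted chain
#'
#' Per-parameter posterior mean, SD and shortest 95% HPD interval, plus the
#' derived genetic and permanent environmental correlations (`r_a`, `r_p`)
#' and the cross effects of each trait re-expressed as deviations from their
#' nine-level mean (the presentation in which cross effects are comparable
#' across identifiability conventions).
#'
#' @param chain a [McmcChain-class] with at least one stored draw.
#' @param prob HPD interval mass.
#' @return data.frame with columns `parameter`, `mean`, `sd`, `hpd_lo`,
#'   `hpd_hi`.
#' @export
summarizeChain <- function(chain, prob = 0.95) {
  stopifnot(is(chain, "McmcChain"))
  dr <- draws(chain)
  if (nrow(dr) == 0) stop("empty chain: no stored draws to summarise")
  dr <- cbind(dr,
              r_a = dr[, "G.lt"] / sqrt(dr[, "G.ll"] * dr[, "G.tt"]),
              r_p = dr[, "P.lt"] / sqrt(dr[, "P.ll"] * dr[, "P.tt"]))
  for (tr in c("t", "l")) {
    cols <- paste0("b_", tr, ".cross.", crossCodes())
    if (all(cols %in% colnames(dr))) {
      dev <- dr[, cols, drop = FALSE] - rowMeans(dr[, cols, drop = FALSE])
      colnames(dev) <- paste0("dev_", tr, ".", crossCodes())
      dr <- cbind(dr, dev)
    }
  }
  out <- t(apply(dr, 2, function(x) {
    h <- hpdInterval(x, prob)
    c(mean = mean(x), sd = sd(x), hpd_lo = h[1], hpd_hi = h[2])
  }))
  data.frame(parameter = rownames(out), out, row.names = NULL,
             check.names = FALSE)
}
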