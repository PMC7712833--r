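#' The multiplicative binomial (MBN) distribution
#'
#' Density, normalizing constant, per-event success probability, moments and
#' random generation for the multiplicative binomial distribution
#' \deqn{MBN(x | nb, \phi, \theta) \propto {nb \choose x} \phi^x
#'   (1-\phi)^{nb-x} \theta^{x(nb-x)},}
#' a two-parameter generalization of the binomial: at \eqn{\theta = 1} it is
#' exactly Binomial(nb, \eqn{\phi}); \eqn{\theta < 1} induces over-dispersion
#' and \eqn{\theta > 1} under-dispersion of the counts.  All probability
#' arithmetic is carried out in log space with log-sum-exp accumulation of
#' the normalizer, so moderate litter sizes and dispersion values are exact
#' to full double precision.
#'
#' @param x integer count(s) in `0..size`.
#' @param size number of Bernoulli events `nb` (litter size), non-negative.
#' @param phi location parameter in (0, 1).
#' @param theta dispersion parameter, > 0.
#' @param log logical; return log density?
#' @return `dmbn`: (log) probabilities. `mbnNormalizer`: the constant
#'   \eqn{K_{nb-a}(\phi,\theta)}. `mbnSuccessProb`: the marginal success
#'   probability of one Bernoulli event. `mbnMoments`: list with `mean` and
#'   `var` (by enumeration; no closed form exists). `rmbn`: integer draws.
#' @examples
#' dmbn(1, size = 2, phi = 0.5, theta = 0.9)    # 0.45 / 0.95
#' mbnSuccessProb(size = 10, phi = 0.25, theta = 1)  # binomial case: 0.25
#' @export
dmbn <- function(x, size, phi, theta, log = FALSE) {
  n <- max(length(x), length(size), length(phi), length(theta))
  x <- rep_len(as.integer(x), n)
  size <- rep_len(as.integer(size), n)
  phi <- rep_len(as.numeric(phi), n)
  theta <- rep_len(as.numeric(theta), n)
  .check_mbn_params(size, phi, theta)
  if (any(x < 0L | x > size))
    stop("x must lie in [0, size]")
  lp <- mbn_logpmf_cpp(x, size, phi, theta)
  if (log) lp else exp(lp)
}

#' @rdname dmbn
#' @param a 0 for \eqn{K_{nb}}, 1 for \eqn{K_{nb-1}}.
#' @export
mbnNormalizer <- function(size, phi, theta, a = 0) {
  if (!length(a) == 1 || !a %in% c(0, 1))
    stop("a must be 0 or 1")
  n <- max(length(size), length(phi), length(theta))
  size <- rep_len(as.integer(size), n)
  phi <- rep_len(as.numeric(phi), n)
  theta <- rep_len(as.numeric(theta), n)
  .check_mbn_params(size, phi, theta)
  if (any(size - a < 0)) stop("size - a must be non-negative")
  mbn_normalizer_cpp(size, phi, theta, as.integer(a))
}

#' @rdname dmbn
#' @export
mbnSuccessProb <- function(size, phi, theta) {
  n <- max(length(size), length(phi), length(theta))
  size <- rep_len(as.integer(size), n)
  phi <- rep_len(as.numeric(phi), n)
  theta <- rep_len(as.numeric(theta), n)
  .check_mbn_params(size, phi, theta)
  if (any(size < 1L)) stop("size must be >= 1 for a success probability")
  phi * mbn_normalizer_cpp(size, phi, theta, 1L) /
    mbn_normalizer_cpp(size, phi, theta, 0L)
}

#' @rdname dmbn
#' @export
mbnMoments <- function(size, phi, theta) {
  stopifnot(length(size) == 1, length(phi) == 1, length(theta) == 1)
  .check_mbn_params(as.integer(size), phi, theta)
  xs <- 0:size
  pr <- dmbn(xs, size, phi, theta)
  m <- sum(xs * pr)
  list(mean = m, var = sum((xs - m)^2 * pr))
}

#' @rdname dmbn
#' @param n number of draws (for `rmbn`); `size`, `phi`, `theta` are recycled
#'   to length `n`.
#' @export
rmbn <- function(n, size, phi, theta) {
  size <- rep_len(as.integer(size), n)
  phi <- rep_len(as.numeric(phi), n)
  theta <- rep_len(as.numeric(theta), n)
  .check_mbn_params(size, phi, theta)
  mbn_sample_cpp(size, phi, theta)
}

.check_mbn_params <- function(size, phi, theta) {
  if (any(!is.finite(phi)) || any(phi <= 0 | phi >= 1))
    stop("phi must be finite and in (0, 1)")
  if (any(!is.finite(theta)) || any(theta <= 0))
    stop("theta must be finite and > 0")
  if (any(is.na(size)) || any(size < 0L))
    stop("size must be a non-negative integer")
  invisible(TRUE)
}
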