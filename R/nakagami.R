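#' Nakagami distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the Nakagami distribution with shape `m` and scale (mean power)
#' `omega`. If `R ~ Nakagami(m, omega)` then `R^2 ~ Gamma(shape = m,
#' rate = m / omega)`, so `omega = E[R^2]`.
#'
#' @param x,q vector of quantiles (amplitudes, `>= 0`).
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param m shape parameter (`> 0`). `m = 1` gives the Rayleigh envelope of
#'   fully developed speckle; `m < 1` indicates pre-Rayleigh statistics.
#' @param omega scale parameter (`> 0`), the mean envelope power.
#' @return `dnaka` the density, `pnaka` the CDF, `qnaka` the quantile
#'   function, `rnaka` a vector of random amplitudes.
#' @examples
#' r <- rnaka(1e4, m = 1, omega = 2)
#' mean(r^2) # close to 2
#' @name nakagami
NULL

.check_naka <- function(m, omega) {
  if (any(!is.finite(m)) || any(m <= 0)) stop("Nakagami shape `m` must be > 0")
  if (any(!is.finite(omega)) || any(omega <= 0)) stop("Nakagami scale `omega` must be > 0")
}

#' @rdname nakagami
#' @export
dnaka <- function(x, m, omega) {
  .check_naka(m, omega)
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- 2 * x[pos] * stats::dgamma(x[pos]^2, shape = m, rate = m / omega)
  out
}

#' @rdname nakagami
#' @export
pnaka <- function(q, m, omega) {
  .check_naka(m, omega)
  stats::pgamma(pmax(q, 0)^2, shape = m, rate = m / omega)
}

#' @rdname nakagami
#' @export
qnaka <- function(p, m, omega) {
  .check_naka(m, omega)
  sqrt(stats::qgamma(p, shape = m, rate = m / omega))
}

#' @rdname nakagami
#' @export
rnaka <- function(n, m, omega) {
  .check_naka(m, omega)
  sqrt(stats::rgamma(n, shape = m, rate = m / omega))
}
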