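#' Von Mises density on the circle
#'
#' Density of the von Mises distribution with mean direction `mu` and
#' concentration `kappa`, evaluated at angles `theta` (radians). Numerically
#' stable for large `kappa` (uses the exponentially scaled Bessel function).
#'
#' @param theta Numeric vector of angles in radians.
#' @param mu Mean direction in radians.
#' @param kappa Concentration parameter, `kappa >= 0`. `kappa = 0` gives the
#'   uniform density `1/(2*pi)`.
#' @return Numeric vector of densities.
#' @export
#' @examples
#' dvonmises(c(0, pi), mu = 0, kappa = 2)
dvonmises <- function(theta, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  exp(kappa * (cos(theta - mu) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Sample from a von Mises distribution
#'
#' Best & Fisher (1979) rejection sampler with a wrapped-Cauchy envelope.
#' Draws are governed by R's RNG, so `set.seed()` makes them reproducible.
#'
#' @param n Number of draws.
#' @param mu Mean direction in radians.
#' @param kappa Concentration, `kappa >= 0`.
#' @return Numeric vector of angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  cpp_rvm(as.integer(n), mu %% (2 * pi), kappa)
}

#' Von Mises mixture density and sampler
#'
#' @param theta Angles in radians.
#' @param mu Component mean directions (radians).
#' @param kappa Component concentrations.
#' @param weight Mixture weights; must sum to 1.
#' @return `dvonmises_mix()`: densities; `rvonmises_mix()`: draws in
#'   `[0, 2*pi)`.
#' @export
dvonmises_mix <- function(theta, mu, kappa, weight) {
  stopifnot(length(mu) == length(kappa), length(mu) == length(weight))
  if (abs(sum(weight) - 1) > 1e-8) abort("mixture weights must sum to 1")
  out <- numeric(length(theta))
  for (i in seq_along(mu)) out <- out + weight[i] * dvonmises(theta, mu[i], kappa[i])
  out
}

#' @rdname dvonmises_mix
#' @param n Number of draws.
#' @export
rvonmises_mix <- function(n, mu, kappa, weight) {
  stopifnot(length(mu) == length(kappa), length(mu) == length(weight))
  if (abs(sum(weight) - 1) > 1e-8) abort("mixture weights must sum to 1")
  comp <- sample.int(length(mu), n, replace = TRUE, prob = weight)
  out <- numeric(n)
  for (i in seq_along(mu)) {
    idx <- which(comp == i)
    if (length(idx)) out[idx] <- cpp_rvm(length(idx), mu[i] %% (2 * pi), kappa[i])
  }
  out
}

# Ratio A(kappa) = I1(kappa)/I0(kappa), stable via scaled Bessel functions.
vm_A <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# Maximum-likelihood von Mises concentration from the mean resultant length
# of an angular sample: solves A(kappa) = Rbar.
kappa_ml <- function(theta) {
  rbar <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  if (rbar >= 1 - 1e-12) {
    abort("angles are (nearly) all identical; concentration is unbounded - consider jittering")
  }
  if (rbar < 1e-10) return(0)
  uniroot(function(k) vm_A(k) - rbar, interval = c(1e-8, 1e5), tol = 1e-10)$root
}

# Plug-in kernel concentration for the von Mises kernel density estimator:
# nu = [ 3 n kappa^2 I2(2 kappa) / (4 sqrt(pi) I0(kappa)^2) ]^(2/5),
# where kappa is the largest ML concentration of the k-fold wrapped sample
# (k = 1..kmax). The wrapping matters for diel data: dawn/dusk activity is
# bimodal with nearly antipodal modes, whose k = 1 resultant length is close
# to zero; wrapping at k = 2 merges the modes and recovers a sensible
# concentration instead of flattening the estimate.
kde_bandwidth <- function(theta, adjust = 1, kmax = 3) {
  rbar <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  if (rbar >= 1 - 1e-12) {
    abort("angles are (nearly) all identical; concentration is unbounded - consider jittering")
  }
  cpp_bandwidth(theta, as.integer(kmax), adjust)
}
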