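# Independent oracles used to validate the package's implementations.
# These are deliberately naive (brute force / direct summation / normal
# equations) and share no code with the functions they check.

# O(n^2) independence filter: repeatedly scan for the next event at least
# `window` minutes after the last retained one.
brute_force_independent <- function(times, window = 30) {
  ord <- order(times)
  t_sorted <- times[ord]
  kept <- integer(0)
  remaining <- seq_along(t_sorted)
  while (length(remaining)) {
    nxt <- remaining[1]
    kept <- c(kept, nxt)
    anchor <- t_sorted[nxt]
    ok <- vapply(remaining, function(i) {
      as.numeric(difftime(t_sorted[i], anchor, units = "mins")) >= window
    }, logical(1))
    remaining <- remaining[ok]
  }
  sort(ord[kept])
}

# Pianka index by direct elementwise summation (explicit loops).
pianka_direct <- function(u, v) {
  p <- u / sum(u)
  q <- v / sum(v)
  num <- 0
  du <- 0
  dv <- 0
  for (i in seq_along(p)) {
    num <- num + p[i] * q[i]
    du <- du + p[i]^2
    dv <- dv + q[i]^2
  }
  num / sqrt(du * dv)
}

# Least-squares coefficients via the normal equations.
ls_coef <- function(X, y) {
  X1 <- cbind(1, X)
  as.numeric(solve(t(X1) %*% X1, t(X1) %*% y))
}

# Gaussian ML log-likelihood of a fitted mean vector.
gaussian_loglik <- function(y, mu) {
  n <- length(y)
  s2 <- mean((y - mu)^2)
  -n / 2 * (log(2 * pi * s2) + 1)
}

# random detection stream for one camera+species
random_stream <- function(n, span_minutes = 600, origin = as.POSIXct("2021-06-01", tz = "UTC")) {
  origin + sort(round(runif(n, 0, span_minutes))) * 60
}

# convenience detection tibble
det_tbl <- function(times, camera = "C01", species = "oryx") {
  tibble::tibble(camera_id = camera, species = species, timestamp = times)
}

# calendar with fixed sunrise/sunset for all 12 months
flat_calendar <- function(sunrise = 6, sunset = 18) {
  tibble::tibble(month = 1:12, sunrise = sunrise, sunset = sunset)
}
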