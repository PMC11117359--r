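#' Circular kernel density estimate of diel activity
#'
#' Nonparametric density of activity over the 24 h cycle, using a von Mises
#' kernel centred at each detection time (in radians). The kernel
#' concentration comes from a plug-in rule: the sample's von Mises
#' concentration is estimated by maximum likelihood from the mean resultant
#' length and transformed to the asymptotically optimal kernel
#' concentration, then multiplied by `adjust`.
#'
#' @param times Numeric vector of detection times in radians `[0, 2*pi)`,
#'   length >= 2 and not all identical.
#' @param adjust Bandwidth multiplier applied to the plug-in kernel
#'   concentration (values < 1 smooth more).
#' @param n_grid Number of equally spaced grid angles on `[0, 2*pi)`.
#' @return Object of class `activity_kde`: list with `times`, `n`, `kappa`
#'   (kernel concentration), `adjust`, `grid`, `density`. The density
#'   integrates to 1 over the circle.
#' @export
#' @examples
#' set.seed(1)
#' k <- fit_activity_kde(rvonmises(200, pi, 3))
#' sum(k$density) * 2 * pi / length(k$grid)  # ~1
fit_activity_kde <- function(times, adjust = 1, n_grid = 128) {
  times <- as.numeric(times) %% (2 * pi)
  if (length(times) < 2) abort("need at least 2 detection times")
  if (diff(range(times)) < 1e-12) {
    abort("all detection times identical; density is degenerate - consider jittering")
  }
  kappa <- kde_bandwidth(times, adjust)
  grid <- seq(0, 2 * pi, length.out = n_grid + 1)[1:n_grid]
  structure(list(times = times, n = length(times), kappa = kappa,
                 adjust = adjust, grid = grid,
                 density = cpp_vm_kde(grid, times, kappa)),
            class = "activity_kde")
}

#' @rdname fit_activity_kde
#' @param x An `activity_kde` object.
#' @param theta Angles at which to evaluate the fitted density.
#' @param ... Unused.
#' @export
predict.activity_kde <- function(x, theta, ...) {
  cpp_vm_kde(as.numeric(theta) %% (2 * pi), x$times, x$kappa)
}

#' @rdname fit_activity_kde
#' @param object An `activity_kde` object.
#' @export
autoplot.activity_kde <- function(object, ...) {
  d <- tibble::tibble(hour = object$grid * 24 / (2 * pi), density = object$density)
  ggplot2::ggplot(d, ggplot2::aes(.data$hour, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6), limits = c(0, 24)) +
    ggplot2::labs(x = "Time of day (h)", y = "Activity density") +
    ggplot2::theme_minimal()
}

#' Diel activity overlap coefficient
#'
#' The coefficient of overlap between two activity densities is the area
#' under the pointwise minimum of the two fitted kernel densities, in
#' `[0, 1]`. Two estimators are provided: `dhat1` integrates
#' `min(fhat, ghat)` over a regular grid; `dhat4` averages the clamped
#' density ratios at the observed detection times,
#' `0.5 * (mean(min(1, g/f)) at a-times + mean(min(1, f/g)) at b-times)`.
#' By default the estimator follows the sample-size rule: `dhat1` when the
#' smaller sample has fewer than 75 detections, `dhat4` when both have at
#' least 75. Bandwidths use [fit_activity_kde()]'s plug-in rule with
#' `adjust = 0.8` for `dhat1` and `adjust = 1` for `dhat4`.
#'
#' With `ci = TRUE`, a smoothed bootstrap resamples each species' times from
#' its fitted density (a kernel centre plus von Mises noise), re-estimates
#' the coefficient with the same estimator, and forms a symmetric bootstrap
#' interval `delta +/- q`, where `q` is the `level` quantile of the absolute
#' resampling deviations `|delta* - delta|`, clamped to `[0, 1]`. In
#' simulation this construction attains near-nominal coverage where the
#' equal-tailed percentile forms undercover (see the methods vignette).
#'
#' @param a,b Numeric vectors of detection times in radians.
#' @param estimator `"auto"` (default sample-size rule), `"dhat1"` or
#'   `"dhat4"`.
#' @param n_grid Grid size for `dhat1` (default 128).
#' @param adjust Optional bandwidth multiplier overriding the
#'   estimator-specific default.
#' @param ci Compute a smoothed-bootstrap confidence interval?
#' @param resamples Number of bootstrap resamples (default 10,000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed making the bootstrap reproducible.
#' @return Object of class `overlap_result`: `delta`, `estimator`, `n1`,
#'   `n2`, `strength` ([classify_overlap()]), and with `ci = TRUE` also
#'   `ci_low`, `ci_high`, `resamples`, `seed`.
#' @export
#' @examples
#' set.seed(42)
#' a <- rvonmises(100, pi / 2, 3)
#' b <- rvonmises(100, pi, 3)
#' overlap_delta(a, b)
overlap_delta <- function(a, b, estimator = c("auto", "dhat1", "dhat4"),
                          n_grid = 128, adjust = NULL, ci = FALSE,
                          resamples = 10000, level = 0.95, seed = NULL) {
  estimator <- match.arg(estimator)
  a <- as.numeric(a) %% (2 * pi)
  b <- as.numeric(b) %% (2 * pi)
  if (length(a) < 2 || length(b) < 2) abort("need at least 2 detections per sample")
  if (estimator == "auto") {
    estimator <- if (min(length(a), length(b)) < 75) "dhat1" else "dhat4"
  }
  adj <- adjust %||% if (estimator == "dhat1") 0.8 else 1
  ka <- kde_bandwidth(a, adj)
  kb <- kde_bandwidth(b, adj)
  delta <- if (estimator == "dhat1") {
    cpp_dhat1(a, b, ka, kb, as.integer(n_grid))
  } else {
    cpp_dhat4(a, b, ka, kb, 1e-12)
  }
  out <- structure(list(delta = delta, estimator = estimator,
                        n1 = length(a), n2 = length(b),
                        strength = classify_overlap(delta),
                        ci_low = NA_real_, ci_high = NA_real_,
                        resamples = NA_integer_, seed = seed,
                        level = level),
                   class = "overlap_result")
  if (ci) {
    ci_b <- overlap_boot_ci(a, b, estimator = estimator, n_grid = n_grid,
                            adjust = adj, resamples = resamples,
                            level = level, seed = seed, delta = delta)
    out$ci_low <- ci_b[1]
    out$ci_high <- ci_b[2]
    out$resamples <- as.integer(resamples)
  }
  out
}

#' Smoothed-bootstrap confidence interval for the overlap coefficient
#'
#' @inheritParams overlap_delta
#' @param delta Optional precomputed point estimate (recomputed if `NULL`).
#' @return Length-2 numeric `c(ci_low, ci_high)`.
#' @export
overlap_boot_ci <- function(a, b, estimator = c("dhat1", "dhat4"),
                            n_grid = 128, adjust = NULL, resamples = 10000,
                            level = 0.95, seed = NULL, delta = NULL) {
  estimator <- match.arg(estimator)
  stopifnot(resamples >= 100)
  a <- as.numeric(a) %% (2 * pi)
  b <- as.numeric(b) %% (2 * pi)
  adj <- adjust %||% if (estimator == "dhat1") 0.8 else 1
  ka <- kde_bandwidth(a, adj)
  kb <- kde_bandwidth(b, adj)
  if (is.null(delta)) {
    delta <- if (estimator == "dhat1") cpp_dhat1(a, b, ka, kb, as.integer(n_grid))
             else cpp_dhat4(a, b, ka, kb, 1e-12)
  }
  boot <- with_seed(seed,
    cpp_boot_deltas(a, b, estimator == "dhat1", as.integer(resamples),
                    as.integer(n_grid), adj, 3L, 1e-12))
  q <- unname(quantile(abs(boot - delta), level, type = 7))
  c(ci_low = max(0, delta - q), ci_high = min(1, delta + q))
}

# evaluate `code` under a temporary RNG seed, restoring the caller's state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' True overlap of two circular densities
#'
#' High-resolution numeric integral of the pointwise minimum of two density
#' functions over the circle. Intended as ground truth for synthetic
#' scenarios and as an independent oracle when validating the kernel
#' estimators.
#'
#' @param f,g Vectorised density functions on `[0, 2*pi)`, each integrating
#'   to 1 over the circle.
#' @param n Number of midpoint-rule evaluation points (default `2^15`).
#' @return The overlap coefficient in `[0, 1]`.
#' @export
#' @examples
#' f <- function(t) dvonmises(t, 0, 8)
#' g <- function(t) dvonmises(t, pi, 8)
#' true_overlap(f, g)
true_overlap <- function(f, g, n = 32768) {
  h <- 2 * pi / n
  mid <- (seq_len(n) - 0.5) * h
  min(1, max(0, sum(pmin(f(mid), g(mid))) * h))
}

#' Classify overlap strength
#'
#' Maps an overlap coefficient to the conventional strength classes:
#' strong if `delta > 0.75`, moderate if `0.5 <= delta <= 0.75`, low if
#' `delta < 0.5` (both boundaries fall in the moderate class).
#'
#' @param delta Overlap coefficient(s) in `[0, 1]`.
#' @return Factor with levels `low`, `moderate`, `strong`.
#' @export
#' @examples
#' classify_overlap(c(0.2, 0.5, 0.75, 0.83))
classify_overlap <- function(delta) {
  stopifnot(all(delta >= 0 & delta <= 1))
  factor(ifelse(delta > 0.75, "strong", ifelse(delta >= 0.5, "moderate", "low")),
         levels = c("low", "moderate", "strong"))
}

#' @rdname overlap_delta
#' @param x An `overlap_result` object.
#' @param ... Unused.
#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Overlap %s = %.3f (%s; n1 = %d, n2 = %d)\n",
              toupper(x$estimator), x$delta, as.character(x$strength), x$n1, x$n2))
  if (!is.na(x$ci_low)) {
    cat(sprintf("%.0f%% smoothed-bootstrap CI: [%.3f, %.3f] (%d resamples)\n",
                100 * x$level, x$ci_low, x$ci_high, x$resamples))
  }
  invisible(x)
}

#' @rdname overlap_delta
#' @export
tidy.overlap_result <- function(x, ...) {
  tibble::tibble(estimator = x$estimator, delta = x$delta,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 n1 = x$n1, n2 = x$n2, strength = as.character(x$strength),
                 resamples = x$resamples)
}

#' Seasonal temporal overlap between two species
#'
#' Computes the diel activity overlap per season (or over the whole study)
#' from an independent-detection table, applying the sample-size estimator
#' rule per season, with optional smoothed-bootstrap intervals.
#'
#' @param detections Tibble from [filter_independent()] (columns `species`,
#'   `season_label`, `time_radians`).
#' @param species_pair The two species to compare.
#' @param by_season One value per season (default) or one for the whole
#'   study.
#' @inheritParams overlap_delta
#' @return Tibble with one row per period: `period`, `n1`, `n2`,
#'   `estimator`, `delta`, `ci_low`, `ci_high`, `strength`.
#' @export
temporal_overlap <- function(detections, species_pair = unique(detections$species)[1:2],
                             by_season = TRUE, ci = FALSE, resamples = 10000,
                             level = 0.95, seed = NULL) {
  stopifnot(length(species_pair) == 2)
  d <- dplyr::filter(detections, .data$species %in% species_pair)
  d$period <- if (by_season) d$season_label else "study"
  purrr::map_dfr(unique(d$period), function(per) {
    a <- d$time_radians[d$period == per & d$species == species_pair[1]]
    b <- d$time_radians[d$period == per & d$species == species_pair[2]]
    if (length(a) < 2 || length(b) < 2) {
      warn(paste0("period '", per, "' has too few detections; omitted"))
      return(NULL)
    }
    res <- overlap_delta(a, b, ci = ci, resamples = resamples, level = level,
                         seed = seed)
    dplyr::bind_cols(tibble::tibble(period = per), tidy(res))
  })
}

#' Plot the diel overlap of two activity samples
#'
#' Draws both fitted activity densities over the 24 h cycle and shades
#' their pointwise minimum (the area equal to the overlap coefficient).
#'
#' @param a,b Detection times in radians.
#' @param names Labels for the two samples.
#' @param n_grid Grid resolution.
#' @return A ggplot object.
#' @export
plot_overlap <- function(a, b, names = c("species A", "species B"), n_grid = 256) {
  fa <- fit_activity_kde(a, n_grid = n_grid)
  fb <- fit_activity_kde(b, n_grid = n_grid)
  hour <- fa$grid * 24 / (2 * pi)
  d <- tibble::tibble(hour = rep(hour, 2),
                      density = c(fa$density, fb$density),
                      species = rep(names, each = n_grid))
  m <- tibble::tibble(hour = hour, density = pmin(fa$density, fb$density))
  ggplot2::ggplot(d, ggplot2::aes(.data$hour, .data$density)) +
    ggplot2::geom_area(data = m, fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$species, linetype = .data$species)) +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6), limits = c(0, 24)) +
    ggplot2::labs(x = "Time of day (h)", y = "Activity density",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}
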