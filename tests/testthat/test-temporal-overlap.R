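# dawn/dusk activity mixture used throughout: bimodal von Mises with modes
# near 06:30 and 17:30, the shape typical of crepuscular ungulates
dawn_dusk <- list(mu = c(6.5, 17.5) * pi / 12, kappa = c(3, 3), weight = c(0.5, 0.5))

test_that("circular KDE integrates to 1, is periodic, and finds the mode", {
  set.seed(61)
  k <- fit_activity_kde(rvonmises(2000, pi, 4))
  step <- 2 * pi / length(k$grid)
  expect_equal(sum(k$density) * step, 1, tolerance = 1e-3)
  expect_true(all(k$density >= 0))
  # mode within one grid step of the generating mean
  expect_lt(abs(k$grid[which.max(k$density)] - pi), step + 1e-9)
  # periodic consistency: density at 0 equals density at 2*pi
  expect_equal(predict(k, 0), predict(k, 2 * pi))
  # density at every data point is strictly positive
  expect_true(all(predict(k, k$times) > 0))

  expect_error(fit_activity_kde(1), "at least 2")
  expect_error(fit_activity_kde(rep(1.5, 20)), "jitter")
})

test_that("KDE of uniform activity flattens as the sample grows", {
  set.seed(62)
  dev <- vapply(c(200, 5000), function(n) {
    k <- fit_activity_kde(runif(n, 0, 2 * pi))
    max(abs(k$density - 1 / (2 * pi)))
  }, numeric(1))
  expect_lt(dev[2], dev[1])
  expect_lt(dev[2], 0.2 / (2 * pi))
})

test_that("overlap estimator follows the sample-size rule and is symmetric", {
  set.seed(63)
  a <- rvonmises(50, 0, 2)
  b <- rvonmises(200, 1, 2)
  expect_equal(overlap_delta(a, b)$estimator, "dhat1")
  expect_equal(overlap_delta(b, rvonmises(80, 1, 2))$estimator, "dhat4")

  # a sample against itself: complete overlap
  expect_equal(overlap_delta(a, a)$delta, 1, tolerance = 1e-6)

  # Dhat1 symmetry
  d_ab <- overlap_delta(a, b, estimator = "dhat1")$delta
  d_ba <- overlap_delta(b, a, estimator = "dhat1")$delta
  expect_equal(d_ab, d_ba, tolerance = 1e-10)
  # Dhat4 symmetry holds by construction of the two-term average
  expect_equal(overlap_delta(a, b, estimator = "dhat4")$delta,
               overlap_delta(b, a, estimator = "dhat4")$delta, tolerance = 1e-10)
})

test_that("true_overlap is a faithful quadrature oracle", {
  f <- function(t) dvonmises(t, 0, 8)
  g <- function(t) dvonmises(t, pi, 8)
  expect_equal(true_overlap(f, f), 1, tolerance = 1e-9)
  # nearly disjoint concentrated densities
  expect_lt(true_overlap(f, g), 1e-3)
  # refinement stability: doubling the resolution changes nothing material
  expect_equal(true_overlap(f, g, n = 2^15), true_overlap(f, g, n = 2^17),
               tolerance = 1e-6)
})

test_that("estimated overlap converges to the true overlap of the generators", {
  f <- function(t) dvonmises(t, 0, 3)
  g <- function(t) dvonmises(t, pi / 2, 3)
  truth <- true_overlap(f, g)
  set.seed(64)
  err <- vapply(c(100, 1000), function(n) {
    mean(replicate(5, {
      abs(overlap_delta(rvonmises(n, 0, 3), rvonmises(n, pi / 2, 3),
                        estimator = "dhat1")$delta - truth)
    }))
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
})

test_that("Dhat4 recovers bimodal crepuscular overlap with small error", {
  f <- function(t) dvonmises_mix(t, dawn_dusk$mu, dawn_dusk$kappa, dawn_dusk$weight)
  shift <- 0.6
  g <- function(t) dvonmises_mix(t, dawn_dusk$mu + shift, dawn_dusk$kappa, dawn_dusk$weight)
  truth <- true_overlap(f, g)
  set.seed(65)
  errs <- replicate(50, {
    a <- rvonmises_mix(200, dawn_dusk$mu, dawn_dusk$kappa, dawn_dusk$weight)
    b <- rvonmises_mix(200, dawn_dusk$mu + shift, dawn_dusk$kappa, dawn_dusk$weight)
    abs(overlap_delta(a, b, estimator = "dhat4")$delta - truth)
  })
  expect_lte(mean(errs), 0.06)
})

test_that("smoothed bootstrap intervals are reproducible and sane", {
  set.seed(66)
  a <- rvonmises_mix(200, dawn_dusk$mu, dawn_dusk$kappa, dawn_dusk$weight)
  b <- rvonmises_mix(200, dawn_dusk$mu, dawn_dusk$kappa, dawn_dusk$weight)
  r1 <- overlap_delta(a, b, ci = TRUE, resamples = 500, seed = 99)
  r2 <- overlap_delta(a, b, ci = TRUE, resamples = 500, seed = 99)
  expect_identical(c(r1$ci_low, r1$ci_high), c(r2$ci_low, r2$ci_high))
  # identical generating distributions at n = 200: upper bound is high
  expect_gte(r1$ci_high, 0.9)
  # interval brackets the point estimate
  expect_lte(r1$ci_low, r1$delta)
  expect_gte(r1$ci_high, r1$delta)
})

test_that("overlap strength classes split at 0.5 and 0.75", {
  cls <- classify_overlap(c(0.2, 0.49, 0.5, 0.6, 0.75, 0.76, 0.83))
  expect_equal(as.character(cls),
               c("low", "low", "moderate", "moderate", "moderate", "strong", "strong"))
})

test_that("seasonal temporal overlap table applies the estimator rule per season", {
  set.seed(67)
  n_small <- 40
  n_big <- 120
  det <- tibble::tibble(
    species = c(rep("oryx", n_big), rep("gazelle", n_big),
                rep("oryx", n_small), rep("gazelle", n_big)),
    season_label = c(rep("winter 2020-2021", 2 * n_big),
                     rep("spring 2021", n_small + n_big)),
    time_radians = c(rvonmises_mix(2 * n_big, dawn_dusk$mu, dawn_dusk$kappa, dawn_dusk$weight),
                     rvonmises_mix(n_small + n_big, dawn_dusk$mu, dawn_dusk$kappa,
                                   dawn_dusk$weight)))
  tab <- temporal_overlap(det, c("oryx", "gazelle"))
  expect_equal(tab$estimator[tab$period == "winter 2020-2021"], "dhat4")
  expect_equal(tab$estimator[tab$period == "spring 2021"], "dhat1")
  expect_true(all(tab$delta >= 0 & tab$delta <= 1))
})
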