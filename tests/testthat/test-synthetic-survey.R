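# small, fast configuration reused across tests
small_config <- function(...) {
  synthetic_config(
    n_cameras = 12, n_days = 90, p_active = 1,
    covariates = list(GC = c(0, 50), FC = c(0, 35), WA = c(0, 3000), DP = c(100, 4000)),
    species = list(
      oryx = list(beta0 = log(0.3), beta = c(GC = 0.4),
                  diel = list(mu = c(6.5, 17.5), kappa = c(3, 3), weight = c(0.5, 0.5))),
      gazelle = list(beta0 = log(0.2), beta = c(FC = 0.4),
                     diel = list(mu = c(6.5, 17.5), kappa = c(2.5, 2.5),
                                 weight = c(0.5, 0.5)))),
    ...)
}

test_that("identical config and seed reproduce the survey exactly", {
  s1 <- simulate_survey(small_config(), seed = 5)
  s2 <- simulate_survey(small_config(), seed = 5)
  expect_identical(s1$detections, s2$detections)
  expect_identical(s1$effort, s2$effort)
  expect_identical(s1$sites, s2$sites)
  s3 <- simulate_survey(small_config(), seed = 6)
  expect_false(identical(s1$detections, s3$detections))

  # written files round-trip through the package readers
  dir <- tempfile()
  write_survey(s1, dir)
  det <- read_detections(file.path(dir, "detections.csv"))
  expect_equal(nrow(det), nrow(s1$detections))
  expect_equal(read_effort(file.path(dir, "effort.csv"))$date, s1$effort$date)
  expect_equal(read_calendar(file.path(dir, "calendar.csv"))$month, 1:12)
  sites <- read_sites(file.path(dir, "sites.csv"))
  expect_true(all(c("GC", "FC", "WA", "DP") %in% names(sites)))
})

test_that("per-site RAI1 is unbiased for 100 times the generating rate", {
  cfg <- synthetic_config(
    n_cameras = 26, n_days = 120, p_active = 1,
    covariates = list(GC = c(0, 50), FC = c(0, 35)),
    species = list(oryx = list(beta0 = log(0.2), beta = c(GC = 0),
                               diel = list(mu = c(6.5, 17.5), kappa = c(3, 3),
                                           weight = c(0.5, 0.5)))))
  set.seed(81)
  seeds <- sample.int(1e6, 20)
  res <- purrr::map_dfr(seeds, function(sd) {
    sv <- simulate_survey(cfg, seed = sd)
    r <- rai1(sv$detections, sv$effort)  # generated events are independent
    dplyr::inner_join(r, sv$truth$rai1, by = c("camera_id", "species"))
  })
  # overall mean against truth, within 3 Monte-Carlo SE
  err <- res$rai1.x - res$rai1.y
  expect_lt(abs(mean(err)), 3 * sd(err) / sqrt(nrow(res)))
})

test_that("the diel mixture sampler matches its density (goodness of fit)", {
  mu <- c(6.5, 17.5) * pi / 12
  kap <- c(3, 2)
  wt <- c(0.6, 0.4)
  set.seed(82)
  draws <- rvonmises_mix(1e6, mu, kap, wt)
  breaks <- seq(0, 2 * pi, length.out = 49)
  obs <- table(cut(draws, breaks))
  # expected bin mass by fine midpoint integration
  probs <- vapply(seq_len(48), function(i) {
    tt <- seq(breaks[i], breaks[i + 1], length.out = 201)
    mid <- (tt[-1] + tt[-201]) / 2
    sum(dvonmises_mix(mid, mu, kap, wt)) * diff(breaks[i:(i + 1)]) / 200
  }, numeric(1))
  gof <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = probs / sum(probs)))
  expect_gt(gof$p.value, 0.01)
  # and the density itself integrates to 1
  expect_equal(true_overlap(function(t) dvonmises_mix(t, mu, kap, wt),
                            function(t) dvonmises_mix(t, mu, kap, wt)), 1,
               tolerance = 1e-9)
})

test_that("species confined to disjoint camera subsets have zero spatial overlap", {
  cfg <- small_config()
  cfg$species$oryx$sites <- 1:6
  cfg$species$gazelle$sites <- 7:12
  sv <- simulate_survey(cfg, seed = 9)
  expect_equal(sv$truth$pianka, 0)
  r <- rai1(filter_independent(sv$detections), sv$effort)
  expect_equal(pianka_overlap(r, c("oryx", "gazelle"))$pianka, 0)
})

test_that("identical diel mixtures give estimated overlap near 1 at large n", {
  cfg <- small_config()
  cfg$species$gazelle$diel <- cfg$species$oryx$diel
  cfg$species$gazelle$beta0 <- cfg$species$oryx$beta0
  sv <- simulate_survey(cfg, seed = 10)
  ind <- filter_independent(sv$detections)
  ov <- temporal_overlap(ind, c("oryx", "gazelle"), by_season = FALSE)
  expect_gt(ov$delta, 0.9)
  expect_equal(sv$truth$temporal$delta_true, rep(1, 4), tolerance = 1e-6)
})

test_that("burst emulation adds only dependent events that the filter removes", {
  cfg <- small_config(emulate_bursts = TRUE)
  sv_burst <- simulate_survey(cfg, seed = 11)
  sv_clean <- simulate_survey(small_config(), seed = 11)
  expect_gt(nrow(sv_burst$detections), nrow(sv_clean$detections))
  kept <- filter_independent(sv_burst$detections)
  # bursts live within 30 min of a true event, so the filtered count comes
  # back near the clean count (exact equality only when no two true events
  # fall within one window)
  expect_lt(abs(nrow(kept) - nrow(filter_independent(sv_clean$detections))) /
              nrow(sv_clean$detections), 0.1)
})

test_that("configurations implying runaway detection volumes are refused", {
  cfg <- small_config()
  cfg$species$oryx$beta0 <- 10
  expect_error(simulate_survey(cfg, seed = 1), "1e6")
})

test_that("recovery report tracks truth for the main estimators", {
  sv <- simulate_survey(synthetic_config(n_days = 365), seed = 12)
  rep_tbl <- recovery_report(sv)
  expect_true(all(c("mean_rai1", "pianka", "delta", "w_crepuscular") %in%
                    rep_tbl$quantity))
  expect_true(all(is.finite(rep_tbl$abs_error)))
  # temporal overlap recovered within 0.05 at this sample size
  expect_lt(rep_tbl$abs_error[rep_tbl$quantity == "delta"], 0.05)
})
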