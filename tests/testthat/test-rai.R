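make_survey_tbls <- function() {
  eff <- tibble::tibble(
    camera_id = rep(c("C01", "C02"), each = 200),
    date = rep(seq(as.Date("2021-01-01"), by = "day", length.out = 200), 2))
  det <- tibble::tibble(
    camera_id = c(rep("C01", 10), rep("C02", 4)),
    species = "oryx",
    timestamp = as.POSIXct("2021-01-05 08:00", tz = "UTC") + (1:14) * 86400)
  list(det = det, eff = eff)
}

test_that("RAI1 is detections per 100 camera-days per site", {
  s <- make_survey_tbls()
  r <- rai1(s$det, s$eff)
  expect_equal(r$rai1[r$camera_id == "C01"], 100 * 10 / 200)
  expect_equal(r$rai1[r$camera_id == "C02"], 100 * 4 / 200)

  # zero detections yield zero, not a missing row
  det2 <- dplyr::mutate(s$det, camera_id = "C01")
  r2 <- rai1(det2, s$eff)
  expect_equal(r2$rai1[r2$camera_id == "C02"], 0)
})

test_that("RAI is invariant to splitting a period and recombining counts", {
  s <- make_survey_tbls()
  whole <- rai1(s$det, s$eff)
  # split into two halves, recombine counts and effort
  cut <- as.Date("2021-01-12")
  h1 <- rai1(dplyr::filter(s$det, as.Date(timestamp) < cut),
             dplyr::filter(s$eff, date < cut))
  h2 <- rai1(dplyr::filter(s$det, as.Date(timestamp) >= cut),
             dplyr::filter(s$eff, date >= cut))
  recombined <- dplyr::full_join(h1, h2, by = c("camera_id", "species")) |>
    dplyr::mutate(rai = 100 * (detections.x + detections.y) /
                    (camera_days.x + camera_days.y))
  expect_equal(sort(recombined$rai), sort(whole$rai1))
})

test_that("RAI2 pools detections and effort across years within a month", {
  # year 1: 10 detections / 300 days; year 2: 20 / 300 -> pooled 100*30/600 = 5
  eff <- tibble::tibble(
    camera_id = rep(sprintf("C%02d", 1:10), each = 60),
    date = as.Date(c(rep(seq(as.Date("2021-01-01"), by = "day", length.out = 30), 10),
                     rep(seq(as.Date("2022-01-01"), by = "day", length.out = 30), 10))))
  det <- tibble::tibble(
    camera_id = "C01", species = "oryx",
    timestamp = c(as.POSIXct("2021-01-10 08:00", tz = "UTC") + seq_len(10) * 3600,
                  as.POSIXct("2022-01-10 08:00", tz = "UTC") + seq_len(20) * 3600))
  r <- rai2(det, eff)
  expect_equal(r$rai2[r$month == 1], 5)
  expect_equal(r$camera_days[r$month == 1], 600)
})

test_that("species shares are percentages of total detections", {
  sh <- species_share(tibble::tibble(species = c("oryx", "gazelle"),
                                     n = c(1865, 1208)))
  expect_equal(round(sh$share, 2), c(60.69, 39.31))
  expect_equal(sum(sh$share), 100)

  even <- species_share(tibble::tibble(species = c("a", "b"), n = c(1, 1)))
  expect_equal(even$share, c(50, 50))
  single <- species_share(tibble::tibble(species = "a", n = 3073))
  expect_equal(single$share, 100)
  expect_error(species_share(tibble::tibble(species = "a", n = 0)), "zero")
})

test_that("Welch comparison of RAI1 behaves under null and shifted alternatives", {
  ident <- tibble::tibble(species = rep(c("a", "b"), each = 5),
                          rai1 = rep(c(1, 2, 3, 4, 5), 2))
  expect_equal(compare_rai1(ident, c("a", "b"))$statistic, 0)

  flat <- tibble::tibble(species = rep(c("a", "b"), each = 3), rai1 = 1)
  expect_true(compare_rai1(flat, c("a", "b"))$degenerate)

  # type-I error near nominal under the null
  set.seed(31)
  p <- replicate(1000, {
    d <- tibble::tibble(species = rep(c("a", "b"), each = 26),
                        rai1 = rnorm(52))
    compare_rai1(d, c("a", "b"))$p_value
  })
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)

  # power > 0.9 for a 2-SD mean shift at n = 26 per group
  set.seed(32)
  p2 <- replicate(300, {
    d <- tibble::tibble(species = rep(c("a", "b"), each = 26),
                        rai1 = c(rnorm(26), rnorm(26, mean = 2)))
    compare_rai1(d, c("a", "b"))$p_value
  })
  expect_gt(mean(p2 < 0.05), 0.9)
})

test_that("seasonal ANOVA detects a shifted season and controls type I error", {
  flat <- tibble::tibble(season = rep(c("winter", "spring", "summer"), each = 3),
                         rai2 = rep(c(4, 5, 6), 3))
  expect_equal(glance(seasonal_anova(flat))$statistic, 0)

  set.seed(33)
  rej <- replicate(500, {
    d <- tibble::tibble(season = rep(c("w", "sp", "su", "f"), each = 6),
                        rai2 = rnorm(24))
    glance(seasonal_anova(d))$p_value < 0.05
  })
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.08)

  # the strongly shifted season carries the smallest adjusted p in post hoc
  set.seed(34)
  d <- tibble::tibble(season = rep(c("w", "sp", "su", "f"), each = 6),
                      rai2 = c(rnorm(6, 10), rnorm(6), rnorm(6), rnorm(6)))
  ph <- tidy(seasonal_anova(d))
  worst <- ph$contrast[which.min(ph$adj_p_value)]
  expect_match(worst, "w")

  # seasons with fewer than 2 observations are excluded with a warning
  short <- tibble::tibble(season = c(rep("w", 3), rep("sp", 3), "su"),
                          rai2 = c(1, 2, 3, 2, 3, 4, 9))
  expect_warning(fit <- seasonal_anova(short), "excluding")
  expect_equal(glance(fit)$df, 1)
})
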