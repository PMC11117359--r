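#' Approximate sunrise/sunset calendar for a latitude
#'
#' Mean monthly sunrise and sunset (local solar time) from the standard
#' solar-declination approximation, evaluated on the 15th of each month.
#' Used to generate calendars for synthetic surveys; real analyses should
#' use a published local calendar.
#'
#' @param latitude Latitude in degrees (default 32.7, an arid-steppe
#'   latitude).
#' @return Tibble `month, sunrise, sunset` (fractional hours).
#' @export
make_calendar <- function(latitude = 32.7) {
  doy <- as.integer(format(as.Date(paste0("2021-", 1:12, "-15")), "%j"))
  decl <- -23.44 * cos(2 * pi * (doy + 10) / 365.25)
  phi <- latitude * pi / 180
  dl <- decl * pi / 180
  cosw <- pmin(1, pmax(-1, -tan(phi) * tan(dl)))
  half <- acos(cosw) * 12 / pi  # half day length in hours
  tibble::tibble(month = 1:12,
                 sunrise = round((12 - half) * 60) / 60,
                 sunset = round((12 + half) * 60) / 60)
}

#' Configuration for a synthetic camera-trap survey
#'
#' Defaults mirror a two-year, 26-camera arid-steppe survey of two
#' sympatric antelope: about 17,000 camera-days, per-site detection rates
#' log-linear in eight standardised habitat covariates (a grass-driven
#' "oryx" and a forb-driven "gazelle"), and bimodal crepuscular
#' (dawn/dusk) von Mises mixture diel activity, with a partial nocturnal
#' shift for oryx in summer.
#'
#' @param n_cameras Number of camera sites.
#' @param start First survey date.
#' @param n_days Survey length in days (default 730: Dec 2020 - Nov 2022).
#' @param p_active Daily probability a camera is active (effort thinning).
#' @param covariates Named list of `c(min, max)` ranges for the site
#'   covariates.
#' @param covariate_rho Pairwise latent Gaussian correlation between
#'   covariates (exchangeable copula).
#' @param species Named list; each species has `beta0` (log rate per
#'   camera-day at average habitat), `beta` (named log-linear coefficients
#'   on standardised covariates), `diel` (list `mu` (hours), `kappa`,
#'   `weight`), optionally `diel_season` (per-season overrides, names in
#'   winter/spring/summer/fall), and optionally `sites` (camera indices the
#'   species can occur at; its rate is zero elsewhere).
#' @param latitude Latitude for the synthetic sunrise/sunset calendar.
#' @param emulate_bursts If `TRUE`, each true detection spawns extra
#'   non-independent photos within the independence window, exercising the
#'   30-min filter.
#' @param burst_mean Mean number of extra photos per burst.
#' @param seed Default seed used by [simulate_survey()].
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_cameras = 26,
    start = as.Date("2020-12-01"),
    n_days = 730,
    p_active = 0.91,
    covariates = list(SC = c(0, 40), FC = c(0, 35), GC = c(0, 50),
                      WA = c(0, 3000), AL = c(20, 178), DP = c(100, 4000),
                      DR = c(50, 3000), WT = c(100, 3500)),
    covariate_rho = 0.2,
    species = list(
      oryx = list(beta0 = -2.45, beta = c(GC = 0.5, FC = 0.15),
                  diel = list(mu = c(6.5, 17.5), kappa = c(3, 3),
                              weight = c(0.55, 0.45)),
                  diel_season = list(
                    summer = list(mu = c(5.5, 22), kappa = c(3, 1.5),
                                  weight = c(0.5, 0.5)))),
      gazelle = list(beta0 = -2.9, beta = c(FC = 0.5, GC = -0.15, DR = -0.2),
                     diel = list(mu = c(6.5, 17.5), kappa = c(2.5, 2.5),
                                 weight = c(0.5, 0.5)))),
    latitude = 32.7,
    emulate_bursts = FALSE,
    burst_mean = 1.5,
    seed = 20201201) {
  cfg <- list(n_cameras = n_cameras, start = as.Date(start), n_days = n_days,
              p_active = p_active, covariates = covariates,
              covariate_rho = covariate_rho, species = species,
              latitude = latitude, emulate_bursts = emulate_bursts,
              burst_mean = burst_mean, seed = seed)
  for (sp in species) {
    if (abs(sum(sp$diel$weight) - 1) > 1e-8) abort("diel mixture weights must sum to 1")
    if (any(sp$diel$kappa <= 0)) abort("diel concentrations must be positive")
    bad <- setdiff(names(sp$beta), names(covariates))
    if (length(bad)) {
      abort(paste0("species coefficients name unknown covariate(s): ",
                   paste(bad, collapse = ", ")))
    }
  }
  structure(cfg, class = "synthetic_config")
}

# species- and season-specific diel mixture, in radians
diel_mixture <- function(sp_cfg, season) {
  mix <- sp_cfg$diel
  if (!is.null(sp_cfg$diel_season[[as.character(season)]])) {
    mix <- sp_cfg$diel_season[[as.character(season)]]
  }
  list(mu = mix$mu * pi / 12, kappa = mix$kappa, weight = mix$weight)
}

#' Simulate a camera-trap survey with known ground truth
#'
#' Generates the four survey tables (detections, site covariates, effort,
#' calendar) from a [synthetic_config()]: site covariates are drawn from an
#' exchangeable Gaussian copula over the requested ranges; per camera-day
#' detection counts are Poisson with log rate `beta0 + beta' z` (z the
#' standardised covariates); detection times are drawn from the species'
#' (season-specific) von Mises mixture. The same config and seed reproduce
#' the output exactly.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List of class `camtrap_survey`: `detections`, `sites`, `effort`,
#'   `calendar`, `truth` (per-site expected rates and RAI1, the spatial
#'   Pianka index of the expected rates, per-season true temporal overlap,
#'   true period proportions and selection ratios), and `config`.
#' @export
simulate_survey <- function(config = synthetic_config(), seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(seed, simulate_survey_impl(config, seed))
}

simulate_survey_impl <- function(config, seed) {
  covs <- names(config$covariates)
  p <- length(covs)
  cams <- sprintf("C%02d", seq_len(config$n_cameras))

  # exchangeable Gaussian copula -> uniform over the requested ranges
  rho <- config$covariate_rho
  shared <- rnorm(config$n_cameras)
  z <- sqrt(rho) * matrix(shared, config$n_cameras, p) +
    sqrt(1 - rho) * matrix(rnorm(config$n_cameras * p), config$n_cameras, p)
  u <- stats::pnorm(z)
  x <- sapply(seq_len(p), function(j) {
    r <- config$covariates[[j]]
    r[1] + u[, j] * (r[2] - r[1])
  })
  colnames(x) <- covs
  zstd <- scale(x)

  dates <- config$start + seq_len(config$n_days) - 1
  active <- matrix(runif(config$n_cameras * length(dates)) < config$p_active,
                   config$n_cameras, length(dates))
  effort <- purrr::map_dfr(seq_len(config$n_cameras), function(i) {
    tibble::tibble(camera_id = cams[i], date = dates[active[i, ]])
  })

  season_of <- assign_season(dates)$season
  rates <- sapply(config$species, function(sp) {
    b <- setNames(numeric(p), covs)
    b[names(sp$beta)] <- sp$beta
    r <- as.numeric(exp(sp$beta0 + zstd %*% b))
    if (!is.null(sp$sites)) r[-sp$sites] <- 0
    r
  })  # cameras x species
  total_expected <- sum(rates) * config$n_days * config$p_active
  if (total_expected > 1e6) {
    abort("configuration implies more than 1e6 expected detections; refusing")
  }

  det <- purrr::map_dfr(seq_along(config$species), function(s) {
    spn <- names(config$species)[s]
    purrr::map_dfr(seq_len(config$n_cameras), function(i) {
      days <- which(active[i, ])
      counts <- rpois(length(days), rates[i, s])
      keep <- counts > 0
      if (!any(keep)) return(NULL)
      day_idx <- rep(days[keep], counts[keep])
      theta <- numeric(length(day_idx))
      for (sea in levels(season_of)) {
        sel <- season_of[day_idx] == sea
        if (any(sel)) {
          mix <- diel_mixture(config$species[[s]], sea)
          theta[sel] <- rvonmises_mix(sum(sel), mix$mu, mix$kappa, mix$weight)
        }
      }
      mins <- round(theta * 1440 / (2 * pi)) %% 1440
      tibble::tibble(
        camera_id = cams[i], species = spn,
        timestamp = as.POSIXct(dates[day_idx], tz = "UTC") + mins * 60)
    })
  })

  if (config$emulate_bursts && nrow(det)) {
    extra <- purrr::map_dfr(seq_len(nrow(det)), function(r) {
      k <- rpois(1, config$burst_mean)
      if (k == 0) return(NULL)
      tibble::tibble(camera_id = det$camera_id[r], species = det$species[r],
                     timestamp = det$timestamp[r] + round(runif(k, 1, 25)) * 60)
    })
    det <- dplyr::bind_rows(det, extra)
  }
  det <- dplyr::arrange(det, .data$timestamp, .data$camera_id, .data$species)

  season_labels <- unique(assign_season(dates)$season_label)
  sites <- purrr::map_dfr(season_labels, function(sl) {
    dplyr::bind_cols(tibble::tibble(camera_id = cams, season = sl),
                     tibble::as_tibble(x))
  })
  calendar <- make_calendar(config$latitude)
  truth <- ground_truth(config, cams, rates, dates, calendar)

  structure(list(detections = det, sites = sites, effort = effort,
                 calendar = calendar, truth = truth, config = config,
                 seed = seed),
            class = "camtrap_survey")
}

# deterministic ground truth derived from the configuration + realized sites
ground_truth <- function(config, cams, rates, dates, calendar) {
  spn <- names(config$species)
  rai1_true <- tibble::tibble(
    camera_id = rep(cams, length(spn)),
    species = rep(spn, each = length(cams)),
    rate = as.numeric(rates),
    rai1 = 100 * as.numeric(rates))
  pianka_true <- if (length(spn) >= 2) pianka(rates[, 1], rates[, 2]) else NA_real_

  seasons <- levels(assign_season(dates)$season)
  months_of <- list(winter = c(12, 1, 2), spring = 3:5, summer = 6:8, fall = 9:11)
  per_season <- purrr::map_dfr(seasons, function(sea) {
    mixes <- purrr::map(config$species, diel_mixture, season = sea)
    delta <- if (length(spn) >= 2) {
      true_overlap(function(t) dvonmises_mix(t, mixes[[1]]$mu, mixes[[1]]$kappa, mixes[[1]]$weight),
                   function(t) dvonmises_mix(t, mixes[[2]]$mu, mixes[[2]]$kappa, mixes[[2]]$weight))
    } else NA_real_
    pp <- period_proportions(calendar, months = months_of[[sea]])
    sel <- purrr::map_dfr(seq_along(spn), function(s) {
      mix <- mixes[[s]]
      o <- true_period_mass(mix, calendar, months_of[[sea]])
      tibble::tibble(species = spn[s], season = sea, period = pp$period,
                     o = o, pi = pp$pi, w = o / pp$pi)
    })
    tibble::tibble(season = sea, delta_true = delta, selection = list(sel))
  })
  list(rai1 = rai1_true, pianka = pianka_true,
       temporal = per_season[, c("season", "delta_true")],
       selection = dplyr::bind_rows(per_season$selection))
}

# probability mass of a diel mixture in each period, averaged over months
true_period_mass <- function(mix, calendar, months) {
  masses <- sapply(months, function(m) {
    cal <- calendar[calendar$month == m, ]
    grid_n <- 86400
    h <- (seq_len(grid_n) - 0.5) * 24 / grid_n
    dens <- dvonmises_mix(h * pi / 12, mix$mu, mix$kappa, mix$weight) * pi / 12
    lab <- ifelse((h >= cal$sunrise - 1 & h <= cal$sunrise + 1) |
                    (h >= cal$sunset - 1 & h <= cal$sunset + 1), "crepuscular",
                  ifelse(h > cal$sunrise + 1 & h < cal$sunset - 1, "diurnal", "nocturnal"))
    tapply(dens * 24 / grid_n, factor(lab, c("crepuscular", "diurnal", "nocturnal")), sum)
  })
  rowMeans(masses)
}

#' @rdname simulate_survey
#' @param x A `camtrap_survey` object.
#' @param ... Unused.
#' @export
print.camtrap_survey <- function(x, ...) {
  cat(sprintf("Synthetic camera-trap survey: %d cameras, %d camera-days, %d detections (%s)\n",
              length(unique(x$effort$camera_id)), nrow(x$effort), nrow(x$detections),
              paste(unique(x$detections$species), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic survey to CSV files
#'
#' Writes `detections.csv`, `sites.csv`, `effort.csv`, `calendar.csv` (in
#' the formats the readers expect) and `ground_truth.json` to `dir`.
#'
#' @param survey A `camtrap_survey` from [simulate_survey()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  det <- dplyr::mutate(survey$detections,
                       timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%S"))
  readr::write_csv(det, file.path(dir, "detections.csv"), progress = FALSE)
  readr::write_csv(survey$sites, file.path(dir, "sites.csv"), progress = FALSE)
  readr::write_csv(dplyr::mutate(survey$effort, date = format(.data$date)),
                   file.path(dir, "effort.csv"), progress = FALSE)
  cal <- tibble::tibble(month = survey$calendar$month,
                        sunrise = hm_string(survey$calendar$sunrise),
                        sunset = hm_string(survey$calendar$sunset))
  readr::write_csv(cal, file.path(dir, "calendar.csv"), progress = FALSE)
  jsonlite::write_json(list(rai1 = survey$truth$rai1,
                            pianka = survey$truth$pianka,
                            temporal = survey$truth$temporal,
                            selection = survey$truth$selection,
                            seed = survey$seed),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

hm_string <- function(hours) {
  mins <- round(hours * 60)
  sprintf("%02d:%02d", mins %/% 60, mins %% 60)
}

#' Estimator recovery against synthetic ground truth
#'
#' Runs the analysis pipeline on a simulated survey and tabulates, per
#' estimated quantity, the truth, the estimate, the bias and the absolute
#' error: per-site RAI1 (averaged over sites), the spatial Pianka index,
#' the study-wide temporal overlap coefficient, and the crepuscular
#' selection ratios.
#'
#' @param survey A `camtrap_survey` from [simulate_survey()].
#' @param window Independence window (minutes) used before estimation.
#' @return Tibble `quantity, species, truth, estimate, bias, abs_error`.
#' @export
recovery_report <- function(survey, window = 30) {
  ind <- filter_independent(survey$detections, window = window)
  spn <- names(survey$config$species)
  r1 <- rai1(ind, survey$effort)

  rows <- list()
  for (sp in spn) {
    est <- mean(r1$rai1[r1$species == sp], na.rm = TRUE)
    tr <- mean(survey$truth$rai1$rai1[survey$truth$rai1$species == sp])
    rows[[length(rows) + 1]] <- tibble::tibble(
      quantity = "mean_rai1", species = sp, truth = tr, estimate = est)
  }
  if (length(spn) >= 2) {
    po <- pianka_overlap(r1, spn[1:2])
    rows[[length(rows) + 1]] <- tibble::tibble(
      quantity = "pianka", species = NA_character_,
      truth = survey$truth$pianka, estimate = po$pianka[po$period == "study"])
    ov <- temporal_overlap(ind, spn[1:2], by_season = TRUE)
    ov$season <- sub(" .*", "", ov$period)
    ov <- dplyr::left_join(ov, survey$truth$temporal, by = "season")
    rows[[length(rows) + 1]] <- tibble::tibble(
      quantity = "delta", species = NA_character_,
      truth = mean(ov$delta_true), estimate = mean(ov$delta))
  }
  sel <- diel_selection(ind, survey$calendar, survey$effort)
  for (sp in spn) {
    est <- sel |>
      dplyr::filter(.data$species == sp, .data$diel_period == "crepuscular")
    tr <- survey$truth$selection |>
      dplyr::filter(.data$species == sp, .data$period == "crepuscular")
    rows[[length(rows) + 1]] <- tibble::tibble(
      quantity = "w_crepuscular", species = sp,
      truth = mean(tr$w), estimate = sum(est$n * est$w) / sum(est$n))
  }
  dplyr::bind_rows(rows) |>
    dplyr::mutate(bias = .data$estimate - .data$truth,
                  abs_error = abs(.data$bias))
}
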