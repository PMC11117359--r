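#' Diel period proportions from a sunrise/sunset calendar
#'
#' Partitions the 24 h day into crepuscular, diurnal and nocturnal periods.
#' Crepuscular is the 1 h before and after sunrise plus the 1 h before and
#' after sunset (4 h in total, so its proportion is exactly 1/6); diurnal is
#' the remaining daylight; nocturnal the remaining night. With several
#' months the monthly proportions are averaged (unweighted by default, or
#' weighted by `weights`, e.g. monthly effort).
#'
#' @param calendar Tibble from [read_calendar()] (`month`, `sunrise`,
#'   `sunset` in fractional hours).
#' @param months Optional integer vector restricting to a season's months.
#' @param weights Optional per-month weights (same order as the selected
#'   months).
#' @return Tibble `period, pi` with `sum(pi) == 1`.
#' @export
#' @examples
#' cal <- tibble::tibble(month = 1, sunrise = 6, sunset = 18)
#' period_proportions(cal)  # 4/24, 10/24, 10/24
period_proportions <- function(calendar, months = NULL, weights = NULL) {
  cal <- calendar
  if (!is.null(months)) {
    missing_m <- setdiff(months, cal$month)
    if (length(missing_m)) {
      abort(paste0("calendar lacks month(s): ", paste(missing_m, collapse = ", ")))
    }
    cal <- cal[match(months, cal$month), ]
  }
  day_len <- cal$sunset - cal$sunrise
  if (any(day_len < 2) || any(day_len > 22)) {
    abort("crepuscular windows overlap (day or night shorter than 2 h)")
  }
  p <- cbind(crepuscular = rep(4 / 24, nrow(cal)),
             diurnal = (day_len - 2) / 24,
             nocturnal = (24 - day_len - 2) / 24)
  w <- weights %||% rep(1, nrow(cal))
  stopifnot(length(w) == nrow(cal))
  avg <- colSums(p * w) / sum(w)
  tibble::tibble(period = factor(names(avg), levels = c("crepuscular", "diurnal", "nocturnal")),
                 pi = unname(avg))
}

#' Classify detection times into diel periods
#'
#' Labels each timestamp crepuscular, diurnal or nocturnal using its
#' month's mean sunrise and sunset. Crepuscular intervals are closed, so
#' boundary instants (exactly 1 h before sunrise, etc.) are crepuscular.
#'
#' @param timestamp POSIXct vector.
#' @param calendar Tibble (`month`, `sunrise`, `sunset`), fractional hours.
#' @return Factor with levels `crepuscular`, `diurnal`, `nocturnal`.
#' @export
classify_period <- function(timestamp, calendar) {
  lt <- as.POSIXlt(timestamp)
  m <- lt$mon + 1L
  missing_m <- setdiff(unique(m), calendar$month)
  if (length(missing_m)) {
    abort(paste0("calendar lacks month(s): ", paste(missing_m, collapse = ", ")))
  }
  idx <- match(m, calendar$month)
  sr <- calendar$sunrise[idx]
  ss <- calendar$sunset[idx]
  h <- lt$hour + lt$min / 60 + lt$sec / 3600
  crep <- (h >= sr - 1 & h <= sr + 1) | (h >= ss - 1 & h <= ss + 1)
  diur <- !crep & h > sr + 1 & h < ss - 1
  out <- ifelse(crep, "crepuscular", ifelse(diur, "diurnal", "nocturnal"))
  factor(out, levels = c("crepuscular", "diurnal", "nocturnal"))
}

#' Diel period selection ratios
#'
#' The selection ratio for period i is `w_i = o_i / pi_i`, where `o_i` is
#' the proportion of detections observed in the period and `pi_i` the
#' period's share of the 24 h day. `w > 1` indicates selective use of the
#' period and `w < 1` avoidance; values are exact
#' (`sum(o) = 1`, `sum(pi * w) = 1`), with rounding left to report time.
#'
#' @param counts Detections per period: a named numeric vector or a tibble
#'   with `period` and `n` columns; total must be positive.
#' @param proportions Tibble `period, pi` from [period_proportions()] (or a
#'   named vector).
#' @return Tibble `period, n, o, pi, w`.
#' @export
#' @examples
#' pp <- period_proportions(tibble::tibble(month = 1, sunrise = 6, sunset = 18))
#' selection_ratio(c(crepuscular = 60, diurnal = 114, nocturnal = 123), pp)
selection_ratio <- function(counts, proportions) {
  if (is.data.frame(counts)) {
    cn <- setNames(counts$n, as.character(counts$period))
  } else {
    cn <- counts
  }
  pp <- if (is.data.frame(proportions)) {
    setNames(proportions$pi, as.character(proportions$period))
  } else proportions
  periods <- names(pp)
  cn <- setNames(ifelse(is.na(cn[periods]), 0, cn[periods]), periods)
  if (sum(cn) <= 0) abort("no detections; selection ratios undefined")
  if (abs(sum(pp) - 1) > 1e-8 || any(pp <= 0)) abort("period proportions must be positive and sum to 1")
  o <- cn / sum(cn)
  tibble::tibble(period = factor(periods, levels = periods),
                 n = as.numeric(cn), o = unname(o), pi = unname(pp),
                 w = unname(o / pp))
}

#' Per-month diel period detection rates
#'
#' Builds the replicate units for the non-randomness test: for each month
#' present in the effort table, the number of detections in each diel
#' period divided by the hours that period occupied in that month
#' (`pi * 24 * active camera-days`), i.e. detections per period-hour.
#'
#' @param detections Independent-detection tibble (`timestamp`).
#' @param calendar Sunrise/sunset calendar tibble.
#' @param effort Effort tibble (`camera_id`, `date`).
#' @return Tibble `year, month, period, n, hours, rate`.
#' @export
diel_rates <- function(detections, calendar, effort) {
  det <- detections |>
    dplyr::mutate(period = classify_period(.data$timestamp, calendar),
                  year = as.integer(format(as.Date(.data$timestamp), "%Y")),
                  month = as.integer(format(as.Date(.data$timestamp), "%m"))) |>
    dplyr::count(.data$year, .data$month, .data$period, name = "n")
  eff <- effort |>
    dplyr::mutate(year = as.integer(format(.data$date, "%Y")),
                  month = as.integer(format(.data$date, "%m"))) |>
    dplyr::count(.data$year, .data$month, name = "camera_days")
  grid <- tidyr::expand_grid(eff,
                             period = factor(c("crepuscular", "diurnal", "nocturnal"),
                                             levels = c("crepuscular", "diurnal", "nocturnal")))
  grid$pi <- purrr::map2_dbl(grid$month, grid$period, function(m, p) {
    pp <- period_proportions(calendar, months = m)
    pp$pi[pp$period == p]
  })
  grid |>
    dplyr::left_join(det, by = c("year", "month", "period")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  hours = .data$pi * 24 * .data$camera_days,
                  rate = .data$n / .data$hours) |>
    dplyr::select("year", "month", "period", "n", "hours", "rate")
}

#' Test for non-random diel period use
#'
#' One-way ANOVA (between-groups df = 2) across the three diel periods on
#' per-unit detection rates standardised by period length, the units being
#' the months supplied in `rates` (see [diel_rates()]).
#'
#' @param rates Tibble with `period` and `rate` columns, one row per
#'   replicate unit and period.
#' @return One-row tibble `statistic, df, df_residual, p_value`.
#' @export
nonrandom_use_test <- function(rates) {
  counts <- table(rates$period)
  if (any(counts < 2)) abort("need at least 2 replicate units per period")
  fit <- aov(rate ~ period, data = rates)
  s <- summary(fit)[[1]]
  tibble::tibble(statistic = s[["F value"]][1], df = s[["Df"]][1],
                 df_residual = s[["Df"]][2], p_value = s[["Pr(>F)"]][1])
}

#' Seasonal diel selection summary
#'
#' For each species and season: detections per diel period, selection
#' ratios against the season's period proportions (monthly proportions
#' averaged), and the non-randomness ANOVA over month-by-period rates —
#' one row per species-season-period.
#'
#' @param detections Independent detections ([filter_independent()] output).
#' @param calendar Sunrise/sunset calendar.
#' @param effort Effort tibble.
#' @return Tibble `species, period (season label), diel_period, n, o, pi,
#'   w, statistic, df, p_value`.
#' @export
diel_selection <- function(detections, calendar, effort) {
  eff_season <- assign_season(effort$date)$season_label
  combos <- detections |> dplyr::distinct(.data$species, .data$season_label)
  purrr::pmap_dfr(combos, function(species, season_label) {
    d <- detections[detections$species == species &
                      detections$season_label == season_label, ]
    months <- sort(unique(as.integer(format(as.Date(d$timestamp), "%m"))))
    pp <- period_proportions(calendar, months = months)
    cnt <- table(classify_period(d$timestamp, calendar))
    sr <- selection_ratio(setNames(as.numeric(cnt), names(cnt)), pp)
    test <- tryCatch({
      rates <- diel_rates(d, calendar, effort[eff_season == season_label, ])
      nonrandom_use_test(rates)
    }, error = function(e) tibble::tibble(statistic = NA_real_, df = NA_integer_,
                                          df_residual = NA_integer_,
                                          p_value = NA_real_))
    dplyr::bind_cols(tibble::tibble(species = species, period = season_label),
                     dplyr::rename(sr, diel_period = "period"),
                     test[rep(1, nrow(sr)), ])
  })
}
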