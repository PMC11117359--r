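#' Relative activity indices
#'
#' `rai1()` is the spatial index: independent detections per 100 camera-days,
#' computed per camera site (optionally within each season). `rai2()` is the
#' temporal index: detections per 100 camera-days per calendar month, with
#' the two survey years pooled (counts and effort are summed across years
#' before the ratio is taken).
#'
#' Ratios are kept at full precision; any rounding is left to report
#' writers. A camera with zero effort in the period yields `rai1 = NA` and
#' is flagged `undefined`.
#'
#' @param detections Tibble of independent detections
#'   ([filter_independent()] output); `rai1()` uses `camera_id`, `species`
#'   and (if `by_season`) `season_label`; `rai2()` uses `species` and
#'   `timestamp`.
#' @param effort Effort tibble (`camera_id`, `date`).
#' @param by_season If `TRUE`, compute one record per camera-species-season;
#'   otherwise over the whole study.
#' @return A tibble with counts, effort and the index; `rai1()` includes
#'   every camera in `effort` for every species observed (zero counts kept).
#' @export
rai1 <- function(detections, effort, by_season = FALSE) {
  species <- unique(detections$species)
  if (by_season) {
    eff <- effort |>
      dplyr::mutate(period = assign_season(.data$date)$season_label) |>
      dplyr::count(.data$camera_id, .data$period, name = "camera_days")
    det <- detections |>
      dplyr::count(.data$camera_id, .data$species, period = .data$season_label,
                   name = "detections")
  } else {
    eff <- dplyr::count(effort, .data$camera_id, name = "camera_days") |>
      dplyr::mutate(period = "study")
    det <- detections |>
      dplyr::count(.data$camera_id, .data$species, name = "detections") |>
      dplyr::mutate(period = "study")
  }
  tidyr::expand_grid(eff, species = species) |>
    dplyr::left_join(det, by = c("camera_id", "period", "species")) |>
    dplyr::mutate(
      detections = dplyr::coalesce(.data$detections, 0L),
      undefined = .data$camera_days == 0,
      rai1 = dplyr::if_else(.data$undefined, NA_real_,
                            100 * .data$detections / .data$camera_days)
    ) |>
    dplyr::select("camera_id", "species", "period", "detections",
                  "camera_days", "rai1", "undefined") |>
    dplyr::arrange(.data$period, .data$species, .data$camera_id)
}

#' @rdname rai1
#' @export
rai2 <- function(detections, effort) {
  eff <- effort |>
    dplyr::mutate(month = as.integer(format(.data$date, "%m"))) |>
    dplyr::count(.data$month, name = "camera_days")
  species <- unique(detections$species)
  det <- detections |>
    dplyr::mutate(month = as.integer(format(as.Date(.data$timestamp), "%m"))) |>
    dplyr::count(.data$species, .data$month, name = "detections")
  tidyr::expand_grid(eff, species = species) |>
    dplyr::left_join(det, by = c("month", "species")) |>
    dplyr::mutate(detections = dplyr::coalesce(.data$detections, 0L),
                  rai2 = 100 * .data$detections / .data$camera_days) |>
    dplyr::select("species", "month", "detections", "camera_days", "rai2") |>
    dplyr::arrange(.data$species, .data$month)
}

#' Share of independent detections per species
#'
#' @param x Either a detections tibble (a `species` column; rows are
#'   counted) or a tibble with columns `species` and `n`.
#' @return Tibble `species, n, share` where `share` is the percentage of all
#'   detections (full precision; percentages sum to 100).
#' @export
#' @examples
#' species_share(tibble::tibble(species = c("oryx", "gazelle"), n = c(1865, 1208)))
species_share <- function(x) {
  tot <- if (all(c("species", "n") %in% names(x))) {
    dplyr::summarise(dplyr::group_by(x, .data$species), n = sum(.data$n), .groups = "drop")
  } else {
    dplyr::count(x, .data$species)
  }
  if (any(tot$n < 0)) abort("negative species totals")
  if (sum(tot$n) == 0) abort("all species totals are zero; shares undefined")
  dplyr::mutate(tot, share = 100 * .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$n))
}

#' Compare RAI1 between two species
#'
#' Welch's unequal-variance two-sample t-test on per-site RAI1 values of two
#' species. Degenerate input (both groups constant and equal) is flagged
#' rather than tested.
#'
#' @param rai Tibble from [rai1()] (columns `species`, `rai1`), or any tibble
#'   with those columns.
#' @param species_pair Character vector of the two species to compare.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `degenerate`.
#' @export
compare_rai1 <- function(rai, species_pair = unique(rai$species)[1:2]) {
  stopifnot(length(species_pair) == 2)
  a <- rai$rai1[rai$species == species_pair[1] & !is.na(rai$rai1)]
  b <- rai$rai1[rai$species == species_pair[2] & !is.na(rai$rai1)]
  if (length(a) < 2 || length(b) < 2) abort("need at least 2 values per species")
  if (var(a) == 0 && var(b) == 0) {
    return(tibble::tibble(statistic = if (mean(a) == mean(b)) 0 else NA_real_,
                          df = NA_real_, p_value = NA_real_,
                          mean_a = mean(a), mean_b = mean(b), degenerate = TRUE))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b),
                 degenerate = FALSE)
}

#' Seasonal one-way ANOVA on monthly activity
#'
#' Tests whether monthly activity (RAI2) varies across seasons for one
#' species, with Tukey HSD all-pairs post-hoc comparisons.
#'
#' @param data Tibble with one observation per month (or other unit).
#' @param value Name of the numeric response column (default `"rai2"`).
#' @param group Name of the season/grouping column (default `"season"`).
#' @return Object of class `seasonal_anova`; see [glance.seasonal_anova()]
#'   for the F-test and [tidy.seasonal_anova()] for the post-hoc table.
#' @export
seasonal_anova <- function(data, value = "rai2", group = "season") {
  d <- tibble::tibble(value = data[[value]], group = as.character(data[[group]]))
  sizes <- table(d$group)
  drop <- names(sizes)[sizes < 2]
  if (length(drop)) {
    warn(paste0("excluding group(s) with < 2 observations: ", paste(drop, collapse = ", ")))
    d <- d[!d$group %in% drop, ]
  }
  if (length(unique(d$group)) < 2) abort("need at least 2 groups with >= 2 observations")
  d$group <- factor(d$group)
  fit <- aov(value ~ group, data = d)
  structure(list(fit = fit, data = d), class = "seasonal_anova")
}

#' @rdname seasonal_anova
#' @param x A `seasonal_anova` object.
#' @param ... Unused.
#' @export
glance.seasonal_anova <- function(x, ...) {
  s <- summary(x$fit)[[1]]
  tibble::tibble(statistic = s[["F value"]][1], df = s[["Df"]][1],
                 df_residual = s[["Df"]][2], p_value = s[["Pr(>F)"]][1])
}

#' @rdname seasonal_anova
#' @export
tidy.seasonal_anova <- function(x, ...) {
  tk <- TukeyHSD(x$fit)$group
  tibble::tibble(contrast = rownames(tk), estimate = tk[, "diff"],
                 conf_low = tk[, "lwr"], conf_high = tk[, "upr"],
                 adj_p_value = tk[, "p adj"])
}

#' @rdname seasonal_anova
#' @export
print.seasonal_anova <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("One-way ANOVA: F = %.3f, df = %d, %d, p = %.4f\n",
              g$statistic, g$df, g$df_residual, g$p_value))
  invisible(x)
}
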