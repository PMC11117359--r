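#' Read camera-trap survey tables
#'
#' Strictly validated readers for the three survey inputs plus the
#' sunrise/sunset calendar. Headers must match exactly; malformed rows are
#' reported with their line numbers and dropped with a warning.
#'
#' * `read_detections()`: `camera_id, species, timestamp` (ISO 8601, minute
#'   precision or finer).
#' * `read_effort()`: `camera_id, date` — one row per active camera-day.
#' * `read_sites()`: `camera_id, season, SC, FC, GC, WA, AL, DP, DR, WT` —
#'   per-season habitat covariates (percent cover for SC/FC/GC; metres for
#'   the distances WA/DP/DR/WT; metres a.s.l. for AL).
#' * `read_calendar()`: `month, sunrise, sunset` with times as `HH:MM`.
#'
#' @param path Path to a CSV file.
#' @param exclude_before Optional `Date`: detections (strictly) before this
#'   date are dropped, e.g. to discard a post-deployment burn-in period.
#' @return A tibble with parsed, validated columns.
#' @export
read_detections <- function(path, exclude_before = NULL) {
  x <- read_strict(path, c("camera_id", "species", "timestamp"))
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")
  ts <- as.POSIXct(rep(NA_character_, nrow(x)), tz = "UTC")
  for (f in fmts) {
    miss <- is.na(ts)
    if (!any(miss)) break
    ts[miss] <- as.POSIXct(strptime(x$timestamp[miss], f, tz = "UTC"))
  }
  bad <- which(is.na(ts))
  if (length(bad)) {
    warn(paste0("dropping ", length(bad), " row(s) with unparseable timestamps (lines ",
                paste(head(bad + 1L, 10), collapse = ", "),
                if (length(bad) > 10) ", ..." else "", ") in ", path))
  }
  out <- tibble::tibble(camera_id = as.character(x$camera_id),
                        species = as.character(x$species),
                        timestamp = ts) |>
    dplyr::filter(!is.na(.data$timestamp))
  if (!is.null(exclude_before)) {
    out <- dplyr::filter(out, as.Date(.data$timestamp) >= as.Date(exclude_before))
  }
  out
}

#' @rdname read_detections
#' @export
read_effort <- function(path) {
  x <- read_strict(path, c("camera_id", "date"))
  d <- as.Date(x$date)
  bad <- which(is.na(d))
  if (length(bad)) {
    warn(paste0("dropping ", length(bad), " row(s) with unparseable dates (lines ",
                paste(head(bad + 1L, 10), collapse = ", "), ") in ", path))
  }
  tibble::tibble(camera_id = as.character(x$camera_id), date = d) |>
    dplyr::filter(!is.na(.data$date)) |>
    dplyr::distinct()
}

#' @rdname read_detections
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (!identical(names(x)[1:2], c("camera_id", "season")) || ncol(x) < 3) {
    abort(paste0("unexpected header in ", path,
                 ": expected camera_id, season, then covariate columns"))
  }
  out <- tibble::as_tibble(x)
  out$camera_id <- as.character(out$camera_id)
  out$season <- as.character(out$season)
  num <- names(out)[-(1:2)]
  out[num] <- lapply(out[num], as.numeric)
  covers <- intersect(c("SC", "FC", "GC"), num)
  if (length(covers) && any(out[covers] < 0 | out[covers] > 100, na.rm = TRUE)) {
    abort("cover percentages (SC, FC, GC) must lie in [0, 100]")
  }
  dists <- intersect(c("WA", "AL", "DP", "DR", "WT"), num)
  if (length(dists) && any(out[dists] < 0, na.rm = TRUE)) {
    abort("distances and altitude must be non-negative")
  }
  out
}

#' @rdname read_detections
#' @export
read_calendar <- function(path) {
  x <- read_strict(path, c("month", "sunrise", "sunset"))
  out <- tibble::tibble(month = as.integer(x$month),
                        sunrise = parse_hm(x$sunrise),
                        sunset = parse_hm(x$sunset))
  if (any(is.na(out$month)) || any(out$month < 1 | out$month > 12)) {
    abort("calendar months must be integers 1-12")
  }
  if (any(is.na(out$sunrise)) || any(is.na(out$sunset))) {
    abort("calendar sunrise/sunset must be HH:MM times")
  }
  if (any(out$sunrise >= out$sunset)) abort("sunrise must precede sunset")
  out
}

# header-validated CSV read
read_strict <- function(path, expected) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (!identical(names(x), expected)) {
    abort(paste0("unexpected header in ", path, ": got [",
                 paste(names(x), collapse = ", "), "], expected [",
                 paste(expected, collapse = ", "), "]"))
  }
  x
}

# "HH:MM" -> fractional hours
parse_hm <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
  vapply(m, function(p) {
    if (length(p) != 3) return(NA_real_)
    as.numeric(p[2]) + as.numeric(p[3]) / 60
  }, numeric(1))
}

#' Filter detections to temporally independent events
#'
#' Applies the standard camera-trap independence rule: within each
#' camera-by-species stream (events in chronological order), an event is
#' retained iff it is the first of its stream or at least `window` minutes
#' after the last *retained* event (sliding anchor). Events exactly `window`
#' minutes apart are both retained. Retained events are annotated with the
#' season, its year tag, and time-of-day in radians.
#'
#' @param detections Tibble with `camera_id`, `species`, `timestamp`
#'   (POSIXct), as returned by [read_detections()].
#' @param window Independence window in minutes (default 30).
#' @param cameras Optional character vector of known camera ids; an unknown
#'   `camera_id` in `detections` is then an error naming the id.
#' @return A tibble of independent detections, chronological within each
#'   camera-species stream, with columns `season`, `year_tag`,
#'   `season_label` and `time_radians` appended.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   camera_id = "C01", species = "oryx",
#'   timestamp = as.POSIXct("2021-01-01 06:00", tz = "UTC") + c(0, 20, 40) * 60
#' )
#' filter_independent(ev)  # minutes 0 and 40 survive
filter_independent <- function(detections, window = 30, cameras = NULL) {
  stopifnot(window > 0)
  if (!inherits(detections$timestamp, "POSIXct")) {
    abort("`detections$timestamp` must be POSIXct; use read_detections()")
  }
  if (!is.null(cameras)) {
    unknown <- setdiff(unique(detections$camera_id), cameras)
    if (length(unknown)) {
      abort(paste0("unknown camera_id: ", paste(unknown, collapse = ", ")))
    }
  }
  out <- detections |>
    dplyr::arrange(.data$camera_id, .data$species, .data$timestamp) |>
    dplyr::group_by(.data$camera_id, .data$species) |>
    dplyr::filter(keep_independent(.data$timestamp, window)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$timestamp, .data$camera_id, .data$species)
  sea <- assign_season(as.Date(out$timestamp))
  out$season <- sea$season
  out$year_tag <- sea$year_tag
  out$season_label <- sea$season_label
  out$time_radians <- time_to_radians(out$timestamp)
  out
}

# single pass over a sorted stream; anchor moves only when an event is kept
keep_independent <- function(ts, window) {
  n <- length(ts)
  keep <- logical(n)
  if (n == 0) return(keep)
  keep[1] <- TRUE
  anchor <- ts[1]
  if (n > 1) {
    for (i in 2:n) {
      if (as.numeric(difftime(ts[i], anchor, units = "mins")) >= window) {
        keep[i] <- TRUE
        anchor <- ts[i]
      }
    }
  }
  keep
}

#' Assign meteorological seasons to dates
#'
#' Seasons follow the meteorological convention: fall = Sep-Nov,
#' winter = Dec-Feb, spring = Mar-May, summer = Jun-Aug. Winter spans two
#' calendar years; its year tag is `"Y-Y+1"` for December and `"Y-1-Y"` for
#' January/February, so that e.g. 2020-12-15 and 2021-02-28 share the label
#' `"winter 2020-2021"`.
#'
#' @param date A `Date` vector (or anything coercible by `as.Date()`).
#' @return Tibble with `season` (factor: winter, spring, summer, fall),
#'   `year_tag` and `season_label`.
#' @export
#' @examples
#' assign_season(as.Date(c("2020-12-15", "2021-03-01")))
assign_season <- function(date) {
  date <- as.Date(date)
  if (any(is.na(date))) abort("invalid date passed to assign_season()")
  m <- as.integer(format(date, "%m"))
  y <- as.integer(format(date, "%Y"))
  season <- dplyr::case_when(
    m %in% c(12, 1, 2) ~ "winter",
    m %in% 3:5 ~ "spring",
    m %in% 6:8 ~ "summer",
    TRUE ~ "fall"
  )
  year_tag <- dplyr::case_when(
    m == 12 ~ paste0(y, "-", y + 1),
    m %in% 1:2 ~ paste0(y - 1, "-", y),
    TRUE ~ as.character(y)
  )
  tibble::tibble(
    season = factor(season, levels = c("winter", "spring", "summer", "fall")),
    year_tag = year_tag,
    season_label = paste(season, year_tag)
  )
}

#' Convert clock time to radians and back
#'
#' Maps time of day linearly onto the circle: midnight is 0, a full day is
#' `2*pi` (so 12:00 is `pi`).
#'
#' @param x A POSIXct vector, or a `"HH:MM"` character vector.
#' @return `time_to_radians()`: numeric angles in `[0, 2*pi)`.
#' @export
#' @examples
#' time_to_radians("18:00")  # 3*pi/2
time_to_radians <- function(x) {
  if (is.character(x)) {
    mins <- parse_hm(x) * 60
    if (any(is.na(mins))) abort("times must be in HH:MM format")
  } else if (inherits(x, "POSIXct")) {
    lt <- as.POSIXlt(x)
    mins <- lt$hour * 60 + lt$min + lt$sec / 60
  } else {
    abort("x must be POSIXct or HH:MM character")
  }
  (2 * pi * mins / 1440) %% (2 * pi)
}

#' @rdname time_to_radians
#' @param theta Angles in radians.
#' @return `radians_to_time()`: `"HH:MM"` strings (rounded to the minute).
#' @export
radians_to_time <- function(theta) {
  mins <- round((theta %% (2 * pi)) * 1440 / (2 * pi)) %% 1440
  sprintf("%02d:%02d", mins %/% 60, mins %% 60)
}

#' Count active camera-days
#'
#' Tallies sampling effort (active camera-days) from an effort table, for
#' one camera or all cameras, optionally restricted to a date range or a
#' season label.
#'
#' @param effort Tibble with `camera_id` and `date` (one row per active
#'   camera-day), as from [read_effort()].
#' @param camera_id Optional camera id; must be present in `effort`.
#' @param start,end Optional inclusive date bounds.
#' @param season_label Optional season label (e.g. `"winter 2020-2021"`)
#'   selecting the dates of that season.
#' @return If `camera_id` is given, a single count; otherwise a tibble
#'   `camera_id, camera_days`.
#' @export
camera_days <- function(effort, camera_id = NULL, start = NULL, end = NULL,
                        season_label = NULL) {
  eff <- effort
  if (!is.null(camera_id)) {
    if (!camera_id %in% effort$camera_id) {
      abort(paste0("camera_id not present in effort table: ", camera_id))
    }
    eff <- dplyr::filter(eff, .data$camera_id == !!camera_id)
  }
  if (!is.null(start)) eff <- dplyr::filter(eff, .data$date >= as.Date(start))
  if (!is.null(end)) eff <- dplyr::filter(eff, .data$date <= as.Date(end))
  if (!is.null(season_label)) {
    lab <- assign_season(eff$date)$season_label
    eff <- eff[lab == season_label, ]
  }
  if (!is.null(camera_id)) return(nrow(eff))
  dplyr::count(eff, .data$camera_id, name = "camera_days")
}
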