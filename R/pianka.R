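#' Pianka niche overlap index
#'
#' Symmetric overlap between two utilization distributions:
#' `O = sum(p*q) / sqrt(sum(p^2) * sum(q^2))` where `p` and `q` are the two
#' vectors rescaled to proportions. The index lies in `[0, 1]` (0 = disjoint
#' niches, 1 = identical) and is invariant to multiplying either vector by a
#' positive scalar, so raw per-site activity indices can be passed directly.
#'
#' @param u,v Non-negative numeric vectors of equal length (>= 2), aligned
#'   over the same sites, each with a positive sum.
#' @param sites_u,sites_v Optional site identifiers used to verify
#'   alignment; a mismatch is an error listing the discrepancy.
#' @return The overlap in `[0, 1]`.
#' @export
#' @examples
#' pianka(c(1, 1), c(1, 0))  # 1/sqrt(2)
pianka <- function(u, v, sites_u = NULL, sites_v = NULL) {
  if (!is.null(sites_u) || !is.null(sites_v)) {
    if (!identical(as.character(sites_u), as.character(sites_v))) {
      only_u <- setdiff(sites_u, sites_v)
      only_v <- setdiff(sites_v, sites_u)
      abort(paste0("site sets are not aligned",
                   if (length(only_u)) paste0("; only in u: ", paste(only_u, collapse = ", ")),
                   if (length(only_v)) paste0("; only in v: ", paste(only_v, collapse = ", "))))
    }
  }
  if (length(u) != length(v)) abort("vectors must have equal length")
  if (length(u) < 2) abort("need at least 2 sites")
  if (any(u < 0) || any(v < 0)) abort("utilization values must be non-negative")
  if (sum(u) <= 0 || sum(v) <= 0) abort("each utilization vector must have a positive sum")
  p <- u / sum(u)
  q <- v / sum(v)
  min(1, max(0, sum(p * q) / sqrt(sum(p^2) * sum(q^2))))
}

#' Seasonal spatial overlap table
#'
#' Computes the Pianka index between two species from their per-site RAI1
#' vectors, one value per period (season), mirroring a seasonal spatial
#' overlap table. Periods in which either species was never detected are
#' omitted with a warning.
#'
#' @param rai Tibble from [rai1()] (columns `camera_id`, `species`,
#'   `period`, `rai1`).
#' @param species_pair The two species to compare (default: first two in
#'   the table).
#' @return Tibble `period, n_sites, pianka` (full precision; round at
#'   report time).
#' @export
pianka_overlap <- function(rai, species_pair = unique(rai$species)[1:2]) {
  stopifnot(length(species_pair) == 2)
  wide <- rai |>
    dplyr::filter(.data$species %in% species_pair, !is.na(.data$rai1)) |>
    dplyr::select("camera_id", "species", "period", "rai1") |>
    tidyr::pivot_wider(names_from = "species", values_from = "rai1")
  purrr::map_dfr(unique(wide$period), function(per) {
    d <- wide[wide$period == per, ]
    u <- d[[species_pair[1]]]
    v <- d[[species_pair[2]]]
    ok <- !is.na(u) & !is.na(v)
    u <- u[ok]; v <- v[ok]
    if (sum(u) <= 0 || sum(v) <= 0) {
      warn(paste0("period '", per, "' lacks detections for one species; omitted"))
      return(NULL)
    }
    tibble::tibble(period = per, n_sites = sum(ok),
                   pianka = pianka(u, v, d$camera_id[ok], d$camera_id[ok]))
  })
}
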