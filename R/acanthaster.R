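#' Crown-of-thorns functional response: attack rate and ingestion rate
#'
#' The sea star's attack rate comes from search geometry: at live coral
#' cover `R` percent, the mean free distance between corals is taken as
#' `(100 - R)/10` m along a 10 m transect; the sea star must search a circle
#' with that distance as diameter, and covers ground at `speed` m per day
#' during `active_hours` hours of active predation. A tiny `epsilon` keeps
#' the distance positive at `R = 100`. Ingestion is a Holling type-II
#' response in the coral resource, `a R / (1 + a h R)`, with handling time
#' `h` days per colony, rescaled by the calibration constant `rescale`
#' (4.53) so that the resource-dependent rate matches the observed average
#' consumption.
#'
#' @param R live coral cover, percent in `[0, 100]`.
#' @param params an [acanthaster_params()].
#' @param a attack rate, from `attack_rate()`.
#' @return `attack_rate()`: attack rate (model units, increasing in `R`);
#'   `ingestion_rate()`: rescaled ingestion rate `RI`.
#' @examples
#' p <- acanthaster_params()
#' a <- attack_rate(90, p)   # ~0.0303
#' ingestion_rate(90, a, p)  # ~1.17
#' @export
attack_rate <- function(R, params = acanthaster_params()) {
  if (any(R < 0 | R > 100)) {
    stop("live coral cover R must be in [0, 100]", call. = FALSE)
  }
  search_area <- (((100 - R + params$epsilon) / 10) / 2)^2 * pi
  params$active_hours / search_area / params$speed
}

#' @rdname attack_rate
#' @export
ingestion_rate <- function(R, a, params = acanthaster_params()) {
  if (any(R < 0) || any(a < 0)) {
    stop("R and attack rate must be non-negative", call. = FALSE)
  }
  (a * R / (1 + a * params$h * R)) * params$rescale
}

#' Per-transect consumption by the observed sea stars
#'
#' The mean count per transect is scaled by the average consumption area
#' `con` (m2 d-1), the mean coral skeletal density (g cm-3), the g cm-2 to
#' kg m-2 conversion (10), and 365 days.
#'
#' @param count total sea stars observed over the site's belts.
#' @param n_transects number of belt transects (>= 1).
#' @param D mean coral skeletal density (g cm-3).
#' @param params an [acanthaster_params()].
#' @return Per-transect consumption `tc` (model units).
#' @examples
#' transect_consumption(12, 6, 1.5)  # A.sp = 2 -> 109.5
#' @export
transect_consumption <- function(count, n_transects, D,
                                 params = acanthaster_params()) {
  if (n_transects < 1) stop("n_transects must be >= 1", call. = FALSE)
  if (any(count < 0)) stop("count must be >= 0", call. = FALSE)
  (count / n_transects) * params$con * D * 10 * 365
}

#' Site-level carbonate reduction by *Acanthaster solaris*
#'
#' Combines the per-transect consumption and the ingestion rate into a
#' per-m2 annual reduction (`tc * RI / belt_area`), then clamps at the
#' site's gross production: sea stars can at most net the gross production
#' to zero, never force it negative. Also reports the observed density per
#' 300 m2 (six 50 m2 belts) and an outbreak flag at the conventional
#' 30 ha-1 density.
#'
#' @param survey a [site_survey()] (supplies the count and belt areas).
#' @param cover a [site_cover()] (supplies `R` and `D`).
#' @param gross site gross production (kg CaCO3 m-2 yr-1).
#' @param params an [acanthaster_params()].
#' @param outbreak_density_ha outbreak threshold (individuals ha-1).
#' @return List of class `"acanthaster_impact"`: `reduction` (clamped),
#'   `raw_reduction`, `density_per_300m2`, `outbreak_flag`.
#' @export
acanthaster_reduction <- function(survey, cover, gross,
                                  params = acanthaster_params(),
                                  outbreak_density_ha = 30) {
  stopifnot(gross >= 0)
  n_tr <- nrow(survey$geometry)
  tc <- transect_consumption(survey$acanthaster_count, n_tr,
                             cover$coral_density, params)
  a <- attack_rate(cover$live_coral_cover, params)
  RI <- ingestion_rate(cover$live_coral_cover, a, params)
  raw <- tc * RI / params$belt_area
  belt_total <- survey$areas$acanthaster
  density_ha <- survey$acanthaster_count / belt_total * 1e4
  structure(list(
    reduction = min(raw, gross),
    raw_reduction = raw,
    density_per_300m2 = survey$acanthaster_count / belt_total * 300,
    outbreak_flag = density_ha > outbreak_density_ha
  ), class = "acanthaster_impact")
}

#' Sea-star density that zeroes a site's gross production
#'
#' The reduction is linear in the sea-star count at fixed coral cover (the
#' ingestion rate depends only on `R`), so the smallest count `N` whose
#' reduction reaches the gross production has a closed form; it is returned
#' as an integer count over the site's belts together with the equivalent
#' count per 100 m2 and that count expressed as a percentage of the
#' live-coral-cover units (`100 * count_per_100m2 / R`), the scale on which
#' a single sustainable-density rule of thumb can be read across sites.
#'
#' @param R live coral cover (percent), > 0.
#' @param gross gross production (kg CaCO3 m-2 yr-1), > 0.
#' @param D mean coral skeletal density (g cm-3), > 0.
#' @param params an [acanthaster_params()].
#' @param n_transects number of belt transects.
#' @return List `threshold_count` (integer, per `n_transects` belts),
#'   `count_per_100m2`, `percent_of_cover`, and the `per_count_reduction`
#'   slope (kg m-2 yr-1 per sea star). Degenerate inputs (no coral or no
#'   production) return a zero threshold with a warning.
#' @examples
#' density_threshold(R = 30, gross = 5, D = 1.4)
#' @export
density_threshold <- function(R, gross, D, params = acanthaster_params(),
                              n_transects = 6) {
  if (R <= 0 || gross <= 0 || D <= 0) {
    warning("degenerate inputs (R, gross or D not positive): threshold 0",
            call. = FALSE)
    return(list(threshold_count = 0L, count_per_100m2 = 0,
                percent_of_cover = 0, per_count_reduction = 0))
  }
  a <- attack_rate(R, params)
  RI <- ingestion_rate(R, a, params)
  # reduction(N) = (N / n_transects) * con * D * 10 * 365 * RI / belt_area
  slope <- params$con * D * 10 * 365 * RI / (params$belt_area * n_transects)
  n <- ceiling(gross / slope)
  belt_total <- n_transects * params$belt_area
  per_100 <- n / belt_total * 100
  list(threshold_count = as.integer(n),
       count_per_100m2 = per_100,
       percent_of_cover = 100 * per_100 / R,
       per_count_reduction = slope)
}
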