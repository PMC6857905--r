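#' Budget configuration: every named constant in the production model
#'
#' All constants of the carbonate-budget equations are surfaced here rather
#' than hard-coded, so sensitivity analyses are a single argument change.
#' Units follow the census-based budget convention: production and erosion in
#' kg CaCO3 m-2 yr-1, lengths in cm, areas in m2.
#'
#' @param sedimentation_rate magnitude of the signed sedimentation term
#'   (kg CaCO3 m-2 yr-1). Added for normal (calcareous) sediment regimes,
#'   subtracted where terrigenous sedimentation smothers corals.
#' @param ca_rate gross production rate of crustose coralline algae at full
#'   cover (g cm-2 yr-1).
#' @param unit_kg conversion factor from g cm-2 to kg m-2 (x10), kept
#'   explicit rather than folded into trait values.
#' @param mec macroboring erosion constant: erosion at full macroborer cover
#'   (kg CaCO3 m-2 yr-1), a conservative literature value.
#' @param reeftime hours per day parrotfish spend grazing on the reef.
#' @param default_brc fallback parrotfish bite-rate constant used (with a
#'   warning) for species without a `brc` entry in the trait table.
#' @param fish_transect_area area of one fish transect (m2; 30 m x 4 m).
#' @param urchin_belt_area area of one urchin belt (m2; 10 m x 0.6 m).
#' @param acanthaster_belt_area area of one *Acanthaster* belt (m2;
#'   10 m x 5 m).
#' @param n_transects transects per site.
#' @param alpha quadratic coefficient converting net production to vertical
#'   accretion (mm yr-1 per (kg m-2 yr-1)^2); see [vertical_accretion()].
#' @param outbreak_density_ha *Acanthaster* density (individuals ha-1) above
#'   which a population is conventionally called an outbreak.
#'
#' @return A named list of class `"budget_config"`.
#' @examples
#' cfg <- budget_config()
#' cfg$sedimentation_rate
#' @export
budget_config <- function(sedimentation_rate = 0.4,
                          ca_rate = 0.018,
                          unit_kg = 10,
                          mec = 10,
                          reeftime = 9,
                          default_brc = 20,
                          fish_transect_area = 120,
                          urchin_belt_area = 6,
                          acanthaster_belt_area = 50,
                          n_transects = 6,
                          alpha = -0.01949,
                          outbreak_density_ha = 30) {
  stopifnot(sedimentation_rate >= 0, ca_rate >= 0, unit_kg > 0, mec >= 0,
            reeftime > 0, fish_transect_area > 0, urchin_belt_area > 0,
            acanthaster_belt_area > 0, n_transects >= 1)
  structure(list(
    sedimentation_rate = sedimentation_rate,
    ca_rate = ca_rate,
    unit_kg = unit_kg,
    mec = mec,
    reeftime = reeftime,
    default_brc = default_brc,
    fish_transect_area = fish_transect_area,
    urchin_belt_area = urchin_belt_area,
    acanthaster_belt_area = acanthaster_belt_area,
    n_transects = n_transects,
    alpha = alpha,
    outbreak_density_ha = outbreak_density_ha
  ), class = "budget_config")
}

#' Parameters of the *Acanthaster solaris* consumption model
#'
#' The sea-star model is a Holling type-II functional response: an attack
#' rate derived from search geometry (mean inter-coral distance sets the
#' search circle, covered at crawling `speed` during `active_hours` per day)
#' and a handling time `h` per coral colony, rescaled to carbonate units.
#'
#' @param con average area of live coral consumed per sea star (m2 d-1).
#' @param h handling time: days one sea star takes to eat one coral colony.
#' @param speed crawling speed (m d-1).
#' @param active_hours hours per day spent actively hunting.
#' @param rescale dimensionless constant matching the resource-dependent
#'   ingestion rate to the observed average consumption rate.
#' @param belt_area area of a single observation belt (m2); converts a
#'   per-belt consumption total to per-m2.
#' @param epsilon small positive guard keeping the attack rate finite at
#'   100 % coral cover (the mean free path goes to zero there).
#'
#' @return Named list of class `"acanthaster_params"`.
#' @examples
#' attack_rate(90, acanthaster_params())
#' @export
acanthaster_params <- function(con = 0.01,
                               h = 3.5,
                               speed = 504,
                               active_hours = 12,
                               rescale = 4.53,
                               belt_area = 50,
                               epsilon = 1e-10) {
  stopifnot(con > 0, h > 0, speed > 0, active_hours > 0, rescale > 0,
            belt_area > 0, epsilon >= 0)
  structure(list(con = con, h = h, speed = speed,
                 active_hours = active_hours, rescale = rescale,
                 belt_area = belt_area, epsilon = epsilon),
            class = "acanthaster_params")
}
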