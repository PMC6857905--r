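#' Vertical reef accretion from net carbonate production
#'
#' Net carbonate production (kg CaCO3 m-2 yr-1) converts to vertical reef
#' growth (mm yr-1) by the quadratic
#' \deqn{accretion = Cp + Cp (Cp \alpha)}
#' with `alpha = -0.01949`. The curve passes through the origin, is concave,
#' and peaks at `Cp = -1/(2 alpha)` (about 25.65 kg m-2 yr-1): beyond that,
#' additional mass goes into densification and lateral infill rather than
#' vertical growth.
#'
#' @param Cp net carbonate production (kg CaCO3 m-2 yr-1).
#' @param alpha quadratic coefficient (default -0.01949).
#' @return Vertical accretion (mm yr-1).
#' @examples
#' round(vertical_accretion(18.5), 1)  # 11.8
#' round(vertical_accretion(16.4), 1)  # 11.2
#' @export
vertical_accretion <- function(Cp, alpha = -0.01949) {
  Cp + Cp * (Cp * alpha)
}

#' Sea-level-rise scenarios
#'
#' Projected year-2100 sea-level-rise rates under the four Representative
#' Concentration Pathways, as conservatively estimated rates of rise.
#'
#' @return `data.frame(name, rise_mm_yr)` with RCP2.6/4.5/6.0/8.5 at
#'   5, 6.5, 6.7 and 9 mm yr-1.
#' @export
sea_level_scenarios <- function() {
  data.frame(name = c("RCP2.6", "RCP4.5", "RCP6.0", "RCP8.5"),
             rise_mm_yr = c(5, 6.5, 6.7, 9))
}

#' Does a reef keep up with a sea-level-rise scenario?
#'
#' `TRUE` when accretion is at least the scenario's rise rate; the boundary
#' (exact equality) counts as keeping up.
#'
#' @param accretion vertical accretion (mm yr-1).
#' @param scenario a scenario name (`"RCP8.5"`), a rise rate in mm yr-1, or
#'   a row of [sea_level_scenarios()].
#' @return Logical.
#' @examples
#' keeps_up(11.8, "RCP8.5")  # TRUE
#' keeps_up(1.3, "RCP2.6")   # FALSE
#' @export
keeps_up <- function(accretion, scenario) {
  rate <- if (is.numeric(scenario)) {
    scenario
  } else if (is.character(scenario)) {
    sc <- sea_level_scenarios()
    i <- match(scenario, sc$name)
    if (anyNA(i)) stop("unknown scenario: ",
                       paste(scenario[is.na(i)], collapse = ", "),
                       call. = FALSE)
    sc$rise_mm_yr[i]
  } else if (is.data.frame(scenario)) {
    scenario$rise_mm_yr
  } else {
    stop("unrecognised scenario", call. = FALSE)
  }
  accretion >= rate
}
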