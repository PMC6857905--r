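#' Parrotfish bite allometry
#'
#' Three per-individual allometric relationships drive parrotfish erosion:
#' bite volume grows exponentially with body length (regression on
#' observational bite data, mm3 converted to cm3); the proportion of bites
#' that actually scar (excavate) the substrate follows a logistic in body
#' length; and the daily bite rate declines linearly with body length from
#' a species-specific intercept (`brc`), clamped at zero because large,
#' slow-biting fish cannot take a negative number of bites.
#'
#' @param length fish fork length (cm), positive.
#' @param brc species bite-rate constant (dimensionless).
#' @param reeftime hours per day spent grazing (default 9).
#' @return `bite_volume`: cm3 per bite; `scar_proportion`: proportion in
#'   (0, 1); `bite_rate`: bites per day (>= 0).
#' @examples
#' bite_volume(30)        # ~0.0227 cm3
#' scar_proportion(40)    # ~0.75
#' bite_rate(30, brc = 20)  # 708 bites/day
#' @export
bite_volume <- function(length) {
  if (any(length <= 0)) stop("fish length must be > 0", call. = FALSE)
  exp(1.32 + 0.06 * length) / 1000
}

#' @rdname bite_volume
#' @export
scar_proportion <- function(length) {
  if (any(length <= 0)) stop("fish length must be > 0", call. = FALSE)
  stats::plogis(-2.46 + 0.089 * length)
}

#' @rdname bite_volume
#' @export
bite_rate <- function(length, brc, reeftime = 9) {
  if (any(length <= 0)) stop("fish length must be > 0", call. = FALSE)
  if (any(is.na(brc))) stop("missing bite-rate constant (brc)", call. = FALSE)
  pmax(0, 60 * ((4.31 + brc - 0.36) - 0.045 * reeftime * length))
}

#' Parrotfish erosion at a site
#'
#' Per fish, the eroded mass is bite volume x scarring proportion x daily
#' bite rate x mean coral skeletal density, accumulated over 365 days and
#' converted g -> kg; the site total is divided by the surveyed fish
#' transect area to give kg CaCO3 m-2 yr-1.
#'
#' @param fish `data.frame(species, length_cm)`, one row per individual.
#' @param D site mean coral skeletal density (g cm-3).
#' @param traits trait table supplying `brc` per species; species without an
#'   entry fall back to `default_brc` with a warning.
#' @param surveyed_area total fish transect area (m2).
#' @param reeftime grazing hours per day.
#' @param default_brc fallback bite-rate constant.
#' @return kg CaCO3 m-2 yr-1.
#' @export
parrotfish_erosion <- function(fish, D, traits, surveyed_area,
                               reeftime = 9, default_brc = 20) {
  stopifnot(surveyed_area > 0, D >= 0)
  if (!nrow(fish)) return(0)
  brc <- lookup_brc(fish$species, traits, default_brc)
  per_fish <- bite_volume(fish$length_cm) *
    scar_proportion(fish$length_cm) *
    bite_rate(fish$length_cm, brc, reeftime)
  sum(per_fish) * D * 365 * 0.001 / surveyed_area
}

# annual eroded mass (kg CaCO3 yr-1) of one urchin individual, by group
urchin_individual_erosion <- function(group, diameter) {
  if (any(diameter <= 0)) stop("urchin diameter must be > 0", call. = FALSE)
  rate <- numeric(length(group))
  di <- group == "Diadema"
  ec <- group == "Echinometra"
  ot <- group == "Other"
  if (!all(di | ec | ot)) {
    stop("unknown urchin group label(s): ",
         paste(setdiff(unique(group), c("Diadema", "Echinometra", "Other")),
               collapse = ", "), call. = FALSE)
  }
  rate[di] <- 0.000001 * diameter[di]^3.42 * 0.365 * 0.57
  rate[ec] <- 0.0004 * diameter[ec]^1.98 * 0.365 * 0.57
  rate[ot] <- 0.0001 * diameter[ot]^2.32 * 0.365 * 0.57
  rate
}

#' Urchin erosion at a site
#'
#' Group-specific allometries convert each test diameter to an annual
#' eroded mass: *Diadema* `1e-6 d^3.42`, *Echinometra* `4e-4 d^1.98`, other
#' urchins `1e-4 d^2.32`, each times `0.365 * 0.57` (day-to-year and
#' reef-carbonate fraction constants from the source allometry). The site
#' sum is divided by the total belt area surveyed.
#'
#' @param urchins `data.frame(group, diameter_cm)`, one row per individual;
#'   `group` in `{Diadema, Echinometra, Other}`.
#' @param surveyed_area total urchin belt area (m2).
#' @return kg CaCO3 m-2 yr-1.
#' @examples
#' urchin_erosion(data.frame(group = "Diadema", diameter_cm = 10),
#'                surveyed_area = 36)
#' @export
urchin_erosion <- function(urchins, surveyed_area) {
  stopifnot(surveyed_area > 0)
  if (!nrow(urchins)) return(0)
  sum(urchin_individual_erosion(urchins$group, urchins$diameter_cm)) /
    surveyed_area
}

#' Macroboring erosion
#'
#' Internal erosion by boring sponges and allied macroborers, linear in
#' their planar cover: full cover erodes at the conservative constant `mec`.
#'
#' @param plamc macroborer planar cover as a proportion in `[0, 1]`.
#' @param mec erosion at full macroborer cover (kg CaCO3 m-2 yr-1).
#' @return kg CaCO3 m-2 yr-1.
#' @examples
#' macroboring_erosion(0.01)  # 0.1
#' @export
macroboring_erosion <- function(plamc, mec = 10) {
  if (any(plamc < 0 | plamc > 1)) {
    stop("plamc must be a proportion in [0, 1]", call. = FALSE)
  }
  plamc * mec
}

#' Assemble the gross erosion components
#'
#' @param parrotfish,urchin,macroboring component rates
#'   (kg CaCO3 m-2 yr-1), each non-negative.
#' @return List of class `"erosion_result"` with the three components and
#'   their `total`.
#' @export
total_erosion <- function(parrotfish, urchin, macroboring) {
  if (any(c(parrotfish, urchin, macroboring) < 0)) {
    stop("erosion components must be non-negative", call. = FALSE)
  }
  structure(list(parrotfish = parrotfish, urchin = urchin,
                 macroboring = macroboring,
                 total = parrotfish + urchin + macroboring),
            class = "erosion_result")
}
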