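#' Configuration for the synthetic survey generator
#'
#' Describes a two-island, habitat-stratified survey campaign with known
#' ground truth: per-habitat mean coral cover and taxon mixtures, rugosity
#' range, urchin and parrotfish densities, per-island *Acanthaster*
#' intensities with designated outbreak sites, and a terrigenous-sediment
#' stratum. Defaults emulate the study design the package targets: 24 sites
#' on each of two islands (one with inner/patch/outer strata, one with
#' inner/outer), six 10 m line-intercept transects per site, 0.6 x 10 m
#' urchin belts, 5 x 10 m sea-star belts and 30 x 4 m fish transects, with
#' coral assemblages dominated by *Porites* inshore and encrusting
#' *Montipora* / tabular *Acropora* on outer reefs, and sea-star outbreak
#' sites (> 30 ha-1) on one island's outer reefs. Distributional forms
#' (Dirichlet mixtures, lognormal fish lengths, Poisson sea-star counts)
#' are documented stand-ins: the real study fixes only the survey geometry.
#'
#' @param seed integer seed; generation is deterministic given the config.
#' @param islands named list: per island, a named integer vector of sites
#'   per habitat.
#' @param habitats named list: per habitat, `mean_coral_cover` and
#'   `sd_coral_cover` (percent), `mixture` (named weights over coral taxa,
#'   summing to 1), `ca_cover` and `macroborer_cover` (percent),
#'   `urchin_density` and `fish_density` (individuals m-2).
#' @param acanthaster list: `base_intensity` (named per island, expected
#'   count per site over the six belts; islands not named fall back to the
#'   mean of the listed intensities), `outbreak` list with `island`,
#'   `habitat`, `n_sites`, `intensity`.
#' @param terrigenous list with `island`, `habitat`, `fraction` of that
#'   stratum's sites flagged `high_terrigenous`.
#' @param rugosity_range range of per-transect rugosity draws.
#' @param n_transects,transect_cm survey geometry.
#' @param dirichlet_conc concentration of the per-site Dirichlet around the
#'   habitat mixture (larger = less site-to-site compositional noise).
#' @return List of class `"synthetic_config"`.
#' @export
synthetic_config <- function(
    seed = 1,
    islands = list(
      Pohnpei = c(inner = 8, patch = 8, outer = 8),
      Kosrae = c(inner = 12, outer = 12)
    ),
    habitats = list(
      inner = list(
        mean_coral_cover = 30, sd_coral_cover = 8,
        mixture = c(Porites_rus = 0.32, Porites_cylindrica = 0.18,
                    Porites_lobata = 0.22, Porites_massive = 0.08,
                    Montipora_encrusting = 0.08,
                    Goniastrea_retiformis = 0.07, Porites_lichen = 0.05),
        ca_cover = 3, macroborer_cover = 0.4,
        urchin_density = 0.02, fish_density = 0.008
      ),
      patch = list(
        mean_coral_cover = 35, sd_coral_cover = 7,
        mixture = c(Porites_rus = 0.30, Porites_cylindrica = 0.25,
                    Porites_lobata = 0.20, Montipora_encrusting = 0.10,
                    Acropora_hyacinthus = 0.08,
                    Goniastrea_retiformis = 0.07),
        ca_cover = 4, macroborer_cover = 0.3,
        urchin_density = 0.02, fish_density = 0.010
      ),
      outer = list(
        mean_coral_cover = 28, sd_coral_cover = 10,
        mixture = c(Montipora_encrusting = 0.30,
                    Acropora_hyacinthus = 0.18, Porites_rus = 0.15,
                    Porites_lobata = 0.15, Goniastrea_retiformis = 0.12,
                    Porites_lichen = 0.10),
        ca_cover = 6, macroborer_cover = 0.5,
        urchin_density = 0.10, fish_density = 0.015
      )
    ),
    acanthaster = list(
      base_intensity = c(Pohnpei = 0.4, Kosrae = 2.5),
      outbreak = list(island = "Kosrae", habitat = "outer",
                      n_sites = 2, intensity = 15)
    ),
    terrigenous = list(island = "Kosrae", habitat = "inner",
                       fraction = 0.15),
    rugosity_range = c(1.2, 2.0),
    n_transects = 6,
    transect_cm = 1000,
    dirichlet_conc = 60) {
  cfg <- structure(as.list(environment()), class = "synthetic_config")
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  stopifnot(length(cfg$islands) >= 1, cfg$n_transects >= 1,
            cfg$transect_cm >= 100, cfg$dirichlet_conc > 0,
            length(cfg$rugosity_range) == 2,
            cfg$rugosity_range[1] >= 1,
            diff(cfg$rugosity_range) >= 0)
  for (isl in names(cfg$islands)) {
    if (any(cfg$islands[[isl]] < 1)) {
      stop("site counts must be >= 1 (island ", isl, ")", call. = FALSE)
    }
    miss <- setdiff(names(cfg$islands[[isl]]), names(cfg$habitats))
    if (length(miss)) {
      stop("no habitat parameters for: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  for (h in names(cfg$habitats)) {
    hp <- cfg$habitats[[h]]
    if (abs(sum(hp$mixture) - 1) > 1e-8) {
      stop("taxon mixture weights for habitat '", h, "' must sum to 1",
           call. = FALSE)
    }
    stopifnot(hp$mean_coral_cover > 0, hp$sd_coral_cover > 0,
              hp$ca_cover >= 0, hp$macroborer_cover >= 0,
              hp$urchin_density >= 0, hp$fish_density >= 0)
  }
  invisible(cfg)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic survey campaign with ground truth
#'
#' Draws a full multi-site survey from a [synthetic_config()]. Per site:
#' total coral cover from a truncated normal around the habitat mean, a
#' Dirichlet draw of the taxon mixture, multinomial allocation of every
#' transect's centimetres to taxa (so segments sum exactly to the tape
#' length), per-transect rugosity, Poisson urchin and fish counts with
#' group/species-specific size distributions, a Poisson sea-star count, and
#' the configured terrigenous flags. The ground-truth table carries the
#' generating covers and the analytically expected gross production, so
#' pipeline estimates can be checked for recovery.
#'
#' @param config a [synthetic_config()].
#' @param traits trait table used for the expected-production calculation
#'   (defaults to [default_traits()]).
#' @param budget_cfg a [budget_config()] for areas and rates.
#' @return List with `surveys` (named list of [site_survey()]) and `truth`
#'   (`data.frame` of per-site generating values incl. `expected_gross`).
#' @examples
#' \donttest{
#' gs <- generate_survey(synthetic_config(seed = 7))
#' length(gs$surveys)  # 48
#' }
#' @export
generate_survey <- function(config = synthetic_config(),
                            traits = default_traits(),
                            budget_cfg = budget_config()) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  fish_species <- traits$taxon[!is.na(traits$brc)]
  surveys <- list()
  truth <- list()

  for (isl in names(config$islands)) {
    strata <- config$islands[[isl]]
    for (hab in names(strata)) {
      n_sites <- strata[[hab]]
      hp <- config$habitats[[hab]]
      terr_here <- identical(config$terrigenous$island, isl) &&
        identical(config$terrigenous$habitat, hab)
      n_terr <- if (terr_here) round(config$terrigenous$fraction * n_sites) else 0
      ob <- config$acanthaster$outbreak
      ob_here <- identical(ob$island, isl) && identical(ob$habitat, hab)
      n_ob <- if (ob_here) min(ob$n_sites, n_sites) else 0

      for (k in seq_len(n_sites)) {
        id <- sprintf("%s_%s_%02d", isl, hab, k)
        C <- min(70, max(5, stats::rnorm(1, hp$mean_coral_cover,
                                         hp$sd_coral_cover)))
        w <- rdirichlet1(config$dirichlet_conc * hp$mixture)
        names(w) <- names(hp$mixture)
        taxon_cover <- C * w
        other <- 100 - C - hp$ca_cover - hp$macroborer_cover
        if (other < 0) stop("covers exceed 100%: lower ca/macroborer cover",
                            call. = FALSE)
        probs <- c(taxon_cover,
                   coralline_algae = hp$ca_cover,
                   macroborer = hp$macroborer_cover,
                   sand = 0.6 * other, turf_algae = 0.4 * other) / 100

        benthic <- NULL
        geometry <- NULL
        for (t in seq_len(config$n_transects)) {
          counts <- stats::rmultinom(1, config$transect_cm, probs)[, 1]
          keep <- counts > 0
          benthic <- rbind(benthic, data.frame(
            transect_no = t, taxon = names(probs)[keep],
            intercept_cm = unname(counts[keep])))
          r_t <- stats::runif(1, config$rugosity_range[1],
                              config$rugosity_range[2])
          geometry <- rbind(geometry, data.frame(
            transect_no = t, contour_cm = config$transect_cm,
            planar_cm = max(1, round(config$transect_cm / r_t))))
        }
        rownames(benthic) <- NULL

        u_area <- config$n_transects * budget_cfg$urchin_belt_area
        n_u <- stats::rpois(1, hp$urchin_density * u_area)
        urchins <- if (n_u > 0) {
          grp <- sample(c("Echinometra", "Diadema", "Other"), n_u,
                        replace = TRUE, prob = c(0.6, 0.15, 0.25))
          mu_d <- c(Echinometra = 4, Diadema = 6, Other = 5)[grp]
          data.frame(group = grp,
                     diameter_cm = pmax(0.5, round(
                       stats::rgamma(n_u, shape = 8, rate = 8 / mu_d) * 2) / 2))
        } else empty_urchins()

        f_area <- config$n_transects * budget_cfg$fish_transect_area
        n_f <- stats::rpois(1, hp$fish_density * f_area)
        fish <- if (n_f > 0) {
          data.frame(species = sample(fish_species, n_f, replace = TRUE),
                     length_cm = pmax(5, round(
                       stats::rlnorm(n_f, log(22), 0.3))))
        } else empty_fish()

        bi <- config$acanthaster$base_intensity
        intensity <- if (k <= n_ob) ob$intensity else
          if (isl %in% names(bi)) bi[[isl]] else mean(bi)
        a_count <- stats::rpois(1, intensity)
        regime <- if (k > n_ob && k <= n_ob + n_terr) "high_terrigenous"
                  else "normal"

        sv <- site_survey(id, isl, hab, benthic, geometry, urchins, fish,
                          acanthaster_count = a_count,
                          sediment_regime = regime, config = budget_cfg)
        surveys[[id]] <- sv

        r_mean <- mean(geometry$contour_cm / geometry$planar_cm)
        i <- match(names(taxon_cover), traits$taxon)
        exp_coral <- r_mean * sum(traits$morphology_m[i] *
                                    (taxon_cover / 100) *
                                    traits$density_d[i] *
                                    traits$growth_g[i] * budget_cfg$unit_kg)
        exp_ca <- r_mean * budget_cfg$ca_rate * (hp$ca_cover / 100) *
          budget_cfg$unit_kg
        truth[[id]] <- data.frame(
          site_id = id, island = isl, habitat = hab,
          true_coral_cover = C, true_rugosity = r_mean,
          acanthaster_intensity = intensity,
          sediment_regime = regime,
          expected_gross = exp_coral + exp_ca)
      }
    }
  }
  list(surveys = surveys, truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Generate a site-level dataset with known cover thresholds
#'
#' Produces net-production data whose population curves are linear in coral
#' cover with habitat-specific zero crossings:
#' `net = slope * (cover - crossing[habitat]) + site_effect + noise`.
#' Because the habitat curves are parallel, habitat differences are pure
#' vertical offsets -- exactly the structure the threshold model estimates
#' -- and the generating crossing is the true live-coral-cover threshold.
#'
#' @param n_sites named integer vector: sites per habitat.
#' @param crossings named numeric vector: true zero-crossing cover
#'   (percent) per habitat; must lie in (0, 100).
#' @param slope production gain per percent cover (kg CaCO3 m-2 yr-1).
#' @param site_sd standard deviation of the per-site random intercept.
#' @param noise_sd residual standard deviation.
#' @param cover_range range of observed covers (uniform draws).
#' @param seed integer seed.
#' @return List with `data` (`net`, `cover`, `habitat`, `site`) and `truth`
#'   (`crossings`, `slope`, `site_sd`, `noise_sd`).
#' @examples
#' d <- generate_threshold_dataset(seed = 3)
#' head(d$data)
#' @export
generate_threshold_dataset <- function(
    n_sites = c(inner = 16, patch = 16, outer = 16),
    crossings = c(inner = 12, patch = 10, outer = 7),
    slope = 0.2,
    site_sd = 0.5,
    noise_sd = 0.7,
    cover_range = c(2, 60),
    seed = 1) {
  stopifnot(length(n_sites) >= 2, all(n_sites >= 2), slope > 0,
            site_sd >= 0, noise_sd >= 0)
  if (!all(names(n_sites) %in% names(crossings))) {
    stop("crossings must be supplied for every habitat", call. = FALSE)
  }
  if (any(crossings <= 0 | crossings >= 100)) {
    stop("configured curves must cross zero inside (0, 100)% cover",
         call. = FALSE)
  }
  set.seed(seed)
  rows <- lapply(names(n_sites), function(hab) {
    n <- n_sites[[hab]]
    cover <- stats::runif(n, cover_range[1], cover_range[2])
    b <- stats::rnorm(n, 0, site_sd)
    data.frame(
      net = slope * (cover - crossings[[hab]]) + b +
        stats::rnorm(n, 0, noise_sd),
      cover = cover,
      habitat = hab,
      site = sprintf("%s_%02d", hab, seq_len(n))
    )
  })
  list(data = do.call(rbind, c(rows, make.row.names = FALSE)),
       truth = list(crossings = crossings[names(n_sites)], slope = slope,
                    site_sd = site_sd, noise_sd = noise_sd))
}
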