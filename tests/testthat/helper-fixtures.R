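# Programmatic fixtures: tiny trait tables and surveys built in code.

toy_traits <- function() {
  structure(data.frame(
    taxon = c("coral_A", "coral_B", "parrot_X", "parrot_Y"),
    morphology_m = c(1.0, 0.8, NA, NA),
    density_d = c(1.2, 1.8, NA, NA),
    growth_g = c(1.0, 2.0, NA, NA),
    brc = c(NA, NA, 20, 12)
  ), class = c("reef_traits", "data.frame"))
}

# one site: each transect `contour` cm with the given taxon intercepts
# (named vector, padded with sand), identical across n transects
uniform_survey <- function(intercepts, contour = 1000, planar = 1000,
                           n_transects = 6, site_id = "T1",
                           island = "TestIsl", habitat = "outer",
                           regime = "normal", ...) {
  pad <- contour - sum(intercepts)
  stopifnot(pad >= 0)
  taxa <- c(names(intercepts), if (pad > 0) "sand")
  lens <- c(unname(intercepts), if (pad > 0) pad)
  taxa <- taxa[lens > 0]
  lens <- lens[lens > 0]
  benthic <- do.call(rbind, lapply(seq_len(n_transects), function(t) {
    data.frame(transect_no = t, taxon = taxa, intercept_cm = lens)
  }))
  geometry <- data.frame(transect_no = seq_len(n_transects),
                         contour_cm = contour, planar_cm = planar)
  site_survey(site_id, island, habitat, benthic, geometry,
              sediment_regime = regime, ...)
}

# random survey over the toy trait taxa, for property-style loops
random_survey <- function(seed, site_id = paste0("R", seed)) {
  set.seed(seed)
  contour <- 1000
  planar <- sample(600:1000, 1)
  n_cor <- sample(50:300, 2)
  other <- sample(c(0, 5, 20), 2, replace = TRUE)
  parts <- c(coral_A = n_cor[1], coral_B = n_cor[2],
             coralline_algae = other[1], macroborer = other[2])
  n_u <- sample(0:12, 1)
  urch <- if (n_u > 0) {
    data.frame(group = sample(c("Diadema", "Echinometra", "Other"), n_u,
                              replace = TRUE),
               diameter_cm = round(runif(n_u, 1, 12) * 2) / 2)
  } else data.frame(group = character(), diameter_cm = numeric())
  n_f <- sample(0:10, 1)
  fsh <- if (n_f > 0) {
    data.frame(species = sample(c("parrot_X", "parrot_Y"), n_f,
                                replace = TRUE),
               length_cm = sample(8:45, n_f, replace = TRUE))
  } else data.frame(species = character(), length_cm = numeric())
  uniform_survey(parts, contour = contour, planar = planar,
                 site_id = site_id,
                 regime = sample(c("normal", "high_terrigenous"), 1),
                 urchins = urch, fish = fsh,
                 acanthaster_count = sample(0:18, 1))
}

small_sim_config <- function(seed = 1) {
  synthetic_config(
    seed = seed,
    islands = list(IslA = c(inner = 3, outer = 3),
                   IslB = c(inner = 2, outer = 2))
  )
}
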