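#' Species trait tables
#'
#' Carbonate production per coral taxon needs three constants: a morphology
#' adjustment `morphology_m` (how much of the planar cover actually deposits
#' carbonate, relative to a solid massive colony), skeletal bulk density
#' `density_d` (g cm-3) and vertical extension rate `growth_g` (cm yr-1).
#' Parrotfish erosion needs a per-species bite-rate constant `brc`.
#' One long table carries both: coral rows leave `brc` as `NA`, fish rows
#' leave the coral columns as `NA`.
#'
#' `default_traits()` loads the trait table shipped with the package
#' (`inst/extdata/traits.csv`); its values are documented, editable
#' stand-ins at literature scale, not field calibrations.
#'
#' @param path path to a trait CSV with columns
#'   `taxon, morphology_m, density_d, growth_g, brc` (`#` comments allowed).
#' @return A `data.frame` of class `"reef_traits"`.
#' @examples
#' tr <- default_traits()
#' coral_taxa(tr)
#' @export
default_traits <- function() {
  read_traits(system.file("extdata", "traits.csv", package = "reefbudget",
                          mustWork = TRUE))
}

#' @rdname default_traits
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) {
    stop("trait file not found: ", path, call. = FALSE)
  }
  tr <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("taxon", "morphology_m", "density_d", "growth_g", "brc")
  missing <- setdiff(required, names(tr))
  if (length(missing)) {
    stop("trait table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in required[-1]) tr[[col]] <- as.numeric(tr[[col]])
  if (anyDuplicated(tr$taxon)) {
    stop("duplicated taxon in trait table: ",
         paste(unique(tr$taxon[duplicated(tr$taxon)]), collapse = ", "),
         call. = FALSE)
  }
  is_coral <- !is.na(tr$density_d)
  bad <- is_coral & (tr$density_d <= 0 | tr$growth_g < 0 |
                       is.na(tr$morphology_m) | tr$morphology_m <= 0 |
                       is.na(tr$growth_g))
  if (any(bad)) {
    stop("invalid coral trait values (need morphology_m > 0, density_d > 0, ",
         "growth_g >= 0) for: ", paste(tr$taxon[bad], collapse = ", "),
         call. = FALSE)
  }
  class(tr) <- c("reef_traits", "data.frame")
  tr
}

#' @rdname default_traits
#' @param traits a `reef_traits` table.
#' @export
coral_taxa <- function(traits) {
  traits$taxon[!is.na(traits$density_d)]
}

#' Benthic labels that are valid without a trait entry
#'
#' Line-intercept records of substrate that neither calcifies through the
#' coral model nor erodes through the fish model: abiotic cover, fleshy
#' algae, and the two functional labels used directly by the budget
#' (`coralline_algae`, `macroborer`).
#'
#' @return Character vector of reserved labels.
#' @export
noncoral_labels <- function() {
  c("coralline_algae", "macroborer",
    "sand", "rubble", "pavement", "turf_algae", "macroalgae",
    "soft_coral", "sponge", "other")
}

# brc lookup with the documented default for unknown species; one warning
# listing all species that fell back.
lookup_brc <- function(species, traits, default_brc) {
  brc <- traits$brc[match(species, traits$taxon)]
  fallback <- is.na(brc)
  if (any(fallback)) {
    warning("no bite-rate constant (brc) for species ",
            paste(sort(unique(species[fallback])), collapse = ", "),
            "; using default brc = ", default_brc, call. = FALSE)
    brc[fallback] <- default_brc
  }
  brc
}
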