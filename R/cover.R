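#' Site-level cover, rugosity and mean coral density from raw transects
#'
#' Per-taxon planar percent cover is the taxon's share of each survey tape,
#' averaged over transects. Intercepts are recorded along the
#' substrate-following tape, so a taxon's planar projection is
#' `intercept / rugosity` and its share of the planar length equals
#' `intercept / contour`; covers therefore sum to 100 within a transect and
#' the rugosity multiplier is applied once, in the production equation,
#' never per segment.
#'
#' Mean coral skeletal density `D` is the cover-weighted mean of the trait
#' densities over live coral taxa (0 when there is no live coral).
#' Coralline-algae and macroborer covers are returned as proportions (0-1)
#' because their production/erosion rates are defined at full cover.
#'
#' @param survey a [site_survey()].
#' @param traits a trait table from [default_traits()] or [read_traits()];
#'   must resolve every coral taxon observed.
#' @param other_labels benthic labels accepted without a trait entry
#'   (default [noncoral_labels()]).
#'
#' @return Object of class `"site_cover"`: list with `cover` (named percent
#'   vector over all observed taxa), `live_coral_cover` (percent), `pca`,
#'   `plamc` (proportions), `rugosity`, `coral_density` (g cm-3), and the
#'   site's metadata.
#' @examples
#' sv <- site_survey("S1", "Pohnpei", "outer",
#'   benthic  = data.frame(transect_no = 1,
#'                         taxon = c("Porites_lobata", "sand"),
#'                         intercept_cm = c(200, 800)),
#'   geometry = data.frame(transect_no = 1, contour_cm = 1000,
#'                         planar_cm = 800))
#' site_cover(sv, default_traits())
#' @export
site_cover <- function(survey, traits, other_labels = noncoral_labels()) {
  stopifnot(inherits(survey, "site_survey"))
  b <- survey$benthic
  g <- survey$geometry

  corals <- coral_taxa(traits)
  known <- c(corals, other_labels)
  unmatched <- setdiff(unique(b$taxon), known)
  if (length(unmatched)) {
    stop("site ", survey$site_id, ": taxa absent from the trait table ",
         "(and not recognised abiotic/other labels): ",
         paste(sort(unmatched), collapse = ", "), call. = FALSE)
  }

  taxa <- sort(unique(b$taxon))
  n_tr <- nrow(g)
  # percent of each transect tape occupied by each taxon, then transect mean
  per_transect <- vapply(seq_len(n_tr), function(i) {
    tn <- g$transect_no[i]
    rows <- b$transect_no == tn
    tot <- tapply(b$intercept_cm[rows], factor(b$taxon[rows], levels = taxa),
                  sum, default = 0)
    100 * tot / g$contour_cm[i]
  }, numeric(length(taxa)))
  if (length(taxa) == 1L) per_transect <- matrix(per_transect, nrow = 1)
  cover <- rowMeans(per_transect)
  names(cover) <- taxa

  rugosity <- mean(g$contour_cm / g$planar_cm)
  coral_cover <- cover[names(cover) %in% corals]
  R <- sum(coral_cover)
  D <- if (R > 0) {
    d <- traits$density_d[match(names(coral_cover), traits$taxon)]
    sum(coral_cover * d) / R
  } else 0

  structure(list(
    site_id = survey$site_id,
    island = survey$island,
    habitat = survey$habitat,
    sediment_regime = survey$sediment_regime,
    cover = cover,
    live_coral_cover = unname(R),
    pca = unname(cover["coralline_algae"] %|na|% 0) / 100,
    plamc = unname(cover["macroborer"] %|na|% 0) / 100,
    rugosity = rugosity,
    coral_density = D
  ), class = "site_cover")
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' @export
print.site_cover <- function(x, ...) {
  cat("<site_cover> ", x$site_id, ": live coral ",
      round(x$live_coral_cover, 1), "%, rugosity ", round(x$rugosity, 2),
      ", mean density ", round(x$coral_density, 2), " g/cm3\n", sep = "")
  invisible(x)
}
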