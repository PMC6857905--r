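#' Gross carbonate production by corals
#'
#' Each coral taxon deposits carbonate at `m * (x/100) * d * g * 10`
#' kg CaCO3 m-2 yr-1, where `m` is the morphology adjustment, `x` the
#' planar percent cover, `d` the skeletal density (g cm-3) and `g` the
#' vertical extension rate (cm yr-1); the factor 10 converts g cm-2 yr-1 to
#' kg m-2 yr-1. The site sum is scaled by rugosity `r`, converting planar
#' cover to the true accreting surface.
#'
#' @param cover a [site_cover()].
#' @param traits trait table resolving every coral taxon in `cover`.
#' @param unit_kg the g cm-2 to kg m-2 conversion (kept explicit; default 10).
#'
#' @return List of class `"calcification_result"` with `gross_coral`
#'   (kg CaCO3 m-2 yr-1) and `per_taxon` (named vector summing to
#'   `gross_coral`), both rugosity-scaled.
#' @examples
#' sv <- site_survey("S1", "Pohnpei", "outer",
#'   benthic  = data.frame(transect_no = 1,
#'                         taxon = c("Porites_lobata", "sand"),
#'                         intercept_cm = c(200, 800)),
#'   geometry = data.frame(transect_no = 1, contour_cm = 1000,
#'                         planar_cm = 800))
#' coral_calcification(site_cover(sv, default_traits()), default_traits())
#' @export
coral_calcification <- function(cover, traits, unit_kg = 10) {
  stopifnot(inherits(cover, "site_cover"))
  corals <- intersect(names(cover$cover), coral_taxa(traits))
  if (!length(corals)) {
    return(structure(list(gross_coral = 0, per_taxon = numeric(0)),
                     class = "calcification_result"))
  }
  i <- match(corals, traits$taxon)
  x <- cover$cover[corals]
  per_taxon <- cover$rugosity * traits$morphology_m[i] * (x / 100) *
    traits$density_d[i] * traits$growth_g[i] * unit_kg
  structure(list(gross_coral = sum(per_taxon), per_taxon = per_taxon),
            class = "calcification_result")
}

#' Gross carbonate production by crustose coralline algae
#'
#' Coralline algae calcify at `ca_rate` g cm-2 yr-1 when covering the whole
#' substrate; production scales linearly with the cover proportion and the
#' factor `unit_kg` (10) converts to kg m-2 yr-1, so full cover yields
#' 0.18 kg CaCO3 m-2 yr-1 at the default rate. The caller ([site_budget()])
#' applies the rugosity multiplier along with the coral term.
#'
#' @param pca coralline-algae planar cover as a proportion in `[0, 1]`.
#' @param ca_rate production rate at full cover (g cm-2 yr-1).
#' @param unit_kg unit conversion to kg m-2 (default 10).
#' @return kg CaCO3 m-2 yr-1.
#' @examples
#' coralline_algae_production(0.10)  # 0.018
#' @export
coralline_algae_production <- function(pca, ca_rate = 0.018, unit_kg = 10) {
  if (any(pca < 0 | pca > 1)) {
    stop("pca must be a proportion in [0, 1], got ", pca[which.max(pca < 0 | pca > 1)],
         call. = FALSE)
  }
  ca_rate * pca * unit_kg
}

#' Signed sedimentation term
#'
#' Calcareous sediment supplements reef accretion at a background rate;
#' where terrigenous runoff deposits fine sediment it smothers corals and
#' the same magnitude enters the budget with a negative sign.
#'
#' @param regime `"normal"` or `"high_terrigenous"`.
#' @param rate magnitude (kg CaCO3 m-2 yr-1), default 0.4.
#' @return Signed kg CaCO3 m-2 yr-1 (`+rate` or `-rate`).
#' @examples
#' sedimentation_term("normal")            # +0.4
#' sedimentation_term("high_terrigenous")  # -0.4
#' @export
sedimentation_term <- function(regime, rate = 0.4) {
  switch(regime,
         normal = rate,
         high_terrigenous = -rate,
         stop("unknown sediment regime '", regime, "'", call. = FALSE))
}
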