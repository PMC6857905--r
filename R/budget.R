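#' Per-site carbonate budget
#'
#' Composes the full census-based budget for one site:
#' \deqn{net = gross + sgn(sediment) \cdot sedimentation - erosion}
#' with gross production `r * (sum_j m_j x_j/100 d_j g_j 10 + ca)` (corals
#' plus rugosity-scaled coralline algae), erosion the sum of parrotfish,
#' urchin and macroboring terms, and the *Acanthaster* reduction reported
#' both separately and folded into `net_with_acanthaster` (clamped so sea
#' stars can at most zero the gross production). Net production is converted
#' to vertical accretion via [vertical_accretion()].
#'
#' @param survey a [site_survey()].
#' @param traits a trait table ([default_traits()]).
#' @param config a [budget_config()].
#' @param acanthaster an [acanthaster_params()].
#' @param accretion_basis which net to convert to accretion:
#'   `"with_acanthaster"` (default) or `"without_acanthaster"`.
#' @return Object of class `"carbonate_budget"`: site metadata plus
#'   `gross` (coral + CA), `gross_coral`, `ca`, `per_taxon`,
#'   `sedimentation` (signed), `erosion` (an `erosion_result`),
#'   `acanthaster` (an `acanthaster_impact`), `net`,
#'   `net_with_acanthaster`, `accretion` (mm yr-1) and the `cover` used.
#' @examples
#' sv <- site_survey("S1", "Pohnpei", "outer",
#'   benthic  = data.frame(transect_no = 1,
#'                         taxon = c("Porites_lobata", "sand"),
#'                         intercept_cm = c(300, 700)),
#'   geometry = data.frame(transect_no = 1, contour_cm = 1000,
#'                         planar_cm = 800))
#' site_budget(sv, default_traits())
#' @export
site_budget <- function(survey, traits,
                        config = budget_config(),
                        acanthaster = acanthaster_params(),
                        accretion_basis = c("with_acanthaster",
                                            "without_acanthaster")) {
  accretion_basis <- match.arg(accretion_basis)
  cov <- site_cover(survey, traits)

  calc <- coral_calcification(cov, traits, unit_kg = config$unit_kg)
  ca <- cov$rugosity *
    coralline_algae_production(cov$pca, ca_rate = config$ca_rate,
                               unit_kg = config$unit_kg)
  gross <- calc$gross_coral + ca

  sed <- sedimentation_term(survey$sediment_regime,
                            rate = config$sedimentation_rate)

  ero <- total_erosion(
    parrotfish = parrotfish_erosion(survey$fish, cov$coral_density, traits,
                                    surveyed_area = survey$areas$fish,
                                    reeftime = config$reeftime,
                                    default_brc = config$default_brc),
    urchin = urchin_erosion(survey$urchins,
                            surveyed_area = survey$areas$urchin),
    macroboring = macroboring_erosion(cov$plamc, mec = config$mec)
  )

  acr <- acanthaster_reduction(survey, cov, gross, params = acanthaster,
                               outbreak_density_ha = config$outbreak_density_ha)

  net <- gross + sed - ero$total
  net_wa <- net - acr$reduction
  accr_net <- if (accretion_basis == "with_acanthaster") net_wa else net

  structure(list(
    site_id = survey$site_id,
    island = survey$island,
    habitat = survey$habitat,
    sediment_regime = survey$sediment_regime,
    gross = gross,
    gross_coral = calc$gross_coral,
    ca = ca,
    per_taxon = calc$per_taxon,
    sedimentation = sed,
    erosion = ero,
    acanthaster = acr,
    net = net,
    net_with_acanthaster = net_wa,
    accretion = vertical_accretion(accr_net, alpha = config$alpha),
    cover = cov
  ), class = "carbonate_budget")
}

#' @export
print.carbonate_budget <- function(x, ...) {
  cat("<carbonate_budget> ", x$site_id, " (", x$island, ", ", x$habitat,
      ")\n", sep = "")
  cat(sprintf("  gross %.2f | sed %+.2f | erosion %.3f | COTS %.3f\n",
              x$gross, x$sedimentation, x$erosion$total,
              x$acanthaster$reduction))
  cat(sprintf("  net %.2f (with COTS %.2f) kg CaCO3/m2/yr; accretion %.2f mm/yr\n",
              x$net, x$net_with_acanthaster, x$accretion))
  invisible(x)
}

#' Flatten budgets to a per-site table
#'
#' @param budgets list of `carbonate_budget` objects.
#' @return `data.frame`, one row per site, with the budget components,
#'   live coral cover, rugosity and *Acanthaster* diagnostics.
#' @export
budget_table <- function(budgets) {
  do.call(rbind, lapply(budgets, function(b) {
    data.frame(
      site_id = b$site_id, island = b$island, habitat = b$habitat,
      sediment_regime = b$sediment_regime,
      live_coral_cover = b$cover$live_coral_cover,
      rugosity = b$cover$rugosity,
      coral_density = b$cover$coral_density,
      gross = b$gross, ca = b$ca,
      sedimentation = b$sedimentation,
      erosion_parrotfish = b$erosion$parrotfish,
      erosion_urchin = b$erosion$urchin,
      erosion_macroboring = b$erosion$macroboring,
      erosion_total = b$erosion$total,
      acanthaster_reduction = b$acanthaster$reduction,
      acanthaster_density_300m2 = b$acanthaster$density_per_300m2,
      outbreak = b$acanthaster$outbreak_flag,
      net = b$net,
      net_with_acanthaster = b$net_with_acanthaster,
      accretion = b$accretion,
      row.names = NULL
    )
  }))
}

#' Habitat summary table (means and standard deviations)
#'
#' Summarises budgets by island x habitat, per-island combined rows, and
#' both-islands rows for habitats shared across islands. `erosion` here is
#' the parrotfish + urchin component (the mobile grazers), reported
#' separately from the *Acanthaster* column; `net` is gross + sedimentation
#' minus all erosion (excluding *Acanthaster*).
#'
#' @param budgets list of `carbonate_budget` objects.
#' @return `data.frame` with group label, `n`, and `mean`/`sd` columns for
#'   gross, erosion, net and *Acanthaster* reduction. Groups of a single
#'   site report `sd = 0` and are flagged by `n = 1`.
#' @export
habitat_summary <- function(budgets) {
  tb <- budget_table(budgets)
  tb$erosion_grazers <- tb$erosion_parrotfish + tb$erosion_urchin

  one <- function(rows, label) {
    if (!nrow(rows)) return(NULL)
    s <- function(v) if (nrow(rows) > 1) stats::sd(v) else 0
    data.frame(group = label, n = nrow(rows),
               gross_mean = mean(rows$gross), gross_sd = s(rows$gross),
               erosion_mean = mean(rows$erosion_grazers),
               erosion_sd = s(rows$erosion_grazers),
               net_mean = mean(rows$net), net_sd = s(rows$net),
               acanthaster_mean = mean(rows$acanthaster_reduction),
               acanthaster_sd = s(rows$acanthaster_reduction))
  }

  out <- list()
  for (isl in unique(tb$island)) {
    sub <- tb[tb$island == isl, ]
    out[[length(out) + 1]] <- one(sub, paste(isl, "(combined)"))
    for (hab in intersect(c("inner", "patch", "outer"), unique(sub$habitat))) {
      out[[length(out) + 1]] <- one(sub[sub$habitat == hab, ],
                                    paste(isl, hab))
    }
  }
  if (length(unique(tb$island)) > 1) {
    shared <- Reduce(intersect, tapply(tb$habitat, tb$island, unique))
    for (hab in intersect(c("inner", "patch", "outer"), shared)) {
      out[[length(out) + 1]] <- one(tb[tb$habitat == hab, ],
                                    paste("Both islands", hab))
    }
  }
  empty <- vapply(out, is.null, logical(1))
  if (any(empty)) warning("empty summary group(s) omitted", call. = FALSE)
  do.call(rbind, out[!empty])
}

#' Ranked cumulative species contributions to gross production
#'
#' Sums each taxon's production over the supplied budgets, ranks taxa by
#' contribution, and reports shares and cumulative shares of the total --
#' the basis for "top five species contributed X%" statements.
#'
#' @param budgets list of `carbonate_budget` objects (subset by island
#'   before calling for per-island rankings).
#' @param include_ca also rank the coralline-algae contribution as a
#'   pseudo-taxon (default `FALSE`: shares are of coral gross production).
#' @return `data.frame(taxon, production, share_pct, cumulative_pct)`
#'   sorted by decreasing contribution; shares sum to 100.
#' @export
species_contributions <- function(budgets, include_ca = FALSE) {
  acc <- list()
  for (b in budgets) {
    pt <- b$per_taxon
    if (include_ca && b$ca > 0) pt <- c(pt, coralline_algae = b$ca)
    for (tx in names(pt)) acc[[tx]] <- (acc[[tx]] %||% 0) + pt[[tx]]
  }
  if (!length(acc)) {
    return(data.frame(taxon = character(), production = numeric(),
                      share_pct = numeric(), cumulative_pct = numeric()))
  }
  v <- sort(unlist(acc), decreasing = TRUE)
  share <- 100 * v / sum(v)
  data.frame(taxon = names(v), production = unname(v),
             share_pct = unname(share),
             cumulative_pct = unname(cumsum(share)),
             row.names = NULL)
}
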