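#' Construct and validate a single-site reef survey
#'
#' A `site_survey` bundles one site's raw census data in the layout produced
#' by the field protocol: six line-intercept transects recording the benthic
#' taxon for every centimetre of a substrate-following tape, a planar tape
#' for rugosity, urchin belt records, parrotfish transect records, and a
#' total crown-of-thorns count over the belt transects.
#'
#' @param site_id site identifier (coerced to character).
#' @param island island label.
#' @param habitat one of `"inner"`, `"patch"`, `"outer"`.
#' @param benthic `data.frame(transect_no, taxon, intercept_cm)`; segment
#'   lengths on each transect must sum to that transect's contour length.
#' @param geometry `data.frame(transect_no, contour_cm, planar_cm)`, one row
#'   per transect, with `contour_cm >= planar_cm > 0` (so rugosity >= 1).
#' @param urchins `data.frame(group, diameter_cm)` with group in
#'   `{Diadema, Echinometra, Other}`; one row per individual. May be empty.
#' @param fish `data.frame(species, length_cm)`; one row per individual.
#'   May be empty.
#' @param acanthaster_count non-negative total count over the belt
#'   transects.
#' @param sediment_regime `"normal"` (calcareous sediment supplements the
#'   budget) or `"high_terrigenous"` (runoff sediment smothers corals and
#'   the term switches sign).
#' @param urchin_area,fish_area,acanthaster_area total surveyed areas (m2)
#'   for the respective record sets; defaults are the per-transect areas in
#'   `config` times the number of transects.
#' @param config a [budget_config()].
#'
#' @return An object of class `"site_survey"`.
#' @examples
#' sv <- site_survey("S1", "Pohnpei", "outer",
#'   benthic  = data.frame(transect_no = 1, taxon = "Porites_lobata",
#'                         intercept_cm = 1000),
#'   geometry = data.frame(transect_no = 1, contour_cm = 1000,
#'                         planar_cm = 800))
#' sv$geometry$contour_cm / sv$geometry$planar_cm  # rugosity
#' @export
site_survey <- function(site_id, island, habitat,
                        benthic, geometry,
                        urchins = empty_urchins(),
                        fish = empty_fish(),
                        acanthaster_count = 0L,
                        sediment_regime = "normal",
                        urchin_area = NULL,
                        fish_area = NULL,
                        acanthaster_area = NULL,
                        config = budget_config()) {
  n_tr <- nrow(geometry)
  x <- structure(list(
    site_id = as.character(site_id),
    island = as.character(island),
    habitat = as.character(habitat),
    sediment_regime = as.character(sediment_regime),
    benthic = as.data.frame(benthic),
    geometry = as.data.frame(geometry),
    urchins = as.data.frame(urchins),
    fish = as.data.frame(fish),
    acanthaster_count = as.integer(acanthaster_count),
    areas = list(
      urchin = urchin_area %||% (n_tr * config$urchin_belt_area),
      fish = fish_area %||% (n_tr * config$fish_transect_area),
      acanthaster = acanthaster_area %||% (n_tr * config$acanthaster_belt_area)
    )
  ), class = "site_survey")
  validate_site_survey(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname site_survey
#' @param x a `site_survey`.
#' @export
validate_site_survey <- function(x) {
  stopifnot(inherits(x, "site_survey"))
  id <- x$site_id
  if (!x$habitat %in% c("inner", "patch", "outer")) {
    stop("site ", id, ": unknown habitat label '", x$habitat,
         "' (expected inner/patch/outer)", call. = FALSE)
  }
  if (!x$sediment_regime %in% c("normal", "high_terrigenous")) {
    stop("site ", id, ": unknown sediment_regime '", x$sediment_regime, "'",
         call. = FALSE)
  }
  g <- x$geometry
  need <- setdiff(c("transect_no", "contour_cm", "planar_cm"), names(g))
  if (length(need)) {
    stop("site ", id, ": geometry missing column(s) ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(g$planar_cm <= 0) || any(g$contour_cm < g$planar_cm)) {
    stop("site ", id, ": each transect needs contour_cm >= planar_cm > 0 ",
         "(rugosity >= 1)", call. = FALSE)
  }
  b <- x$benthic
  need <- setdiff(c("transect_no", "taxon", "intercept_cm"), names(b))
  if (length(need)) {
    stop("site ", id, ": benthic missing column(s) ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(b$intercept_cm <= 0)) {
    stop("site ", id, ": non-positive intercept_cm at benthic row(s) ",
         paste(utils::head(which(b$intercept_cm <= 0), 5), collapse = ", "),
         call. = FALSE)
  }
  if (!all(b$transect_no %in% g$transect_no)) {
    stop("site ", id, ": benthic rows reference transects without geometry",
         call. = FALSE)
  }
  seg_sum <- tapply(b$intercept_cm, b$transect_no, sum)
  contour <- g$contour_cm[match(names(seg_sum), g$transect_no)]
  off <- abs(seg_sum - contour) > 1e-6
  if (any(off)) {
    stop("site ", id, ": segment lengths do not sum to the contour length ",
         "on transect(s) ", paste(names(seg_sum)[off], collapse = ", "),
         call. = FALSE)
  }
  u <- x$urchins
  if (nrow(u)) {
    if (!all(u$group %in% c("Diadema", "Echinometra", "Other"))) {
      stop("site ", id, ": unknown urchin group label(s): ",
           paste(setdiff(unique(u$group),
                         c("Diadema", "Echinometra", "Other")),
                 collapse = ", "), call. = FALSE)
    }
    if (any(u$diameter_cm <= 0)) {
      stop("site ", id, ": non-positive urchin test diameter at row(s) ",
           paste(utils::head(which(u$diameter_cm <= 0), 5), collapse = ", "),
           call. = FALSE)
    }
  }
  f <- x$fish
  if (nrow(f) && any(f$length_cm <= 0)) {
    stop("site ", id, ": non-positive fish length at row(s) ",
         paste(utils::head(which(f$length_cm <= 0), 5), collapse = ", "),
         call. = FALSE)
  }
  if (x$acanthaster_count < 0) {
    stop("site ", id, ": acanthaster_count must be >= 0", call. = FALSE)
  }
  if (any(unlist(x$areas) <= 0)) {
    stop("site ", id, ": surveyed areas must be > 0", call. = FALSE)
  }
  invisible(x)
}

empty_urchins <- function() {
  data.frame(group = character(), diameter_cm = numeric())
}

empty_fish <- function() {
  data.frame(species = character(), length_cm = numeric())
}

#' @export
print.site_survey <- function(x, ...) {
  r <- x$geometry$contour_cm / x$geometry$planar_cm
  cat("<site_survey> ", x$site_id, " (", x$island, ", ", x$habitat,
      " reef, ", x$sediment_regime, " sediment)\n", sep = "")
  cat("  transects: ", nrow(x$geometry),
      "; mean rugosity ", round(mean(r), 2), "\n", sep = "")
  cat("  urchins: ", nrow(x$urchins), "; fish: ", nrow(x$fish),
      "; Acanthaster count: ", x$acanthaster_count, "\n", sep = "")
  invisible(x)
}

benthic_schema <- c("site_id", "island", "habitat", "transect_no", "taxon",
                    "intercept_cm", "contour_cm", "planar_cm",
                    "sediment_regime")
mobile_schema <- c("site_id", "transect_no", "record_type", "group",
                   "diameter_cm", "count")
fish_schema <- c("site_id", "transect_no", "species", "length_cm")

read_checked <- function(path, schema, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(schema, names(df))
  if (length(missing)) {
    stop(what, " file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a survey from the three delimited census files
#'
#' The on-disk layout is three UTF-8 comma-separated files with header rows:
#' `benthic.csv` (`site_id, island, habitat, transect_no, taxon,
#' intercept_cm, contour_cm, planar_cm, sediment_regime`; contour and planar
#' lengths repeat on every row of a transect), `mobile.csv` (`site_id,
#' transect_no, record_type, group, diameter_cm, count` with `record_type`
#' either `"urchin"` or `"acanthaster"`) and `fish.csv` (`site_id,
#' transect_no, species, length_cm`). Urchin rows with `count > 1` are
#' expanded to individuals.
#'
#' @param benthic,mobile,fish file paths.
#' @param config a [budget_config()]; supplies per-transect survey areas.
#' @return Named list of [site_survey()] objects, one per `site_id`.
#' @seealso [write_survey()] for the inverse.
#' @export
read_survey <- function(benthic, mobile, fish, config = budget_config()) {
  bn <- read_checked(benthic, benthic_schema, "benthic")
  mb <- read_checked(mobile, mobile_schema, "mobile")
  fs <- read_checked(fish, fish_schema, "fish")

  if (any(bn$intercept_cm <= 0)) {
    stop("benthic: non-positive intercept_cm at row(s) ",
         paste(utils::head(which(bn$intercept_cm <= 0), 5), collapse = ", "),
         call. = FALSE)
  }
  bad_rt <- !mb$record_type %in% c("urchin", "acanthaster")
  if (any(bad_rt)) {
    stop("mobile: unknown record_type at row(s) ",
         paste(utils::head(which(bad_rt), 5), collapse = ", "), call. = FALSE)
  }
  u_rows <- mb$record_type == "urchin"
  if (any(u_rows & (is.na(mb$diameter_cm) | mb$diameter_cm <= 0))) {
    stop("mobile: urchin rows need positive diameter_cm; offending row(s) ",
         paste(utils::head(which(u_rows & (is.na(mb$diameter_cm) |
                                             mb$diameter_cm <= 0)), 5),
               collapse = ", "), call. = FALSE)
  }
  if (any(fs$length_cm <= 0)) {
    stop("fish: non-positive length_cm at row(s) ",
         paste(utils::head(which(fs$length_cm <= 0), 5), collapse = ", "),
         call. = FALSE)
  }

  sites <- unique(bn$site_id)
  out <- lapply(sites, function(id) {
    b <- bn[bn$site_id == id, , drop = FALSE]
    meta <- unique(b[, c("island", "habitat", "sediment_regime")])
    if (nrow(meta) != 1) {
      stop("benthic: inconsistent island/habitat/sediment_regime within ",
           "site ", id, call. = FALSE)
    }
    geom <- unique(b[, c("transect_no", "contour_cm", "planar_cm")])
    if (anyDuplicated(geom$transect_no)) {
      stop("benthic: inconsistent contour/planar lengths within a transect ",
           "of site ", id, call. = FALSE)
    }
    m <- mb[mb$site_id == id, , drop = FALSE]
    mu <- m[m$record_type == "urchin", , drop = FALSE]
    cnt <- ifelse(is.na(mu$count), 1L, as.integer(mu$count))
    urch <- data.frame(
      group = rep(mu$group, cnt),
      diameter_cm = rep(mu$diameter_cm, cnt)
    )
    acount <- sum(m$count[m$record_type == "acanthaster"], na.rm = TRUE)
    f <- fs[fs$site_id == id, c("species", "length_cm"), drop = FALSE]
    rownames(f) <- NULL
    site_survey(id, meta$island, meta$habitat,
                benthic = b[, c("transect_no", "taxon", "intercept_cm")],
                geometry = geom,
                urchins = urch,
                fish = f,
                acanthaster_count = acount,
                sediment_regime = meta$sediment_regime,
                config = config)
  })
  names(out) <- sites
  out
}

#' Write surveys back to the three-file census layout
#'
#' Inverse of [read_survey()]: writing then re-reading reproduces the same
#' `site_survey` structures (urchins one row per individual, *Acanthaster*
#' as one total-count row per site).
#'
#' @param surveys list of `site_survey` objects.
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_survey <- function(surveys, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bn <- do.call(rbind, lapply(surveys, function(s) {
    b <- s$benthic
    g <- s$geometry
    i <- match(b$transect_no, g$transect_no)
    data.frame(site_id = s$site_id, island = s$island, habitat = s$habitat,
               transect_no = b$transect_no, taxon = b$taxon,
               intercept_cm = b$intercept_cm,
               contour_cm = g$contour_cm[i], planar_cm = g$planar_cm[i],
               sediment_regime = s$sediment_regime)
  }))
  mb <- do.call(rbind, lapply(surveys, function(s) {
    u <- s$urchins
    rows <- data.frame(site_id = character(), transect_no = integer(),
                       record_type = character(), group = character(),
                       diameter_cm = numeric(), count = integer())
    if (nrow(u)) {
      rows <- data.frame(site_id = s$site_id, transect_no = NA_integer_,
                         record_type = "urchin", group = u$group,
                         diameter_cm = u$diameter_cm, count = 1L)
    }
    rbind(rows, data.frame(site_id = s$site_id, transect_no = NA_integer_,
                           record_type = "acanthaster", group = NA_character_,
                           diameter_cm = NA_real_,
                           count = s$acanthaster_count))
  }))
  fs <- do.call(rbind, lapply(surveys, function(s) {
    f <- s$fish
    if (!nrow(f)) return(NULL)
    data.frame(site_id = s$site_id, transect_no = NA_integer_,
               species = f$species, length_cm = f$length_cm)
  }))
  if (is.null(fs)) {
    fs <- data.frame(site_id = character(), transect_no = integer(),
                     species = character(), length_cm = numeric())
  }
  paths <- file.path(dir, c("benthic.csv", "mobile.csv", "fish.csv"))
  utils::write.csv(bn, paths[1], row.names = FALSE)
  utils::write.csv(mb, paths[2], row.names = FALSE)
  utils::write.csv(fs, paths[3], row.names = FALSE)
  invisible(paths)
}
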