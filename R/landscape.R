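#' Default land-cover category mapping
#'
#' Land-cover classes are grouped into two categories by level of
#' anthropogenic disturbance and expected pollinator habitat value:
#' \code{semi_natural} (woodland, unmowed grassland, marsh and similar) and
#' \code{disturbed} (urban, mowed and agricultural covers). The default
#' vocabulary covers the classes commonly digitised around blueberry fields;
#' it is deliberately partial (regional land-cover products use larger, and
#' differing, legends) and anything outside it must be supplied explicitly
#' via \code{extra} or a user mapping — unmapped classes are an error, never
#' silently categorised.
#'
#' @param extra named character vector of additional class -> category
#'   entries (values \code{"semi_natural"} or \code{"disturbed"}); may also
#'   override defaults.
#' @return named character vector mapping class name to category.
#' @export
defaultCoverMapping <- function(extra = character(0)) {
  semi <- c("woodland", "forest", "deciduous_forest", "coniferous_forest",
            "mixed_forest", "shrubland", "scrubland", "unmowed_grassland",
            "grassland_unmowed", "marsh", "wetland", "hedgerow",
            "old_field", "riparian")
  dist <- c("urban", "residential", "roads", "mowed_grass", "mowed_area",
            "lawn", "agriculture", "cropland", "blueberry", "orchard",
            "pasture", "bare_soil")
  m <- c(setNames(rep("semi_natural", length(semi)), semi),
         setNames(rep("disturbed", length(dist)), dist))
  if (length(extra)) {
    bad <- setdiff(extra, c("semi_natural", "disturbed"))
    if (length(bad))
      stop("cover categories must be 'semi_natural' or 'disturbed', got: ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    m[names(extra)] <- extra
  }
  m
}

#' Read a land-cover mapping override from a YAML file
#'
#' The file maps class names to categories, e.g. \code{bog: semi_natural}.
#' Entries are merged over [defaultCoverMapping()] unless
#' \code{base = NULL}, in which case the file must be a total mapping for
#' the classes in the data.
#'
#' @param path YAML file of class -> category entries.
#' @param base mapping to merge over (default the built-in vocabulary).
#' @return named character vector mapping class name to category.
#' @export
readCoverMapping <- function(path, base = defaultCoverMapping()) {
  entries <- unlist(yaml::read_yaml(path))
  if (is.null(entries) || is.null(names(entries)))
    stop("mapping file must contain class: category entries", call. = FALSE)
  if (is.null(base)) defaultCoverMapping(extra = entries)[names(entries)]
  else defaultCoverMapping(extra = entries)
}

#' Categorise land-cover areas as semi-natural or disturbed
#'
#' Assigns each cover class area to exactly one of the two categories and
#' sums within category. Total area is conserved exactly. A class without a
#' mapping entry is an error naming the class; there is no silent default.
#'
#' @param areas named numeric vector of areas (m^2) by cover class.
#' @param mapping class -> category map, see [defaultCoverMapping()].
#' @return numeric vector with elements \code{semi_natural} and
#'   \code{disturbed}.
#' @export
mapCoverClasses <- function(areas, mapping = defaultCoverMapping()) {
  if (!length(areas)) stop("no cover-class areas supplied", call. = FALSE)
  if (any(areas < 0)) stop("cover areas must be >= 0", call. = FALSE)
  cats <- mapping[names(areas)]
  if (anyNA(cats))
    stop("unmapped class: ",
         paste(names(areas)[is.na(cats)], collapse = ", "), call. = FALSE)
  c(semi_natural = sum(areas[cats == "semi_natural"]),
    disturbed = sum(areas[cats == "disturbed"]))
}

#' Proportion of semi-natural habitat
#'
#' @param categorized numeric vector as returned by [mapCoverClasses()].
#' @return proportion of total area that is semi-natural, in [0, 1].
#' @export
proportionSemiNatural <- function(categorized) {
  tot <- sum(categorized)
  if (!length(categorized) || tot <= 0)
    stop("total area must be > 0 to form a proportion", call. = FALSE)
  unname(categorized["semi_natural"] / tot)
}

#' Semi-natural habitat profile per field and radius
#'
#' Computes, for every field and every radius present in the landscape
#' table, the proportion of the buffer that is semi-natural. Radii are
#' treated as alternative measurement scales and computed independently (no
#' correction for nesting of the buffers).
#'
#' @param study a [StudyBundle-class] (or a landscape data.frame with
#'   columns field_id, radius_m, cover_class, area_m2).
#' @param mapping class -> category map, see [defaultCoverMapping()].
#' @return data.frame with columns \code{field_id}, \code{landuse_300},
#'   \code{landuse_1000}, \code{landuse_2000} (NA where a radius is absent).
#' @export
semiNaturalProfile <- function(study, mapping = defaultCoverMapping()) {
  ls <- if (is(study, "StudyBundle")) landscapeData(study) else study
  out <- data.frame(field_id = unique(ls$field_id))
  for (r in RADII) out[[paste0("landuse_", r)]] <- NA_real_
  for (i in seq_len(nrow(out))) {
    for (r in RADII) {
      sub <- ls[ls$field_id == out$field_id[i] & ls$radius_m == r, ]
      if (nrow(sub)) {
        areas <- tapply(sub$area_m2, sub$cover_class, sum)
        out[[paste0("landuse_", r)]][i] <-
          proportionSemiNatural(mapCoverClasses(areas, mapping))
      }
    }
  }
  out
}
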