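#' @import methods
#' @importFrom stats aggregate anova as.dist as.formula cmdscale coef
#'   complete.cases cor dist dnbinom isoreg kruskal.test lm lm.fit logLik
#'   model.matrix na.pass p.adjust pnorm prcomp rbinom relevel rmultinom
#'   rnbinom rnorm rpois runif sd setNames t.test var wilcox.test
#' @importFrom utils combn head modifyList read.csv write.csv
NULL

REGIONS <- c("BC", "MI")
DISTANCES <- c(0L, 25L, 50L, 100L)
RADII <- c(300L, 1000L, 2000L)
TREATMENTS <- c("excluded", "open", "hand")
VISITOR_GROUPS <- c("honey_bee", "bumble_bee", "other_bee", "other_visitor")
TIME_BLOCKS <- c("morning", "midday", "afternoon")

#' StudyBundle: validated container for a two-region pollination study
#'
#' A \code{StudyBundle} holds the five related tables of a blueberry
#' pollination field study in one validated object: per-field metadata
#' (region, honey-bee stocking rate, row orientation, plant spacing, yield
#' components, farm-gate price), timed flower-visitor surveys along in-field
#' transects, the field-by-species matrix of netted specimens (honey bees
#' excluded by design), flower-cluster pollination-treatment outcomes with
#' focal-berry measurements, and tabulated land-cover areas at three radii.
#' All downstream pipeline stages consume a \code{StudyBundle}; no stage
#' reads files directly.
#'
#' Validity enforces the study invariants: unique field identifiers,
#' referential integrity of every child table against the metadata, known
#' factor levels (region, distance, treatment, radius, time block), 10-minute
#' survey duration, non-negative counts, \code{n_fruit <= n_flowers}, and a
#' honey-bee-free specimen matrix.
#'
#' @slot fields data.frame of per-field metadata.
#' @slot surveys data.frame of 10-minute timed visitation counts.
#' @slot specimens integer matrix, fields x species, netted-specimen counts.
#' @slot clusters data.frame of per-cluster treatment outcomes.
#' @slot berries data.frame of focal berries (weight g, mature seed count).
#' @slot landscape data.frame of land-cover class areas per field and radius.
#' @slot config named list of free-form study settings.
#'
#' @seealso [readStudy()], [writeStudy()], [simulateStudy()], [runPipeline()]
#' @export
setClass("StudyBundle",
  representation(
    fields    = "data.frame",
    surveys   = "data.frame",
    specimens = "matrix",
    clusters  = "data.frame",
    berries   = "data.frame",
    landscape = "data.frame",
    config    = "list"
  )
)

.required_cols <- list(
  fields = c("field_id", "region", "stocking_rate", "row_orientation",
             "bush_spacing", "row_spacing", "canes_per_bush",
             "clusters_per_cane", "berries_per_cluster"),
  surveys = c("field_id", "distance", "date", "time_block", "duration",
              VISITOR_GROUPS),
  specimens = c("field_id", "species_id", "count"),
  clusters = c("field_id", "distance", "bush_id", "cluster_id", "treatment",
               "n_flowers", "n_fruit", "cluster_weight"),
  berries = c("field_id", "distance", "bush_id", "cluster_id", "berry_id",
              "weight", "mature_seeds"),
  landscape = c("field_id", "radius_m", "cover_class", "area_m2"),
  prices = c("region", "price_per_kg")
)

validStudyBundle <- function(object) {
  msg <- character(0)
  fl <- object@fields
  add <- function(cond, text) if (cond) c(msg, text) else msg

  msg <- add(anyDuplicated(fl$field_id) > 0, "duplicated field_id in fields")
  msg <- add(!all(fl$region %in% REGIONS),
             sprintf("unknown region value(s): %s",
                     paste(setdiff(unique(fl$region), REGIONS), collapse = ", ")))
  msg <- add(!all(fl$row_orientation %in% c("parallel", "perpendicular")),
             "row_orientation must be 'parallel' or 'perpendicular'")
  msg <- add(any(fl$stocking_rate < 0 | fl$stocking_rate > 50),
             "stocking_rate outside [0, 50] hives/ha")
  msg <- add(any(fl$bush_spacing <= 0) || any(fl$row_spacing <= 0),
             "bush_spacing and row_spacing must be > 0 m")
  if ("price" %in% names(fl))
    msg <- add(any(fl$price <= 0), "price must be > 0 $/kg")

  ids <- fl$field_id
  orphan <- function(tab, nm) {
    bad <- setdiff(unique(tab$field_id), ids)
    if (length(bad))
      sprintf("integrity error: %s references unknown field_id: %s",
              nm, paste(bad, collapse = ", "))
    else character(0)
  }
  sv <- object@surveys
  if (nrow(sv)) {
    msg <- c(msg, orphan(sv, "surveys"))
    msg <- add(!all(sv$distance %in% DISTANCES),
               "surveys: distance must be one of 0, 25, 50, 100 m")
    msg <- add(!all(sv$duration == 10), "surveys: duration must be 10 minutes")
    msg <- add(!all(sv$time_block %in% TIME_BLOCKS),
               "surveys: unknown time_block level")
    cnt <- as.matrix(sv[, VISITOR_GROUPS])
    msg <- add(any(cnt < 0) || any(cnt != round(cnt)),
               "surveys: counts must be non-negative integers")
    key <- paste(sv$field_id, sv$distance, sv$date)
    msg <- add(anyDuplicated(key) > 0,
               "surveys: (field_id, distance, date) must be unique")
  }
  sp <- object@specimens
  if (length(sp)) {
    bad <- setdiff(rownames(sp), ids)
    if (length(bad))
      msg <- c(msg, sprintf(
        "integrity error: specimens references unknown field_id: %s",
        paste(bad, collapse = ", ")))
    msg <- add(any(sp < 0) || any(sp != round(sp)),
               "specimens: counts must be non-negative integers")
    msg <- add(any(grepl("^apis|honey", colnames(sp), ignore.case = TRUE)),
               "specimens: honey bees (Apis mellifera) must be excluded")
  }
  cl <- object@clusters
  if (nrow(cl)) {
    msg <- c(msg, orphan(cl, "clusters"))
    msg <- add(!all(cl$treatment %in% TREATMENTS),
               "clusters: treatment must be excluded/open/hand")
    msg <- add(any(cl$n_flowers <= 0), "clusters: n_flowers must be > 0")
    bad <- which(cl$n_fruit > cl$n_flowers | cl$n_fruit < 0)
    if (length(bad))
      msg <- c(msg, sprintf(
        "integrity error: n_fruit > n_flowers (or < 0) in clusters row(s) %s",
        paste(head(bad, 5L), collapse = ", ")))
    msg <- add(any(cl$cluster_weight < 0), "clusters: cluster_weight must be >= 0")
    key <- paste(cl$field_id, cl$distance, cl$bush_id, cl$treatment)
    msg <- add(anyDuplicated(key) > 0,
               "clusters: one cluster group per treatment per bush")
  }
  br <- object@berries
  if (nrow(br)) {
    msg <- c(msg, orphan(br, "berries"))
    msg <- add(any(br$weight < 0), "berries: weight must be >= 0 g")
    msg <- add(any(br$mature_seeds < 0 | br$mature_seeds != round(br$mature_seeds)),
               "berries: mature_seeds must be a non-negative integer")
  }
  ls <- object@landscape
  if (nrow(ls)) {
    msg <- c(msg, orphan(ls, "landscape"))
    msg <- add(!all(ls$radius_m %in% RADII),
               "landscape: radius_m must be one of 300, 1000, 2000")
    msg <- add(any(ls$area_m2 < 0), "landscape: area_m2 must be >= 0")
  }
  if (length(msg)) msg else TRUE
}

setValidity("StudyBundle", validStudyBundle)

#' @describeIn StudyBundle compact summary of the study design
#' @param object a \code{StudyBundle}
#' @export
setMethod("show", "StudyBundle", function(object) {
  fl <- object@fields
  cat("StudyBundle:", nrow(fl), "fields (",
      paste(sprintf("%s: %d", REGIONS, tabulate(factor(fl$region, REGIONS), 2L)),
            collapse = ", "), ")\n")
  cat("  surveys:  ", nrow(object@surveys), " timed counts\n", sep = "")
  cat("  specimens:", ncol(object@specimens), "species,",
      sum(object@specimens), "individuals\n")
  cat("  clusters: ", nrow(object@clusters), " treatment clusters; berries: ",
      nrow(object@berries), "\n", sep = "")
  cat("  landscape:", nrow(object@landscape), "cover-class areas\n")
  invisible(object)
})

#' Accessors for StudyBundle tables
#'
#' Return the component tables of a [StudyBundle-class]: field metadata,
#' timed surveys, the field-by-species specimen matrix, cluster treatment
#' outcomes, focal berries, and land-cover areas. \code{regions()} returns
#' the region label of each field, named by \code{field_id}.
#'
#' @param x a \code{StudyBundle}
#' @return a data.frame (or matrix for \code{specimenMatrix}, named character
#'   vector for \code{regions}).
#' @name StudyBundle-accessors
NULL

#' @rdname StudyBundle-accessors
#' @export
fieldInfo <- function(x) x@fields

#' @rdname StudyBundle-accessors
#' @export
surveyData <- function(x) x@surveys

#' @rdname StudyBundle-accessors
#' @export
specimenMatrix <- function(x) x@specimens

#' @rdname StudyBundle-accessors
#' @export
clusterData <- function(x) x@clusters

#' @rdname StudyBundle-accessors
#' @export
berryData <- function(x) x@berries

#' @rdname StudyBundle-accessors
#' @export
landscapeData <- function(x) x@landscape

#' @rdname StudyBundle-accessors
#' @export
regions <- function(x) setNames(x@fields$region, x@fields$field_id)

#' Construct a StudyBundle from component tables
#'
#' Low-level constructor used by [readStudy()] and [simulateStudy()].
#' Tables are coerced to the canonical column order and the full validity
#' check is run.
#'
#' @param fields,surveys,clusters,berries,landscape data.frames with the
#'   documented columns.
#' @param specimens fields x species count matrix with field_id rownames,
#'   or a long data.frame (field_id, species_id, count).
#' @param config optional named list of study settings.
#' @return a validated \code{StudyBundle}.
#' @export
StudyBundle <- function(fields, surveys, specimens, clusters, berries,
                        landscape, config = list()) {
  if (is.data.frame(specimens))
    specimens <- specimenLongToMatrix(specimens, fields$field_id)
  new("StudyBundle",
      fields = as.data.frame(fields), surveys = as.data.frame(surveys),
      specimens = specimens, clusters = as.data.frame(clusters),
      berries = as.data.frame(berries), landscape = as.data.frame(landscape),
      config = config)
}

specimenLongToMatrix <- function(long, field_ids) {
  sp <- sort(unique(long$species_id))
  m <- matrix(0L, nrow = length(field_ids), ncol = length(sp),
              dimnames = list(field_ids, sp))
  if (nrow(long)) {
    idx <- cbind(match(long$field_id, field_ids), match(long$species_id, sp))
    for (i in seq_len(nrow(long)))
      m[idx[i, 1L], idx[i, 2L]] <- m[idx[i, 1L], idx[i, 2L]] + long$count[i]
  }
  m
}

specimenMatrixToLong <- function(m) {
  long <- data.frame(
    field_id = rep(rownames(m), times = ncol(m)),
    species_id = rep(colnames(m), each = nrow(m)),
    count = as.integer(m))
  long <- long[long$count > 0, ]
  long[order(long$field_id, long$species_id), , drop = FALSE]
}
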