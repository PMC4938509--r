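#' Read a study from delimited text files
#'
#' Loads the seven comma-separated tables of a study directory
#' (\code{fields.csv}, \code{surveys.csv}, \code{specimens.csv},
#' \code{clusters.csv}, \code{berries.csv}, \code{landscape.csv},
#' \code{prices.csv}) into a validated [StudyBundle-class]. Files are UTF-8
#' CSV with a mandatory header row and \code{.} decimal separator. Units are
#' fixed at ingestion: berry and cluster weights in grams, areas in square
#' metres, distances and radii in metres, prices in dollars per kilogram.
#' Region-level farm-gate prices from \code{prices.csv} are joined onto the
#' field table as a \code{price} column (an explicit \code{price} column in
#' \code{fields.csv} takes precedence).
#'
#' Schema problems raise errors naming the offending column; unknown factor
#' levels and referential-integrity violations raise errors naming the
#' offending rows.
#'
#' @param dir directory containing the study CSV files.
#' @param paths optional named character vector overriding individual file
#'   locations (names among fields, surveys, specimens, clusters, berries,
#'   landscape, prices).
#' @param config named list of free-form settings stored on the bundle.
#' @return a validated \code{StudyBundle}.
#' @seealso [writeStudy()] for the inverse; load then write is a fixed point.
#' @export
readStudy <- function(dir, paths = character(0), config = list()) {
  tabs <- c("fields", "surveys", "specimens", "clusters", "berries",
            "landscape", "prices")
  files <- setNames(file.path(dir, paste0(tabs, ".csv")), tabs)
  files[names(paths)] <- paths
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("study file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  raw <- lapply(files, read.csv, stringsAsFactors = FALSE)
  for (nm in tabs) checkSchema(raw[[nm]], nm)

  fl <- raw$fields
  if (!"price" %in% names(fl)) {
    pr <- raw$prices
    idx <- match(fl$region, pr$region)
    if (anyNA(idx))
      stop("prices.csv has no price for region(s): ",
           paste(unique(fl$region[is.na(idx)]), collapse = ", "), call. = FALSE)
    fl$price <- pr$price_per_kg[idx]
  }
  checkEnum(fl, "region", REGIONS, "fields")
  checkEnum(fl, "row_orientation", c("parallel", "perpendicular"), "fields")
  checkEnum(raw$surveys, "time_block", TIME_BLOCKS, "surveys")
  checkEnum(raw$clusters, "treatment", TREATMENTS, "clusters")

  StudyBundle(fields = fl, surveys = raw$surveys, specimens = raw$specimens,
              clusters = raw$clusters, berries = raw$berries,
              landscape = raw$landscape, config = config)
}

checkSchema <- function(tab, name) {
  need <- .required_cols[[name]]
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("schema error in %s.csv: missing column(s) %s",
                 name, paste(miss, collapse = ", ")), call. = FALSE)
  invisible(tab)
}

checkEnum <- function(tab, col, levels, name) {
  bad <- which(!tab[[col]] %in% levels)
  if (length(bad))
    stop(sprintf(
      "validation error in %s: unknown %s value %s (row %s); expected one of %s",
      name, col, deparse(tab[[col]][bad[1L]]), bad[1L],
      paste(levels, collapse = ", ")), call. = FALSE)
  invisible(tab)
}

#' Write a study bundle back to delimited text files
#'
#' Writes the canonical CSV files of a [StudyBundle-class] into \code{dir}
#' (created if needed). The representation round-trips:
#' \code{readStudy(writeStudy(x))} reproduces \code{x} up to byte
#' normalisation (column order is canonical, the specimen matrix is stored
#' long-form with zero cells dropped, rows sorted by field and species).
#'
#' @param study a \code{StudyBundle}.
#' @param dir output directory.
#' @return invisibly, the vector of files written.
#' @export
writeStudy <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fl <- fieldInfo(study)
  prices <- unique(data.frame(region = fl$region, price_per_kg = fl$price))
  prices <- prices[order(prices$region), ]
  tabs <- list(
    fields = fl[, c(.required_cols$fields,
                    intersect("price", names(fl))), drop = FALSE],
    surveys = surveyData(study)[, .required_cols$surveys],
    specimens = specimenMatrixToLong(specimenMatrix(study)),
    clusters = clusterData(study)[, .required_cols$clusters],
    berries = berryData(study)[, .required_cols$berries],
    landscape = landscapeData(study)[, .required_cols$landscape],
    prices = prices)
  files <- file.path(dir, paste0(names(tabs), ".csv"))
  for (i in seq_along(tabs))
    write.csv(tabs[[i]], files[i], row.names = FALSE, quote = FALSE)
  invisible(setNames(files, names(tabs)))
}
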