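#' Berries per hectare from yield components
#'
#' Total berry count per hectare as the product of bushes per hectare,
#' canes per bush, flower clusters per cane, and berries per cluster.
#'
#' @param bushes_per_ha,canes_per_bush,clusters_per_cane,berries_per_cluster
#'   non-negative yield components (vectorised).
#' @return berries per hectare.
#' @export
berriesPerHa <- function(bushes_per_ha, canes_per_bush, clusters_per_cane,
                         berries_per_cluster) {
  args <- cbind(bushes_per_ha, canes_per_bush, clusters_per_cane,
                berries_per_cluster)
  if (any(args < 0)) stop("yield components must be >= 0", call. = FALSE)
  bushes_per_ha * canes_per_bush * clusters_per_cane * berries_per_cluster
}

#' Open-pollination yield in kg per hectare
#'
#' @param berries_per_ha berry count per hectare.
#' @param W_o mean berry weight in the open treatment, grams.
#' @return yield in kg/ha (\code{berries_per_ha * W_o / 1000}).
#' @export
yieldOpen <- function(berries_per_ha, W_o) {
  if (any(W_o < 0)) stop("berry weight must be >= 0", call. = FALSE)
  berries_per_ha * W_o / 1000
}

#' Yield attributable to insect pollination (kg/ha)
#'
#' Compares the realised open-pollination yield with the yield the field
#' would produce if flowers set fruit and sized berries as in the
#' pollinator-exclusion treatment:
#' \deqn{Y_p = (B W_o - B (FS_e / FS_o) W_e) / 1000}
#' with \eqn{B} berries/ha, fruit sets \eqn{FS} and berry weights \eqn{W}
#' (grams) from the excluded (e) and open (o) treatments.
#'
#' @param berries_per_ha berry count per hectare.
#' @param FS_e,FS_o fruit set in the excluded and open treatments.
#' @param W_e,W_o mean berry weight (g) in the excluded and open treatments.
#' @return Y_p in kg/ha (negative values possible from sampling noise).
#' @export
yieldDueToPollination <- function(berries_per_ha, FS_e, FS_o, W_e, W_o) {
  if (any(FS_o <= 0))
    stop("undefined ratio: open-treatment fruit set must be > 0",
         call. = FALSE)
  (berries_per_ha * W_o - berries_per_ha * (FS_e / FS_o) * W_e) / 1000
}

#' Unrealized yield under the pollination deficit (kg/ha)
#'
#' Yield forgone because open pollination fell short of the
#' hand-supplemented maximum:
#' \deqn{Y_d = (B (FS_s / FS_o) W_s - B W_o) / 1000}
#' with fruit set \eqn{FS_s} and berry weight \eqn{W_s} from the
#' hand-supplemented treatment.
#'
#' @inheritParams yieldDueToPollination
#' @param FS_s,W_s fruit set and mean berry weight (g) in the
#'   hand-supplemented treatment.
#' @return Y_d in kg/ha (negative values possible from sampling noise).
#' @export
unrealizedYield <- function(berries_per_ha, FS_s, FS_o, W_s, W_o) {
  if (any(FS_o <= 0))
    stop("undefined ratio: open-treatment fruit set must be > 0",
         call. = FALSE)
  (berries_per_ha * (FS_s / FS_o) * W_s - berries_per_ha * W_o) / 1000
}

#' Farm-gate valuation of yield and pollination services
#'
#' Converts per-field yields to dollar values at the field's farm-gate
#' price: crop value = Yield x price, pollination value = Y_p x price,
#' potential increase = Y_d x price, proportion of maximum yield currently
#' achieved = Yield / (Yield + Y_d), and the proportional increase
#' attainable = potential increase / crop value. Region rows are the mean
#' and standard error over fields. Negative Y_p or Y_d are kept raw in the
#' per-field table; in the region summary they are floored at zero, with
#' the number of floored fields reported.
#'
#' @param fields data.frame with one row per field: \code{field_id},
#'   \code{region}, \code{yield}, \code{Yp}, \code{Yd} (kg/ha) and
#'   \code{price} ($/kg).
#' @return list with \code{per_field} (adds crop_value, pollination_value,
#'   potential_increase, proportion_of_max, proportion_increase) and
#'   \code{region} (mean and SE per region of every quantity, floored
#'   values, plus \code{n_floored_Yp}, \code{n_floored_Yd}).
#' @export
economicValuation <- function(fields) {
  if (any(fields$price <= 0)) stop("price must be > 0", call. = FALSE)
  pf <- fields
  pf$crop_value <- pf$yield * pf$price
  pf$pollination_value <- pf$Yp * pf$price
  pf$potential_increase <- pf$Yd * pf$price
  pf$proportion_of_max <- pf$yield / (pf$yield + pmax(pf$Yd, 0))
  pf$proportion_increase <- pmax(pf$potential_increase, 0) / pf$crop_value

  reg <- do.call(rbind, lapply(split(pf, pf$region), function(s) {
    fl <- s
    fl$Yp <- pmax(fl$Yp, 0); fl$Yd <- pmax(fl$Yd, 0)
    fl$pollination_value <- pmax(fl$pollination_value, 0)
    fl$potential_increase <- pmax(fl$potential_increase, 0)
    se <- function(v) sd(v) / sqrt(length(v))
    qty <- c("yield", "Yp", "Yd", "proportion_of_max", "crop_value",
             "pollination_value", "potential_increase",
             "proportion_increase")
    out <- data.frame(region = s$region[1L], n_fields = nrow(s),
                      price = mean(s$price))
    for (q in qty) {
      out[[paste0(q, "_mean")]] <- mean(fl[[q]])
      out[[paste0(q, "_se")]] <- se(fl[[q]])
    }
    out$n_floored_Yp <- sum(s$Yp < 0)
    out$n_floored_Yd <- sum(s$Yd < 0)
    out
  }))
  rownames(reg) <- NULL
  list(per_field = pf, region = reg)
}

#' Per-field economic summary from a study bundle
#'
#' Runs the full economics stage: berries per hectare from the field
#' metadata (bushes/ha derived from bush and row spacing when not given
#' directly), treatment summaries from the cluster data, the yield model
#' (open yield, yield due to pollination, unrealized yield) and the
#' farm-gate valuation. The identity
#' \code{yield + Yd == berries_per_ha * (FS_s/FS_o) * W_s / 1000}
#' (hand-supplemented yield) holds exactly per field.
#'
#' @param study a [StudyBundle-class].
#' @param summary optional precomputed [summarizeTreatments()] table.
#' @return as [economicValuation()], with yield columns added to
#'   \code{per_field}.
#' @export
economicSummary <- function(study, summary = summarizeTreatments(study)) {
  fl <- fieldInfo(study)
  wide <- function(col) {
    out <- matrix(NA_real_, nrow(fl), 3L,
                  dimnames = list(fl$field_id, TREATMENTS))
    idx <- cbind(match(summary$field_id, fl$field_id),
                 match(summary$treatment, TREATMENTS))
    out[idx] <- summary[[col]]
    out
  }
  fs <- wide("fruit_set"); w <- wide("berry_weight")
  bph <- if ("bushes_per_ha" %in% names(fl)) fl$bushes_per_ha
         else 1e4 / (fl$bush_spacing * fl$row_spacing)
  B <- berriesPerHa(bph, fl$canes_per_bush, fl$clusters_per_cane,
                    fl$berries_per_cluster)
  per <- data.frame(
    field_id = fl$field_id, region = fl$region, price = fl$price,
    berries_per_ha = B,
    FS_e = fs[, "excluded"], FS_o = fs[, "open"], FS_s = fs[, "hand"],
    W_e = w[, "excluded"], W_o = w[, "open"], W_s = w[, "hand"])
  per$yield <- yieldOpen(B, per$W_o)
  per$Yp <- yieldDueToPollination(B, per$FS_e, per$FS_o, per$W_e, per$W_o)
  per$Yd <- unrealizedYield(B, per$FS_s, per$FS_o, per$W_s, per$W_o)
  val <- economicValuation(per)
  val
}
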