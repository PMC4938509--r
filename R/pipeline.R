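PIPELINE_STAGES <- c("diversity", "composition", "glmm", "pollination",
                     "economics")

# Polynomial rolling hash over the serialized object; cheap content
# fingerprint for the run log.
configHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the analysis pipeline on a study bundle
#'
#' Executes the requested stages on a validated [StudyBundle-class] and
#' returns their report tables; with \code{out_dir} set, each table is also
#' written as a CSV together with a run log (seed, configuration hash,
#' package versions). Progress and diagnostics go to standard error. Two
#' runs with the same study, stages, seed and settings produce
#' byte-identical outputs.
#'
#' Stages: \code{diversity} (per-field/regional richness and diversity,
#' accumulation curves, between-region tests), \code{composition}
#' (Bray-Curtis, NMDS, environmental vectors, PERMANOVA), \code{glmm}
#' (NB-GLMM multimodel inference per region and response group),
#' \code{pollination} (treatment summaries, contribution and deficit,
#' contrasts, seed-weight ANCOVA), \code{economics} (yield model and
#' farm-gate valuation).
#'
#' @param study a \code{StudyBundle}.
#' @param stages subset of the stage names above (non-empty).
#' @param out_dir optional output directory for CSV tables and the run log.
#' @param seed integer seed governing all stochastic steps (permutation
#'   tests, NMDS restarts, accumulation curves).
#' @param settings named list of tuning settings: \code{n_perm} (default
#'   999), \code{nmds_restarts} (default 20), \code{glmm_responses}
#'   (default \code{c("wild_bees", "honey_bee")}), \code{glmm_interaction}
#'   (default FALSE), \code{collinearity_threshold} (default 0.6),
#'   \code{contrast_adjust} ("none" or "holm"), \code{transform}
#'   (abundance transformation for Bray-Curtis).
#' @return named list of data.frames, one or more per stage.
#' @export
runPipeline <- function(study, stages = PIPELINE_STAGES, out_dir = NULL,
                        seed = 1L, settings = list()) {
  if (!length(stages))
    stop("configuration error: no stages requested", call. = FALSE)
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad))
    stop("configuration error: unknown stage(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  defaults <- list(n_perm = 999L, nmds_restarts = 20L,
                   glmm_responses = c("wild_bees", "honey_bee"),
                   glmm_interaction = FALSE,
                   collinearity_threshold = 0.6,
                   contrast_adjust = "none", transform = "none")
  st <- modifyList(defaults, settings)
  out <- list()

  if ("diversity" %in% stages) {
    message("stage diversity")
    if (!length(specimenMatrix(study)))
      stop("configuration error: diversity stage requires specimen data",
           call. = FALSE)
    dstats <- diversityStats(study)
    out$diversity <- dstats
    m <- specimenMatrix(study)
    reg <- regions(study)
    out$accumulation <- do.call(rbind, lapply(REGIONS, function(r) {
      sub <- m[reg[rownames(m)] == r, , drop = FALSE]
      if (nrow(sub) < 1L) return(NULL)
      acc <- accumulationCurve(sub, n_perm = st$n_perm,
                               seed = deriveSeed(seed, paste0("acc_", r)))
      cbind(region = r, acc)
    }))
    out$diversity_tests <- regionalDiversityTests(dstats)
  }

  if ("composition" %in% stages) {
    message("stage composition")
    m <- specimenMatrix(study)
    if (!length(m))
      stop("configuration error: composition stage requires specimen data",
           call. = FALSE)
    keep <- rowSums(m) > 0
    m <- m[keep, , drop = FALSE]
    reg <- regions(study)[rownames(m)]
    d <- brayCurtis(m, transform = st$transform)
    out$braycurtis <- as.data.frame(as.matrix(d))
    ord <- nmdsOrdination(d, k = 2L, n_restarts = st$nmds_restarts,
                          seed = deriveSeed(seed, "nmds"))
    out$nmds_coords <- data.frame(field_id = rownames(ord$points),
                                  region = unname(reg),
                                  ord$points, stress = ord$stress,
                                  converged = ord$converged)
    prof <- semiNaturalProfile(study)
    pidx <- match(rownames(ord$points), prof$field_id)
    out$envfit <- do.call(rbind, lapply(RADII, function(r) {
      v <- prof[[paste0("landuse_", r)]][pidx]
      if (anyNA(v) || sd(v) == 0) return(NULL)
      cbind(variable = paste0("landuse_", r),
            envfitVector(ord, v, n_perm = st$n_perm,
                         seed = deriveSeed(seed, paste0("envfit_", r))))
    }))
    out$permanova <- permanovaTest(d, reg, n_perm = st$n_perm,
                                   seed = deriveSeed(seed, "permanova"))
  }

  if ("glmm" %in% stages) {
    message("stage glmm")
    if (!nrow(surveyData(study)))
      stop("configuration error: glmm stage requires survey data",
           call. = FALSE)
    sel <- list(); avg <- list()
    for (r in intersect(REGIONS, unique(fieldInfo(study)$region))) {
      for (resp in st$glmm_responses) {
        message("  ", r, " / ", resp)
        res <- abundanceModelTable(
          study, resp, r, threshold = st$collinearity_threshold,
          interaction = st$glmm_interaction)
        sel[[length(sel) + 1L]] <- cbind(response = resp, region = r,
                                         res$selection)
        avg[[length(avg) + 1L]] <- cbind(response = resp, region = r,
                                         res$average)
      }
    }
    out$model_selection <- do.call(rbind, sel)
    out$model_average <- do.call(rbind, avg)
  }

  if ("pollination" %in% stages) {
    message("stage pollination")
    if (!nrow(clusterData(study)))
      stop("configuration error: pollination stage requires cluster data",
           call. = FALSE)
    sm <- summarizeTreatments(study)
    out$treatment_summary <- sm
    eff <- contributionAndDeficit(sm)
    out$effects <- eff
    rows <- list()
    for (r in intersect(REGIONS, unique(sm$region))) {
      s <- sm[sm$region == r, ]
      for (col in c("fruit_set", "berry_weight", "seeds")) {
        v <- s[[col]]
        if (sum(complete.cases(v, s$treatment)) < 4L) next
        ct <- treatmentContrasts(v, s$treatment,
                                 adjust = st$contrast_adjust)
        rows[[length(rows) + 1L]] <- data.frame(
          region = r, outcome = col, chisq = ct$kruskal$chisq,
          df = ct$kruskal$df, p = ct$kruskal$p,
          letters = paste(paste0(names(ct$letters), "=", ct$letters),
                          collapse = ";"))
      }
    }
    out$contrasts <- do.call(rbind, rows)
    anc <- tryCatch(seedWeightAncova(eff), error = function(e) NULL)
    if (!is.null(anc))
      out$ancova <- data.frame(
        slope = anc$slope, slope_se = anc$slope_se,
        interaction_F = anc$interaction_F,
        interaction_p = anc$interaction_p, n = anc$n,
        intercepts = paste(sprintf("%s=%.3f(%.3f)", anc$intercepts$region,
                                   anc$intercepts$intercept,
                                   anc$intercepts$se), collapse = ";"))
  }

  if ("economics" %in% stages) {
    message("stage economics")
    if (!nrow(clusterData(study)))
      stop("configuration error: economics stage requires cluster data",
           call. = FALSE)
    eco <- economicSummary(study)
    out$economics_per_field <- eco$per_field
    out$economics <- eco$region
  }

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in names(out))
      write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                row.names = FALSE)
    log <- c(
      sprintf("seed: %d", seed),
      sprintf("stages: %s", paste(stages, collapse = ",")),
      sprintf("config_hash: %s", configHash(list(stages, seed, st))),
      sprintf("package: beescape %s",
              as.character(utils::packageVersion("beescape"))),
      sprintf("R: %s", R.version.string))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  out
}
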