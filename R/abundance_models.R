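#' Small-sample Akaike Information Criterion
#'
#' \deqn{AICc = -2 \log L + 2k + 2k(k+1)/(n - k - 1)}
#' where \eqn{k} is the number of estimated parameters and \eqn{n} the
#' number of observation units. For \eqn{n \le k + 1} the correction is
#' undefined and \code{Inf} is returned with a warning (infinite penalty).
#'
#' @param logLik maximised log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observation units.
#' @return the AICc value.
#' @examples
#' aicc(-717.93, 6, 204)   # 1448.29
#' @export
aicc <- function(logLik, k, n) {
  if (n <= k + 1) {
    warning("AICc undefined for n <= k + 1; returning Inf")
    return(Inf)
  }
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Collinearity screening of candidate explanatory variables
#'
#' Computes pairwise Pearson correlations between candidate variables
#' (categorical variables enter through their dummy columns; a pair is
#' flagged if any dummy-column correlation crosses the threshold). Pairs
#' with \eqn{|r| \ge} \code{threshold} are marked inadmissible and are never
#' co-included in one model. Constant columns are dropped with a warning.
#'
#' @param data data.frame holding the candidate variables.
#' @param vars character vector of candidate variable names.
#' @param threshold absolute-correlation bound (default 0.6).
#' @param exempt variables never excluded by screening (they remain
#'   admissible with every partner).
#' @return list with \code{admissible} (logical var x var matrix, TRUE where
#'   the pair may be co-included), \code{correlations} (max |r| per pair)
#'   and \code{dropped} (constant variables removed).
#' @export
screenCollinearity <- function(data, vars, threshold = 0.6,
                               exempt = character(0)) {
  dummies <- list()
  dropped <- character(0)
  for (v in vars) {
    col <- data[[v]]
    if (is.character(col) || is.factor(col)) {
      mm <- model.matrix(~ x, data.frame(x = factor(col)))[, -1L, drop = FALSE]
    } else mm <- matrix(as.numeric(col), ncol = 1L)
    keep <- apply(mm, 2L, sd) > 0
    if (!any(keep)) {
      warning("dropping constant variable: ", v)
      dropped <- c(dropped, v)
    } else dummies[[v]] <- mm[, keep, drop = FALSE]
  }
  vs <- names(dummies)
  adm <- matrix(TRUE, length(vs), length(vs), dimnames = list(vs, vs))
  cors <- matrix(0, length(vs), length(vs), dimnames = list(vs, vs))
  if (length(vs) > 1L) for (i in seq_len(length(vs) - 1L))
    for (j in seq.int(i + 1L, length(vs))) {
      r <- max(abs(cor(dummies[[i]], dummies[[j]])))
      cors[i, j] <- cors[j, i] <- r
      ok <- r < threshold || vs[i] %in% exempt || vs[j] %in% exempt
      adm[i, j] <- adm[j, i] <- ok
    }
  list(admissible = adm, correlations = cors, dropped = dropped)
}

#' Build the candidate model set for one response group
#'
#' Enumerates all subsets of the admissible fixed-effect terms, always
#' including the null (random-effects-only) model, and never co-including a
#' pair flagged by [screenCollinearity()]. When \code{interaction = TRUE}
#' and a subset contains both \code{distance} and the land-use term, an
#' additional model with the distance x land-use interaction is added
#' (interactions only ever appear alongside both main effects). For the
#' honey-bee response, hive stocking rate belongs in the candidate list
#' regardless of the screening outcome (pass it via \code{exempt} in the
#' screen and include it in \code{terms}).
#'
#' @param response response group name (one of the visitor groups or
#'   \code{wild_bees}).
#' @param terms candidate fixed-effect term names.
#' @param admissible logical term x term matrix from [screenCollinearity()];
#'   \code{NULL} means all pairs admissible.
#' @param interaction allow the distance x land-use interaction.
#' @return list of model specs: each a list with \code{response},
#'   \code{fixed} (character vector, possibly empty) and \code{interaction}.
#' @export
buildModelSet <- function(response, terms, admissible = NULL,
                          interaction = FALSE) {
  if (!length(terms)) {
    warning("empty admissible term set; returning the null model only")
    return(list(list(response = response, fixed = character(0),
                     interaction = FALSE)))
  }
  subsets <- list(character(0))
  for (t in terms)
    subsets <- c(subsets, lapply(subsets, function(s) c(s, t)))
  ok <- vapply(subsets, function(s) {
    if (length(s) < 2L || is.null(admissible)) return(TRUE)
    prs <- combn(s, 2L)
    all(apply(prs, 2L, function(p) admissible[p[1L], p[2L]]))
  }, TRUE)
  subsets <- subsets[ok]
  specs <- lapply(subsets, function(s)
    list(response = response, fixed = s, interaction = FALSE))
  if (interaction) {
    lu <- grep("^landuse_", terms, value = TRUE)
    for (s in subsets) {
      if ("distance" %in% s && any(lu %in% s))
        specs <- c(specs, list(list(response = response, fixed = s,
                                    interaction = TRUE)))
    }
  }
  specs
}

specLabel <- function(spec) {
  if (!length(spec$fixed)) return("(null)")
  lab <- paste(spec$fixed, collapse = " + ")
  if (isTRUE(spec$interaction)) {
    lu <- grep("^landuse_", spec$fixed, value = TRUE)[1L]
    lab <- paste0(lab, " + distance:", lu)
  }
  lab
}

specFormula <- function(spec, random = c("date", "time_block")) {
  rhs <- spec$fixed
  if (isTRUE(spec$interaction)) {
    lu <- grep("^landuse_", spec$fixed, value = TRUE)[1L]
    rhs <- c(rhs, paste0("distance:", lu))
  }
  if (!length(rhs)) rhs <- "1"
  rhs <- c(rhs, sprintf("(1 | %s)", random))
  as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")))
}

#' Fit a negative-binomial mixed model of visitor counts
#'
#' Fits the NB2 (quadratic mean-variance) negative-binomial generalized
#' linear mixed model with log link and normal random intercepts for sample
#' date and time-of-day block, by maximised marginal likelihood (Laplace
#' approximation; glmmTMB engine). The parameter count \eqn{k} includes the
#' fixed effects (with intercept), the NB dispersion, and one variance per
#' random-effect term.
#'
#' @param spec a model spec from [buildModelSet()], or a formula (random
#'   effects written in lme4 syntax; omit them for a fixed-effects-only
#'   fit).
#' @param data model frame, typically from [abundanceModelData()]; one row
#'   per transect x visit.
#' @param random random-intercept grouping variables used when \code{spec}
#'   is a spec list.
#' @return list of class \code{"nbglmmFit"}: \code{label}, \code{formula},
#'   \code{coefficients} (data.frame term/estimate/se), \code{logLik},
#'   \code{k}, \code{n}, \code{AICc}, \code{converged}, \code{model} (the
#'   underlying fit).
#' @export
fitNbGlmm <- function(spec, data, random = c("date", "time_block")) {
  if (inherits(spec, "formula")) {
    fo <- spec
    label <- deparse(fo)
  } else {
    fo <- specFormula(spec, random)
    label <- specLabel(spec)
  }
  fit <- suppressWarnings(
    glmmTMB::glmmTMB(fo, data = data, family = glmmTMB::nbinom2()))
  ll <- logLik(fit)
  sm <- summary(fit)$coefficients$cond
  conv <- fit$fit$convergence == 0 && isTRUE(fit$sdr$pdHess) &&
    all(is.finite(sm[, 1L:2L])) && is.finite(as.numeric(ll))
  n <- nrow(fit$frame)
  k <- attr(ll, "df")
  structure(list(
    label = label, formula = fo,
    coefficients = data.frame(term = rownames(sm), estimate = sm[, 1L],
                              se = sm[, 2L], row.names = NULL),
    logLik = as.numeric(ll), k = k, n = n,
    AICc = aicc(as.numeric(ll), k, n),
    converged = conv, model = fit), class = "nbglmmFit")
}

#' Choose the land-use radius by preliminary AICc
#'
#' Fits one single-predictor model per candidate radius (semi-natural
#' proportion at 300, 1000 and 2000 m) and returns the radius whose model
#' attains the lowest AICc.
#'
#' @param response response group name.
#' @param data model frame from [abundanceModelData()].
#' @param radii candidate radii (m).
#' @return list with \code{radius} (chosen, integer), \code{term}
#'   (e.g. \code{"landuse_300"}) and \code{AICc} per radius.
#' @export
selectLanduseRadius <- function(response, data, radii = RADII) {
  scores <- vapply(radii, function(r) {
    sp <- list(response = response, fixed = paste0("landuse_", r),
               interaction = FALSE)
    fitNbGlmm(sp, data)$AICc
  }, numeric(1L))
  names(scores) <- paste0("landuse_", radii)
  best <- which.min(scores)
  list(radius = radii[best], term = names(scores)[best], AICc = scores)
}

#' Rank fitted models by AICc and form full model averages
#'
#' Ranks converged fits by AICc (\eqn{\Delta} relative to the best model;
#' ties broken by smaller \eqn{k}, then label), computes Akaike weights
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)} over the whole
#' converged set, flags the substantial-support subset
#' (\eqn{\Delta \le 2}), and forms the full model average of every
#' coefficient: each term's estimate is averaged over \emph{all} models,
#' taken as 0 (with zero variance) where the term is absent. The
#' unconditional standard error follows the revised Burnham-Anderson
#' formula \eqn{\sqrt{\sum_i w_i (var_i + (\hat\beta_i - \bar\beta)^2)}};
#' \eqn{z = |\bar\beta| / SE} with a two-sided normal p-value.
#'
#' @param fits list of [fitNbGlmm()] results.
#' @return list with \code{selection} (data.frame: model, df, logLik, AICc,
#'   delta, weight, substantial) and \code{average} (data.frame: term,
#'   estimate, se, z, p).
#' @export
rankAndAverage <- function(fits) {
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  dropped <- length(fits) - length(conv)
  if (dropped)
    message(dropped, " non-convergent fit(s) excluded from ranking")
  if (!length(conv)) stop("no converged fits to rank", call. = FALSE)
  tab <- data.frame(
    model = vapply(conv, `[[`, "", "label"),
    df = vapply(conv, `[[`, 0, "k"),
    logLik = vapply(conv, `[[`, 0, "logLik"),
    AICc = vapply(conv, `[[`, 0, "AICc"))
  ord <- order(tab$AICc, tab$df, tab$model)
  tab <- tab[ord, ]
  conv <- conv[ord]
  tab$delta <- tab$AICc - tab$AICc[1L]
  w <- exp(-tab$delta / 2)
  tab$weight <- w / sum(w)
  tab$substantial <- tab$delta <= 2
  rownames(tab) <- NULL

  terms <- unique(unlist(lapply(conv, function(f) f$coefficients$term)))
  avg <- do.call(rbind, lapply(terms, function(tm) {
    est <- se <- numeric(length(conv))
    for (i in seq_along(conv)) {
      co <- conv[[i]]$coefficients
      hit <- match(tm, co$term)
      if (!is.na(hit)) {
        est[i] <- co$estimate[hit]
        se[i] <- co$se[hit]
      }
    }
    bbar <- sum(tab$weight * est)
    use <- sqrt(sum(tab$weight * (se^2 + (est - bbar)^2)))
    z <- if (is.finite(use) && use > 0) abs(bbar) / use else NA_real_
    data.frame(term = tm, estimate = bbar, se = use, z = z,
               p = if (is.na(z)) NA_real_ else 2 * pnorm(-z))
  }))
  rownames(avg) <- NULL
  list(selection = tab, average = avg)
}

#' Assemble the visitor-count modelling frame
#'
#' One row per transect x visit: the four visitor-group counts plus
#' \code{wild_bees} (bumble + other bees), the design covariates (distance
#' as a factor with 0 m reference, row orientation, stocking rate), the
#' semi-natural proportions at the three radii, and the random-effect
#' grouping factors (date, time block).
#'
#' @param study a [StudyBundle-class].
#' @return data.frame ready for [fitNbGlmm()].
#' @export
abundanceModelData <- function(study) {
  sv <- surveyData(study)
  fl <- fieldInfo(study)
  prof <- semiNaturalProfile(study)
  d <- sv
  d$wild_bees <- sv$bumble_bee + sv$other_bee
  idx <- match(d$field_id, fl$field_id)
  d$region <- fl$region[idx]
  d$row_orientation <- factor(fl$row_orientation[idx],
                              levels = c("parallel", "perpendicular"))
  d$stocking_rate <- fl$stocking_rate[idx]
  pidx <- match(d$field_id, prof$field_id)
  for (r in RADII)
    d[[paste0("landuse_", r)]] <- prof[[paste0("landuse_", r)]][pidx]
  d$distance <- factor(d$distance, levels = DISTANCES)
  d$date <- factor(d$date)
  d$time_block <- factor(d$time_block, levels = TIME_BLOCKS)
  d
}

#' Full multimodel inference for one response group in one region
#'
#' The complete abundance-modelling stage for one visitor group:
#' collinearity screening of the candidate covariates, land-use radius
#' selection by preliminary AICc, candidate-set enumeration (stocking rate
#' is screened-exempt and candidate for the honey-bee response only),
#' NB-GLMM fitting of every candidate, AICc ranking and full model
#' averaging.
#'
#' @param study a [StudyBundle-class].
#' @param response response group (\code{"wild_bees"},
#'   \code{"honey_bee"}, ...).
#' @param region region to analyse (\code{"BC"} or \code{"MI"}).
#' @param threshold collinearity screening threshold.
#' @param interaction allow the distance x land-use interaction.
#' @param covisitors other visitor groups offered as covariates.
#' @return as [rankAndAverage()], plus \code{radius} (chosen land-use
#'   radius) and \code{screen} (screening result).
#' @export
abundanceModelTable <- function(study, response, region,
                                threshold = 0.6, interaction = FALSE,
                                covisitors = character(0)) {
  d <- abundanceModelData(study)
  d <- d[d$region == region, , drop = FALSE]
  rad <- selectLanduseRadius(response, d)
  cand <- c("distance", rad$term, "row_orientation", covisitors)
  exempt <- character(0)
  if (response == "honey_bee") {
    cand <- c(cand, "stocking_rate")
    exempt <- "stocking_rate"
  }
  scr <- screenCollinearity(d, cand, threshold = threshold, exempt = exempt)
  cand <- setdiff(cand, scr$dropped)
  specs <- buildModelSet(response, cand, scr$admissible,
                         interaction = interaction)
  fits <- lapply(specs, fitNbGlmm, data = d)
  out <- rankAndAverage(fits)
  out$radius <- rad$radius
  out$screen <- scr
  out
}
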