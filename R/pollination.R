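#' Fruit set of a flower cluster
#'
#' Proportion of a cluster's counted flowers that developed into fruit.
#'
#' @param n_fruit number of developing fruit (0 <= n_fruit <= n_flowers).
#' @param n_flowers number of flowers counted at the start of the season
#'   (> 0).
#' @return n_fruit / n_flowers, vectorised.
#' @export
fruitSet <- function(n_fruit, n_flowers) {
  if (any(n_flowers <= 0))
    stop("n_flowers must be > 0", call. = FALSE)
  if (any(n_fruit < 0 | n_fruit > n_flowers))
    stop("data error: n_fruit must lie in [0, n_flowers]", call. = FALSE)
  n_fruit / n_flowers
}

#' Per-field treatment summaries
#'
#' Aggregates cluster-level outcomes to field-level means per pollination
#' treatment, averaging clusters to bushes first and bushes to fields
#' second, so bushes with unequal cluster numbers carry equal weight. Mean
#' berry weight per bush uses the focal-berry means where focal berries
#' were measured and falls back to \code{cluster_weight / n_fruit}
#' otherwise; mean mature seeds per berry comes from focal berries only.
#'
#' @param study a [StudyBundle-class] (or a list with \code{clusters} and
#'   \code{berries} data.frames).
#' @return data.frame, one row per field x treatment: \code{field_id},
#'   \code{region}, \code{treatment}, \code{fruit_set}, \code{berry_weight}
#'   (g), \code{seeds} (mature seeds per berry; NA if no focal berries),
#'   \code{n_bushes}.
#' @export
summarizeTreatments <- function(study) {
  cl <- if (is(study, "StudyBundle")) clusterData(study) else study$clusters
  br <- if (is(study, "StudyBundle")) berryData(study) else study$berries
  reg <- if (is(study, "StudyBundle")) regions(study) else NULL
  cl$fs <- fruitSet(cl$n_fruit, cl$n_flowers)
  cl$mw <- ifelse(cl$n_fruit > 0, cl$cluster_weight / cl$n_fruit, NA)
  bkey <- paste(br$field_id, br$distance, br$bush_id, br$cluster_id)
  ckey <- paste(cl$field_id, cl$distance, cl$bush_id, cl$cluster_id)
  if (nrow(br)) {
    bw <- tapply(br$weight, bkey, mean)
    bs <- tapply(br$mature_seeds, bkey, mean)
    hit <- match(ckey, names(bw))
    cl$mw <- ifelse(is.na(hit), cl$mw, unname(bw[hit]))
    cl$seeds <- unname(bs[match(ckey, names(bs))])
  } else cl$seeds <- NA_real_

  nanmean <- function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }
  bush <- aggregate(cl[, c("fs", "mw", "seeds")],
                    by = cl[, c("field_id", "distance", "bush_id",
                                "treatment")], FUN = nanmean)
  field <- aggregate(bush[, c("fs", "mw", "seeds")],
                     by = bush[, c("field_id", "treatment")], FUN = nanmean)
  nb <- aggregate(list(bush_id = bush$bush_id),
                  by = bush[, c("field_id", "treatment")], FUN = length)
  out <- data.frame(field_id = field$field_id,
                    region = if (is.null(reg)) NA_character_
                             else unname(reg[field$field_id]),
                    treatment = field$treatment,
                    fruit_set = field$fs,
                    berry_weight = field$mw,
                    seeds = field$seeds,
                    n_bushes = nb$bush_id[match(
                      paste(field$field_id, field$treatment),
                      paste(nb$field_id, nb$treatment))])
  out[order(out$field_id, match(out$treatment, TREATMENTS)), ]
}

#' Pollinator contribution and pollination deficit per field
#'
#' The pollinator contribution is the open-pollination outcome minus the
#' pollinator-exclusion outcome; the pollination deficit is the
#' hand-supplemented outcome minus the open outcome, each computed for
#' fruit set, berry weight and mature seed count. Negative values are
#' retained (sampling noise). Fields missing the open or excluded treatment
#' are excluded from contributions; fields missing the hand treatment are
#' excluded from deficits but retained for contributions. The proportion of
#' potential yield lost is derived from the weight-based yields downstream
#' in the economics stage.
#'
#' @param summary per-field treatment summary from [summarizeTreatments()].
#' @return data.frame, one row per field: \code{field_id}, \code{region},
#'   \code{contrib_fs}, \code{contrib_weight}, \code{contrib_seeds},
#'   \code{deficit_fs}, \code{deficit_weight}, \code{deficit_seeds} (NA
#'   where the needed treatment is absent).
#' @export
contributionAndDeficit <- function(summary) {
  out <- lapply(split(summary, summary$field_id), function(s) {
    g <- function(tr, col) {
      v <- s[[col]][s$treatment == tr]
      if (length(v)) v else NA_real_
    }
    data.frame(
      field_id = s$field_id[1L], region = s$region[1L],
      contrib_fs = g("open", "fruit_set") - g("excluded", "fruit_set"),
      contrib_weight = g("open", "berry_weight") - g("excluded", "berry_weight"),
      contrib_seeds = g("open", "seeds") - g("excluded", "seeds"),
      deficit_fs = g("hand", "fruit_set") - g("open", "fruit_set"),
      deficit_weight = g("hand", "berry_weight") - g("open", "berry_weight"),
      deficit_seeds = g("hand", "seeds") - g("open", "seeds"))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Nonparametric contrasts of per-field outcomes
#'
#' Kruskal-Wallis test (with tie correction) across the groups, followed by
#' all pairwise two-sided Mann-Whitney tests (exact p-values when the
#' smaller group has at most \code{exact_max} observations and no ties;
#' normal approximation with continuity and tie correction otherwise), and
#' a Tukey-style compact letter display built from the pairwise decisions
#' at \code{alpha}. If every value is tied across all groups, the
#' chi-squared statistic is 0, p is 1 and all groups share one letter.
#'
#' A Dunn-style alternative with Holm adjustment of the pairwise p-values is
#' available via \code{adjust = "holm"} (off by default: the primary path
#' reports unadjusted pairwise Mann-Whitney decisions).
#'
#' @param values numeric outcome, one value per field.
#' @param groups grouping factor (treatment or distance), >= 2 groups with
#'   >= 2 fields each.
#' @param alpha significance level for the letter display.
#' @param exact_max largest minimum group size for which exact Mann-Whitney
#'   p-values are attempted.
#' @param adjust p-value adjustment across the pairwise tests ("none" or
#'   "holm").
#' @return list with \code{kruskal} (one-row data.frame: chisq, df, p),
#'   \code{pairwise} (data.frame: group1, group2, U, p, p_adj),
#'   \code{letters} (named character vector) and \code{means} (group
#'   means).
#' @export
treatmentContrasts <- function(values, groups, alpha = 0.05,
                               exact_max = 8L, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  groups <- factor(groups)
  keep <- complete.cases(values, groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  sizes <- table(groups)
  if (length(sizes) < 2L || any(sizes < 2L))
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  lev <- levels(groups)
  if (length(unique(values)) == 1L) {
    kw <- data.frame(chisq = 0, df = length(lev) - 1L, p = 1)
    pw <- as.data.frame(t(combn(lev, 2L)))
    names(pw) <- c("group1", "group2")
    pw$U <- vapply(seq_len(nrow(pw)), function(i)
      unname(sizes[pw$group1[i]] * sizes[pw$group2[i]] / 2), numeric(1L))
    pw$p <- 1; pw$p_adj <- 1
    ltr <- setNames(rep("a", length(lev)), lev)
    return(list(kruskal = kw, pairwise = pw, letters = ltr,
                means = tapply(values, groups, mean)))
  }
  k <- kruskal.test(values, groups)
  kw <- data.frame(chisq = unname(k$statistic),
                   df = unname(k$parameter), p = k$p.value)
  prs <- combn(lev, 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
    x <- values[groups == prs[1L, i]]
    y <- values[groups == prs[2L, i]]
    w <- safeWilcox(x, y, exact_max)
    data.frame(group1 = prs[1L, i], group2 = prs[2L, i], U = w$U, p = w$p)
  }))
  pw$p_adj <- if (adjust == "holm") p.adjust(pw$p, "holm") else pw$p
  diffmat <- matrix(FALSE, length(lev), length(lev),
                    dimnames = list(lev, lev))
  for (i in seq_len(nrow(pw)))
    diffmat[pw$group1[i], pw$group2[i]] <-
      diffmat[pw$group2[i], pw$group1[i]] <- pw$p_adj[i] < alpha
  list(kruskal = kw, pairwise = pw, letters = compactLetters(diffmat),
       means = tapply(values, groups, mean))
}

#' Seed-weight analysis of covariance across regions
#'
#' Tests whether the relationship between pollination-driven seed gain and
#' berry-weight gain differs between regions: a linear model
#' \code{delta_weight ~ delta_seeds * region} provides the interaction F
#' (difference in slopes); the additive model provides the common slope and
#' per-region intercepts with standard errors.
#'
#' @param effects per-field effects from [contributionAndDeficit()].
#' @param which which effect pair to relate: \code{"contribution"}
#'   (open - excluded, the default) or \code{"deficit"}.
#' @return list with \code{slope}, \code{slope_se} (common slope, g per
#'   seed), \code{intercepts} (data.frame: region, intercept, se),
#'   \code{interaction_F}, \code{interaction_p}, \code{n}.
#' @export
seedWeightAncova <- function(effects, which = c("contribution", "deficit")) {
  which <- match.arg(which)
  cols <- if (which == "contribution") c("contrib_seeds", "contrib_weight")
          else c("deficit_seeds", "deficit_weight")
  d <- data.frame(seeds = effects[[cols[1L]]],
                  weight = effects[[cols[2L]]],
                  region = factor(effects$region))
  d <- d[complete.cases(d), ]
  if (any(table(d$region) < 3L))
    stop("need >= 3 fields per region", call. = FALSE)
  if (sd(d$seeds) == 0)
    stop("undefined slope: seed effect is constant", call. = FALSE)
  full <- lm(weight ~ seeds * region, data = d)
  add <- lm(weight ~ seeds + region, data = d)
  rss_add <- sum(add$residuals^2)
  rss_full <- sum(full$residuals^2)
  df2 <- full$df.residual
  num <- rss_add - rss_full
  # an exactly collinear configuration has a zero slope difference, not a
  # 0/0 artefact
  if (num <= 1e-10 * max(1, rss_add)) {
    Fint <- 0; pint <- 1
  } else {
    Fint <- num / (rss_full / df2)
    pint <- stats::pf(Fint, 1L, df2, lower.tail = FALSE)
  }
  co <- summary(add)$coefficients
  regs <- levels(d$region)
  ints <- data.frame(region = regs, intercept = NA_real_, se = NA_real_)
  # reference-region intercept straight from the fit; others by releveling
  for (i in seq_along(regs)) {
    fit_i <- lm(weight ~ seeds + relevel(region, regs[i]), data = d)
    ci <- summary(fit_i)$coefficients
    ints$intercept[i] <- ci["(Intercept)", 1L]
    ints$se[i] <- ci["(Intercept)", 2L]
  }
  list(slope = co["seeds", 1L], slope_se = co["seeds", 2L],
       intercepts = ints,
       interaction_F = Fint, interaction_p = pint,
       n = nrow(d))
}
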