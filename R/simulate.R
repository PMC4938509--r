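#' Default simulation configuration for the two-region study design
#'
#' Returns the full parameter set of the synthetic-study generator, with
#' defaults emulating the field design: 17 fields per region, four 10-minute
#' transects per field at 0/25/50/100 m from the semi-natural border, 2 (BC)
#' or 3 (MI) visits, a species-poor bumble-bee-dominated community in BC
#' versus a species-rich community in MI, semi-natural proportions
#' uncorrelated across radii in BC but strongly correlated in MI, and
#' cluster-level pollination treatments with a configurable per-region
#' pollination deficit (the hand-supplemented treatment equals the open
#' treatment plus the deficit terms, so a zero deficit makes the two
#' treatments exchangeable).
#'
#' Visitation coefficients are on the log scale of a negative-binomial model
#' (NB2, dispersion \code{theta}) with normal random intercepts for sample
#' date and time block; magnitudes are loose, order-of-magnitude analogues
#' of published model-averaged coefficients for this system, not fitted
#' values.
#'
#' @param ... named overrides, merged recursively into the defaults (e.g.
#'   \code{simulationConfig(n_fields_per_region = 5)}).
#' @return nested named list of generator parameters.
#' @export
simulationConfig <- function(...) {
  cfg <- list(
    n_fields_per_region = 17L,
    visits = c(BC = 2L, MI = 3L),
    design = list(bushes_per_transect = 10L, focal_bushes = 4L,
                  focal_berries = 3L, flowers_mean = 8),
    theta = 1.5,
    re_sd = c(date = 0.3, time_block = 0.15),
    bloom_days = 21L,
    pools = list(BC = list(pool = 11L, x = 0.5),
                 MI = list(pool = 72L, x = 0.95)),
    specimens_per_field = c(BC = 24, MI = 36),
    landscape = list(
      BC = list(mean = c(`300` = 0.08, `1000` = 0.15, `2000` = 0.20),
                sd = c(`300` = 0.05, `1000` = 0.08, `2000` = 0.10),
                rho = 0),
      MI = list(mean = c(`300` = 0.45, `1000` = 0.50, `2000` = 0.55),
                sd = c(`300` = 0.15, `1000` = 0.15, `2000` = 0.15),
                rho = 0.8)),
    visitation = list(
      BC = list(
        honey_bee = list(intercept = 0.7, distance = c(0, 0, 0),
                         landuse = 12, radius = 300, orientation = 0),
        bumble_bee = list(intercept = -1.0, distance = c(0, 0, 0),
                          landuse = 4, radius = 2000, orientation = 0.5),
        other_bee = list(intercept = -1.8, distance = c(0, 0, 0),
                         landuse = 2, radius = 2000, orientation = 0.5),
        other_visitor = list(intercept = -1.5, distance = c(0, 0, 0),
                             landuse = 0, radius = 300, orientation = 0)),
      MI = list(
        honey_bee = list(intercept = 2.5, distance = c(0, 0, 0),
                         landuse = -1.5, radius = 1000, orientation = 0),
        bumble_bee = list(intercept = -2.4, distance = c(-0.9, -1.5, -2.0),
                          landuse = 5, radius = 300, orientation = 0.9),
        other_bee = list(intercept = -2.7, distance = c(-0.9, -1.5, -2.0),
                         landuse = 5, radius = 300, orientation = 0.9),
        other_visitor = list(intercept = -1.8, distance = c(0, 0, 0),
                             landuse = 0, radius = 300, orientation = 0))),
    stocking = list(BC = c(0, 39.5), MI = c(4.9, 9.4)),
    spacing = c(bush = 1.2, row = 3.0),
    yield_components = list(canes_per_bush = c(15, 2),
                            clusters_per_cane = c(25, 3),
                            berries_per_cluster = c(6.5, 0.8)),
    treatments = list(
      BC = list(fs = c(excluded = 0.45, open = 0.65),
                seeds = c(excluded = 5, open = 14),
                fs_deficit = 0.08, seed_deficit = 11,
                weight = c(a = 1.44, b = 0.04, sd = 0.15)),
      MI = list(fs = c(excluded = 0.30, open = 0.80),
                seeds = c(excluded = 4, open = 20),
                fs_deficit = 0.03, seed_deficit = 1,
                weight = c(a = 1.44, b = 0.04, sd = 0.15))),
    prices = c(BC = 3.30, MI = 2.84)
  )
  modifyList(cfg, list(...))
}

checkSimulationConfig <- function(cfg) {
  for (r in REGIONS) {
    tr <- cfg$treatments[[r]]
    p <- c(tr$fs, tr$fs["open"] + tr$fs_deficit)
    if (any(p < 0 | p > 1))
      stop("configuration error: fruit-set probabilities outside [0, 1] for ",
           r, call. = FALSE)
    if (any(c(tr$seeds, tr$seeds["open"] + tr$seed_deficit) < 0))
      stop("configuration error: negative seed means for ", r, call. = FALSE)
    ls <- cfg$landscape[[r]]
    if (any(ls$mean < 0 | ls$mean > 1))
      stop("configuration error: semi-natural means outside [0, 1]",
           call. = FALSE)
    R <- matrix(ls$rho, 3L, 3L); diag(R) <- 1
    ok <- tryCatch({ chol(R); TRUE }, error = function(e) FALSE)
    if (!ok)
      stop("configuration error: cross-radius correlation matrix for ", r,
           " is not positive definite", call. = FALSE)
    if (cfg$pools[[r]]$pool < 1L)
      stop("configuration error: species pool must be >= 1", call. = FALSE)
  }
  if (cfg$theta <= 0)
    stop("configuration error: NB dispersion theta must be > 0",
         call. = FALSE)
  invisible(cfg)
}

# Fisher log-series abundance sampler: pmf(k) proportional to x^k / k.
rlogseries <- function(n, x, kmax = 1000L) {
  k <- seq_len(kmax)
  p <- x^k / k
  sample(k, n, replace = TRUE, prob = p)
}

#' Simulate land-cover composition around fields
#'
#' Draws per-field semi-natural proportions at the three radii from a
#' Gaussian copula with region-specific means, SDs and cross-radius
#' correlation (clamped to [0.01, 0.99]), then expands each proportion into
#' cover-class areas (woodland, unmowed grassland and marsh inside the
#' semi-natural share; agriculture, urban and mowed area inside the
#' disturbed share) over the full buffer area \eqn{\pi r^2}.
#'
#' @param fields data.frame with \code{field_id} and \code{region}.
#' @param params per-region landscape parameters
#'   (see [simulationConfig()]).
#' @param seed integer seed.
#' @return landscape data.frame (field_id, radius_m, cover_class, area_m2).
#' @export
simulateLandscape <- function(fields, params, seed = 1L) {
  semi_split <- c(woodland = 0.60, unmowed_grassland = 0.25, marsh = 0.15)
  dist_split <- c(agriculture = 0.50, urban = 0.30, mowed_area = 0.20)
  withSeed(seed, {
    rows <- list()
    for (i in seq_len(nrow(fields))) {
      pr <- params[[fields$region[i]]]
      R <- matrix(pr$rho, 3L, 3L); diag(R) <- 1
      z <- drop(t(chol(R)) %*% rnorm(3L))
      p <- pmin(pmax(pr$mean + pr$sd * z, 0.01), 0.99)
      for (j in seq_along(RADII)) {
        A <- pi * RADII[j]^2
        shares <- c(p[j] * semi_split, (1 - p[j]) * dist_split)
        rows[[length(rows) + 1L]] <- data.frame(
          field_id = fields$field_id[i], radius_m = RADII[j],
          cover_class = names(shares), area_m2 = unname(A * shares))
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate timed visitation counts
#'
#' Generates one survey row per field x transect x visit. Counts per
#' visitor group are negative-binomial (NB2, dispersion \code{theta}) on a
#' log link: linear predictor = intercept + distance effect (0 m reference)
#' + land-use slope x semi-natural proportion at the group's radius + row
#' orientation effect (perpendicular) + normal random intercepts for date
#' and time block.
#'
#' @param fields data.frame with \code{field_id}, \code{region},
#'   \code{row_orientation}.
#' @param landuse per-field semi-natural profile
#'   ([semiNaturalProfile()] layout).
#' @param coefs per-group coefficient lists (a single region's entry of
#'   \code{simulationConfig()$visitation}).
#' @param theta NB dispersion (> 0); \code{Inf} gives the Poisson limit.
#' @param re_sd named SDs of the date and time-block random intercepts
#'   (zeros remove the random effects).
#' @param n_visits visits per field.
#' @param bloom_start,bloom_days calendar window the visit dates are drawn
#'   from.
#' @param seed integer seed.
#' @return surveys data.frame in the canonical schema.
#' @export
simulateVisitCounts <- function(fields, landuse, coefs, theta = 1.5,
                                re_sd = c(date = 0.3, time_block = 0.15),
                                n_visits = 2L,
                                bloom_start = "2013-05-01",
                                bloom_days = 21L, seed = 1L) {
  groups <- names(coefs)
  withSeed(seed, {
    days <- as.character(as.Date(bloom_start) + seq_len(bloom_days) - 1L)
    u_date <- setNames(rnorm(length(days), 0, re_sd[["date"]]), days)
    u_time <- setNames(rnorm(length(TIME_BLOCKS), 0, re_sd[["time_block"]]),
                       TIME_BLOCKS)
    rows <- list()
    for (i in seq_len(nrow(fields))) {
      vdays <- sample(days, n_visits)
      perp <- fields$row_orientation[i] == "perpendicular"
      li <- match(fields$field_id[i], landuse$field_id)
      for (v in seq_len(n_visits)) {
        tb <- sample(TIME_BLOCKS, 1L)
        for (k in seq_along(DISTANCES)) {
          cnt <- vapply(groups, function(g) {
            b <- coefs[[g]]
            eta <- b$intercept +
              (if (k > 1L) b$distance[k - 1L] else 0) +
              b$landuse * landuse[[paste0("landuse_", b$radius)]][li] +
              b$orientation * perp +
              u_date[[vdays[v]]] + u_time[[tb]]
            if (!is.finite(eta))
              stop("simulation error: non-finite linear predictor",
                   call. = FALSE)
            mu <- exp(eta)
            if (is.infinite(theta)) rpois(1L, mu)
            else rnbinom(1L, mu = mu, size = theta)
          }, numeric(1L))
          getc <- function(nm) if (nm %in% names(cnt)) cnt[[nm]] else 0
          rows[[length(rows) + 1L]] <- data.frame(
            field_id = fields$field_id[i], distance = DISTANCES[k],
            date = vdays[v], time_block = tb, duration = 10L,
            honey_bee = getc("honey_bee"),
            bumble_bee = getc("bumble_bee"),
            other_bee = getc("other_bee"),
            other_visitor = getc("other_visitor"))
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate pollination treatment outcomes
#'
#' For every bush, three flower clusters are assigned one treatment each
#' (exclusion, open, hand-supplemented). Flower counts are
#' 1 + Poisson(\code{flowers_mean} - 1); fruit counts are binomial with the
#' treatment's fruit-set probability; each fruit carries a Poisson mature
#' seed count at the treatment's seed mean and a berry weight following the
#' linear law weight = a + b x seeds + Normal(0, sd) (floored at 0.01 g).
#' Cluster weight is the sum of its berry weights, so weight-per-fruit is
#' exactly consistent with the underlying berries. Focal-berry rows (up to
#' \code{focal_berries} per cluster) are recorded for \code{focal_bushes}
#' randomly chosen bushes per transect. The hand treatment equals the open
#' treatment shifted by the configured fruit-set and seed deficits.
#'
#' @param fields data.frame with \code{field_id} and \code{region}.
#' @param treatments per-region treatment parameters
#'   (\code{simulationConfig()$treatments}).
#' @param design cluster-design parameters
#'   (\code{simulationConfig()$design}).
#' @param seed integer seed.
#' @return list with \code{clusters} and \code{berries} data.frames.
#' @export
simulatePollinationOutcomes <- function(fields, treatments,
                                        design = simulationConfig()$design,
                                        seed = 1L) {
  withSeed(seed, {
    clusters <- list(); berries <- list()
    for (i in seq_len(nrow(fields))) {
      tr <- treatments[[fields$region[i]]]
      p <- c(excluded = unname(tr$fs[["excluded"]]),
             open = unname(tr$fs[["open"]]),
             hand = unname(tr$fs[["open"]]) + tr$fs_deficit)
      lam <- c(excluded = unname(tr$seeds[["excluded"]]),
               open = unname(tr$seeds[["open"]]),
               hand = unname(tr$seeds[["open"]]) + tr$seed_deficit)
      w <- tr$weight
      for (d in DISTANCES) {
        focal <- sample.int(design$bushes_per_transect,
                            min(design$focal_bushes,
                                design$bushes_per_transect))
        for (b in seq_len(design$bushes_per_transect)) {
          for (t in TREATMENTS) {
            nf <- 1L + rpois(1L, max(design$flowers_mean - 1, 0))
            nfr <- rbinom(1L, nf, p[[t]])
            if (nfr > 0) {
              seeds <- rpois(nfr, lam[[t]])
              wts <- pmax(w[["a"]] + w[["b"]] * seeds +
                            rnorm(nfr, 0, w[["sd"]]), 0.01)
            } else { seeds <- integer(0); wts <- numeric(0) }
            cid <- paste0(t, "_", b)
            clusters[[length(clusters) + 1L]] <- data.frame(
              field_id = fields$field_id[i], distance = d, bush_id = b,
              cluster_id = cid, treatment = t, n_flowers = nf,
              n_fruit = nfr, cluster_weight = round(sum(wts), 4L))
            if (b %in% focal && nfr > 0) {
              nb <- min(design$focal_berries, nfr)
              berries[[length(berries) + 1L]] <- data.frame(
                field_id = fields$field_id[i], distance = d, bush_id = b,
                cluster_id = cid, berry_id = seq_len(nb),
                weight = round(wts[seq_len(nb)], 4L),
                mature_seeds = seeds[seq_len(nb)])
            }
          }
        }
      }
    }
    list(clusters = do.call(rbind, clusters),
         berries = if (length(berries)) do.call(rbind, berries)
                   else data.frame(field_id = character(0),
                                   distance = integer(0),
                                   bush_id = integer(0),
                                   cluster_id = character(0),
                                   berry_id = integer(0),
                                   weight = numeric(0),
                                   mature_seeds = integer(0)))
  })
}

simulateSpecimens <- function(fields, pools, per_field, seed = 1L) {
  withSeed(seed, {
    rows <- list()
    for (r in REGIONS) {
      idx <- which(fields$region == r)
      if (!length(idx)) next
      pool <- pools[[r]]$pool
      wts <- sort(rlogseries(pool, pools[[r]]$x), decreasing = TRUE)
      sp <- sprintf("%s_sp%03d", tolower(r), seq_len(pool))
      for (i in idx) {
        tot <- rpois(1L, per_field[[r]])
        if (tot == 0L) next
        cnt <- drop(rmultinom(1L, tot, wts))
        keep <- cnt > 0
        rows[[length(rows) + 1L]] <- data.frame(
          field_id = fields$field_id[i], species_id = sp[keep],
          count = as.integer(cnt[keep]))
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a complete synthetic study with known ground truth
#'
#' Builds a validated [StudyBundle-class] emulating the two-region field
#' design, together with the ground truth that produced it (visitation
#' coefficients and dispersion, random-effect SDs, species pool sizes,
#' per-region treatment parameters and deficits, landscape parameters).
#' One master seed governs all sub-generators through derived sub-stream
#' seeds, so partial re-runs of a sub-generator reproduce exactly.
#'
#' @param config a [simulationConfig()] list.
#' @param seed master integer seed.
#' @return list with \code{study} (StudyBundle) and \code{truth} (list).
#' @export
simulateStudy <- function(config = simulationConfig(), seed = 1L) {
  checkSimulationConfig(config)
  nf <- config$n_fields_per_region
  fields <- withSeed(deriveSeed(seed, "fields"), {
    do.call(rbind, lapply(REGIONS, function(r) {
      yc <- config$yield_components
      tn <- function(ms, n) pmax(rnorm(n, ms[1L], ms[2L]), 0.1 * ms[1L])
      data.frame(
        field_id = sprintf("%s%02d", r, seq_len(nf)),
        region = r,
        stocking_rate = round(runif(nf, config$stocking[[r]][1L],
                                    config$stocking[[r]][2L]), 1L),
        row_orientation = sample(c("parallel", "perpendicular"), nf,
                                 replace = TRUE),
        bush_spacing = config$spacing[["bush"]],
        row_spacing = config$spacing[["row"]],
        canes_per_bush = round(tn(yc$canes_per_bush, nf), 1L),
        clusters_per_cane = round(tn(yc$clusters_per_cane, nf), 1L),
        berries_per_cluster = round(tn(yc$berries_per_cluster, nf), 2L),
        price = unname(config$prices[r]))
    }))
  })
  landscape <- simulateLandscape(fields, config$landscape,
                                 deriveSeed(seed, "landscape"))
  prof <- semiNaturalProfile(landscape)
  surveys <- do.call(rbind, lapply(REGIONS, function(r) {
    fl <- fields[fields$region == r, ]
    simulateVisitCounts(fl, prof, config$visitation[[r]],
                        theta = config$theta, re_sd = config$re_sd,
                        n_visits = config$visits[[r]],
                        bloom_days = config$bloom_days,
                        seed = deriveSeed(seed, paste0("visits_", r)))
  }))
  specimens <- simulateSpecimens(fields, config$pools,
                                 config$specimens_per_field,
                                 deriveSeed(seed, "specimens"))
  poll <- simulatePollinationOutcomes(fields, config$treatments,
                                      config$design,
                                      deriveSeed(seed, "pollination"))
  study <- StudyBundle(fields = fields, surveys = surveys,
                       specimens = specimens, clusters = poll$clusters,
                       berries = poll$berries, landscape = landscape,
                       config = list(seed = seed))
  truth <- list(
    visitation = config$visitation, theta = config$theta,
    re_sd = config$re_sd,
    pools = vapply(config$pools, `[[`, 0L, "pool"),
    treatments = config$treatments,
    deficits = lapply(config$treatments, function(tr) list(
      fs = tr$fs_deficit, seeds = tr$seed_deficit,
      weight = unname(tr$weight[["b"]]) * tr$seed_deficit)),
    landscape = config$landscape)
  list(study = study, truth = truth)
}
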