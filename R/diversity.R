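#' Chao-1 species richness estimator
#'
#' Classic (uncorrected) Chao-1 lower-bound estimate of species richness
#' from an abundance vector. With \eqn{f_1} singletons and \eqn{f_2}
#' doubletons,
#' \deqn{\hat S = S_{obs} + f_1^2 / (2 f_2)}
#' when \eqn{f_2 > 0}, and the \eqn{f_2 = 0} fallback
#' \eqn{\hat S = S_{obs} + f_1 (f_1 - 1) / 2} otherwise. The estimate never
#' falls below the observed richness; equality holds when \eqn{f_1 \le 1}.
#'
#' @param x non-negative integer abundance vector (zeros allowed; at least
#'   one positive entry required).
#' @return one-row data.frame with \code{S_obs}, \code{f1}, \code{f2},
#'   \code{chao1} (unrounded) and \code{chao1_rounded} (nearest integer).
#' @examples
#' chao1(c(1, 1, 2))$chao1   # 3 + 2^2/(2*1) = 5
#' @export
chao1 <- function(x) {
  x <- checkAbundances(x)
  s <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  est <- if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / 2
  data.frame(S_obs = s, f1 = f1, f2 = f2, chao1 = est,
             chao1_rounded = round(est))
}

#' Shannon-Wiener diversity index
#'
#' \eqn{H = -\sum p_i \ln p_i} over species with positive abundance,
#' in nats (natural logarithm). Zero if and only if at most one species is
#' present.
#'
#' @inheritParams chao1
#' @return H in nats.
#' @export
shannonIndex <- function(x) {
  x <- checkAbundances(x)
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

checkAbundances <- function(x) {
  x <- as.numeric(x)
  if (!length(x) || anyNA(x) || any(x < 0) || any(x != round(x)))
    stop("abundances must be non-negative integers", call. = FALSE)
  if (all(x == 0))
    stop("undefined for an all-zero abundance vector", call. = FALSE)
  x
}

#' Sample-based species accumulation (rarefaction) curve
#'
#' Accumulated species richness as sites are added in random order, averaged
#' over \code{n_perm} permutations of site order. The envelope is the mean
#' plus or minus two standard deviations across permutations. With
#' \code{exhaustive = TRUE} (feasible for up to about 7 sites) all site
#' orderings are enumerated instead of sampled.
#'
#' @param mat site x species abundance (or incidence) matrix.
#' @param n_perm number of random site orderings (>= 2).
#' @param seed integer seed for the permutations.
#' @param exhaustive enumerate all orderings instead of sampling.
#' @return data.frame with columns \code{m} (sites), \code{mean}, \code{sd},
#'   \code{lo}, \code{hi} (mean -/+ 2 sd).
#' @export
accumulationCurve <- function(mat, n_perm = 999, seed = 1L,
                              exhaustive = FALSE) {
  mat <- as.matrix(mat) > 0
  n <- nrow(mat)
  if (n < 1L) stop("need at least one site", call. = FALSE)
  orders <- if (exhaustive) {
    if (n > 7L) stop("exhaustive enumeration limited to 7 sites", call. = FALSE)
    allPermutations(n)
  } else {
    if (n_perm < 2L)
      stop("n_perm must be >= 2 for a defined standard deviation",
           call. = FALSE)
    withSeed(seed, replicate(n_perm, sample.int(n), simplify = FALSE))
  }
  rich <- vapply(orders, function(o) {
    seen <- rep(FALSE, ncol(mat))
    out <- numeric(n)
    for (i in seq_len(n)) {
      seen <- seen | mat[o[i], ]
      out[i] <- sum(seen)
    }
    out
  }, numeric(n))
  rich <- matrix(rich, nrow = n)
  mu <- rowMeans(rich)
  sdev <- apply(rich, 1L, sd)
  data.frame(m = seq_len(n), mean = mu, sd = sdev,
             lo = mu - 2 * sdev, hi = mu + 2 * sdev)
}

allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- allPermutations(n - 1L)
    out <- c(out, lapply(rest, function(p) c(i, setdiff(seq_len(n), i)[p])))
  }
  out
}

#' Per-field and regional diversity statistics
#'
#' Pools each field's netted specimens across transects and visits and
#' reports observed richness, singleton and doubleton counts, Chao-1 and
#' Shannon-Wiener H per field, plus one pooled row per region and one for
#' the whole study. Honey bees are excluded upstream by the specimen-matrix
#' invariant.
#'
#' @param study a [StudyBundle-class].
#' @return data.frame with columns \code{unit} ("field", "region",
#'   "study"), \code{id}, \code{region}, \code{S_obs}, \code{f1}, \code{f2},
#'   \code{chao1}, \code{chao1_rounded}, \code{shannon}.
#' @export
diversityStats <- function(study) {
  m <- specimenMatrix(study)
  reg <- regions(study)
  one <- function(unit, id, region, x) {
    cbind(data.frame(unit = unit, id = id, region = region), chao1(x),
          data.frame(shannon = shannonIndex(x)))
  }
  rows <- lapply(rownames(m), function(f)
    one("field", f, unname(reg[f]), m[f, ]))
  for (r in REGIONS) {
    sub <- m[reg[rownames(m)] == r, , drop = FALSE]
    if (nrow(sub)) rows <- c(rows, list(one("region", r, r, colSums(sub))))
  }
  rows <- c(rows, list(one("study", "all", "all", colSums(m))))
  do.call(rbind, rows)
}

#' Between-region diversity tests
#'
#' Compares per-field diversity between the two regions: Welch two-sample
#' t-test on observed richness, and two-sided Mann-Whitney tests on the
#' Chao-1 estimates and on Shannon H (exact p-values when sample sizes
#' permit and there are no ties).
#'
#' @param stats per-field diversity table from [diversityStats()] (rows with
#'   \code{unit == "field"} are used).
#' @return data.frame with columns \code{metric}, \code{test},
#'   \code{statistic}, \code{df} (NA for U tests), \code{p}.
#' @export
regionalDiversityTests <- function(stats) {
  st <- stats[stats$unit == "field", ]
  groups <- split(st, st$region)
  if (length(groups) < 2L || any(vapply(groups, nrow, 1L) < 2L))
    stop("need at least two fields in each of two regions", call. = FALSE)
  a <- groups[[1L]]; b <- groups[[2L]]
  tt <- tryCatch(t.test(a$S_obs, b$S_obs), error = function(e) {
    # essentially-constant data: equal means are a null result
    if (isTRUE(all.equal(mean(a$S_obs), mean(b$S_obs))))
      list(statistic = c(t = 0), parameter = c(df = NA_real_), p.value = 1)
    else stop(e)
  })
  mw <- function(metric, x, y) {
    w <- safeWilcox(x, y)
    data.frame(metric = metric, test = "mann_whitney",
               statistic = w$U, df = NA_real_, p = w$p)
  }
  rbind(
    data.frame(metric = "S_obs", test = "welch_t",
               statistic = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value),
    mw("chao1", a$chao1, b$chao1),
    mw("shannon", a$shannon, b$shannon))
}
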