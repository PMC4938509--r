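#' Bray-Curtis dissimilarity among fields
#'
#' Pairwise Bray-Curtis dissimilarity
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} between the rows
#' of an abundance matrix (fields pooled across transects and visits).
#' Values lie in [0, 1]: 0 for identical abundance vectors, 1 for fields
#' sharing no species.
#'
#' @param mat field x species abundance matrix with rownames.
#' @param transform optional count transformation applied first: "none"
#'   (default, raw counts), "sqrt", or "wisconsin" (double standardisation).
#' @return a \code{\link[stats]{dist}} object with field labels.
#' @export
brayCurtis <- function(mat, transform = c("none", "sqrt", "wisconsin")) {
  transform <- match.arg(transform)
  mat <- as.matrix(mat)
  zero <- rowSums(mat) == 0
  if (any(zero))
    stop("undefined distance: all-zero abundance row(s): ",
         paste(rownames(mat)[zero], collapse = ", "), call. = FALSE)
  if (transform == "sqrt") mat <- sqrt(mat)
  if (transform == "wisconsin") {
    mat <- sweep(mat, 2L, apply(mat, 2L, max), "/")
    mat <- sweep(mat, 1L, rowSums(mat), "/")
  }
  n <- nrow(mat)
  out <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    out[i, j] <- out[j, i] <-
      sum(abs(mat[i, ] - mat[j, ])) / sum(mat[i, ] + mat[j, ])
  }
  as.dist(out)
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Global NMDS minimising Kruskal stress-1 by iterative monotone (isotonic)
#' regression of configuration distances on the dissimilarities
#' (vegan's \code{monoMDS} engine). The search runs from a classical-scaling
#' (principal coordinates) start plus \code{n_restarts - 1} random starts and
#' keeps the lowest-stress solution. The returned configuration is centred
#' at the origin and rotated to its principal axes.
#'
#' @param d dissimilarities (\code{dist} or symmetric matrix).
#' @param k number of ordination dimensions (default 2).
#' @param n_restarts total number of starts (>= 1).
#' @param max_iter,tol iteration cap and stress-change convergence tolerance
#'   passed to the engine.
#' @param seed integer seed for the random starts.
#' @return list with \code{points} (n x k matrix), \code{stress} (Kruskal
#'   stress-1 in [0, 1]), \code{n_restarts}, \code{converged}.
#' @export
nmdsOrdination <- function(d, k = 2L, n_restarts = 100L, max_iter = 500L,
                           tol = 1e-6, seed = 1L) {
  d <- as.dist(d)
  n <- attr(d, "Size")
  if (n < k + 1L) stop("need at least k + 1 points", call. = FALSE)
  init <- cmdscale(d, k = k)
  if (ncol(init) < k)
    init <- cbind(init, matrix(0, n, k - ncol(init)))
  starts <- withSeed(seed, c(list(init), lapply(
    seq_len(max(0L, n_restarts - 1L)),
    function(i) matrix(runif(n * k, -1, 1), n, k))))
  best <- NULL
  for (s in starts) {
    fit <- vegan::monoMDS(d, y = s, k = k, model = "global",
                          maxit = max_iter, sratmax = 1 - tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  pts <- pts %*% prcomp(pts, center = FALSE)$rotation
  dimnames(pts) <- list(attr(d, "Labels"), paste0("NMDS", seq_len(k)))
  list(points = pts, stress = best$stress, n_restarts = length(starts),
       converged = best$icause != 1L)
}

#' Kruskal stress-1 of a configuration against dissimilarities
#'
#' Recomputes \eqn{\sqrt{\sum (d^{conf} - \hat d)^2 / \sum (d^{conf})^2}}
#' where \eqn{\hat d} is the monotone (isotonic) regression of the
#' configuration distances on the dissimilarity order. Invariant under
#' rigid rotation, reflection and uniform scaling of the configuration.
#'
#' @param points n x k configuration matrix.
#' @param d the dissimilarities the ordination was fitted to.
#' @return stress-1 value in [0, 1].
#' @export
kruskalStress <- function(points, d) {
  dv <- as.vector(as.dist(d))
  cv <- as.vector(dist(points))
  ord <- order(dv, cv)
  fit <- isoreg(cv[ord])$yf
  sqrt(sum((cv[ord] - fit)^2) / sum(cv^2))
}

#' Fit an environmental vector to an ordination
#'
#' Least-squares regression of a per-field variable on the ordination axes.
#' The fitted direction (unit vector) points toward increasing values of the
#' variable; its strength is the squared multiple correlation r^2, with a
#' permutation p-value obtained by permuting the variable across fields.
#'
#' @param ordination result of [nmdsOrdination()] (or any list with a
#'   \code{points} matrix).
#' @param variable numeric vector, one value per ordinated field.
#' @param n_perm number of permutations for the p-value.
#' @param seed integer seed.
#' @return one-row data.frame: direction coordinates (\code{dir1} ...),
#'   \code{r2}, \code{p}.
#' @export
envfitVector <- function(ordination, variable, n_perm = 999, seed = 1L) {
  X <- ordination$points
  if (length(variable) != nrow(X))
    stop("variable must have one value per ordinated field", call. = FALSE)
  if (sd(variable) == 0)
    stop("undefined direction: variable is constant", call. = FALSE)
  r2of <- function(v) {
    f <- lm.fit(cbind(1, X), v)
    1 - sum(f$residuals^2) / sum((v - mean(v))^2)
  }
  b <- lm.fit(cbind(1, X), variable)$coefficients[-1L]
  dir <- b / sqrt(sum(b^2))
  r2 <- r2of(variable)
  perm <- withSeed(seed, replicate(n_perm, r2of(sample(variable))))
  p <- (1 + sum(perm >= r2)) / (1 + n_perm)
  out <- as.data.frame(as.list(setNames(dir, paste0("dir", seq_along(dir)))))
  out$r2 <- r2
  out$p <- p
  out
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the squared dissimilarities among groups
#' (Gower-centred partition): with total sum of squares
#' \eqn{SS_T = \sum_{i<j} d_{ij}^2 / n} and within-group
#' \eqn{SS_W = \sum_g \sum_{i<j \in g} d_{ij}^2 / n_g}, the pseudo-F is
#' \eqn{((SS_T - SS_W)/(a-1)) / (SS_W/(n-a))}. Significance is assessed by
#' free permutation of the observation labels, upper tail, with
#' \eqn{p = (1 + \#\{F^{perm} \ge F\}) / (1 + n_{perm})}; with
#' \code{exhaustive = TRUE} (two groups) all distinct label splits are
#' enumerated and \eqn{p = \#\{F^{perm} \ge F\} / n_{splits}} (the observed
#' split included).
#'
#' @param d dissimilarities (\code{dist} or symmetric matrix).
#' @param groups group label per observation (>= 2 groups, each >= 2
#'   members).
#' @param n_perm number of random permutations.
#' @param seed integer seed.
#' @param exhaustive enumerate all label splits (two groups only).
#' @return one-row data.frame: \code{F}, \code{df_between}, \code{df_within},
#'   \code{R2}, \code{p}, \code{n_perm}.
#' @export
permanovaTest <- function(d, groups, n_perm = 999, seed = 1L,
                          exhaustive = FALSE) {
  dm2 <- as.matrix(d)^2
  n <- nrow(dm2)
  groups <- as.character(groups)
  if (length(groups) != n)
    stop("one group label per observation required", call. = FALSE)
  sizes <- table(groups)
  if (length(sizes) < 2L || any(sizes < 2L))
    stop("insufficient data: need >= 2 groups with >= 2 members each",
         call. = FALSE)
  a <- length(sizes)
  ssT <- sum(dm2[lower.tri(dm2)]) / n
  ssW <- function(g) {
    tot <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      sub <- dm2[idx, idx, drop = FALSE]
      tot <- tot + sum(sub[lower.tri(sub)]) / length(idx)
    }
    tot
  }
  fstat <- function(g) {
    w <- ssW(g)
    ((ssT - w) / (a - 1)) / (w / (n - a))
  }
  fobs <- fstat(groups)
  if (exhaustive) {
    if (a != 2L)
      stop("exhaustive enumeration implemented for two groups", call. = FALSE)
    lev <- names(sizes)
    idx <- combn(n, sizes[[1L]])
    fperm <- apply(idx, 2L, function(ii) {
      g <- rep(lev[2L], n); g[ii] <- lev[1L]; fstat(g)
    })
    p <- sum(fperm >= fobs - 1e-12) / ncol(idx)
    nperm_used <- ncol(idx)
  } else {
    fperm <- withSeed(seed, replicate(n_perm, fstat(sample(groups))))
    p <- (1 + sum(fperm >= fobs - 1e-12)) / (1 + n_perm)
    nperm_used <- n_perm
  }
  data.frame(F = fobs, df_between = a - 1L, df_within = n - a,
             R2 = (ssT - ssW(groups)) / ssT, p = p, n_perm = nperm_used)
}
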