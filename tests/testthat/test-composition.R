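test_that("Bray-Curtis matches the definition and its bounds", {
  m <- rbind(a = c(1, 2), b = c(2, 0), c = c(1, 2), d = c(0, 5))
  d <- as.matrix(brayCurtis(m))
  expect_equal(d["a", "b"], 0.6)       # (1+2)/(3+2)
  expect_equal(d["a", "c"], 0)         # identical rows
  expect_equal(d["b", "d"], 1)         # disjoint rows
  expect_error(brayCurtis(rbind(a = c(0, 0), b = c(1, 1))), "all-zero.*a")

  set.seed(12)
  for (i in 1:10) {
    m <- matrix(rpois(5 * 8, 2), 5, 8)
    m[rowSums(m) == 0, 1] <- 1
    rownames(m) <- paste0("f", 1:5)
    d <- as.matrix(brayCurtis(m))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
    expect_equal(diag(d), setNames(rep(0, 5), rownames(m)))
    # cross-check against the vegan implementation
    expect_equal(as.vector(brayCurtis(m)),
                 as.vector(vegan::vegdist(m, "bray")), tolerance = 1e-12)
  }
})

test_that("NMDS recovers an exactly embeddable 2-D configuration", {
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1.2, 1.1))
  d <- dist(pts)
  ord <- nmdsOrdination(d, k = 2, n_restarts = 10, seed = 3)
  expect_lte(ord$stress, 1e-3)
  expect_equal(colMeans(ord$points), c(NMDS1 = 0, NMDS2 = 0),
               tolerance = 1e-8)
})

test_that("recomputed stress is invariant under rigid rotation", {
  set.seed(5)
  m <- matrix(rpois(6 * 10, 3), 6, 10)
  rownames(m) <- paste0("f", 1:6)
  d <- brayCurtis(m)
  ord <- nmdsOrdination(d, n_restarts = 5, seed = 2)
  s0 <- kruskalStress(ord$points, d)
  for (th in c(0.3, 1.2, 2.5)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    expect_equal(kruskalStress(ord$points %*% R, d), s0, tolerance = 1e-10)
  }
  # monotone-regression fit can only improve on the metric-scaling start
  start <- cmdscale(d, k = 2)
  expect_lte(ord$stress, kruskalStress(start, d) + 1e-8)
})

test_that("environmental vectors recover axis-aligned and closed-form fits", {
  set.seed(8)
  pts <- matrix(rnorm(20), 10, 2)
  pts <- scale(pts, scale = FALSE)
  ord <- list(points = pts)
  v <- pts[, 1]
  ef <- envfitVector(ord, v, n_perm = 99, seed = 1)
  expect_equal(abs(ef$dir1), 1, tolerance = 1e-8)
  expect_equal(ef$dir2, 0, tolerance = 1e-8)
  expect_equal(ef$r2, 1, tolerance = 1e-10)

  # 4-point hand example against the normal equations
  pts4 <- rbind(c(-1, -1), c(1, -1), c(-1, 1), c(1, 1))
  v4 <- c(0.2, 1.1, 0.4, 2.0)
  ef4 <- envfitVector(list(points = pts4), v4, n_perm = 99, seed = 1)
  B <- solve(t(cbind(1, pts4)) %*% cbind(1, pts4),
             t(cbind(1, pts4)) %*% v4)
  fitted <- cbind(1, pts4) %*% B
  r2_hand <- 1 - sum((v4 - fitted)^2) / sum((v4 - mean(v4))^2)
  expect_equal(ef4$r2, r2_hand, tolerance = 1e-12)
  # and against the vegan implementation
  vf <- vegan::envfit(pts4, data.frame(v = v4), permutations = 0)
  expect_equal(ef4$r2, unname(vf$vectors$r), tolerance = 1e-10)
  expect_error(envfitVector(ord, rep(1, 10)), "constant")
})

test_that("independent variables rarely reach high r2", {
  set.seed(13)
  pts <- scale(matrix(rnorm(68), 34, 2), scale = FALSE)
  r2s <- replicate(100, {
    envfitVector(list(points = pts), rnorm(34), n_perm = 2, seed = 1)$r2
  })
  expect_lt(mean(r2s), 0.25)
})

test_that("PERMANOVA matches exhaustive enumeration and the vegan engine", {
  set.seed(10)
  m <- matrix(rpois(6 * 8, 4) + 1, 6, 8)
  rownames(m) <- paste0("f", 1:6)
  d <- brayCurtis(m)
  g <- rep(c("x", "y"), each = 3L)
  mine <- permanovaTest(d, g, exhaustive = TRUE)
  oracle <- enumPermanovaP(d, g)
  expect_equal(mine$F, oracle$F, tolerance = 1e-10)
  expect_equal(mine$p, oracle$p, tolerance = 1e-12)
  expect_equal(mine$n_perm, choose(6, 3))

  # the R2 and F agree with adonis2 on a larger problem
  set.seed(14)
  m2 <- matrix(rpois(12 * 10, 3) + 1, 12, 10)
  rownames(m2) <- paste0("f", 1:12)
  d2 <- brayCurtis(m2)
  g2 <- rep(c("x", "y"), each = 6L)
  mine2 <- permanovaTest(d2, g2, n_perm = 199, seed = 4)
  ora2 <- as.data.frame(vegan::adonis2(d2 ~ g2, permutations = 0))
  expect_equal(mine2$F, ora2$F[1L], tolerance = 1e-10)
  expect_equal(mine2$R2, ora2$R2[1L], tolerance = 1e-10)
  expect_gte(mine2$p, 1 / 200)
})

test_that("identical multisets across groups give a null-level F", {
  pts <- rbind(diag(3), diag(3)) + 0
  rownames(pts) <- paste0("f", 1:6)
  d <- dist(pts)
  out <- permanovaTest(d, rep(c("x", "y"), each = 3L), exhaustive = TRUE)
  expect_gt(out$p, 0.5)
  expect_error(permanovaTest(d, c("x", rep("y", 5))), "insufficient")
})
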