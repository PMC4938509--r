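test_that("fruit set is the flower-to-fruit ratio with validation", {
  expect_equal(fruitSet(0, 7), 0)
  expect_equal(fruitSet(7, 10), 0.7)
  expect_error(fruitSet(8, 7), "data error")
  expect_error(fruitSet(1, 0), "n_flowers")
})

test_that("treatment summaries average clusters to bushes to fields", {
  b <- handBundle()
  sm <- summarizeTreatments(b)
  # single cluster per treatment per field: summary equals the cluster
  f1 <- sm[sm$field_id == "f1", ]
  expect_equal(f1$fruit_set[f1$treatment == "open"], 0.6)
  expect_equal(f1$fruit_set[f1$treatment == "excluded"], 0.3)
  # focal berries take precedence over cluster_weight / n_fruit
  expect_equal(f1$berry_weight[f1$treatment == "open"], 2.1)   # mean(2.0, 2.2)
  expect_equal(f1$seeds[f1$treatment == "open"], 15)
  # no focal berries for f2: cluster-weight fallback
  f2 <- sm[sm$field_id == "f2", ]
  expect_equal(f2$berry_weight[f2$treatment == "open"], 2.0)   # 16 / 8

  # bush-first averaging: bushes with unequal cluster numbers weigh equally
  cl <- data.frame(
    field_id = "x", distance = 0L, bush_id = c(1L, 2L, 2L),
    cluster_id = c("o_1", "o_2", "o_2b"), treatment = "open",
    n_flowers = 10L, n_fruit = c(4L, 8L, 8L), cluster_weight = 1)
  sm2 <- summarizeTreatments(list(clusters = cl,
                                  berries = data.frame()[0, ]))
  expect_equal(sm2$fruit_set, mean(c(0.4, 0.8)))   # 0.6, not 2/3
})

test_that("contribution and deficit are the stated treatment differences", {
  sm <- data.frame(
    field_id = "f", region = "BC",
    treatment = c("excluded", "open", "hand"),
    fruit_set = c(0.3, 0.6, 0.9),
    berry_weight = c(1.5, 2.0, 2.2),
    seeds = c(5, 10, 20), n_bushes = 1L)
  eff <- contributionAndDeficit(sm)
  expect_equal(eff$contrib_fs, 0.3)
  expect_equal(eff$contrib_weight, 0.5)
  expect_equal(eff$deficit_fs, 0.3)
  expect_equal(eff$deficit_weight, 0.2)
  # missing hand treatment: deficit NA, contribution kept
  eff2 <- contributionAndDeficit(sm[sm$treatment != "hand", ])
  expect_equal(eff2$contrib_fs, 0.3)
  expect_true(is.na(eff2$deficit_fs))
  # identical treatments give zero effects
  sm3 <- sm; sm3$fruit_set <- 0.5; sm3$berry_weight <- 2; sm3$seeds <- 10
  eff3 <- contributionAndDeficit(sm3)
  expect_equal(unlist(eff3[, -(1:2)]), setNames(rep(0, 6), names(eff3)[-(1:2)]))
})

test_that("Mann-Whitney contrasts match full enumeration", {
  ct <- treatmentContrasts(c(1, 2, 3, 4, 5, 6),
                           rep(c("a", "b"), each = 3L))
  expect_equal(ct$pairwise$U, 0)
  expect_equal(ct$pairwise$p, 0.1)   # 2/20 by enumeration
  expect_equal(ct$pairwise$p, enumMannWhitneyP(c(1, 2, 3), c(4, 5, 6)))
  set.seed(40)
  for (i in 1:5) {
    n1 <- sample(3:8, 1L); n2 <- sample(3:8, 1L)
    x <- runif(n1); y <- runif(n2) + runif(1, 0, 2)
    ct <- treatmentContrasts(c(x, y), rep(c("a", "b"), c(n1, n2)))
    expect_equal(ct$pairwise$p, enumMannWhitneyP(x, y), tolerance = 1e-12)
  }
})

test_that("identical groups give a zero K-W statistic and one letter", {
  v <- rep(c(1, 2, 3), 3L)
  g <- rep(c("a", "b", "c"), each = 3L)
  ct <- treatmentContrasts(v, g)
  expect_equal(ct$kruskal$chisq, 0)
  expect_equal(ct$kruskal$p, 1)
  expect_equal(unname(ct$letters), rep("a", 3L))
  # fully tied data across all groups
  ct2 <- treatmentContrasts(rep(5, 9), g)
  expect_equal(ct2$kruskal$p, 1)
  expect_equal(unname(ct2$letters), rep("a", 3L))
  expect_equal(ct2$pairwise$U, rep(9 / 2, 3L))
})

test_that("well-separated treatments earn distinct compact letters", {
  v <- c(1, 2, 3, 4, 11, 12, 13, 14, 21, 22, 23, 24)
  g <- rep(c("excluded", "open", "hand"), each = 4L)
  ct <- treatmentContrasts(v, g)
  expect_equal(length(unique(ct$letters)), 3L)
  expect_lt(ct$kruskal$p, 0.05)
})

test_that("seed-weight ANCOVA: collinear regions give a null interaction", {
  set.seed(50)
  seeds <- runif(20, 0, 10)
  eff <- data.frame(
    field_id = paste0("f", 1:20),
    region = rep(c("BC", "MI"), each = 10L),
    contrib_seeds = seeds, contrib_weight = 0.4 + 0.03 * seeds,
    deficit_seeds = NA, deficit_weight = NA)
  anc <- suppressWarnings(seedWeightAncova(eff))  # exact fit is intended here
  expect_equal(anc$interaction_F, 0, tolerance = 1e-10)
  expect_equal(anc$slope, 0.03, tolerance = 1e-10)
  expect_equal(anc$intercepts$intercept, c(0.4, 0.4), tolerance = 1e-10)
  eff$contrib_seeds <- 1
  expect_error(seedWeightAncova(eff), "constant")
})

test_that("ANCOVA recovers a common slope from noisy synthetic fields", {
  set.seed(51)
  hits <- replicate(40, {
    seeds <- runif(34, 0, 12)
    eff <- data.frame(
      field_id = paste0("f", 1:34),
      region = rep(c("BC", "MI"), each = 17L),
      contrib_seeds = seeds,
      contrib_weight = 0.45 + 0.03 * seeds + rnorm(34, 0, 0.05),
      deficit_seeds = NA, deficit_weight = NA)
    anc <- seedWeightAncova(eff)
    abs(anc$slope - 0.03) < 3 * anc$slope_se
  })
  expect_gte(mean(hits), 0.95)
})
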