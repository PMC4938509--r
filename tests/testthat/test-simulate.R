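test_that("the generator is deterministic in its seed and validates", {
  a <- simulateStudy(tinyConfig(), seed = 5L)
  b <- simulateStudy(tinyConfig(), seed = 5L)
  expect_identical(fieldInfo(a$study), fieldInfo(b$study))
  expect_identical(surveyData(a$study), surveyData(b$study))
  expect_identical(specimenMatrix(a$study), specimenMatrix(b$study))
  expect_identical(clusterData(a$study), clusterData(b$study))
  c2 <- simulateStudy(tinyConfig(), seed = 6L)
  expect_false(identical(surveyData(a$study), surveyData(c2$study)))
  expect_true(validObject(a$study))
  # generated bundles survive the full load validation after a round trip
  dir <- withr::local_tempdir()
  writeStudy(a$study, dir)
  expect_s4_class(readStudy(dir), "StudyBundle")
})

test_that("infeasible configurations are rejected", {
  cfg <- tinyConfig()
  cfg$treatments$BC$fs["open"] <- 1.2
  expect_error(simulateStudy(cfg, 1L), "configuration error.*fruit-set")
  cfg2 <- tinyConfig()
  cfg2$landscape$MI$rho <- -0.9   # 3x3 equicorrelation not PD below -0.5
  expect_error(simulateStudy(cfg2, 1L), "not positive definite")
  cfg3 <- tinyConfig(theta = -1)
  expect_error(simulateStudy(cfg3, 1L), "theta")
})

test_that("zero coefficients without random effects give unit mean counts", {
  fl <- data.frame(field_id = sprintf("F%03d", 1:250), region = "BC",
                   row_orientation = "parallel")
  lu <- data.frame(field_id = fl$field_id, landuse_300 = 0.5,
                   landuse_1000 = 0.5, landuse_2000 = 0.5)
  coefs <- list(bumble_bee = list(intercept = 0, distance = c(0, 0, 0),
                                  landuse = 0, radius = 300,
                                  orientation = 0))
  sv <- simulateVisitCounts(fl, lu, coefs, theta = 2,
                            re_sd = c(date = 0, time_block = 0),
                            n_visits = 10, seed = 9)
  y <- sv$bumble_bee           # 10 000 NB(mu = 1) draws
  se <- sd(y) / sqrt(length(y))
  expect_equal(length(y), 10000L)
  expect_lt(abs(mean(y) - 1), 3 * se)
})

test_that("a strong land-use slope produces the configured abundance gradient", {
  fl <- data.frame(field_id = sprintf("F%03d", 1:125), region = "BC",
                   row_orientation = "parallel")
  set.seed(8)
  lu <- data.frame(field_id = fl$field_id, landuse_300 = 0.5,
                   landuse_1000 = 0.5, landuse_2000 = runif(125))
  coefs <- list(bumble_bee = list(intercept = -1, distance = c(0, 0, 0),
                                  landuse = 4.0, radius = 2000,
                                  orientation = 0))
  sv <- simulateVisitCounts(fl, lu, coefs, theta = 2,
                            re_sd = c(date = 0, time_block = 0),
                            n_visits = 1, seed = 10)
  agg <- aggregate(bumble_bee ~ field_id, sv, sum)    # 500 surveys
  agg$lu <- lu$landuse_2000[match(agg$field_id, lu$field_id)]
  ct <- cor.test(agg$lu, agg$bumble_bee, method = "spearman", exact = FALSE)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("the dispersion parameter reaches the Poisson limit", {
  fl <- data.frame(field_id = sprintf("F%04d", 1:1250), region = "MI",
                   row_orientation = "parallel")
  lu <- data.frame(field_id = fl$field_id, landuse_300 = 0.5,
                   landuse_1000 = 0.5, landuse_2000 = 0.5)
  coefs <- list(other_bee = list(intercept = 1, distance = c(0, 0, 0),
                                 landuse = 0, radius = 300, orientation = 0))
  sv <- simulateVisitCounts(fl, lu, coefs, theta = Inf,
                            re_sd = c(date = 0, time_block = 0),
                            n_visits = 10, seed = 11)
  y <- sv$other_bee            # 50 000 draws, mu = e
  expect_equal(var(y) / mean(y), 1, tolerance = 0.1)
  # and a small theta is overdispersed far beyond Poisson
  sv2 <- simulateVisitCounts(fl, lu, coefs, theta = 0.5,
                             re_sd = c(date = 0, time_block = 0),
                             n_visits = 1, seed = 11)
  expect_gt(var(sv2$other_bee) / mean(sv2$other_bee), 2)
})

test_that("pollination outcomes honour degenerate treatment settings", {
  fl <- data.frame(field_id = c("a", "b"), region = "BC")
  tr <- simulationConfig()$treatments
  tr$BC$fs["excluded"] <- 0
  out <- simulatePollinationOutcomes(fl[fl$region == "BC", , drop = FALSE],
                                     tr, seed = 3)
  excl <- out$clusters[out$clusters$treatment == "excluded", ]
  expect_true(all(excl$n_fruit == 0))
  expect_true(all(out$clusters$n_fruit <= out$clusters$n_flowers))
})

test_that("a zero configured deficit yields deficit estimates centred on zero", {
  cfg <- tinyConfig()
  for (r in c("BC", "MI")) {
    cfg$treatments[[r]]$fs_deficit <- 0
    cfg$treatments[[r]]$seed_deficit <- 0
  }
  reps <- 20L
  yd <- dw <- numeric(reps)
  for (i in seq_len(reps)) {
    sim <- simulateStudy(cfg, seed = 100L + i)
    eco <- economicSummary(sim$study)
    yd[i] <- mean(eco$per_field$Yd)
    eff <- contributionAndDeficit(summarizeTreatments(sim$study))
    dw[i] <- mean(eff$deficit_weight, na.rm = TRUE)
  }
  expect_lt(abs(mean(yd)), 2 * sd(yd) / sqrt(reps))
  expect_lt(abs(mean(dw)), 2 * sd(dw) / sqrt(reps))
})

test_that("seed-weight law parameters are recovered from generated berries", {
  fl <- data.frame(field_id = sprintf("F%02d", 1:17), region = "BC")
  tr <- simulationConfig()$treatments
  tr$BC$weight <- c(a = 0.5, b = 0.03, sd = 0.05)
  out <- simulatePollinationOutcomes(
    fl, tr, design = list(bushes_per_transect = 4L, focal_bushes = 4L,
                          focal_berries = 3L, flowers_mean = 8), seed = 21)
  br <- out$berries
  fit <- lm(weight ~ mature_seeds, br)
  expect_lt(abs(coef(fit)[["mature_seeds"]] - 0.03),
            3 * summary(fit)$coefficients["mature_seeds", 2L])
})
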