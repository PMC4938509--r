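test_that("AICc arithmetic and its large-n AIC limit", {
  expect_equal(aicc(-10, 3, 20), 20 + 6 + 24 / 16)
  expect_equal(aicc(-10, 3, 1e9), 20 + 6, tolerance = 1e-6)
  expect_warning(res <- aicc(-10, 3, 4), "undefined")
  expect_equal(res, Inf)
})

test_that("collinearity screening flags duplicated and spares exempt pairs", {
  set.seed(2)
  d <- data.frame(a = rnorm(50))
  d$b <- d$a                       # r = 1
  d$c <- rnorm(50)
  scr <- screenCollinearity(d, c("a", "b", "c"), threshold = 0.6)
  expect_false(scr$admissible["a", "b"])
  expect_true(scr$admissible["a", "c"])
  scr2 <- screenCollinearity(d, c("a", "b"), threshold = 0.6, exempt = "b")
  expect_true(scr2$admissible["a", "b"])
  # threshold 0 makes every pair inadmissible: single-variable models only
  scr0 <- screenCollinearity(d, c("a", "c"), threshold = 0)
  expect_false(scr0$admissible["a", "c"])
  ms <- buildModelSet("y", c("a", "c"), scr0$admissible)
  expect_true(all(lengths(lapply(ms, `[[`, "fixed")) <= 1L))
  d$k <- 1
  expect_warning(scr3 <- screenCollinearity(d, c("a", "k")), "constant.*k")
  expect_equal(scr3$dropped, "k")
})

test_that("independent covariates are almost always admissible at 0.6", {
  set.seed(6)
  ok <- replicate(100, {
    d <- data.frame(a = rnorm(200), b = rnorm(200), c = rnorm(200))
    scr <- screenCollinearity(d, c("a", "b", "c"), threshold = 0.6)
    all(scr$admissible)
  })
  expect_gte(mean(ok), 0.95)
})

test_that("model-set enumeration follows the power-set and interaction rules", {
  ms <- buildModelSet("y", c("a", "b"))
  expect_length(ms, 4L)    # null, a, b, a+b
  expect_true(any(vapply(ms, function(s) !length(s$fixed), TRUE)))
  msi <- buildModelSet("y", c("distance", "landuse_300"),
                       interaction = TRUE)
  expect_length(msi, 5L)
  inter <- Filter(function(s) s$interaction, msi)
  expect_length(inter, 1L)
  expect_setequal(inter[[1L]]$fixed, c("distance", "landuse_300"))
  expect_warning(ms0 <- buildModelSet("y", character(0)), "null model only")
  expect_length(ms0, 1L)
})

test_that("NB-GLMM: closed-form intercept and independent likelihood check", {
  d <- data.frame(y = rep(4L, 60))
  fit <- fitNbGlmm(y ~ 1, d)
  expect_equal(fit$coefficients$estimate[1L], log(4), tolerance = 1e-6)

  set.seed(20)
  d2 <- data.frame(x = rnorm(150))
  d2$y <- rnbinom(150, mu = exp(0.5 + 0.8 * d2$x), size = 2)
  fit2 <- fitNbGlmm(y ~ x, d2)
  mu <- predict(fit2$model, type = "response")
  theta <- glmmTMB::sigma(fit2$model)
  expect_equal(fit2$logLik, handNbLogLik(d2$y, mu, theta), tolerance = 1e-6)
  expect_equal(fit2$k, 3L)  # intercept, slope, dispersion
  expect_equal(fit2$AICc, aicc(fit2$logLik, 3, 150))
})

test_that("single-replicate recovery of known NB-GLMM coefficients", {
  fl <- data.frame(field_id = sprintf("F%02d", 1:17), region = "BC",
                   row_orientation = rep(c("parallel", "perpendicular"),
                                         length.out = 17))
  set.seed(77)
  lu <- data.frame(field_id = fl$field_id, landuse_300 = runif(17, 0, 0.3),
                   landuse_1000 = runif(17), landuse_2000 = runif(17))
  coefs <- list(bumble_bee = list(intercept = -0.5, distance = c(0, 0, 0),
                                  landuse = 4, radius = 2000,
                                  orientation = 0.6))
  sv <- simulateVisitCounts(fl, lu, coefs, theta = 2,
                            re_sd = c(date = 0.2, time_block = 0.1),
                            n_visits = 3, seed = 123)
  d <- sv
  d$landuse_2000 <- lu$landuse_2000[match(d$field_id, lu$field_id)]
  d$row_orientation <- fl$row_orientation[match(d$field_id, fl$field_id)]
  fit <- fitNbGlmm(bumble_bee ~ landuse_2000 + row_orientation +
                     (1 | date) + (1 | time_block), d)
  co <- fit$coefficients
  truth <- c(`(Intercept)` = -0.5, landuse_2000 = 4,
             row_orientationperpendicular = 0.6)
  for (tm in names(truth)) {
    i <- match(tm, co$term)
    expect_lt(abs(co$estimate[i] - truth[[tm]]), 3 * co$se[i])
  }
})

test_that("ranking and full averaging reproduce the hand-worked weights", {
  mk <- function(label, ll, k, n, est) {
    structure(list(label = label, formula = NULL,
                   coefficients = data.frame(
                     term = names(est), estimate = unname(est),
                     se = rep(0.1, length(est))),
                   logLik = ll, k = k, n = n, AICc = aicc(ll, k, n),
                   converged = TRUE, model = NULL), class = "nbglmmFit")
  }
  # engineer AICc = 100 and 102 at n = 100, k = 2
  ll1 <- -(100 - 4 - 12 / 97) / 2
  ll2 <- -(102 - 4 - 12 / 97) / 2
  f1 <- mk("with_term", ll1, 2, 100, c(`(Intercept)` = 0.5, x = 2.0))
  f2 <- mk("null", ll2, 2, 100, c(`(Intercept)` = 0.4))
  out <- rankAndAverage(list(f2, f1))
  expect_equal(out$selection$AICc, c(100, 102))
  expect_equal(out$selection$delta, c(0, 2))
  expect_equal(out$selection$weight, c(0.7311, 0.2689), tolerance = 1e-4)
  expect_equal(sum(out$selection$weight), 1, tolerance = 1e-12)
  expect_true(all(out$selection$substantial))
  x <- out$average[out$average$term == "x", ]
  expect_equal(x$estimate, 0.7311 * 2.0, tolerance = 1e-3)
  # full-average shrinks toward zero relative to the conditional estimate
  expect_lt(x$estimate, 2.0)
  # unconditional SE, revised formula, by hand
  w <- out$selection$weight
  est <- c(2.0, 0)
  bbar <- sum(w * est)
  se_hand <- sqrt(sum(w * (c(0.1, 0)^2 + (est - bbar)^2)))
  expect_equal(x$se, se_hand, tolerance = 1e-9)
  expect_equal(x$z, abs(x$estimate) / x$se)

  one <- rankAndAverage(list(f1))
  expect_equal(one$average$estimate,
               f1$coefficients$estimate[match(one$average$term,
                                              f1$coefficients$term)])
  expect_error(rankAndAverage(list()), "no converged fits")
})

test_that("a pure-noise covariate raises logLik but usually worsens AICc", {
  set.seed(30)
  worse <- logical(60)
  llgain <- numeric(60)
  for (i in seq_along(worse)) {
    d <- data.frame(x = rnorm(80), z = rnorm(80))
    d$y <- rnbinom(80, mu = exp(0.3 + 0.5 * d$x), size = 2)
    f1 <- fitNbGlmm(y ~ x, d)
    f2 <- fitNbGlmm(y ~ x + z, d)
    llgain[i] <- f2$logLik - f1$logLik
    worse[i] <- f2$AICc > f1$AICc
  }
  ok <- is.finite(llgain)           # rare non-convergent refits excluded
  expect_gte(mean(ok), 0.9)
  expect_true(all(llgain[ok] > -1e-6))
  expect_gte(mean(worse[ok]), 0.6)
})
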