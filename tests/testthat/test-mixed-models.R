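test_that("with no real random variance the LMM collapses to least squares", {
  set.seed(81)
  # each run is one complete replicate of the 15-cell design, and the
  # residuals are centered within run, so the between-run variance
  # component is exactly zero and the boundary fit is deterministic
  d <- expand.grid(treatment = c("T0", "T1", "T2", "T3", "T4"),
                   temperature = factor(c(20, 27, 30)), rep = 1:4)
  d$run <- factor(d$rep)
  eff <- c(T0 = 0, T1 = 5, T2 = 8, T3 = 12, T4 = 20)
  e <- rnorm(nrow(d), 0, 3)
  e <- e - ave(e, d$run)
  d$y <- eff[as.character(d$treatment)] + e
  f <- fit_lmm(d, "y", c("treatment", "temperature"), "run")
  ols <- lm(y ~ treatment + temperature, data = d)
  expect_s3_class(f$model, "lm")  # zero-variance run term was dropped
  expect_identical(f$dropped, "run")
  expect_equal(unname(coef(f$model)), unname(coef(ols)),
               tolerance = 1e-10)
})

test_that("R2 definitions behave at their boundary cases", {
  set.seed(82)
  d <- data.frame(g = factor(rep(1:20, each = 10)))
  d$y <- rep(rnorm(20, 0, 2), each = 10) + rnorm(200)
  # intercept-only fixed part: marginal R2 is exactly 0, conditional > 0
  f0 <- fit_lmm(d, "y", "1", "g", never_drop = "g",
                drop_order = character())
  expect_identical(f0$r2_marginal, 0)
  expect_gt(f0$r2_conditional, 0)
  # no random term: marginal equals conditional
  d$x <- rnorm(200)
  fl <- fit_lmm(d, "y", "x", character())
  expect_identical(fl$r2_marginal, fl$r2_conditional)
})

test_that("R2 recovers known variance fractions (fixed 4, random 2, residual 2)", {
  set.seed(83)
  n <- 2000
  g <- factor(rep(1:100, each = n / 100))
  x <- rnorm(n)
  y <- 2 * x + rep(rnorm(100, 0, sqrt(2)), each = n / 100) +
    rnorm(n, 0, sqrt(2))
  f <- fit_lmm(data.frame(y = y, x = x, g = g), "y", "x", "g",
               never_drop = "g", drop_order = character())
  expect_equal(f$r2_marginal, 0.5, tolerance = 0.05)
  expect_equal(f$r2_conditional, 0.75, tolerance = 0.05)
  expect_lte(f$r2_marginal, f$r2_conditional)
  expect_lte(f$r2_conditional, 1)
})

test_that("likelihood-ratio tests carry fixed-parameter df and reject misuse", {
  set.seed(84)
  d <- expand.grid(treatment = c("T0", "T1", "T2", "T3", "T4"),
                   temperature = factor(c(20, 27, 30)), rep = 1:6)
  d$run <- factor(rep(1:8, length.out = nrow(d)))
  d$y <- rnorm(nrow(d), 50, 10) +
    rep(rnorm(8, 0, 4), length.out = nrow(d))[as.integer(d$run)]
  full <- fit_lmm(d, "y", c("treatment", "temperature"), "run",
                  drop_order = character(), never_drop = "run")
  no_trt <- fit_lmm(d, "y", "temperature", "run",
                    drop_order = character(), never_drop = "run")
  no_tmp <- fit_lmm(d, "y", "treatment", "run",
                    drop_order = character(), never_drop = "run")
  expect_identical(lrt(full, no_trt)$df, 4L)   # 5-level treatment
  expect_identical(lrt(full, no_tmp)$df, 2L)   # 3-level temperature
  self <- lrt(full, full)
  expect_identical(self$chi2, 0)
  expect_identical(self$df, 0L)
  expect_identical(self$p_value, 1)
  # adding a pure-noise covariate never decreases the ML log-likelihood
  d$noise <- rnorm(nrow(d))
  bigger <- fit_lmm(d, "y", c("treatment", "temperature", "noise"), "run",
                    drop_order = character(), never_drop = "run")
  expect_gte(bigger$logLik, full$logLik - 1e-8)
  expect_gte(lrt(bigger, full)$chi2, 0)
  # non-nested fixed parts are refused
  only_noise <- fit_lmm(d, "y", "noise", "run",
                        drop_order = character(), never_drop = "run")
  expect_error(lrt(full, only_noise), "not nested")
})

test_that("rank-deficient or degenerate fixed designs fail loudly", {
  d <- data.frame(y = rnorm(30), a = gl(3, 10))
  d$b <- d$a  # aliased copy
  expect_error(fit_lmm(d, "y", c("a", "b"), character()),
               "rank deficient")
  d1 <- data.frame(y = rnorm(10), a = factor(rep("x", 10)))
  expect_error(fit_lmm(d1, "y", "a", character()), "fewer than 2 levels")
})

test_that("growth regressions recover a deterministic line and ignore row duplication", {
  set.seed(85)
  tab <- data.frame(dspi = runif(40, 0.5, 1.5), pmax = runif(40, 20, 80))
  tab$h_sat <- runif(40, 300, 600)
  tab$ek <- runif(40, 20, 120)
  tab$growth_pct <- 2 * tab$dspi
  r <- suppressWarnings(fit_growth_regressions(tab))
  row <- r[r$predictor == "dspi", ]
  expect_equal(row$slope, 2, tolerance = 1e-10)
  expect_lt(row$p_value, 1e-12)
  r2 <- suppressWarnings(fit_growth_regressions(rbind(tab, tab)))
  expect_equal(r2[r2$predictor == "dspi", "slope"], row$slope,
               tolerance = 1e-10)
  tab$flat <- 1
  expect_error(fit_growth_regressions(tab, "flat"), "constant")
})

test_that("growth~DSPI model tests the slope and degrades gracefully", {
  set.seed(86)
  n <- 180
  tab <- data.frame(treatment = rep(c("T0", "T1", "T2", "T3", "T4",
                                      "T2.5"), each = n / 6),
                    dspi = runif(n, 0.5, 1.6))
  te <- rnorm(6, 0, 4)
  tab$growth_pct <- 3 + 10 * tab$dspi +
    te[as.integer(factor(tab$treatment))] + rnorm(n, 0, 6)
  g <- growth_dspi_lmm(tab)
  expect_equal(unname(g$slope[["estimate"]]), 10,
               tolerance = 0.35)  # ~3 SE at this design
  expect_identical(g$lrt$df, 1L)
  expect_lt(g$lrt$p_value, 0.001)
  # single-treatment table: random intercept degenerates with a warning
  one <- tab[tab$treatment == "T0", ]
  expect_warning(g1 <- growth_dspi_lmm(one), "fewer than 2 treatment")
  expect_s3_class(g1$fit$model, "lm")
  expect_identical(g1$lrt$df, 1L)
})

test_that("marginal R2 never exceeds conditional R2 across random fits", {
  set.seed(87)
  for (i in 1:10) {
    d <- data.frame(g = factor(rep(1:10, each = 8)), x = rnorm(80))
    d$y <- runif(1, 0, 3) * d$x +
      rep(rnorm(10, 0, runif(1, 0, 3)), each = 8) + rnorm(80)
    f <- fit_lmm(d, "y", "x", "g", never_drop = "g",
                 drop_order = character())
    expect_lte(f$r2_marginal, f$r2_conditional + 1e-12)
    expect_lte(f$r2_conditional, 1)
    expect_gte(f$r2_marginal, 0)
  }
})
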