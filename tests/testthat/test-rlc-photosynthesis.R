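test_that("noiseless Webb curves are recovered exactly across the parameter range", {
  set.seed(101)
  for (i in 1:20) {
    alpha <- runif(1, 0.05, 1)
    ek <- runif(1, 5, 300)
    f <- fit_webb(noiseless_curve(alpha, ek))
    expect_true(f$converged)
    expect_lt(abs(f$alpha - alpha), 1e-6)
    expect_lt(abs(f$ek - ek), 1e-4)
    expect_identical(f$pmax, f$alpha * f$ek)
  }
})

test_that("fit matches the global grid-search SSE minimum on noisy curves", {
  set.seed(202)
  for (i in 1:20) {
    alpha <- runif(1, 0.2, 0.8)
    ek <- runif(1, 20, 250)
    phi <- pmin(1, pmax(0, webb_phi(rlc_levels, alpha, ek) +
                          rnorm(9, 0, 0.01)))
    cv <- rlc_curve("n", "D1", rlc_levels, phi)
    f <- fit_webb(cv)
    g <- oracle_webb_global(rlc_levels, phi)
    # the fit sits at the global SSE minimum located by exhaustive grid
    # enumeration plus an independent simplex polish, and is never worse
    # than the best enumerated grid node
    expect_equal(f$alpha, g$alpha, tolerance = 1e-4)
    expect_equal(f$ek, g$ek, tolerance = 1e-3)
    expect_lte(f$rss, g$grid$sse + 1e-12)
    expect_lte(f$rss, g$sse + 1e-10)
  }
})

test_that("scaling all yields scales alpha and pmax, leaving Ek unchanged", {
  set.seed(303)
  for (i in 1:5) {
    alpha <- runif(1, 0.2, 0.9)
    ek <- runif(1, 20, 250)
    cc <- runif(1, 0.3, 1)
    phi <- webb_phi(rlc_levels, alpha, ek)
    f1 <- fit_webb(rlc_curve("a", "D1", rlc_levels, phi))
    f2 <- fit_webb(rlc_curve("b", "D1", rlc_levels, cc * phi))
    expect_equal(f2$alpha, cc * f1$alpha, tolerance = 1e-5)
    expect_equal(f2$ek, f1$ek, tolerance = 1e-3)
    expect_equal(f2$pmax, cc * f1$pmax, tolerance = 1e-4)
  }
})

test_that("pmax is the exact product with domain checks", {
  expect_identical(compute_pmax(0.65, 80), 52)
  expect_identical(compute_pmax(0, 100), 0)
  expect_error(compute_pmax(-0.1, 100), ">=")
  expect_error(compute_pmax(0.5, 0), "> 0")
})

test_that("rETR_max screens on yield > 0.1 and breaks ties low", {
  phi <- c(0.60, 0.50, 0.45, 0.40, 0.30, 0.22, 0.12, 0.08, 0.05)
  cv <- rlc_curve("p", "D1", rlc_levels, phi)
  expect_equal(compute_retr_max(cv), 285 * 0.22)
  # no step passes the screen
  low <- rlc_curve("p", "D1", rlc_levels, rep(0.05, 9))
  expect_true(is.na(compute_retr_max(low)))
  # single qualifying step
  one <- rlc_curve("p", "D1", c(65, 125, 625, 820),
                   c(0.05, 0.40, 0.02, 0.01))
  expect_equal(compute_retr_max(one), 50)
  # exact tie in the product: lower irradiance wins (same value either way,
  # but the screen must never admit a <= 0.1 step)
  tie <- rlc_curve("p", "D1", c(10, 100, 150, 800),
                   c(0.05, 0.30, 0.20, 0.01))
  expect_equal(compute_retr_max(tie), 30)
  set.seed(11)
  for (i in 1:20) {
    phi <- runif(9, 0, 0.6)
    cv <- rlc_curve("p", "D1", rlc_levels, phi)
    r <- compute_retr_max(cv)
    cand <- rlc_levels[phi > 0.1] * phi[phi > 0.1]
    if (length(cand)) expect_equal(r, max(cand)) else expect_true(is.na(r))
  }
})

test_that("all-zero curves raise the unfittable signal and are excluded, not fitted", {
  dead <- rlc_curve("ghost", "D9", rlc_levels, rep(0, 9))
  expect_error(fit_webb(dead), class = "dspi_unfittable_curve")
  live <- noiseless_curve(0.5, 80, id = "ok")
  fits <- fit_webb_all(list(live, dead))
  expect_equal(nrow(fits), 1L)
  expect_equal(fits$plant_id, "ok")
  excl <- attr(fits, "exclusions")
  expect_equal(excl$plant_id, "ghost")
})

test_that("curve construction enforces the step invariants", {
  expect_error(rlc_curve("p", "D1", c(0, 65, 90), c(0.5, 0.4, 0.3)),
               "at least 4")
  expect_error(rlc_curve("p", "D1", c(0, 65, 65, 90), rep(0.4, 4)),
               "distinct")
  expect_error(rlc_curve("p", "D1", rlc_levels, rep(1.2, 9)), "\\[0, 1\\]")
  expect_warning(cv <- rlc_curve("p", "D1", c(90, 0, 65, 125),
                                 c(0.45, 0.6, 0.5, 0.4)), "sorting")
  expect_identical(cv$steps$e_par, c(0, 65, 90, 125))
})

test_that("fits recover the calibrated low-nutrient saturation irradiance", {
  # simulator at the oligotrophic-cell calibration (Ek 27.2): the mean
  # fitted Ek over 200 noisy curves must come back within +/- 2
  set.seed(404)
  cfg <- sim_config(species = "Ulva")
  design <- data.frame(species = "Ulva", treatment = "T0", temperature = 27,
                       plant_id = sprintf("u%03d", 1:200))
  truth <- simulate_plant_params(design, cfg)
  d9 <- truth[truth$day_label == "D9", ]
  eks <- vapply(seq_len(nrow(d9)), function(i) {
    cv <- simulate_rlc(d9$alpha_true[i], d9$ek_true[i], cfg)
    fit_webb(cv)$ek
  }, numeric(1))
  expect_lt(abs(mean(eks) - 27.2), 2)
})
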