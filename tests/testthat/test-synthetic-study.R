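test_that("design enumeration matches the stated replicate structure", {
  set.seed(91)
  cfg <- sim_config()
  d <- enumerate_design(cfg)
  expect_equal(sum(d$species == "Ulva"), 240L)
  expect_equal(sum(d$species == "Hypnea"), 286L)
  excl <- attr(d, "exclusions")
  expect_equal(sum(excl$species == "Ulva"), 48L)    # all T2.5 replicates
  expect_equal(sum(excl$species == "Hypnea"), 2L)   # depigmented
  # single-cell degenerate design
  cfg1 <- sim_config(species = "Ulva", replicates = 16,
                     temperatures = 27,
                     treatments = treatment_specs()[1, ],
                     drop_ulva_t25 = FALSE)
  expect_equal(nrow(enumerate_design(cfg1)), 16L)
  # paired replicates share runs; orders are unique within species-run
  expect_true(all(tapply(d$replicate, d$run, function(x) all(x %in% 1:16))))
  byrun <- split(d[d$species == "Ulva", ], d$run[d$species == "Ulva"])
  expect_true(all(vapply(byrun, function(g)
    !anyDuplicated(g$rlc_order), logical(1))))
})

test_that("a fixed seed reproduces the study bit-for-bit", {
  cfg <- sim_config(seed = 5, replicates = 2)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$weights, s2$weights)
  expect_identical(s1$curves[[10]]$steps, s2$curves[[10]]$steps)
  expect_identical(s1$irradiance[[3]]$samples, s2$irradiance[[3]]$samples)
  s3 <- simulate_study(sim_config(seed = 6, replicates = 2))
  expect_false(identical(s1$weights$w_i, s3$weights$w_i))
})

test_that("zero random SDs pin true parameters at the cell means", {
  set.seed(92)
  cfg <- sim_config(species = "Ulva", plant_alpha_sd = 0,
                    plant_ek_sd_frac = 0, day_ek_sd_frac = 0)
  design <- data.frame(species = "Ulva", treatment = "T2",
                       temperature = 27, plant_id = c("a", "b"))
  tr <- simulate_plant_params(design, cfg)
  d9 <- tr[tr$day_label == "D9", ]
  expect_equal(d9$ek_true, rep(72.8, 2))
  expect_equal(d9$alpha_true, rep(53.3 / 72.8, 2))
  d1 <- tr[tr$day_label == "D1", ]
  expect_equal(d1$ek_true, rep(72.8 * 0.85, 2))
})

test_that("cell sample means concentrate on the configured mean", {
  set.seed(93)
  cfg <- sim_config(species = "Ulva")
  design <- data.frame(species = "Ulva", treatment = "T3",
                       temperature = 27,
                       plant_id = sprintf("p%03d", 1:200))
  tr <- simulate_plant_params(design, cfg)
  d9 <- tr[tr$day_label == "D9", ]
  se <- sd(d9$ek_true) / sqrt(200)
  expect_lt(abs(mean(d9$ek_true) - 105.3), 3 * se + 1e-9)
})

test_that("noise-free curves round-trip through the fitter; noisy yields stay in [0,1]", {
  set.seed(94)
  cfg0 <- sim_config(rlc_noise_sd = 0)
  cv <- simulate_rlc(0.6, 90, cfg0)
  f <- fit_webb(cv)
  expect_lt(abs(f$alpha - 0.6), 1e-6)
  expect_lt(abs(f$ek - 90), 1e-4)
  cfgN <- sim_config(rlc_noise_sd = 0.3)
  for (i in 1:10) {
    cv <- simulate_rlc(0.95, 40, cfgN)
    expect_true(all(cv$steps$phi_psii >= 0 & cv$steps$phi_psii <= 1))
  }
})

test_that("simulated daylight is symmetric, scales with shading, and has the set duration", {
  cfg <- sim_config(cloud_amp = 0)
  set.seed(95)
  s <- simulate_irradiance(cfg, 654)
  e <- s$samples$e_par
  pos <- which(e > 0)
  expect_equal(e[pos], rev(e[pos]), tolerance = 1e-12)
  mid <- pos[ceiling(length(pos) / 2)]
  expect_equal(which.max(e), mid, tolerance = 1)
  # same seed, shading halved -> every sample exactly halved
  cfg_full <- sim_config(cloud_amp = 0.15, shading = 1)
  cfg_half <- sim_config(cloud_amp = 0.15, shading = 0.5)
  set.seed(96)
  s1 <- simulate_irradiance(cfg_full, 640)
  set.seed(96)
  s2 <- simulate_irradiance(cfg_half, 640)
  expect_identical(s2$samples$e_par, s1$samples$e_par / 2)
  # condensed day length tracks the configured daylight window
  set.seed(97)
  expect_lt(abs(day_length(condense_series(
    simulate_irradiance(sim_config(), 654))) - 654), 10 + 1e-9)
  set.seed(98)
  expect_lt(abs(day_length(condense_series(
    simulate_irradiance(sim_config(), 600))) - 600), 10 + 1e-9)
})

test_that("growth generation is exact when noise-free and recoverable via the weights", {
  cfg <- sim_config(growth_beta0 = 0, growth_dspi_slope = 10,
                    growth_treatment_sd = 0, growth_noise_sd = 0,
                    parasite_prob = 1, species = "Hypnea",
                    n_depigmented_hypnea = 0)
  set.seed(99)
  design <- enumerate_design(cfg)[1:20, ]
  w <- simulate_growth(design, rep(1.2, 20), cfg)
  expect_equal(w$growth_true_pct, rep(12, 20))
  # recorded final weight includes the parasite; the adjustment undoes it
  expect_equal(growth_percent(w$w_i, w$w_f, w$parasite_mass),
               w$growth_true_pct, tolerance = 1e-10)
  expect_true(all(w$w_i >= 0.28 & w$w_i <= 0.30))
  expect_true(all(w$parasite_mass > 0))
})
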