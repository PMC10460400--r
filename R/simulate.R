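#' Treatment specifications for the salinity/nutrient gradient
#'
#' The six-step gradient from oligotrophic ocean water (T0) to
#' groundwater-like conditions (T4): decreasing salinity with increasing
#' nitrate and phosphate. T2.5 shares T2's salinity with T3's nutrients.
#'
#' @return data.frame with `treatment`, `salinity` (permille), `nitrate`
#'   and `phosphate` (\eqn{\mu}mol).
#' @export
treatment_specs <- function() {
  data.frame(
    treatment = c("T0", "T1", "T2", "T2.5", "T3", "T4"),
    salinity = c(35, 35, 28, 28, 18, 11),
    nitrate = c(0.5, 14.3, 27.1, 52.9, 52.9, 80.0),
    phosphate = c(0.005, 0.005, 0.15, 1.64, 1.64, 3.79))
}

# Published D9 treatment means used as generator calibration constants.
# The Ulva T2.5 cell was excluded from the source study's summaries, so
# its generating mean here is a synthetic interpolation of the T2 and T3
# means (those rows are generated and then excluded anyway).
calibration_means <- function() {
  list(
    Ulva = data.frame(
      treatment = c("T0", "T1", "T2", "T2.5", "T3", "T4"),
      pmax = c(31.1, 52.3, 53.3, 62.8, 72.3, 74.3),
      ek = c(27.2, 65.2, 72.8, 89.0, 105.3, 110.4)),
    Hypnea = data.frame(
      treatment = c("T0", "T1", "T2", "T2.5", "T3", "T4"),
      pmax = c(43.9, 47.5, 43.8, 58.7, 49.0, 53.1),
      ek = c(51.8, 71.4, 70.7, 93.8, 70.5, 78.3)))
}

#' Configuration for a synthetic study
#'
#' Bundles every constant the generator uses: the experimental design
#' (6 treatments x 3 temperatures x 16 replicates per species, paired
#' replicates grouped into 8 runs), species-level mean surfaces for
#' \eqn{\alpha} and \eqn{E_k} calibrated to the published D9 treatment
#' means, plant-level random-intercept SDs, RLC yield noise, the diurnal
#' irradiance model (half-sine daylight of 611-688 min under ~50% shade
#' cloth with autocorrelated multiplicative cloud noise, logged 05:00 to
#' 19:30), and the growth model (percent growth linear in true DSPI with a
#' treatment random effect).
#'
#' Mean \eqn{E_k} per treatment equals the published means; mean
#' \eqn{\alpha} is the implied ratio P_max/E_k capped at 0.78, since
#' quantum yields cannot exceed 1 and ratios of cell means can (and for
#' the lowest-nutrient cells do) exceed that bound.
#'
#' @param seed integer seed controlling every random draw.
#' @param species character vector, subset of `c("Ulva", "Hypnea")`.
#' @param replicates replicates per treatment x temperature cell.
#' @param temperatures water temperatures, degrees C.
#' @param treatments treatment table, see [treatment_specs()].
#' @param alpha_mean,ek_mean named lists (per species) of named vectors
#'   (per treatment) of cell means.
#' @param alpha_temp_mult multiplicative temperature effect on alpha, per
#'   species; the red alga runs warmer-suppressed (highest P_max at 20
#'   degrees C), the green alga is temperature-neutral.
#' @param day_mult multiplicative drift of both parameters across RLC days
#'   (plants ramp up over the run; D9 sits at the calibrated mean).
#' @param plant_alpha_sd plant-level SD of the alpha intercept.
#' @param plant_ek_sd_frac plant-level SD of the E_k intercept, as a
#'   fraction of the cell mean.
#' @param day_ek_sd_frac day-level E_k jitter, fraction of the cell mean.
#' @param rlc_noise_sd Gaussian SD of simulated quantum-yield noise.
#' @param day_length_range run-level daylight duration range, minutes.
#' @param day_length_jitter_sd day-to-day daylight jitter within a run.
#' @param peak_par unshaded midday PAR peak.
#' @param shading shade-cloth transmission factor in (0, 1].
#' @param cloud_amp amplitude of multiplicative cloud noise (0 disables).
#' @param cloud_ar lag-1 autocorrelation of the cloud process.
#' @param growth_beta0 baseline percent growth.
#' @param growth_dspi_slope percent growth per unit DSPI (mol m^-2).
#' @param growth_treatment_sd SD of the treatment random effect on growth.
#' @param growth_noise_sd residual SD of percent growth.
#' @param parasite_prob probability a Hypnea plant carries the epiphytic
#'   parasite at final weighing.
#' @param parasite_mass_range wet-mass range of a parasite, g.
#' @param drop_ulva_t25 exclude all Ulva T2.5 replicates (reproductive
#'   tissue sloughing).
#' @param n_depigmented_hypnea number of Hypnea individuals excluded as
#'   depigmented/unmeasurable.
#' @return classed list (`sim_config`).
#' @export
sim_config <- function(seed = 1L,
                       species = c("Ulva", "Hypnea"),
                       replicates = 16L,
                       temperatures = c(20, 27, 30),
                       treatments = treatment_specs(),
                       alpha_mean = NULL,
                       ek_mean = NULL,
                       alpha_temp_mult = list(
                         Ulva = c(`20` = 1, `27` = 1, `30` = 1),
                         Hypnea = c(`20` = 1.12, `27` = 0.95, `30` = 0.93)),
                       day_mult = c(D1 = 0.85, D5 = 0.95, D9 = 1),
                       plant_alpha_sd = 0.04,
                       plant_ek_sd_frac = 0.12,
                       day_ek_sd_frac = 0.03,
                       rlc_noise_sd = 0.01,
                       day_length_range = c(611, 688),
                       day_length_jitter_sd = 4,
                       peak_par = 1400,
                       shading = 0.5,
                       cloud_amp = 0.15,
                       cloud_ar = 0.95,
                       growth_beta0 = 2,
                       growth_dspi_slope = 12.2,
                       growth_treatment_sd = 5,
                       growth_noise_sd = 8,
                       parasite_prob = 0.05,
                       parasite_mass_range = c(0.002, 0.02),
                       drop_ulva_t25 = TRUE,
                       n_depigmented_hypnea = 2L) {
  species <- match.arg(species, c("Ulva", "Hypnea"), several.ok = TRUE)
  cal <- calibration_means()
  if (is.null(ek_mean))
    ek_mean <- lapply(cal, function(d) stats::setNames(d$ek, d$treatment))
  if (is.null(alpha_mean))
    alpha_mean <- lapply(cal, function(d)
      stats::setNames(pmin(0.78, d$pmax / d$ek), d$treatment))
  cfg <- list(seed = as.integer(seed), species = species,
              replicates = as.integer(replicates),
              temperatures = temperatures, treatments = treatments,
              alpha_mean = alpha_mean, ek_mean = ek_mean,
              alpha_temp_mult = alpha_temp_mult, day_mult = day_mult,
              plant_alpha_sd = plant_alpha_sd,
              plant_ek_sd_frac = plant_ek_sd_frac,
              day_ek_sd_frac = day_ek_sd_frac,
              rlc_noise_sd = rlc_noise_sd,
              day_length_range = day_length_range,
              day_length_jitter_sd = day_length_jitter_sd,
              peak_par = peak_par, shading = shading,
              cloud_amp = cloud_amp, cloud_ar = cloud_ar,
              growth_beta0 = growth_beta0,
              growth_dspi_slope = growth_dspi_slope,
              growth_treatment_sd = growth_treatment_sd,
              growth_noise_sd = growth_noise_sd,
              parasite_prob = parasite_prob,
              parasite_mass_range = parasite_mass_range,
              drop_ulva_t25 = isTRUE(drop_ulva_t25),
              n_depigmented_hypnea = as.integer(n_depigmented_hypnea))
  sds <- c(plant_alpha_sd, plant_ek_sd_frac, day_ek_sd_frac, rlc_noise_sd,
           day_length_jitter_sd, cloud_amp, growth_treatment_sd,
           growth_noise_sd)
  if (any(sds < 0)) stop("all SDs and noise amplitudes must be >= 0")
  if (shading <= 0 || shading > 1) stop("`shading` must be in (0, 1]")
  structure(cfg, class = "sim_config")
}

#' Enumerate the experimental design with exclusions
#'
#' Full cross of treatments x temperatures x replicates per species.
#' Paired replicates share a run (replicates 1-2 -> run 1, ..., 15-16 ->
#' run 8); RLC measurement order is the plant's position within its
#' species-run group; lunar phase cycles with run. Exclusion switches then
#' remove rows: all Ulva T2.5 replicates, and `n_depigmented_hypnea`
#' randomly chosen Hypnea individuals (uses the RNG — seed the session or
#' call via [simulate_study()] for reproducibility). Removed rows are kept
#' in the `"exclusions"` attribute.
#'
#' With the default configuration this yields 240 Ulva and 286 Hypnea
#' rows.
#'
#' @param config a [sim_config()].
#' @return design data.frame; attribute `"exclusions"` logs removed rows.
#' @export
enumerate_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  one_species <- function(sp) {
    g <- expand.grid(replicate = seq_len(config$replicates),
                     temperature = config$temperatures,
                     treatment = config$treatments$treatment,
                     stringsAsFactors = FALSE)
    g$species <- sp
    g$run <- (g$replicate - 1L) %/% 2L + 1L
    g <- g[order(g$run, g$treatment, g$temperature, g$replicate), ]
    g$rlc_order <- stats::ave(seq_len(nrow(g)), g$run,
                              FUN = seq_along)
    phases <- c("new", "first_quarter", "full", "last_quarter")
    g$lunar_phase <- phases[(g$run - 1L) %% 4L + 1L]
    ab <- if (sp == "Ulva") "Ul" else "Hm"
    g$plant_id <- sprintf("%s_%s_%g_r%02d", ab, g$treatment,
                          g$temperature, g$replicate)
    g$run_start <- as.character(as.Date("2021-09-20") + (g$run - 1L) * 14L)
    g[, c("species", "treatment", "temperature", "replicate", "run",
          "run_start", "rlc_order", "lunar_phase", "plant_id")]
  }
  design <- do.call(rbind, lapply(config$species, one_species))
  excl <- design[0, ]
  excl$reason <- character()
  if (config$drop_ulva_t25 && "Ulva" %in% config$species) {
    out <- design$species == "Ulva" & design$treatment == "T2.5"
    if (any(out)) {
      e <- design[out, ]
      e$reason <- "Ulva T2.5 removed (lunar-phase reproductive sloughing)"
      excl <- rbind(excl, e)
      design <- design[!out, ]
    }
  }
  if (config$n_depigmented_hypnea > 0L && "Hypnea" %in% config$species) {
    hyp <- which(design$species == "Hypnea")
    pick <- sort(sample(hyp, min(config$n_depigmented_hypnea, length(hyp))))
    if (length(pick)) {
      e <- design[pick, ]
      e$reason <- "depigmented on D9; no usable fluorescence signal"
      excl <- rbind(excl, e)
      design <- design[-pick, ]
    }
  }
  rownames(design) <- NULL
  attr(design, "exclusions") <- excl
  design
}

#' Per-plant true photophysiology parameters
#'
#' For each plant and RLC day: true \eqn{\alpha} and \eqn{E_k} are the
#' treatment x temperature cell mean scaled by the day drift, plus a
#' plant-level random intercept (and a small day-level E_k jitter),
#' truncated to stay strictly positive (alpha also capped below 0.95 so
#' simulated yields stay inside [0, 1]).
#'
#' @param design an [enumerate_design()] table.
#' @param config a [sim_config()].
#' @return data.frame: `plant_id`, `day_label`, `alpha_true`, `ek_true`,
#'   `pmax_true`.
#' @export
simulate_plant_params <- function(design, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(design)
  a_int <- stats::rnorm(n, 0, config$plant_alpha_sd)
  days <- names(config$day_mult)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- design$species[i]
    tr <- design$treatment[i]
    tmp <- as.character(design$temperature[i])
    cell_a <- config$alpha_mean[[sp]][[tr]] *
      config$alpha_temp_mult[[sp]][[tmp]]
    cell_k <- config$ek_mean[[sp]][[tr]]
    e_int <- stats::rnorm(1, 0, config$plant_ek_sd_frac * cell_k)
    k_noise <- stats::rnorm(length(days), 0, config$day_ek_sd_frac * cell_k)
    alpha <- pmin(pmax(cell_a * config$day_mult + a_int[i], 0.02), 0.95)
    ek <- pmax(cell_k * config$day_mult + e_int + k_noise, 5)
    rows[[i]] <- data.frame(plant_id = design$plant_id[i],
                            day_label = days,
                            alpha_true = unname(alpha),
                            ek_true = unname(ek),
                            pmax_true = unname(alpha * ek))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate one rapid light curve from true parameters
#'
#' Observed yields are the Webb-model values at the nine standard actinic
#' levels plus Gaussian noise, clipped into `[0, 1]`.
#'
#' @param alpha,ek true parameters.
#' @param config a [sim_config()] (noise SD is taken from it).
#' @param plant_id,day_label,timestamp,rlc_order,species,date curve
#'   identifiers, see [rlc_curve()].
#' @param e_levels actinic irradiance steps.
#' @return an [rlc_curve()].
#' @export
simulate_rlc <- function(alpha, ek, config,
                         plant_id = "sim", day_label = "D1",
                         timestamp = NA_integer_, rlc_order = NA_integer_,
                         species = NA_character_, date = NA_character_,
                         e_levels = c(0, 65, 90, 125, 190, 285, 420,
                                      625, 820)) {
  phi <- webb_phi(e_levels, alpha, ek) +
    stats::rnorm(length(e_levels), 0, config$rlc_noise_sd)
  phi <- pmin(pmax(phi, 0), 1)
  rlc_curve(plant_id, day_label, e_levels, phi, timestamp = timestamp,
            rlc_order = rlc_order, species = species, date = date)
}

#' Simulate one day's irradiance trace
#'
#' Half-sine daylight profile of the requested duration, centered on the
#' midpoint of the 05:00-19:30 logging window, scaled by the unshaded peak
#' and the shade-cloth transmission, then multiplied by a non-negative
#' AR(1) cloud factor (drawn even when `cloud_amp = 0`, so irradiance is
#' exactly proportional to `shading` under a common seed). Minutes outside
#' the daylight window read zero.
#'
#' @param config a [sim_config()].
#' @param day_length_min daylight duration, minutes (must fit in the
#'   logging window).
#' @param date calendar-day key.
#' @return an [irradiance_series()] with 871 one-minute samples.
#' @export
simulate_irradiance <- function(config, day_length_min, date = "2021-09-20") {
  L <- as.integer(round(day_length_min))
  minutes <- 300:1170
  if (L < 1L || L > length(minutes))
    stop("`day_length_min` must fit inside the 05:00-19:30 logging window")
  start <- as.integer(round(735 - L / 2))
  i <- minutes - start + 1L
  base <- numeric(length(minutes))
  inside <- i >= 1L & i <= L
  base[inside] <- config$peak_par * config$shading *
    sin(pi * (i[inside] - 0.5) / L)
  z <- numeric(L)
  innov <- stats::rnorm(L)
  rho <- config$cloud_ar
  z[1] <- innov[1]
  if (L > 1) for (t in 2:L) z[t] <- rho * z[t - 1] + sqrt(1 - rho^2) * innov[t]
  cloud <- pmax(0, 1 + config$cloud_amp * z)
  e <- base
  e[inside] <- base[inside] * cloud
  irradiance_series(date, minutes, e)
}

#' Simulate weights from true DSPI
#'
#' Percent growth is linear in the plant's true DSPI with a
#' treatment-level random intercept and Gaussian residual; initial wet
#' weights are uniform on 0.28-0.30 g (the sectioning target range), and
#' the recorded final weight adds any parasite mass (Hypnea only) so that
#' [growth_percent()] with the parasite adjustment recovers the generated
#' growth exactly.
#'
#' @param design an [enumerate_design()] table.
#' @param dspi_true numeric vector of true DSPI per design row.
#' @param config a [sim_config()].
#' @return data.frame: `plant_id`, `w_i`, `w_f`, `parasite_mass`,
#'   `growth_true_pct`, `dspi_true`.
#' @export
simulate_growth <- function(design, dspi_true, config) {
  stopifnot(nrow(design) == length(dspi_true))
  n <- nrow(design)
  levs <- sort(unique(design$treatment))
  tre <- stats::setNames(stats::rnorm(length(levs), 0,
                                      config$growth_treatment_sd), levs)
  g <- config$growth_beta0 + config$growth_dspi_slope * dspi_true +
    tre[design$treatment] + stats::rnorm(n, 0, config$growth_noise_sd)
  g <- pmax(g, -95)  # a plant cannot lose more than its own mass
  w_i <- stats::runif(n, 0.28, 0.30)
  w_clean <- w_i * (1 + g / 100)
  parasite <- numeric(n)
  hyp <- design$species == "Hypnea"
  has_par <- hyp & stats::runif(n) < config$parasite_prob
  parasite[has_par] <- stats::runif(sum(has_par),
                                    config$parasite_mass_range[1],
                                    config$parasite_mass_range[2])
  data.frame(plant_id = design$plant_id, w_i = w_i,
             w_f = w_clean + parasite, parasite_mass = parasite,
             growth_true_pct = unname(g), dspi_true = dspi_true)
}

#' Generate a complete synthetic study
#'
#' Runs the whole generator under one seed with a fixed draw order
#' (design exclusions, plant parameters, RLC yields, irradiance, growth),
#' so a given seed reproduces the study bit-for-bit. True parameters are
#' retained alongside the data for recovery tests. True DSPI is computed
#' from the true P_max and the simulated irradiance using the package's
#' own saturation machinery (deterministic, so it does not perturb the
#' draw order).
#'
#' @param config a [sim_config()].
#' @return object of class `sim_study`: `config`, `design`, `truth`,
#'   `curves` (list of [rlc_curve()]), `irradiance` (list of
#'   [irradiance_series()] keyed by date), `run_days` (run/day/date/
#'   day-length bookkeeping), `weights`, `metadata` (study table ready for
#'   the pipeline), `exclusions`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  design <- enumerate_design(config)
  truth <- simulate_plant_params(design, config)
  # RLC timestamps: mornings from 08:00, ~5 min per curve in measurement order
  rlc_minute <- 480L + 5L * (design$rlc_order - 1L)
  day_offset <- c(D1 = 0L, D5 = 4L, D9 = 8L)
  curves <- vector("list", nrow(truth))
  k <- 0L
  for (i in seq_len(nrow(design))) {
    for (d in c("D1", "D5", "D9")) {
      k <- k + 1L
      tr <- truth[truth$plant_id == design$plant_id[i] &
                    truth$day_label == d, ]
      curves[[k]] <- simulate_rlc(
        tr$alpha_true, tr$ek_true, config,
        plant_id = design$plant_id[i], day_label = d,
        timestamp = rlc_minute[i], rlc_order = design$rlc_order[i],
        species = design$species[i],
        date = as.character(as.Date(design$run_start[i]) + day_offset[[d]]))
    }
  }
  names(curves) <- vapply(curves, function(cv)
    paste(cv$plant_id, cv$day_label, sep = "."), character(1))
  runs <- sort(unique(design$run))
  run_days <- list()
  irradiance <- list()
  for (r in runs) {
    base_len <- stats::runif(1, config$day_length_range[1],
                             config$day_length_range[2])
    start <- as.Date(design$run_start[match(r, design$run)])
    for (d in 1:9) {
      L <- round(base_len + stats::rnorm(1, 0, config$day_length_jitter_sd))
      date <- as.character(start + d - 1L)
      irradiance[[date]] <- simulate_irradiance(config, L, date)
      run_days[[length(run_days) + 1L]] <-
        data.frame(run = r, day_index = d, date = date, day_length_true = L)
    }
  }
  run_days <- do.call(rbind, run_days)
  # true DSPI per plant (deterministic given truth + irradiance)
  dspi_true <- vapply(seq_len(nrow(design)), function(i) {
    pid <- design$plant_id[i]
    tr <- truth[truth$plant_id == pid, ]
    ek <- stats::setNames(tr$ek_true, tr$day_label)
    pm <- stats::setNames(tr$pmax_true, tr$day_label)
    dates <- run_days$date[run_days$run == design$run[i]]
    daily <- vapply(1:9, function(d) {
      ser <- irradiance[[dates[d]]]
      win <- if (d == 1) c(rlc_minute[i], 1170) else
        if (d == 9) c(300, rlc_minute[i]) else NULL
      hsat_day(ser, assign_period_ek(d, ek), win)
    }, numeric(1))
    dspi(pm, daily)$dspi
  }, numeric(1))
  weights <- simulate_growth(design, dspi_true, config)
  metadata <- cbind(design, weights[, c("w_i", "w_f", "parasite_mass")])
  structure(list(config = config, design = design, truth = truth,
                 curves = curves, irradiance = irradiance,
                 run_days = run_days, weights = weights,
                 metadata = metadata,
                 exclusions = attr(design, "exclusions")),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Synthetic study:", nrow(x$design), "plants,",
      length(x$curves), "RLCs,", length(x$irradiance), "logger days",
      sprintf("(seed %d)\n", x$config$seed))
  print(table(x$design$species, x$design$treatment))
  invisible(x)
}
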