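#' Pipeline configuration
#'
#' Collects inputs and analysis options for [run_pipeline()]. Inputs are
#' either a [simulate_study()] object (`study`) or paths to the three CSV
#' families (`rlc_csv`, `licor_csv`, `metadata_csv`).
#'
#' @param study a `sim_study`, or `NULL` when reading from files.
#' @param rlc_csv,licor_csv,metadata_csv input paths (ignored when `study`
#'   is given).
#' @param out_dir directory for stage outputs (created if needed); `NULL`
#'   to skip writing.
#' @param period_scheme default E_k period mapping; plants lacking a D5
#'   fit automatically fall back to `"no_d5"`.
#' @param hsat_mean_mode averaging mode for [mean_hsat()].
#' @param dspi_mean_mode averaging mode for [dspi()].
#' @param seed integer seed recorded in the manifest and set at the start
#'   of the run.
#' @param fit_models fit the mixed-model layer (needs >= 2 levels of each
#'   fixed factor per species).
#' @param responses responses modelled per species.
#' @param fixed,random model terms, see [fit_lmm()].
#' @param verbose print stage progress.
#' @return classed list (`pipeline_config`).
#' @export
pipeline_config <- function(study = NULL, rlc_csv = NULL, licor_csv = NULL,
                            metadata_csv = NULL, out_dir = NULL,
                            period_scheme = c("standard", "no_d5"),
                            hsat_mean_mode = c("period_means", "all_days"),
                            dspi_mean_mode = c("all_days", "period_means"),
                            seed = 1L, fit_models = TRUE,
                            responses = c("pmax", "ek", "h_sat",
                                          "rel_h_sat", "dspi", "growth_pct"),
                            fixed = c("treatment", "temperature"),
                            random = c("plant_id", "run", "rlc_order",
                                       "lunar_phase"),
                            verbose = FALSE) {
  if (is.null(study) &&
      (is.null(rlc_csv) || is.null(licor_csv) || is.null(metadata_csv)))
    stop("provide either `study` or all three input paths")
  structure(list(study = study, rlc_csv = rlc_csv, licor_csv = licor_csv,
                 metadata_csv = metadata_csv, out_dir = out_dir,
                 period_scheme = match.arg(period_scheme),
                 hsat_mean_mode = match.arg(hsat_mean_mode),
                 dspi_mean_mode = match.arg(dspi_mean_mode),
                 seed = as.integer(seed), fit_models = isTRUE(fit_models),
                 responses = responses, fixed = fixed, random = random,
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

say <- function(config, ...) if (config$verbose) message(...)

stage_fail <- function(stage, msg) {
  stop("pipeline stage '", stage, "' failed: ", msg, call. = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages: read/collect inputs, Webb fits, daily saturation (H_sat, day
#' length, rel-H_sat), production indices (DSPI, growth), study-table
#' assembly, and the mixed-model layer. Each stage logs exclusions rather
#' than dropping rows silently; input plant counts always equal output
#' rows plus exclusions. With a fixed seed and identical inputs the run is
#' deterministic, and every written file is byte-identical across runs.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a result bundle: `fits`, `saturation_daily`,
#'   `study_table`, `model_tests`, `growth_regressions`, `growth_dspi`,
#'   `exclusions`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  ## stage: inputs
  if (!is.null(config$study)) {
    study <- config$study
    curves <- study$curves
    irr <- study$irradiance
    metadata <- study$metadata
  } else {
    curves <- read_rlc_csv(config$rlc_csv)
    irr <- read_licor_csv(config$licor_csv)
    metadata <- read_metadata_csv(config$metadata_csv)
  }
  if (!nrow(metadata)) stage_fail("inputs", "empty metadata table")
  exclusions <- data.frame(plant_id = character(), stage = character(),
                           reason = character())
  note_excl <- function(pid, stage, reason)
    rbind(exclusions, data.frame(plant_id = pid, stage = stage,
                                 reason = reason))
  ## stage: Webb fits
  say(config, "fitting ", length(curves), " rapid light curves")
  fits <- fit_webb_all(curves)
  fx <- attr(fits, "exclusions")
  if (nrow(fx))
    exclusions <- note_excl(fx$plant_id, "rlc_fit", fx$reason)
  ## stage: saturation
  runs <- unique(metadata[, c("run", "run_start")])
  run_dates <- lapply(seq_len(nrow(runs)), function(i)
    as.character(as.Date(runs$run_start[i]) + 0:8))
  names(run_dates) <- as.character(runs$run)
  needed <- unlist(run_dates)
  if (!all(needed %in% names(irr)))
    stage_fail("saturation", paste("missing irradiance for date(s):",
                                   paste(setdiff(needed, names(irr)),
                                         collapse = ", ")))
  day_len <- vapply(needed, function(dt)
    as.numeric(day_length(condense_series(irr[[dt]]))), numeric(1))
  names(day_len) <- needed
  sat_rows <- list()
  plant_rows <- list()
  for (i in seq_len(nrow(metadata))) {
    pid <- metadata$plant_id[i]
    pf <- fits[fits$plant_id == pid, ]
    ek_by_day <- stats::setNames(pf$ek, pf$day_label)
    pm_by_day <- stats::setNames(pf$pmax, pf$day_label)
    if (!all(c("D1", "D9") %in% pf$day_label)) {
      exclusions <- note_excl(pid, "saturation",
                              "missing D1 or D9 fit; plant excluded")
      next
    }
    scheme <- if ("D5" %in% pf$day_label) config$period_scheme else "no_d5"
    cv_d1 <- curves[[paste(pid, "D1", sep = ".")]]
    cv_d9 <- curves[[paste(pid, "D9", sep = ".")]]
    dates <- run_dates[[as.character(metadata$run[i])]]
    daily <- vapply(1:9, function(d) {
      ser <- irr[[dates[d]]]
      win <- if (d == 1 && !is.na(cv_d1$timestamp))
        c(cv_d1$timestamp, max(ser$samples$minute))
      else if (d == 9 && !is.na(cv_d9$timestamp))
        c(min(ser$samples$minute), cv_d9$timestamp)
      else NULL
      as.numeric(hsat_day(ser, assign_period_ek(d, ek_by_day, scheme), win))
    }, numeric(1))
    dls <- day_len[dates]
    sat_rows[[pid]] <- data.frame(
      plant_id = pid, day_index = 1:9, h_sat_min = daily,
      ek_used = vapply(1:9, assign_period_ek, numeric(1),
                       ek_by_day = ek_by_day, scheme = scheme),
      day_length_min = unname(dls), scheme = scheme)
    d9 <- pf[pf$day_label == "D9", ]
    plant_rows[[pid]] <- data.frame(
      plant_id = pid,
      alpha = d9$alpha, ek = d9$ek, pmax = d9$pmax, retr_max = d9$retr_max,
      h_sat = mean_hsat(daily, scheme, config$hsat_mean_mode),
      rel_h_sat = rel_hsat(daily, unname(dls)),
      dspi = dspi(pm_by_day, daily, scheme, config$dspi_mean_mode)$dspi,
      growth_pct = growth_percent(metadata$w_i[i], metadata$w_f[i],
                                  metadata$parasite_mass[i]))
  }
  saturation_daily <- do.call(rbind, sat_rows)
  rownames(saturation_daily) <- NULL
  ## stage: study table
  plant_tab <- do.call(rbind, plant_rows)
  study_table <- merge(metadata, plant_tab, by = "plant_id")
  trt_levels <- intersect(c("T0", "T1", "T2", "T2.5", "T3", "T4"),
                          unique(study_table$treatment))
  study_table$treatment <- factor(study_table$treatment, levels = trt_levels)
  study_table$temperature <- factor(study_table$temperature,
                                    levels = sort(unique(
                                      study_table$temperature)))
  study_table <- study_table[order(study_table$plant_id), ]
  rownames(study_table) <- NULL
  if (nrow(study_table) + length(unique(exclusions$plant_id)) <
      nrow(metadata))
    stage_fail("study_table", "row accounting failure: rows were lost
without an exclusion record")
  ## stage: models
  model_tests <- NULL
  growth_regs <- NULL
  growth_dspi <- NULL
  if (config$fit_models) {
    say(config, "fitting mixed models")
    mt <- list()
    gr <- list()
    gd <- list()
    for (sp in unique(study_table$species)) {
      st <- droplevels(study_table[study_table$species == sp, ])
      enough <- all(vapply(setdiff(config$fixed, "1"), function(tm)
        length(unique(st[[tm]])) >= 2L, logical(1)))
      if (!enough || nrow(st) < 20L) {
        say(config, "skipping models for ", sp,
            ": not enough design variation")
        next
      }
      for (resp in intersect(config$responses, names(st))) {
        res <- lrt_fixed_effects(st, resp, config$fixed, config$random)
        tests <- res$tests
        tests <- cbind(species = sp, response = resp, tests,
                       r2_marginal = res$fit$r2_marginal,
                       r2_conditional = res$fit$r2_conditional,
                       random_used = paste(res$fit$random, collapse = "+"),
                       singular = res$fit$singular)
        mt[[paste(sp, resp)]] <- tests
      }
      gr[[sp]] <- cbind(species = sp, fit_growth_regressions(st))
      g <- growth_dspi_lmm(st)
      gd[[sp]] <- data.frame(species = sp,
                             slope = g$slope[["estimate"]],
                             se = g$slope[["se"]],
                             chi2 = g$lrt$chi2, df = g$lrt$df,
                             p_value = g$lrt$p_value,
                             r2_conditional = g$fit$r2_conditional)
    }
    model_tests <- if (length(mt)) do.call(rbind, mt) else NULL
    growth_regs <- if (length(gr)) do.call(rbind, gr) else NULL
    growth_dspi <- if (length(gd)) do.call(rbind, gd) else NULL
    if (!is.null(model_tests)) rownames(model_tests) <- NULL
    if (!is.null(growth_regs)) rownames(growth_regs) <- NULL
    if (!is.null(growth_dspi)) rownames(growth_dspi) <- NULL
  }
  ## manifest (no wall-clock content: runs must be byte-identical)
  opts <- config[c("period_scheme", "hsat_mean_mode", "dspi_mean_mode",
                   "seed", "fit_models", "responses", "fixed", "random")]
  hash_file <- tempfile()
  writeLines(paste(deparse(opts), collapse = ""), hash_file)
  manifest <- list(
    package = "dspi",
    version = as.character(utils::packageVersion("dspi")),
    seed = config$seed,
    options = opts,
    config_hash = unname(tools::md5sum(hash_file)),
    n_curves_in = length(curves),
    n_curves_fit = nrow(fits),
    n_plants_in = nrow(metadata),
    n_plants_out = nrow(study_table),
    n_exclusions = nrow(exclusions))
  unlink(hash_file)
  bundle <- list(fits = fits, saturation_daily = saturation_daily,
                 study_table = study_table, model_tests = model_tests,
                 growth_regressions = growth_regs,
                 growth_dspi = growth_dspi,
                 exclusions = exclusions, manifest = manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) if (!is.null(x))
      utils::write.csv(x, file.path(config$out_dir, f), row.names = FALSE)
    w(fits, "fits.csv")
    w(saturation_daily, "saturation_daily.csv")
    w(study_table, "study_table.csv")
    w(model_tests, "model_tests.csv")
    w(growth_regs, "growth_regressions.csv")
    w(growth_dspi, "growth_dspi.csv")
    w(exclusions, "exclusions.csv")
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(bundle)
}
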