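# CSV readers/writers for the three input families. Canonical dialect:
# comma-separated, header row, UTF-8, ISO 8601 local timestamps
# ("YYYY-MM-DD HH:MM:SS"); times are wall-clock local.

iso_minute <- function(ts) {
  # minutes since midnight from an ISO 8601 local timestamp (date optional)
  hhmm <- sub("^\\d{4}-\\d{2}-\\d{2}[ T]", "", ts)
  hh <- suppressWarnings(as.integer(substr(hhmm, 1, 2)))
  mm <- suppressWarnings(as.integer(substr(hhmm, 4, 5)))
  hh * 60L + mm
}

iso_date <- function(ts) {
  d <- substr(ts, 1, 10)
  ifelse(grepl("^\\d{4}-\\d{2}-\\d{2}$", d), d, NA_character_)
}

#' Write rapid light curves to CSV
#'
#' One row per step: `plant_id`, `species`, `day_label`, `timestamp`,
#' `rlc_order`, `step_index`, `e_par`, `phi_psii`.
#'
#' @param curves list of [rlc_curve()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rlc_csv <- function(curves, path) {
  rows <- lapply(curves, function(cv) {
    ts <- if (!is.na(cv$timestamp)) {
      sprintf("%s%02d:%02d:00",
              if (!is.na(cv$date)) paste0(cv$date, " ") else "",
              cv$timestamp %/% 60L, cv$timestamp %% 60L)
    } else ""
    data.frame(plant_id = cv$plant_id, species = cv$species,
               day_label = cv$day_label, timestamp = ts,
               rlc_order = cv$rlc_order,
               step_index = cv$steps$step_index,
               e_par = cv$steps$e_par, phi_psii = cv$steps$phi_psii)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read rapid light curves from CSV
#'
#' Parses a WinControl-style per-step export into validated curves grouped
#' by `(plant_id, day_label)`. Rows with missing or out-of-range values are
#' not silently dropped: they are collected in the `"rejects"` attribute.
#' Duplicate `(plant_id, day_label, step_index)` rows are a data error;
#' steps out of irradiance order are sorted with a warning.
#'
#' @param path CSV file with columns `plant_id`, `species`, `day_label`,
#'   `timestamp`, `rlc_order`, `step_index`, `e_par`, `phi_psii`.
#' @return named list of [rlc_curve()] (names `plant_id.day_label`);
#'   attribute `"rejects"` holds the malformed rows.
#' @export
read_rlc_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("plant_id", "day_label", "step_index", "e_par", "phi_psii")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols))
    stop("RLC file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"species" %in% names(d)) d$species <- NA_character_
  if (!"timestamp" %in% names(d)) d$timestamp <- ""
  if (!"rlc_order" %in% names(d)) d$rlc_order <- NA_integer_
  d$e_par <- suppressWarnings(as.numeric(d$e_par))
  d$phi_psii <- suppressWarnings(as.numeric(d$phi_psii))
  bad <- is.na(d$plant_id) | !nzchar(as.character(d$plant_id)) |
    is.na(d$day_label) | is.na(d$e_par) | is.na(d$phi_psii) |
    d$e_par < 0 | d$phi_psii < 0 | d$phi_psii > 1
  rejects <- d[bad, , drop = FALSE]
  d <- d[!bad, , drop = FALSE]
  key <- paste(d$plant_id, d$day_label, d$step_index)
  if (anyDuplicated(key))
    stop("duplicate (plant_id, day_label, step_index) rows in ", path)
  groups <- split(d, paste(d$plant_id, d$day_label, sep = "."))
  curves <- lapply(groups, function(g) {
    g <- g[order(g$step_index), ]
    rlc_curve(g$plant_id[1], g$day_label[1], g$e_par, g$phi_psii,
              timestamp = iso_minute(g$timestamp[1]),
              rlc_order = g$rlc_order[1],
              species = g$species[1],
              date = iso_date(g$timestamp[1]))
  })
  attr(curves, "rejects") <- rejects
  curves
}

#' Write irradiance series to a LI-COR-style CSV
#'
#' Two columns: `timestamp` (ISO 8601 local) and `e_par`.
#'
#' @param series_list list of [irradiance_series()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_licor_csv <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    data.frame(timestamp = sprintf("%s %02d:%02d:00", s$date,
                                   s$samples$minute %/% 60L,
                                   s$samples$minute %% 60L),
               e_par = s$samples$e_par)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a LI-COR-style irradiance CSV
#'
#' One [irradiance_series()] per calendar day. Duplicated minutes are
#' averaged with a warning; decreasing timestamps within a day are a data
#' error; gaps longer than one minute are reported in the `"gaps"`
#' attribute (`date`, `from_minute`, `to_minute`), never filled.
#'
#' @param path CSV file (or vector of files covering the same period,
#'   merged) with columns `timestamp`, `e_par`.
#' @return named list of [irradiance_series()] keyed by date; attribute
#'   `"gaps"`.
#' @export
read_licor_csv <- function(path) {
  d <- do.call(rbind, lapply(path, function(p) {
    x <- utils::read.csv(p, stringsAsFactors = FALSE)
    if (!all(c("timestamp", "e_par") %in% names(x)))
      stop("irradiance file ", p, " must have columns timestamp, e_par")
    x
  }))
  d$date <- iso_date(d$timestamp)
  d$minute <- iso_minute(d$timestamp)
  if (any(is.na(d$date)) || any(is.na(d$minute)))
    stop("unparseable timestamps in irradiance input")
  d$e_par <- suppressWarnings(as.numeric(d$e_par))
  gaps <- list()
  out <- list()
  for (dt in sort(unique(d$date))) {
    g <- d[d$date == dt, ]
    if (is.unsorted(g$minute))
      stop("non-monotone timestamps within ", dt)
    if (anyDuplicated(g$minute)) {
      warning("duplicated minutes on ", dt, " averaged")
      g <- stats::aggregate(e_par ~ minute, data = g, FUN = mean)
    }
    g <- g[order(g$minute), ]
    dm <- diff(g$minute)
    if (any(dm > 1L)) {
      at <- which(dm > 1L)
      gaps[[dt]] <- data.frame(date = dt,
                               from_minute = g$minute[at] + 1L,
                               to_minute = g$minute[at + 1L] - 1L)
    }
    out[[dt]] <- irradiance_series(dt, g$minute, g$e_par)
  }
  attr(out, "gaps") <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(date = character(), from_minute = integer(),
               to_minute = integer())
  out
}

#' Write/read the plant metadata table
#'
#' One row per plant: design cell, run bookkeeping and wet weights.
#'
#' @param metadata data.frame with at least `plant_id`, `species`,
#'   `treatment`, `temperature`, `run`, `run_start`, `rlc_order`,
#'   `lunar_phase`, `w_i`, `w_f`, `parasite_mass`.
#' @param path CSV file.
#' @return `write_metadata_csv`: `path`, invisibly; `read_metadata_csv`:
#'   the validated data.frame.
#' @export
write_metadata_csv <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_csv
#' @export
read_metadata_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("plant_id", "species", "treatment", "temperature", "run",
           "run_start", "rlc_order", "lunar_phase", "w_i", "w_f",
           "parasite_mass")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols))
    stop("metadata file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!nrow(d)) stop("metadata table is empty")
  if (anyDuplicated(d$plant_id)) stop("duplicate plant_id in metadata")
  d
}
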