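#' Webb photosynthesis-irradiance model, yield-normalized form
#'
#' Effective quantum yield predicted at irradiance `e_par` under the
#' exponential-saturation (Webb) model normalized to irradiance:
#' \deqn{\Phi(E) = \alpha \, (E_k/E) \, (1 - e^{-E/E_k})}
#' with the continuous extension \eqn{\Phi(0) = \alpha}. The normalization
#' removes the intrinsic irradiance dependence of PAM quantum-yield
#' measurements, so the curve can be fitted to \eqn{\Phi_{PSII}} directly.
#' The associated rate curve is \eqn{P(E) = \alpha E_k (1 - e^{-E/E_k})},
#' with \eqn{P_{max} = \alpha E_k}.
#'
#' @param e_par irradiance, \eqn{\mu}mol photons m\eqn{^{-2}} s\eqn{^{-1}},
#'   non-negative, vectorized.
#' @param alpha initial slope of the PE curve (light-limited efficiency).
#' @param ek saturation irradiance \eqn{E_k} (> 0), same units as `e_par`.
#' @return numeric vector of predicted quantum yields.
#' @examples
#' webb_phi(c(0, 65, 820), alpha = 0.65, ek = 100)
#' @export
webb_phi <- function(e_par, alpha, ek) {
  if (ek <= 0) stop("`ek` must be > 0")
  if (any(e_par < 0)) stop("`e_par` must be non-negative")
  phi <- rep(alpha, length(e_par))
  pos <- e_par > 0
  phi[pos] <- alpha * (ek / e_par[pos]) * (1 - exp(-e_par[pos] / ek))
  phi
}

#' Construct a rapid light curve
#'
#' One plant's RLC on one day: ordered actinic steps with the effective
#' quantum yield measured at each. Steps are stored sorted by increasing
#' irradiance; if the supplied order differs, they are sorted with a warning
#' (instrument exports occasionally shuffle rows).
#'
#' @param plant_id plant identifier.
#' @param day_label one of `"D1"`, `"D5"`, `"D9"`.
#' @param e_par actinic irradiances (>= 0), at least 4 distinct values.
#' @param phi_psii effective quantum yields in `[0, 1]`, same length.
#' @param timestamp measurement clock time in minutes since midnight
#'   (integer), or `NA`.
#' @param rlc_order ordinal position in the morning measurement sequence.
#' @param species optional species label.
#' @param date optional calendar date (`"YYYY-MM-DD"`).
#' @return an object of class `rlc_curve`.
#' @examples
#' rlc_curve("p1", "D1",
#'           e_par = c(0, 65, 90, 125, 190, 285, 420, 625, 820),
#'           phi_psii = webb_phi(c(0, 65, 90, 125, 190, 285, 420, 625, 820),
#'                               0.6, 90))
#' @export
rlc_curve <- function(plant_id, day_label, e_par, phi_psii,
                      timestamp = NA_integer_, rlc_order = NA_integer_,
                      species = NA_character_, date = NA_character_) {
  if (length(e_par) != length(phi_psii))
    stop("`e_par` and `phi_psii` must have the same length")
  if (length(e_par) < 4L)
    stop("an RLC needs at least 4 steps, got ", length(e_par))
  if (anyDuplicated(e_par))
    stop("`e_par` values must be distinct")
  if (!all(is.finite(e_par)) || any(e_par < 0))
    stop("`e_par` must be finite and non-negative")
  if (!all(is.finite(phi_psii)) || any(phi_psii < 0) || any(phi_psii > 1))
    stop("`phi_psii` must be finite and within [0, 1]")
  if (is.unsorted(e_par, strictly = TRUE)) {
    warning("RLC steps for plant ", plant_id, " (", day_label,
            ") were not in increasing irradiance order; sorting")
    o <- order(e_par)
    e_par <- e_par[o]
    phi_psii <- phi_psii[o]
  }
  structure(
    list(plant_id = as.character(plant_id),
         day_label = as.character(day_label),
         timestamp = as.integer(timestamp),
         rlc_order = as.integer(rlc_order),
         species = as.character(species),
         date = as.character(date),
         steps = data.frame(step_index = seq_along(e_par),
                            e_par = as.numeric(e_par),
                            phi_psii = as.numeric(phi_psii))),
    class = "rlc_curve")
}

#' @export
print.rlc_curve <- function(x, ...) {
  cat("Rapid light curve:", x$plant_id, x$day_label,
      sprintf("(%d steps)\n", nrow(x$steps)))
  print(x$steps, row.names = FALSE)
  invisible(x)
}

# Start values for the bounded fit: alpha0 from the yield at the lowest
# nonzero irradiance, Ek0 from where the yield first halves (fallback 100).
webb_start <- function(e_par, phi) {
  nz <- which(e_par > 0)
  a0 <- if (length(nz)) phi[nz[1]] else phi[1]
  if (!is.finite(a0) || a0 <= 0) a0 <- max(phi, 0.05)
  below <- which(phi < a0 / 2 & e_par > 0)
  k0 <- if (length(below)) e_par[below[1]] else 100
  c(alpha = min(max(a0, 1e-3), 2), ek = min(max(k0, 1), 2000))
}

#' Fit the yield-normalized Webb model to a rapid light curve
#'
#' Bounded Levenberg-Marquardt least squares of [webb_phi()] against the
#' observed yields, minimizing \eqn{\sum (\Phi_{obs} - \Phi_{model})^2}.
#' Unweighted: the irradiance normalization itself stabilizes the variance
#' of quantum-yield observations. The `E = 0` step participates through the
#' analytic limit \eqn{\Phi(0) = \alpha}, so all nine actinic levels of a
#' standard protocol inform the fit.
#'
#' Curves whose yields are all zero (plants unable to sustain a usable
#' fluorescence signal) are rejected with a classed condition
#' (`"dspi_unfittable_curve"`) so callers can exclude the plant rather than
#' crash; optimizer non-convergence is reported via `converged = FALSE`,
#' never as an error.
#'
#' @param curve an [rlc_curve()].
#' @param lower,upper bounds on `c(alpha, ek)`.
#' @param ftol convergence tolerance on the reduction of the residual sum
#'   of squares.
#' @param maxiter maximum optimizer iterations.
#' @return an object of class `pe_fit`: list with `alpha`, `ek`,
#'   `pmax` (`= alpha * ek`), `retr_max` (see [compute_retr_max()]),
#'   `rss`, `converged`, optimizer `info`/`message`, and the curve's
#'   identifiers.
#' @examples
#' e <- c(0, 65, 90, 125, 190, 285, 420, 625, 820)
#' cv <- rlc_curve("p1", "D1", e, webb_phi(e, 0.3, 100))
#' fit_webb(cv)
#' @seealso [compute_pmax()], [compute_retr_max()]
#' @export
fit_webb <- function(curve, lower = c(1e-6, 1e-3), upper = c(2, 2000),
                     ftol = 1e-15, maxiter = 500L) {
  stopifnot(inherits(curve, "rlc_curve"))
  e <- curve$steps$e_par
  y <- curve$steps$phi_psii
  if (length(e) < 4L) stop("fit requires at least 4 steps")
  if (all(y <= 0)) {
    cond <- structure(
      class = c("dspi_unfittable_curve", "error", "condition"),
      list(message = paste0("unfittable curve: all yields are zero for plant ",
                            curve$plant_id, " (", curve$day_label, ")"),
           call = sys.call(-1), plant_id = curve$plant_id,
           day_label = curve$day_label))
    stop(cond)
  }
  start <- webb_start(e, y)
  start <- pmin(pmax(start, lower), upper)
  res <- minpack.lm::nls.lm(
    par = start,
    lower = lower, upper = upper,
    fn = function(p) y - webb_phi(e, p[1], p[2]),
    control = minpack.lm::nls.lm.control(
      ftol = ftol, ptol = ftol, gtol = 0, maxiter = maxiter))
  alpha <- unname(res$par[1])
  ek <- unname(res$par[2])
  structure(
    list(plant_id = curve$plant_id,
         day_label = curve$day_label,
         alpha = alpha,
         ek = ek,
         pmax = compute_pmax(alpha, ek),
         retr_max = compute_retr_max(curve),
         rss = res$deviance,
         converged = res$info %in% 1:4,
         info = res$info,
         message = res$message,
         n_steps = length(e)),
    class = "pe_fit")
}

#' @export
print.pe_fit <- function(x, ...) {
  cat(sprintf(
    "Webb PE fit [%s %s]: alpha = %.4f, Ek = %.2f, Pmax = %.2f, rETRmax = %s\n",
    x$plant_id, x$day_label, x$alpha, x$ek, x$pmax,
    ifelse(is.na(x$retr_max), "NA", sprintf("%.2f", x$retr_max))))
  cat(sprintf("  RSS = %.3g, converged = %s\n", x$rss, x$converged))
  invisible(x)
}

#' Maximum photosynthetic rate from fitted parameters
#'
#' \eqn{P_{max} = \alpha \times E_k}, in \eqn{\mu}mol electrons
#' m\eqn{^{-2}} s\eqn{^{-1}}.
#'
#' @param alpha initial slope (>= 0).
#' @param ek saturation irradiance (> 0).
#' @return numeric, the exact product.
#' @examples
#' compute_pmax(0.65, 80) # 52
#' @export
compute_pmax <- function(alpha, ek) {
  if (any(!is.finite(alpha)) || any(!is.finite(ek)))
    stop("`alpha` and `ek` must be finite")
  if (any(alpha < 0)) stop("`alpha` must be >= 0")
  if (any(ek <= 0)) stop("`ek` must be > 0")
  alpha * ek
}

#' Relative maximum electron transport rate
#'
#' Per-step relative ETR is \eqn{E_{par} \times \Phi_{PSII}} (no absorption
#' factor). `rETR_max` is the largest per-step rETR among steps whose yield
#' passes the reliability screen \eqn{\Phi_{PSII} > 0.1}; steps at or below
#' 0.1 are never used. Returns `NA` when no step qualifies. Ties in the
#' product are broken toward the lower irradiance step (conservative with
#' respect to photoinhibited plateaus).
#'
#' @param curve an [rlc_curve()].
#' @return numeric scalar or `NA_real_`.
#' @examples
#' e <- c(0, 65, 90, 125, 190, 285, 420, 625, 820)
#' phi <- c(0.60, 0.50, 0.45, 0.40, 0.30, 0.22, 0.12, 0.08, 0.05)
#' compute_retr_max(rlc_curve("p1", "D1", e, phi)) # 62.7 at E = 285
#' @export
compute_retr_max <- function(curve) {
  stopifnot(inherits(curve, "rlc_curve"))
  ok <- curve$steps$phi_psii > 0.1
  if (!any(ok)) return(NA_real_)
  e <- curve$steps$e_par[ok]
  retr <- e * curve$steps$phi_psii[ok]
  best <- which(retr == max(retr))
  if (length(best) > 1L) best <- best[which.min(e[best])]
  retr[best]
}

#' Collect Webb fits for many curves into a table
#'
#' Applies [fit_webb()] to each curve, turning unfittable curves into
#' exclusion records instead of errors (mirroring the removal of
#' depigmented individuals from an experiment).
#'
#' @param curves list of [rlc_curve()] objects.
#' @param ... passed to [fit_webb()].
#' @return data.frame with one row per fitted curve (`plant_id`,
#'   `day_label`, `alpha`, `ek`, `pmax`, `retr_max`, `rss`, `converged`);
#'   attribute `"exclusions"` holds a data.frame of rejected curves.
#' @export
fit_webb_all <- function(curves, ...) {
  rows <- list()
  excl <- list()
  for (cv in curves) {
    f <- tryCatch(fit_webb(cv, ...),
                  dspi_unfittable_curve = function(e) e)
    if (inherits(f, "dspi_unfittable_curve")) {
      excl[[length(excl) + 1L]] <- data.frame(
        plant_id = cv$plant_id, day_label = cv$day_label,
        reason = "unfittable curve (all yields zero)")
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        plant_id = f$plant_id, day_label = f$day_label,
        alpha = f$alpha, ek = f$ek, pmax = f$pmax,
        retr_max = f$retr_max, rss = f$rss, converged = f$converged)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(plant_id = character(), day_label = character(),
               alpha = numeric(), ek = numeric(), pmax = numeric(),
               retr_max = numeric(), rss = numeric(), converged = logical())
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(plant_id = character(), day_label = character(),
               reason = character())
  out
}
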