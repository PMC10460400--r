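#' Fit a Gaussian linear mixed model with a singularity fallback
#'
#' Fits `response ~ fixed + (1 | r)` for each random intercept term via
#' [lme4::lmer()], by maximum likelihood (`REML = FALSE`) so that nested
#' fits with different fixed-effect structures have comparable likelihoods
#' for likelihood-ratio tests. If the fit is singular, droppable random
#' terms are removed one at a time in `drop_order` and the model is refit;
#' terms in `never_drop` (plant identity, by default) are always kept, and
#' a fit that stays singular after all droppable terms are gone is returned
#' with `singular = TRUE` rather than an error. With no random terms the
#' model degenerates to ordinary least squares ([stats::lm()]).
#'
#' @param data data.frame, one row per plant-replicate.
#' @param response name of the response column.
#' @param fixed character vector of fixed-effect terms (`"1"` for an
#'   intercept-only fixed part).
#' @param random character vector of random-intercept grouping columns
#'   (may be empty).
#' @param drop_order order in which singular fits shed random terms.
#' @param never_drop random terms never dropped.
#' @return object of class `lmm_fit`: the underlying model plus `logLik`
#'   (ML), `n_par_fixed`, `nobs`, coefficient table, variance components,
#'   `r2_marginal`, `r2_conditional`, `singular`, and the random terms
#'   used/dropped.
#' @examples
#' d <- data.frame(y = rnorm(40), tr = gl(4, 10), g = gl(8, 5))
#' fit_lmm(d, "y", "tr", "g")
#' @export
fit_lmm <- function(data, response, fixed = c("treatment", "temperature"),
                    random = c("plant_id", "run", "rlc_order", "lunar_phase"),
                    drop_order = c("lunar_phase", "rlc_order", "run"),
                    never_drop = "plant_id") {
  stopifnot(is.data.frame(data), response %in% names(data))
  data <- droplevels(data)
  fixed <- fixed[nzchar(fixed)]
  if (!length(fixed)) fixed <- "1"
  random <- intersect(random, names(data))
  # a grouping factor needs at least two sampled levels to carry a variance
  random <- random[vapply(random, function(r)
    length(unique(data[[r]])) >= 2L, logical(1))]
  # pre-checks: >= 2 levels per fixed factor, no aliased fixed columns
  for (tm in setdiff(fixed, "1")) {
    if (tm %in% names(data) && !is.numeric(data[[tm]]) &&
        length(unique(data[[tm]])) < 2L)
      stop("fixed factor '", tm, "' has fewer than 2 levels")
  }
  X <- stats::model.matrix(stats::reformulate(fixed), data = data)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("fixed-effect design is rank deficient; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  fixed_rhs <- paste(fixed, collapse = " + ")
  dropped <- character()
  if (!length(random)) {
    model <- stats::lm(stats::reformulate(fixed, response = response),
                       data = data)
    singular <- FALSE
  } else {
    fit1 <- function(rnd) {
      fml <- stats::as.formula(paste(
        response, "~", fixed_rhs, "+",
        paste(sprintf("(1 | %s)", rnd), collapse = " + ")))
      # one observation per plant is legal here: the plant-level variance
      # is then confounded with the residual and the fit is flagged
      # singular, but plant identity is never silently discarded
      suppressMessages(suppressWarnings(
        lme4::lmer(fml, data = data, REML = FALSE,
                   control = lme4::lmerControl(
                     check.nobs.vs.nlev = "ignore",
                     check.nobs.vs.nRE = "ignore"))))
    }
    rnd <- random
    model <- fit1(rnd)
    while (lme4::isSingular(model, tol = 1e-4)) {
      droppable <- intersect(drop_order, setdiff(rnd, never_drop))
      if (!length(droppable)) break
      dropped <- c(dropped, droppable[1])
      rnd <- setdiff(rnd, droppable[1])
      if (!length(rnd)) {
        model <- stats::lm(stats::reformulate(fixed, response = response),
                           data = data)
        break
      }
      model <- fit1(rnd)
    }
    random <- setdiff(random, dropped)
    singular <- inherits(model, "merMod") && lme4::isSingular(model, tol = 1e-4)
  }
  is_mer <- inherits(model, "merMod")
  beta <- if (is_mer) lme4::fixef(model) else stats::coef(model)
  coefs <- if (is_mer) as.data.frame(summary(model)$coefficients) else
    as.data.frame(summary(model)$coefficients)[, 1:3]
  vc <- if (is_mer) {
    v <- lme4::VarCorr(model)
    stats::setNames(vapply(v, function(m) m[1, 1], numeric(1)), names(v))
  } else numeric()
  r2 <- r2_nakagawa_(model)
  structure(
    list(model = model,
         response = response,
         fixed = fixed,
         random = random,
         dropped = dropped,
         singular = singular,
         reml = FALSE,
         logLik = as.numeric(stats::logLik(model)),
         n_par_fixed = length(beta),
         nobs = stats::nobs(model),
         coefficients = coefs,
         varcomp = vc,
         sigma = stats::sigma(model),
         r2_marginal = r2[["r2_marginal"]],
         r2_conditional = r2[["r2_conditional"]]),
    class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("LMM (ML): %s ~ %s%s\n", x$response,
              paste(x$fixed, collapse = " + "),
              if (length(x$random))
                paste0(" + ", paste(sprintf("(1|%s)", x$random),
                                    collapse = " + ")) else ""))
  if (length(x$dropped))
    cat("  random terms dropped for singularity:",
        paste(x$dropped, collapse = ", "), "\n")
  cat(sprintf("  n = %d, logLik = %.2f, R2m = %.3f, R2c = %.3f%s\n",
              x$nobs, x$logLik, x$r2_marginal, x$r2_conditional,
              if (x$singular) " [singular]" else ""))
  invisible(x)
}

# Nakagawa-Schielzeth variance decomposition for a Gaussian identity-link
# model: fixed-effect variance is the variance of the fixed linear
# predictor; random variance the sum of random-intercept variances.
r2_nakagawa_ <- function(model) {
  if (inherits(model, "merMod")) {
    X <- lme4::getME(model, "X")
    vf <- stats::var(as.vector(X %*% lme4::fixef(model)))
    vr <- sum(vapply(lme4::VarCorr(model), function(m) m[1, 1], numeric(1)))
    ve <- stats::sigma(model)^2
  } else {
    vf <- stats::var(stats::fitted(model))
    vr <- 0
    ve <- stats::sigma(model)^2
  }
  tot <- vf + vr + ve
  if (tot <= 0) return(c(r2_marginal = 0, r2_conditional = 0))
  c(r2_marginal = vf / tot, r2_conditional = (vf + vr) / tot)
}

#' Marginal and conditional R2 for a mixed-model fit
#'
#' Nakagawa-Schielzeth coefficients of determination for a Gaussian LMM:
#' marginal R2 is the fixed-effect variance over the total (fixed + random
#' + residual); conditional R2 adds the random-intercept variance to the
#' numerator. Always `0 <= R2m <= R2c <= 1`.
#'
#' @param fit an [fit_lmm()] result (or a raw `merMod`/`lm`).
#' @return named numeric: `r2_marginal`, `r2_conditional`.
#' @export
r2_nakagawa <- function(fit) {
  model <- if (inherits(fit, "lmm_fit")) fit$model else fit
  r2_nakagawa_(model)
}

#' Likelihood-ratio test between nested ML fits
#'
#' \eqn{\chi^2 = 2(\ell_{full} - \ell_{reduced})}, clipped at zero, with
#' degrees of freedom equal to the difference in fixed-effect parameter
#' counts (the random structure must be identical, so only fixed parameters
#' differ). Both fits must be maximum likelihood on the same data; the
#' reduced fixed terms must be a subset of the full ones.
#'
#' @param full,reduced [fit_lmm()] objects.
#' @return object of class `lrt_result`: `chi2`, `df`, `p_value`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "lmm_fit"), inherits(reduced, "lmm_fit"))
  if (isTRUE(full$reml) || isTRUE(reduced$reml))
    stop("likelihood-ratio tests require ML fits (REML = FALSE)")
  if (full$nobs != reduced$nobs)
    stop("fits use different numbers of observations; refit on common data")
  full_terms <- setdiff(full$fixed, "1")
  red_terms <- setdiff(reduced$fixed, "1")
  if (!all(red_terms %in% full_terms))
    stop("models are not nested: reduced fixed terms are not a subset ",
         "of the full model's")
  if (!identical(sort(full$random), sort(reduced$random)))
    stop("models are not nested: random structures differ")
  df <- full$n_par_fixed - reduced$n_par_fixed
  if (df < 0) stop("reduced model has more fixed parameters than the full")
  chi2 <- max(0, 2 * (full$logLik - reduced$logLik))
  p <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else 1
  structure(list(chi2 = chi2, df = as.integer(df), p_value = p),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi2(%d) = %.2f, p = %.4g\n", x$df, x$chi2, x$p_value))
  invisible(x)
}

#' Likelihood-ratio tests for each fixed effect of a study model
#'
#' Fits the full model once (with the singularity fallback), then for each
#' tested term refits a null lacking that term with the *same* random
#' structure as the pruned full model, and compares by [lrt()].
#'
#' @param data study table.
#' @param response response column name.
#' @param fixed fixed-effect terms of the full model.
#' @param random candidate random intercept terms.
#' @param test_terms fixed terms to test (default: all of `fixed`).
#' @param ... passed to [fit_lmm()].
#' @return list with `fit` (full model) and `tests`, a data.frame of
#'   `effect`, `chi2`, `df`, `p_value`.
#' @export
lrt_fixed_effects <- function(data, response,
                              fixed = c("treatment", "temperature"),
                              random = c("plant_id", "run", "rlc_order",
                                         "lunar_phase"),
                              test_terms = fixed, ...) {
  full <- fit_lmm(data, response, fixed, random, ...)
  rows <- lapply(test_terms, function(tm) {
    red_fixed <- setdiff(fixed, tm)
    if (!length(red_fixed)) red_fixed <- "1"
    reduced <- fit_lmm(data, response, red_fixed, full$random,
                       drop_order = character())
    tst <- lrt(full, reduced)
    data.frame(effect = tm, chi2 = tst$chi2, df = tst$df,
               p_value = tst$p_value)
  })
  list(fit = full, tests = do.call(rbind, rows))
}

#' Simple growth regressions on photophysiology predictors
#'
#' Ordinary least-squares regressions of percent growth on each predictor
#' separately, reporting slope, standard error, t-test p-value and R2.
#'
#' @param table study table with a `growth_pct` column.
#' @param predictors predictor column names fitted one at a time.
#' @return data.frame, one row per predictor.
#' @export
fit_growth_regressions <- function(table,
                                   predictors = c("pmax", "ek", "h_sat",
                                                  "dspi")) {
  stopifnot("growth_pct" %in% names(table))
  predictors <- intersect(predictors, names(table))
  if (!length(predictors)) stop("no predictor columns found")
  rows <- lapply(predictors, function(p) {
    x <- table[[p]]
    if (stats::sd(x, na.rm = TRUE) == 0)
      stop("predictor '", p, "' is constant")
    m <- stats::lm(stats::reformulate(p, "growth_pct"), data = table)
    s <- summary(m)$coefficients
    data.frame(predictor = p, slope = s[2, 1], se = s[2, 2],
               p_value = s[2, 4], r_squared = summary(m)$r.squared)
  })
  do.call(rbind, rows)
}

#' Growth as a function of DSPI, with treatment as a random effect
#'
#' Fits `growth_pct ~ dspi + (1 | treatment)` by ML and tests the DSPI
#' slope with a likelihood-ratio test against the slope-free null (same
#' random structure). With fewer than two treatment levels the random
#' intercept degenerates and the model falls back to a simple regression
#' with a warning.
#'
#' @param table study table with `growth_pct`, `dspi`, `treatment`.
#' @return list with `fit` (full model), `null`, `lrt`, and `slope`
#'   (estimate and standard error for the DSPI coefficient).
#' @export
growth_dspi_lmm <- function(table) {
  stopifnot(all(c("growth_pct", "dspi", "treatment") %in% names(table)))
  if (length(unique(table$treatment)) < 2L) {
    warning("fewer than 2 treatment levels; falling back to simple ",
            "regression without the treatment random intercept")
    rnd <- character()
  } else {
    rnd <- "treatment"
  }
  full <- fit_lmm(table, "growth_pct", "dspi", rnd,
                  drop_order = character(), never_drop = rnd)
  null <- fit_lmm(table, "growth_pct", "1", rnd,
                  drop_order = character(), never_drop = rnd)
  cf <- full$coefficients
  list(fit = full, null = null, lrt = lrt(full, null),
       slope = c(estimate = cf["dspi", 1], se = cf["dspi", 2]))
}
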