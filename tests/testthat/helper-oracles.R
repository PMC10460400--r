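# Independent oracles: plain loops and exhaustive enumeration, written
# without reference to the package implementations they check.

# trailing 10-min moving average sampled at grid minutes, by explicit loop
oracle_condense <- function(series) {
  m <- series$samples$minute
  e <- series$samples$e_par
  lo <- 10L * as.integer(ceiling(min(m) / 10))
  hi <- 10L * (max(m) %/% 10L)
  grid <- if (lo <= hi) as.integer(seq.int(lo, hi, by = 10)) else integer()
  if (!length(grid)) {
    return(data.frame(minute = 10L * as.integer(ceiling(max(m) / 10)),
                      e_par = sum(e) / length(e)))
  }
  vals <- numeric(length(grid))
  for (j in seq_along(grid)) {
    s <- 0; n <- 0L
    for (i in seq_along(m)) {
      if (m[i] >= grid[j] - 9L && m[i] <= grid[j]) {
        s <- s + e[i]; n <- n + 1L
      }
    }
    vals[j] <- s / n
  }
  data.frame(minute = grid, e_par = vals)
}

oracle_day_length <- function(cond_df) {
  n <- 0L
  for (i in seq_len(nrow(cond_df))) if (cond_df$e_par[i] >= 1) n <- n + 1L
  10L * n
}

oracle_hsat <- function(series, ek, window = NULL) {
  m <- series$samples$minute
  e <- series$samples$e_par
  if (is.null(window)) window <- c(min(m), max(m))
  n <- 0L
  for (i in seq_along(m))
    if (m[i] >= window[1] && m[i] <= window[2] && e[i] >= ek) n <- n + 1L
  n
}

oracle_dspi <- function(pmax_by_day, daily_hsat, scheme = "standard") {
  total <- 0
  for (d in seq_along(daily_hsat)) {
    lab <- if (scheme == "standard") {
      if (d <= 3) "D1" else if (d <= 5) "D5" else "D9"
    } else {
      if (d <= 4) "D1" else "D9"
    }
    total <- total + pmax_by_day[[lab]] * 60 * daily_hsat[d] * 1e-6
  }
  total / length(daily_hsat)
}

# Exhaustive grid enumeration of the Webb SSE surface. The SSE at each
# grid node is expanded algebraically (sum(y^2) - 2a*A(k) + a^2*B(k)) so
# the full 991 x 2991 grid is affordable; the minimizing node is the same
# one a naive double loop would find.
oracle_webb_grid <- function(e, y,
                             alpha_grid = seq(0.01, 1, by = 0.001),
                             ek_grid = seq(1, 300, by = 0.1)) {
  G <- vapply(e, function(ee) {
    if (ee == 0) rep(1, length(ek_grid))
    else (ek_grid / ee) * (1 - exp(-ee / ek_grid))
  }, numeric(length(ek_grid)))
  A <- as.vector(G %*% y)
  B <- rowSums(G * G)
  SSE <- outer(alpha_grid^2, B) - 2 * outer(alpha_grid, A) + sum(y * y)
  idx <- arrayInd(which.min(SSE), dim(SSE))
  list(alpha = alpha_grid[idx[1]], ek = ek_grid[idx[2]],
       sse = SSE[idx[1], idx[2]])
}

# grid enumeration to locate the global basin, then a derivative-free
# Nelder-Mead polish (stats::optim, independent of the package's
# Levenberg-Marquardt path) to the continuous minimum
oracle_webb_global <- function(e, y) {
  g <- oracle_webb_grid(e, y)
  sse_fun <- function(p) {
    mod <- ifelse(e == 0, p[1], p[1] * (p[2] / e) * (1 - exp(-e / p[2])))
    sum((y - mod)^2)
  }
  o <- optim(c(g$alpha, g$ek), sse_fun, method = "Nelder-Mead",
             control = list(reltol = 1e-14, maxit = 5000))
  list(alpha = o$par[1], ek = o$par[2], sse = o$value, grid = g)
}

rlc_levels <- c(0, 65, 90, 125, 190, 285, 420, 625, 820)

noiseless_curve <- function(alpha, ek, id = "sim") {
  dspi::rlc_curve(id, "D1", rlc_levels, dspi::webb_phi(rlc_levels, alpha, ek))
}

random_trace <- function() {
  # rough daylight-shaped trace with heavy noise; always 871 one-minute
  # samples over the 05:00-19:30 logging window
  m <- 300:1170
  base <- pmax(0, 600 * sin(pi * (m - 360) / 750))
  e <- pmax(0, base * runif(length(m), 0.3, 1.4) +
              rnorm(length(m), 0, 5))
  dspi::irradiance_series("2021-09-20", m, e)
}

# one null-model replicate for the treatment likelihood-ratio test:
# 5 treatments x 3 temperatures x 4 replicates, run random effect only,
# no treatment or temperature effect in the generator
sim_null_lrt_once <- function() {
  d <- expand.grid(treatment = c("T0", "T1", "T2", "T3", "T4"),
                   temperature = factor(c(20, 27, 30)),
                   rep = 1:4)
  d$run <- factor(((seq_len(nrow(d)) - 1L) %% 8L) + 1L)
  run_eff <- rnorm(8, 0, 5)
  d$y <- 50 + run_eff[as.integer(d$run)] + rnorm(nrow(d), 0, 10)
  full <- fit_lmm(d, "y", c("treatment", "temperature"), "run",
                  drop_order = character(), never_drop = "run")
  null <- fit_lmm(d, "y", "temperature", "run",
                  drop_order = character(), never_drop = "run")
  lrt(full, null)
}

# one slope-recovery replicate: growth generated by the package's own
# growth model from known DSPI, refit with growth_dspi_lmm
sim_slope_ci_once <- function(cfg) {
  design <- enumerate_design(cfg)
  dspi_true <- runif(nrow(design), 0.6, 1.6)
  w <- simulate_growth(design, dspi_true, cfg)
  tab <- data.frame(treatment = design$treatment, dspi = dspi_true,
                    growth_pct = growth_percent(w$w_i, w$w_f,
                                                w$parasite_mass))
  g <- growth_dspi_lmm(tab)
  g$slope[["estimate"]] + c(-1.96, 1.96) * g$slope[["se"]]
}
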