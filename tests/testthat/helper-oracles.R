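# Independent scalar-loop oracles. Deliberately written as plain loops over
# cells and days, mirroring the pipeline's formulas element by element, so
# the vectorized implementation can be checked bit-exactly on small
# instances.

oracle_two_day_average <- function(x) {
  d <- dim(x)
  out <- array(NA_real_, d)
  for (iy in seq_len(d[1])) for (ix in seq_len(d[2])) {
    for (t in seq_len(d[3])) {
      out[iy, ix, t] <- if (t == 1) x[iy, ix, 1]
                        else (x[iy, ix, t] + x[iy, ix, t - 1]) / 2
    }
  }
  out
}

oracle_isolate_ratio <- function(xmean, fire, back, eps = 1e-6) {
  d <- dim(xmean)
  xnf <- array(NA_real_, d)
  for (iy in seq_len(d[1])) for (ix in seq_len(d[2])) for (t in seq_len(d[3])) {
    r <- if (fire[iy, ix, t] > eps) back[iy, ix, t] / fire[iy, ix, t] else 1
    xnf[iy, ix, t] <- xmean[iy, ix, t] * r
  }
  a <- oracle_two_day_average(xmean)
  b <- oracle_two_day_average(xnf)
  dx <- array(NA_real_, d)
  for (i in seq_along(dx)) dx[i] <- max(a[i] - b[i], 0)
  dx
}

oracle_isolate_baseline <- function(xmean, base) {
  d <- dim(xmean)
  a <- oracle_two_day_average(xmean)
  dx <- array(NA_real_, d)
  for (iy in seq_len(d[1])) for (ix in seq_len(d[2])) for (t in seq_len(d[3]))
    dx[iy, ix, t] <- max(a[iy, ix, t] - base[iy, ix], 0)
  dx
}

oracle_impact <- function(dx, ynf, pop, beta) {
  d <- dim(dx)
  dy <- array(NA_real_, d)
  for (iy in seq_len(d[1])) for (ix in seq_len(d[2])) for (t in seq_len(d[3]))
    dy[iy, ix, t] <- ynf[iy, ix] * pop[iy, ix] * expm1(beta * dx[iy, ix, t])
  daily <- numeric(d[3])
  for (t in seq_len(d[3])) daily[t] <- sum(dy[, , t])
  list(dy = dy, daily = daily, total = sum(daily))
}

oracle_regrid_rates <- function(rates, county_map, outcome) {
  out <- matrix(NA_real_, nrow(county_map), ncol(county_map))
  rr <- rates[rates$outcome == outcome, ]
  for (iy in seq_len(nrow(county_map))) for (ix in seq_len(ncol(county_map))) {
    row <- rr[rr$county_id == county_map[iy, ix], ]
    out[iy, ix] <- row$annual_rate_per_100k / 1e5 / 365
  }
  out
}

# Direct evaluation of the drifting-Gaussian plume sum at every cell centre
oracle_fire_field <- function(spec) {
  out <- array(0, c(spec$grid_ny, spec$grid_nx, spec$n_days))
  for (p in spec$plume_sources) for (t in seq_len(spec$n_days)) {
    if (t < p$start_day) next
    age <- t - p$start_day
    cx <- (p$origin[1] - 0.5 + p$drift[1] * age) * spec$cell_size
    cy <- (p$origin[2] - 0.5 + p$drift[2] * age) * spec$cell_size
    amp <- p$peak * spec$plume_decay^age
    for (iy in seq_len(spec$grid_ny)) for (ix in seq_len(spec$grid_nx)) {
      px <- (ix - 0.5) * spec$cell_size
      py <- (iy - 0.5) * spec$cell_size
      d2 <- (px - cx)^2 + (py - cy)^2
      out[iy, ix, t] <- out[iy, ix, t] + amp * exp(-d2 / (2 * p$spread^2))
    }
  }
  out
}

# small-instance builders -----------------------------------------------

tiny_spec <- function(seed = 7, ...) {
  scenario_spec(grid_nx = 10, grid_ny = 10, n_days = 5, n_counties = 3,
                seed = seed, ...)
}

# a random exposure surface + uniform rate/pop on an arbitrary small grid
random_surface <- function(ny, nx, nd, seed = 1, vmax = 2) {
  set.seed(seed)
  exposure_surface(array(runif(ny * nx * nd, 0, 30), c(ny, nx, nd)),
                   array(runif(ny * nx * nd, 0, vmax), c(ny, nx, nd)),
                   method = "test")
}

uniform_rp <- function(ny, nx, rate_annual = 2000, pop_cell = 1000,
                       outcome = "respiratory") {
  rate_pop_grid(matrix(rate_annual / 1e5 / 365, ny, nx),
                matrix(pop_cell, ny, nx),
                matrix(1L, ny, nx), outcome)
}

wf_crf <- function(outcome = "respiratory", subgroup = "all")
  crf_from_table(crf_table("WF"), outcome, subgroup)
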