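#' Generate the true fire and non-fire concentration fields
#'
#' The non-fire (background) field varies smoothly in space and gently from
#' day to day around \code{background_level}. The fire field is a sum of
#' drifting 2-D Gaussian plumes: each source contributes, from its start day
#' onward, \code{peak * decay^(t - start)} at a centre that moves by
#' \code{drift} cells/day, with spatial scale \code{spread} km. Plume
#' intensity is exactly zero before the start day. The total "true"
#' concentration is \code{fire + nonfire}, bit-exactly.
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @return list with elements \code{fire} and \code{nonfire}, each a
#'   \code{[ny, nx, n_days]} array (ug/m3), both nonnegative.
#' @examples
#' tf <- generate_true_fields(scenario_spec(grid_nx = 12, grid_ny = 12,
#'                                          n_days = 5, seed = 3))
#' range(tf$fire)
#' @export
generate_true_fields <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  ny <- spec$grid_ny; nx <- spec$grid_nx; nd <- spec$n_days
  cc <- cell_centers(spec)

  nonfire <- with_seed(sub_seed(spec$seed, 1L), {
    gs <- correlated_noise(ny, nx, spec$noise_range_cells)
    gt <- rnorm(nd, 0, 0.05)
    out <- array(0, c(ny, nx, nd))
    for (t in seq_len(nd))
      out[, , t] <- spec$background_level * exp(0.12 * gs + gt[t])
    out
  })

  fire <- array(0, c(ny, nx, nd))
  for (p in spec$plume_sources) {
    for (t in seq_len(nd)) {
      if (t < p$start_day) next
      age <- t - p$start_day
      cx <- (p$origin[1] - 0.5 + p$drift[1] * age) * spec$cell_size
      cy <- (p$origin[2] - 0.5 + p$drift[2] * age) * spec$cell_size
      amp <- p$peak * spec$plume_decay^age
      if (p$spread <= 0) {
        # point-mass limit: all plume mass in the cell containing the centre
        ix <- min(max(1L, as.integer(ceiling(cx / spec$cell_size))), nx)
        iy <- min(max(1L, as.integer(ceiling(cy / spec$cell_size))), ny)
        fire[iy, ix, t] <- fire[iy, ix, t] + amp
      } else {
        d2 <- (cc$X - cx)^2 + (cc$Y - cy)^2
        fire[, , t] <- fire[, , t] + amp * exp(-d2 / (2 * p$spread^2))
      }
    }
  }
  list(fire = fire, nonfire = nonfire)
}

#' Generate exposure surfaces for each estimation method
#'
#' Each method's surface is the true total concentration plus spatially
#' correlated estimation error; the declared variance grid equals the
#' error-generating variance. The per-cell error sd is
#' \code{sqrt(factor) * exposure_noise_sd * (0.5 + 0.1 * truth)}, so error
#' grows with concentration (heteroscedastic, as estimation error does in
#' smoke plumes) and the method factor controls overall precision:
#' with the default factors, \code{datafusion} is most precise and
#' \code{ctm} least.
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @param truth_total \code{[ny, nx, n_days]} array of true total PM2.5,
#'   normally \code{fire + nonfire} from \code{\link{generate_true_fields}}.
#' @return named list of \code{\link{exposure_surface}} objects, one per
#'   entry of \code{spec$method_variance_scale}.
#' @export
generate_method_surfaces <- function(spec, truth_total) {
  stopifnot(inherits(spec, "scenario_spec"))
  dims <- c(spec$grid_ny, spec$grid_nx, spec$n_days)
  if (!identical(dim(truth_total), as.integer(dims)) &&
      !identical(dim(truth_total), dims))
    stop("truth_total dimensions do not match the scenario grid")
  sd_base <- spec$exposure_noise_sd * (0.5 + 0.1 * truth_total)
  with_seed(sub_seed(spec$seed, 2L), {
    out <- list()
    for (method in names(spec$method_variance_scale)) {
      fac <- spec$method_variance_scale[[method]]
      sdf <- sqrt(fac) * sd_base
      eps <- array(0, dims)
      for (t in seq_len(spec$n_days))
        eps[, , t] <- correlated_noise(spec$grid_ny, spec$grid_nx,
                                       spec$noise_range_cells)
      out[[method]] <- exposure_surface(
        mean = pmax(truth_total + sdf * eps, 0),
        variance = sdf^2,
        method = method, cell_size = spec$cell_size)
    }
    out
  })
}

#' Generate background-model inputs (ratio pair and static baseline)
#'
#' The ratio-type background emulates paired chemical-transport-model runs:
#' a with-fire field \code{noisy(fire + nonfire)} and a without-fire field
#' \code{noisy(nonfire)}, each perturbed by day-consistent multiplicative
#' lognormal noise. The baseline-type background is the time average of the
#' non-fire truth plus a smooth static perturbation, emulating a non-fire
#' period surface whose ambient levels drifted relative to the fire year.
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @param fire,nonfire truth arrays from \code{\link{generate_true_fields}}.
#' @return list with elements \code{ratio} (a \code{\link{background_ratio}})
#'   and \code{baseline} (a \code{\link{background_baseline}}).
#' @export
generate_background_inputs <- function(spec, fire, nonfire) {
  stopifnot(inherits(spec, "scenario_spec"))
  ny <- spec$grid_ny; nx <- spec$grid_nx; nd <- spec$n_days
  with_seed(sub_seed(spec$seed, 3L), {
    cmaq_fire <- array(0, c(ny, nx, nd))
    cmaq_back <- array(0, c(ny, nx, nd))
    for (t in seq_len(nd)) {
      lf <- spec$bg_noise_sd * correlated_noise(ny, nx, spec$noise_range_cells)
      lb <- spec$bg_noise_sd * correlated_noise(ny, nx, spec$noise_range_cells)
      cmaq_fire[, , t] <- (fire[, , t] + nonfire[, , t]) * exp(lf)
      cmaq_back[, , t] <- nonfire[, , t] * exp(lb)
    }
    pert <- spec$baseline_drift *
      correlated_noise(ny, nx, spec$noise_range_cells)
    base <- pmax(apply(nonfire, c(1, 2), mean) + pert, 0)
    list(ratio = background_ratio(fire = cmaq_fire, back = cmaq_back),
         baseline = background_baseline(base))
  })
}

#' Generate county map, annual admission rates and clustered population
#'
#' Counties are the nearest-seed (Voronoi) partition of the grid around
#' \code{n_counties} randomly placed seed cells, so each county is
#' contiguous. Annual admission rates per 100,000 are drawn log-uniformly
#' within outcome-specific ranges spanning roughly one order of magnitude
#' (respiratory 800--4000, cardiovascular 1000--5000, asthma 40--400).
#' Population is organised in census-tract-like units clustered around a few
#' dense centres; each tract covers a small block of cells and carries a
#' lognormal total population.
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @return list with \code{county_map} (integer \code{ny x nx} matrix),
#'   \code{rates} (data.frame: county_id, outcome, annual_rate_per_100k),
#'   \code{tracts} (data.frame: tract_id, county_id, x, y, population --
#'   one row per cell covered by the tract, \code{population} being the
#'   tract total), and \code{total_population}.
#' @export
generate_rates_population <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  ny <- spec$grid_ny; nx <- spec$grid_nx
  if (spec$n_counties > nx * ny)
    stop("n_counties exceeds the number of grid cells")
  with_seed(sub_seed(spec$seed, 4L), {
    cells <- sample.int(nx * ny, spec$n_counties)
    sx <- (cells - 1L) %/% ny + 1L
    sy <- (cells - 1L) %% ny + 1L
    county_map <- matrix(0L, ny, nx)
    for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
      d2 <- (sx - ix)^2 + (sy - iy)^2
      county_map[iy, ix] <- which.min(d2)  # ties -> lowest county id
    }

    ranges <- list(respiratory = c(800, 4000),
                   cardiovascular = c(1000, 5000),
                   asthma = c(40, 400))
    rates <- do.call(rbind, lapply(names(ranges), function(oc) {
      r <- ranges[[oc]]
      data.frame(county_id = seq_len(spec$n_counties), outcome = oc,
                 annual_rate_per_100k =
                   exp(runif(spec$n_counties, log(r[1]), log(r[2]))))
    }))

    n_clusters <- max(2L, ceiling(spec$n_counties / 2))
    ccells <- sample.int(nx * ny, n_clusters)
    cx <- (ccells - 1L) %/% ny + 1L
    cy <- (ccells - 1L) %% ny + 1L
    # tract density ~0.4 per 1-km cell: urban-tract scale, with ~30% of
    # tracts scattered uniformly as low-population rural units
    n_tracts <- max(4L * spec$n_counties,
                    as.integer(round(0.4 * nx * ny)))
    rows <- vector("list", n_tracts)
    for (tr in seq_len(n_tracts)) {
      rural <- runif(1) < 0.3
      if (rural) {
        tx <- sample.int(nx, 1)
        ty <- sample.int(ny, 1)
        pop <- round(exp(rnorm(1, log(800), 0.8)))
      } else {
        cl <- sample.int(n_clusters, 1)
        tx <- min(max(1L, cx[cl] + as.integer(round(rnorm(1, 0, 3)))), nx)
        ty <- min(max(1L, cy[cl] + as.integer(round(rnorm(1, 0, 3)))), ny)
        pop <- round(exp(rnorm(1, log(5000), 0.6)))
      }
      xs <- tx:min(tx + 1L, nx)
      ys <- ty:min(ty + 1L, ny)
      grid <- expand.grid(y = ys, x = xs)
      rows[[tr]] <- data.frame(tract_id = tr,
                               county_id = county_map[ty, tx],
                               x = grid$x, y = grid$y, population = pop)
    }
    tracts <- do.call(rbind, rows)
    total <- sum(vapply(split(tracts$population, tracts$tract_id),
                        function(p) p[1], numeric(1)))
    list(county_map = county_map, rates = rates, tracts = tracts,
         total_population = total)
  })
}

#' Generate a complete synthetic scenario bundle
#'
#' Convenience wrapper running all four generator stages and pre-building
#' the gridded rate-and-population inputs for each outcome.
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @return object of class \code{fire_scenario}: a list with \code{spec},
#'   \code{truth} (fire/nonfire arrays), \code{surfaces} (per-method
#'   \code{\link{exposure_surface}}), \code{backgrounds} (ratio + baseline),
#'   \code{county} (rates/population tables), \code{pop} (population grid)
#'   and \code{rp} (per-outcome \code{\link{rate_pop_grid}}).
#' @examples
#' scn <- generate_scenario(scenario_spec(grid_nx = 10, grid_ny = 10,
#'                                        n_days = 4, n_counties = 3,
#'                                        seed = 11))
#' names(scn)
#' @export
generate_scenario <- function(spec) {
  truth <- generate_true_fields(spec)
  total <- truth$fire + truth$nonfire
  surfaces <- generate_method_surfaces(spec, total)
  backgrounds <- generate_background_inputs(spec, truth$fire, truth$nonfire)
  county <- generate_rates_population(spec)
  pop <- regrid_population(county$tracts, dim(county$county_map))
  rp <- lapply(c(respiratory = "respiratory",
                 cardiovascular = "cardiovascular",
                 asthma = "asthma"), function(oc) {
    rate_pop_grid(regrid_rates(county$rates, county$county_map, oc),
                  pop, county$county_map, outcome = oc)
  })
  structure(list(spec = spec, truth = truth, surfaces = surfaces,
                 backgrounds = backgrounds, county = county,
                 pop = pop, rp = rp),
            class = "fire_scenario")
}

#' @export
print.fire_scenario <- function(x, ...) {
  cat("Synthetic fire scenario bundle\n")
  print(x$spec)
  cat(sprintf("  total population %s across %d tracts\n",
              format(x$county$total_population, big.mark = ","),
              length(unique(x$county$tracts$tract_id))))
  invisible(x)
}
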