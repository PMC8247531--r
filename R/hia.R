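#' Regrid county annual admission rates to a daily-rate grid
#'
#' County-level annual rates per 100,000 population become per-person daily
#' background admission rates on the estimation grid:
#' \code{YNF(s) = annual_rate(county(s)) / 100000 / 365}, piecewise constant
#' within counties.
#'
#' @param rates data.frame with columns \code{county_id}, \code{outcome},
#'   \code{annual_rate_per_100k}.
#' @param county_map integer \code{ny x nx} matrix of county ids.
#' @param outcome outcome label selecting the rate rows.
#' @return \code{ny x nx} matrix of daily per-person admission rates.
#' @examples
#' cm <- matrix(1L, 2, 2)
#' r <- data.frame(county_id = 1, outcome = "respiratory",
#'                 annual_rate_per_100k = 365)
#' regrid_rates(r, cm, "respiratory")[1, 1]  # 1e-5
#' @export
regrid_rates <- function(rates, county_map, outcome) {
  rr <- rates[rates$outcome == outcome, ]
  ids <- sort(unique(as.vector(county_map)))
  missing <- setdiff(ids, rr$county_id)
  if (length(missing))
    stop("no ", outcome, " rate for county id(s): ",
         paste(missing, collapse = ", "))
  lut <- rr$annual_rate_per_100k[match(as.vector(county_map), rr$county_id)]
  matrix(lut / 1e5 / 365, nrow(county_map), ncol(county_map))
}

#' Regrid tract population to the estimation grid
#'
#' Each tract's total population is split equally across the grid cells it
#' covers (one table row per covered cell). Whole-person totals are split
#' as equally as possible in integer persons, so the gridded total equals
#' the tract-table total exactly; fractional totals use a
#' remainder-corrected equal split.
#'
#' @param tracts data.frame with columns \code{tract_id}, \code{x},
#'   \code{y}, \code{population} (tract total, repeated on each of the
#'   tract's rows).
#' @param dim grid dimensions \code{c(ny, nx)} (or a template matrix).
#' @return \code{ny x nx} population grid.
#' @export
regrid_population <- function(tracts, dim) {
  if (is.matrix(dim)) dim <- base::dim(dim)
  ny <- dim[1]; nx <- dim[2]
  req <- c("tract_id", "x", "y", "population")
  if (!all(req %in% names(tracts)))
    stop("tract table needs columns: ", paste(req, collapse = ", "))
  if (any(is.na(tracts$x)) || any(is.na(tracts$y)))
    stop("tract table contains cells with missing grid assignment")
  if (any(tracts$x < 1 | tracts$x > nx | tracts$y < 1 | tracts$y > ny))
    stop("tract table assigns cells outside the grid")
  pop <- matrix(0, ny, nx)
  for (rows in split(seq_len(nrow(tracts)), tracts$tract_id)) {
    total <- tracts$population[rows[1]]
    if (!all(tracts$population[rows] == total))
      stop("inconsistent population entries within tract ",
           tracts$tract_id[rows[1]])
    n <- length(rows)
    if (total == floor(total)) {
      # whole persons: split as equally as possible in integer units, so
      # conservation is exact under any summation order
      base <- floor(total / n)
      share <- rep(base, n)
      rem <- total - base * n
      if (rem > 0) share[seq_len(rem)] <- share[seq_len(rem)] + 1
    } else {
      share <- rep(total / n, n)
      share[n] <- share[n] + (total - sum(share))  # remainder-corrected
    }
    for (i in seq_len(n)) {
      r <- rows[i]
      pop[tracts$y[r], tracts$x[r]] <- pop[tracts$y[r], tracts$x[r]] + share[i]
    }
  }
  pop
}

#' Gridded baseline rates and population for one outcome/subgroup
#'
#' @param ynf \code{ny x nx} matrix of background daily per-person
#'   admission rates (constant within counties).
#' @param pop \code{ny x nx} population grid (persons per cell).
#' @param county_map integer \code{ny x nx} county-id matrix.
#' @param outcome outcome label.
#' @param subgroup subgroup label (default "all").
#' @return object of class \code{rate_pop_grid}.
#' @export
rate_pop_grid <- function(ynf, pop, county_map, outcome,
                          subgroup = "all") {
  stopifnot(is.matrix(ynf), is.matrix(pop), is.matrix(county_map))
  if (!identical(dim(ynf), dim(pop)) ||
      !identical(dim(ynf), dim(county_map)))
    stop("ynf, pop and county_map must be congruent")
  if (any(ynf < 0) || any(pop < 0))
    stop("rates and population must be >= 0")
  within_var <- tapply(as.vector(ynf), as.vector(county_map),
                       function(v) diff(range(v)))
  if (any(within_var > 0))
    stop("ynf must be constant within each county")
  structure(list(ynf = ynf, pop = pop, county = county_map,
                 outcome = outcome, subgroup = subgroup),
            class = "rate_pop_grid")
}

#' Excess admissions from the log-linear health impact function
#'
#' Evaluates, per grid cell and day,
#' \deqn{\Delta Y(s,t) = Y_{NF}(s) \, (e^{\beta \Delta X(s,t)} - 1) \,
#'   Pop(s)}
#' where \eqn{Y_{NF}} is the background daily admission rate per person,
#' \eqn{\beta = \ln(RR)/increment} the CRF risk coefficient and \eqn{Pop}
#' the cell population. Daily totals \eqn{n(t)} sum \eqn{\Delta Y} over
#' cells; the window total sums over days; per-county totals sum within the
#' county map. Full precision is retained everywhere; use
#' \code{\link{round_half_up}} for presentation (whole admissions).
#'
#' @param dx a \code{fire_pm_surface} (must be 2-day averaged, matching the
#'   CRF exposure metric).
#' @param crf a \code{\link{crf_spec}}.
#' @param rp a \code{\link{rate_pop_grid}}.
#' @return object of class \code{impact_result}: per-cell-day \code{dy},
#'   daily series \code{daily}, scalar \code{total}, named
#'   \code{county_totals}, plus the inputs' provenance.
#' @examples
#' x <- exposure_surface(array(18, c(1, 1, 1)), array(0, c(1, 1, 1)))
#' dx <- isolate_fire_baseline(x, background_baseline(matrix(8, 1, 1)))
#' rp <- rate_pop_grid(matrix(1e-5, 1, 1), matrix(1e5, 1, 1),
#'                     matrix(1L, 1, 1), "respiratory")
#' crf <- crf_spec("respiratory", "WF", 1.028, 1.014, 1.041)
#' excess_admissions(dx, crf, rp)$total  # 1e-5 * (1.028 - 1) * 1e5 = 0.028
#' @export
excess_admissions <- function(dx, crf, rp) {
  stopifnot(inherits(dx, "fire_pm_surface"), inherits(crf, "crf_spec"),
            inherits(rp, "rate_pop_grid"))
  if (!isTRUE(dx$two_day_averaged))
    stop("dx must be 2-day averaged to match the CRF exposure metric")
  d <- dim(dx$dx)
  if (!identical(dim(rp$ynf), d[1:2]))
    stop("exposure and rate/population grids are misaligned")
  beta <- beta_from_rr(crf)
  nd <- d[3]
  dy <- array(0, d)
  w <- rp$ynf * rp$pop
  for (t in seq_len(nd))
    dy[, , t] <- w * expm1(beta * dx$dx[, , t])
  daily <- apply(dy, 3, sum)
  cell_tot <- apply(dy, c(1, 2), sum)
  county_totals <- tapply(as.vector(cell_tot), as.vector(rp$county), sum)
  structure(list(dy = dy, daily = daily, total = sum(daily),
                 county_totals = county_totals,
                 crf = crf,
                 provenance = c(dx$provenance,
                                list(outcome = rp$outcome,
                                     subgroup = rp$subgroup))),
            class = "impact_result")
}

#' @export
print.impact_result <- function(x, ...) {
  cat(sprintf("Attributable %s admissions (%s, %s CRF): %d over %d day(s)\n",
              x$provenance$outcome, x$provenance$subgroup, x$crf$crf_type,
              round_half_up(x$total), length(x$daily)))
  cat("  daily:", paste(round_half_up(x$daily), collapse = " "), "\n")
  invisible(x)
}

#' Subgroup-stratified impact assessment
#'
#' Runs \code{\link{excess_admissions}} independently for each subgroup with
#' its own CRF and rate/population grids. Subgroup totals need not sum to
#' the all-population total: each subgroup uses its own CRF, estimated
#' independently in the source epidemiology.
#'
#' @param dx a \code{fire_pm_surface}.
#' @param crf_list named list of \code{\link{crf_spec}}, one per subgroup.
#' @param rp_list named list of \code{\link{rate_pop_grid}} with matching
#'   names.
#' @return named list of \code{impact_result}.
#' @export
stratified_assessment <- function(dx, crf_list, rp_list) {
  missing <- setdiff(names(crf_list), names(rp_list))
  if (length(missing))
    stop("no rate/population grids for subgroup(s): ",
         paste(missing, collapse = ", "))
  out <- lapply(names(crf_list), function(sg)
    excess_admissions(dx, crf_list[[sg]], rp_list[[sg]]))
  names(out) <- names(crf_list)
  out
}
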