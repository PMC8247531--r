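#' Two-day rolling average of a daily gridded series
#'
#' Day \code{t} of the output is the mean of days \code{t} and \code{t-1};
#' the first day, having no predecessor, keeps its own value. The 2-day
#' window matches the exposure metric of the concentration-response
#' functions (rate ratio per 10 ug/m3 of 2-day average PM2.5).
#'
#' @param x a \code{[ny, nx, n_days]} array (or \code{n_days x k} matrix
#'   with days in rows is NOT supported -- pass arrays).
#' @return array of the same dimensions.
#' @examples
#' a <- array(c(10, 20), c(1, 1, 2))
#' two_day_average(a)[1, 1, 2]  # 15
#' @export
two_day_average <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3)
    stop("x must be a [ny, nx, n_days] array")
  if (d[3] < 1) stop("series must contain at least one day")
  out <- x
  if (d[3] > 1) {
    idx <- 2:d[3]
    out[, , idx] <- (x[, , idx, drop = FALSE] +
                     x[, , idx - 1, drop = FALSE]) / 2
  }
  out
}

#' Isolate fire-originated PM2.5
#'
#' Dispatches on the background model kind: the ratio ("zero-out") method
#' (\code{\link{isolate_fire_ratio}}) or static-baseline subtraction
#' (\code{\link{isolate_fire_baseline}}).
#'
#' @param x an \code{\link{exposure_surface}}.
#' @param bg a \code{\link{background_model}}.
#' @param clamp_timing \code{"after"} (default) applies the zero-clamp after
#'   2-day averaging of the total and background series; \code{"before"}
#'   clamps the daily difference first and then averages. The two differ
#'   because the clamp is nonlinear.
#' @return a \code{fire_pm_surface} with the 2-day-averaged fire-originated
#'   concentration \eqn{\Delta X}.
#' @export
isolate_fire <- function(x, bg, clamp_timing = c("after", "before")) {
  stopifnot(inherits(bg, "background_model"))
  if (bg$kind == "ratio") isolate_fire_ratio(x, bg, clamp_timing)
  else isolate_fire_baseline(x, bg, clamp_timing)
}

#' Isolate fire-originated PM2.5 by the model-ratio (zero-out) method
#'
#' The non-fire share of the total concentration is estimated from paired
#' with/without-fire model runs: \eqn{X_{NF}(s,t) = X(s,t) \cdot
#' CMAQ_{back}(s,t) / CMAQ_{fire}(s,t)}, and the fire-originated component
#' is \eqn{\Delta X = X - X_{NF}}, set to zero wherever the background
#' estimate exceeds the total. Both \eqn{X} and \eqn{X_{NF}} are 2-day
#' averaged before differencing (and, by default, before the zero-clamp).
#' Where the with-fire model field is ~0 (below \code{eps}), the ratio is
#' undefined and \eqn{\Delta X} is set to 0.
#'
#' @inheritParams isolate_fire
#' @param eps with-fire model concentrations below this (ug/m3) are treated
#'   as zero and yield \eqn{\Delta X = 0}.
#' @return a \code{fire_pm_surface}.
#' @examples
#' x <- exposure_surface(array(20, c(1, 1, 1)), array(0, c(1, 1, 1)))
#' bg <- background_ratio(array(10, c(1, 1, 1)), array(5, c(1, 1, 1)))
#' isolate_fire_ratio(x, bg)$dx[1, 1, 1]  # 10
#' @export
isolate_fire_ratio <- function(x, bg, clamp_timing = c("after", "before"),
                               eps = 1e-6) {
  clamp_timing <- match.arg(clamp_timing)
  stopifnot(inherits(x, "exposure_surface"),
            inherits(bg, "background_model"))
  if (bg$kind != "ratio") stop("background model must be of kind 'ratio'")
  if (!identical(dim(x$mean), dim(bg$fire)))
    stop("exposure surface and background model grids/days are misaligned")
  ratio <- ifelse(bg$fire > eps, bg$back / bg$fire, 1)
  xnf <- x$mean * ratio
  if (clamp_timing == "after") {
    a <- two_day_average(x$mean)
    b <- two_day_average(xnf)
    raw <- a - b
  } else {
    raw <- two_day_average(pmax(x$mean - xnf, 0)) # already clamped daily
  }
  n_clamped <- if (clamp_timing == "after") sum(raw < 0)
               else sum(x$mean < xnf)
  dx <- pmax(raw, 0)
  new_fire_pm_surface(dx, two_day_averaged = TRUE,
                      provenance = list(total_method = x$method,
                                        background = "ratio",
                                        clamp_timing = clamp_timing),
                      n_clamped = n_clamped)
}

#' Isolate fire-originated PM2.5 by static-baseline subtraction
#'
#' Subtracts a time-invariant non-fire-period surface from the (2-day
#' averaged) total concentration, clamping negative differences to zero:
#' \eqn{\Delta X(s,t) = \max(X(s,t) - X_{NF}(s), 0)}.
#'
#' @inheritParams isolate_fire
#' @return a \code{fire_pm_surface}.
#' @export
isolate_fire_baseline <- function(x, bg, clamp_timing = c("after", "before")) {
  clamp_timing <- match.arg(clamp_timing)
  stopifnot(inherits(x, "exposure_surface"),
            inherits(bg, "background_model"))
  if (bg$kind != "baseline")
    stop("background model must be of kind 'baseline'")
  d <- dim(x$mean)
  if (!identical(dim(bg$surface), d[1:2]))
    stop("exposure surface and baseline grids are misaligned")
  base <- array(bg$surface, d)  # recycle static surface across days
  if (clamp_timing == "after") {
    raw <- two_day_average(x$mean) - base
    n_clamped <- sum(raw < 0)
    dx <- pmax(raw, 0)
  } else {
    n_clamped <- sum(x$mean < base)
    dx <- two_day_average(pmax(x$mean - base, 0))
  }
  new_fire_pm_surface(dx, two_day_averaged = TRUE,
                      provenance = list(total_method = x$method,
                                        background = "baseline",
                                        clamp_timing = clamp_timing),
                      n_clamped = n_clamped)
}

#' Exposure summary statistics
#'
#' Summaries of the fire-originated PM2.5 distribution pooled over all grid
#' cell-days: the population-weighted average and standard deviation
#' (weights = cell population, repeated each day), the unweighted spatial
#' average and standard deviation, and the 95th percentile (type-7 linear
#' interpolation).
#'
#' @param dx a \code{fire_pm_surface} (or bare \code{[ny,nx,nd]} array).
#' @param pop \code{ny x nx} population grid, nonnegative with positive sum.
#' @return one-row data.frame with columns \code{popwt_mean},
#'   \code{popwt_sd}, \code{spatial_mean}, \code{spatial_sd}, \code{p95}.
#' @examples
#' dx <- array(c(0, 10, 20), c(3, 1, 1))
#' exposure_summaries(dx, matrix(c(0, 1, 3), 3, 1))$popwt_mean  # 17.5
#' @export
exposure_summaries <- function(dx, pop) {
  v <- if (inherits(dx, "fire_pm_surface")) dx$dx else dx
  d <- dim(v)
  if (length(d) != 3) stop("dx must be a [ny, nx, n_days] array")
  if (!identical(dim(pop), d[1:2]))
    stop("population grid does not match the exposure grid")
  if (any(pop < 0)) stop("population must be >= 0")
  if (sum(pop) <= 0)
    stop("population-weighted statistics need a positive total population")
  w <- rep(as.vector(pop), d[3])
  vv <- as.vector(v)
  wm <- sum(w * vv) / sum(w)
  wsd <- sqrt(sum(w * (vv - wm)^2) / sum(w))
  data.frame(popwt_mean = wm, popwt_sd = wsd,
             spatial_mean = mean(vv), spatial_sd = sd(vv),
             p95 = unname(quantile(vv, 0.95, type = 7)))
}
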