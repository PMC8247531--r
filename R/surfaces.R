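#' Gridded daily exposure surface (mean + estimation variance)
#'
#' Container for one estimation method's daily total-PM2.5 surface: a mean
#' concentration grid and a per-cell estimation variance grid, both indexed
#' \code{[y, x, day]}.
#'
#' @param mean \code{[ny, nx, n_days]} array of daily mean total PM2.5
#'   (ug/m3), nonnegative.
#' @param variance array of the same dimensions with per-cell estimation
#'   variance (ug2/m6), nonnegative.
#' @param method label of the estimation method (e.g. "datafusion").
#' @param cell_size cell edge length in km.
#' @return object of class \code{exposure_surface}.
#' @export
exposure_surface <- function(mean, variance, method = "unknown",
                             cell_size = 1) {
  if (length(dim(mean)) != 3)
    stop("mean must be a [ny, nx, n_days] array")
  if (!identical(dim(mean), dim(variance)))
    stop("mean and variance grids must be congruent")
  if (any(!is.finite(mean)) || any(!is.finite(variance)))
    stop("mean and variance must be finite")
  if (any(mean < 0)) stop("mean concentrations must be >= 0")
  if (any(variance < 0)) stop("variances must be >= 0")
  structure(list(mean = mean, variance = variance, method = method,
                 cell_size = cell_size,
                 days = seq_len(dim(mean)[3])),
            class = "exposure_surface")
}

#' @export
print.exposure_surface <- function(x, ...) {
  d <- dim(x$mean)
  cat(sprintf("Exposure surface '%s': %d x %d grid, %d day(s)\n",
              x$method, d[1], d[2], d[3]))
  cat(sprintf("  mean PM2.5 range %.2f-%.2f ug/m3, mean variance %.3f\n",
              min(x$mean), max(x$mean), mean(x$variance)))
  invisible(x)
}

#' Ratio-type background model (paired with/without-fire model fields)
#'
#' Holds the paired chemical-transport-model outputs used by the ratio
#' ("zero-out") attribution: \code{fire} is the model run with fire
#' emissions, \code{back} the run without. The per-cell-day background
#' fraction \code{back/fire} multiplies the total surface to give the
#' non-fire concentration estimate.
#'
#' @param fire,back \code{[ny, nx, n_days]} arrays, nonnegative.
#' @return object of class \code{background_model}, kind \code{"ratio"}.
#' @export
background_ratio <- function(fire, back) {
  if (length(dim(fire)) != 3 || !identical(dim(fire), dim(back)))
    stop("fire and back must be congruent [ny, nx, n_days] arrays")
  if (any(fire < 0) || any(back < 0))
    stop("background model fields must be >= 0")
  structure(list(kind = "ratio", fire = fire, back = back),
            class = "background_model")
}

#' Baseline-type background model (static non-fire-period surface)
#'
#' @param surface \code{ny x nx} matrix of non-fire-period mean PM2.5
#'   (ug/m3), nonnegative and time-invariant.
#' @return object of class \code{background_model}, kind \code{"baseline"}.
#' @export
background_baseline <- function(surface) {
  if (!is.matrix(surface)) stop("baseline surface must be a matrix")
  if (any(surface < 0)) stop("baseline surface must be >= 0")
  structure(list(kind = "baseline", surface = surface),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  if (x$kind == "ratio") {
    d <- dim(x$fire)
    cat(sprintf("Background model (ratio): %d x %d grid, %d day(s)\n",
                d[1], d[2], d[3]))
  } else {
    cat(sprintf("Background model (baseline): %d x %d static surface, mean %.2f ug/m3\n",
                nrow(x$surface), ncol(x$surface), mean(x$surface)))
  }
  invisible(x)
}

# internal constructor for isolated fire-PM2.5 surfaces
new_fire_pm_surface <- function(dx, two_day_averaged, provenance, n_clamped) {
  structure(list(dx = dx, two_day_averaged = two_day_averaged,
                 provenance = provenance, n_clamped = n_clamped),
            class = "fire_pm_surface")
}

#' @export
print.fire_pm_surface <- function(x, ...) {
  d <- dim(x$dx)
  cat(sprintf("Fire-originated PM2.5: %d x %d grid, %d day(s)%s\n",
              d[1], d[2], d[3],
              if (x$two_day_averaged) ", 2-day averaged" else ""))
  cat(sprintf("  total method '%s', background '%s'; %d cell-day(s) clamped at 0\n",
              x$provenance$total_method, x$provenance$background,
              x$n_clamped))
  cat(sprintf("  range %.2f-%.2f ug/m3\n", min(x$dx), max(x$dx)))
  invisible(x)
}
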