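#' Percent change between two estimates
#'
#' \code{100 * (alt - base) / base}; negative values are decreases. Full
#' precision is returned; round with \code{\link{round_half_up}} for
#' summary text (whole percent).
#'
#' @param base,alt scalars; \code{base} must be nonzero.
#' @return percent change.
#' @examples
#' round_half_up(percent_change(240, 177))  # -26
#' round_half_up(percent_change(68, 163))   # 140
#' @export
percent_change <- function(base, alt) {
  if (base == 0) stop("percent change is undefined for base = 0")
  100 * (alt - base) / base
}

#' Percent change in confidence-interval width
#'
#' @param base,alt \code{mc_result} objects or length-2 numeric vectors
#'   \code{c(lower, upper)}.
#' @return percent change of \code{upper - lower}.
#' @examples
#' round_half_up(ci_width_change(c(114, 404), c(126, 544)))  # 44
#' @export
ci_width_change <- function(base, alt) {
  width <- function(ci) {
    if (inherits(ci, "mc_result")) return(ci$width)
    if (length(ci) != 2) stop("CI must be c(lower, upper)")
    diff(ci)
  }
  wb <- width(base)
  if (wb == 0) stop("base confidence interval is degenerate")
  percent_change(wb, width(alt))
}

#' Per-county admissions table
#'
#' County totals of attributable admissions with each county's share of the
#' regional total, population-weighted fire-PM2.5 mean and sd (pooled over
#' the window), and total population. Sorted by descending admissions (ties
#' broken by county id). Both full-precision and presentation-rounded
#' admission columns are included so rounding never feeds back into
#' computation.
#'
#' @param result an \code{impact_result}.
#' @param dx the \code{fire_pm_surface} used for the assessment.
#' @param rp the \code{\link{rate_pop_grid}} used (supplies county map and
#'   population).
#' @return data.frame with columns \code{county_id}, \code{admissions},
#'   \code{admissions_rounded}, \code{share_pct} (one decimal),
#'   \code{pm_popwt_mean}, \code{pm_popwt_sd}, \code{population}.
#' @export
county_report <- function(result, dx, rp) {
  stopifnot(inherits(result, "impact_result"),
            inherits(dx, "fire_pm_surface"),
            inherits(rp, "rate_pop_grid"))
  ids <- as.integer(names(result$county_totals))
  nd <- dim(dx$dx)[3]
  cm <- as.vector(rp$county)
  popv <- as.vector(rp$pop)
  dxm <- matrix(dx$dx, nrow = length(cm))  # cell x day
  stats <- t(vapply(ids, function(cid) {
    sel <- cm == cid
    w <- rep(popv[sel], nd)
    v <- as.vector(dxm[sel, , drop = FALSE])
    if (sum(w) > 0) {
      m <- sum(w * v) / sum(w)
      s <- sqrt(sum(w * (v - m)^2) / sum(w))
    } else m <- s <- NA_real_
    c(m, s, sum(popv[sel]))
  }, numeric(3)))
  adm <- as.numeric(result$county_totals)
  out <- data.frame(county_id = ids,
                    admissions = adm,
                    admissions_rounded = round_half_up(adm),
                    share_pct = round_half_up(100 * adm / result$total, 1),
                    pm_popwt_mean = stats[, 1],
                    pm_popwt_sd = stats[, 2],
                    population = stats[, 3])
  out[order(-out$admissions, out$county_id), , drop = FALSE]
}

#' Map of attributable-admission rates per 1,000,000 person-days
#'
#' Per cell: \code{1e6 * sum_t dy(s, t) / (Pop(s) * n_days)}. Cells with
#' zero population are masked (NA).
#'
#' @param result an \code{impact_result}.
#' @param pop \code{ny x nx} population grid.
#' @return \code{ny x nx} matrix of rates.
#' @export
rate_map <- function(result, pop) {
  stopifnot(inherits(result, "impact_result"))
  d <- dim(result$dy)
  if (!identical(dim(pop), d[1:2]))
    stop("population grid does not match the impact grid")
  tot <- apply(result$dy, c(1, 2), sum)
  out <- 1e6 * tot / (pop * d[3])
  out[pop == 0] <- NA_real_
  out
}

#' One assessment configuration (a sensitivity-matrix row)
#'
#' @param id short configuration label.
#' @param total_method exposure-estimation method: \code{"datafusion"},
#'   \code{"kriging"} or \code{"ctm"}.
#' @param background_method \code{"ratio"} or \code{"baseline"}.
#' @param crf_type \code{"WF"} or \code{"NF"}.
#' @param sources uncertainty sources (subset of exposure/crf).
#' @return object of class \code{assessment_config}.
#' @export
assessment_config <- function(id, total_method = "datafusion",
                              background_method = "ratio",
                              crf_type = "WF",
                              sources = c("exposure", "crf")) {
  total_method <- match.arg(total_method,
                            c("datafusion", "kriging", "ctm"))
  background_method <- match.arg(background_method, c("ratio", "baseline"))
  crf_type <- match.arg(crf_type, c("WF", "NF"))
  structure(list(id = id, total_method = total_method,
                 background_method = background_method,
                 crf_type = crf_type, sources = sources),
            class = "assessment_config")
}

#' The default one-input-at-a-time sensitivity matrix
#'
#' Eleven configurations: the base case (data-fusion surface, model-ratio
#' background, wildfire CRF, both uncertainty sources), three alternative
#' exposure configurations (CTM surface; kriging surface; baseline
#' background), one alternative CRF (ambient NF), and six
#' uncertainty-decomposition rows (each surface with CRF-only and
#' exposure-only uncertainty). Every non-decomposition row changes exactly
#' one input relative to the base case.
#'
#' @return list of \code{\link{assessment_config}}.
#' @export
default_assessment_configs <- function() {
  both <- c("exposure", "crf")
  list(
    assessment_config("base",          "datafusion", "ratio", "WF", both),
    assessment_config("ctm_surface",   "ctm",        "ratio", "WF", both),
    assessment_config("kriging_surface", "kriging",  "ratio", "WF", both),
    assessment_config("baseline_bg",   "datafusion", "baseline", "WF", both),
    assessment_config("nf_crf",        "datafusion", "ratio", "NF", both),
    assessment_config("datafusion_crf_only", "datafusion", "ratio", "WF", "crf"),
    assessment_config("datafusion_exposure_only", "datafusion", "ratio", "WF", "exposure"),
    assessment_config("ctm_crf_only",  "ctm",        "ratio", "WF", "crf"),
    assessment_config("ctm_exposure_only", "ctm",    "ratio", "WF", "exposure"),
    assessment_config("kriging_crf_only", "kriging", "ratio", "WF", "crf"),
    assessment_config("kriging_exposure_only", "kriging", "ratio", "WF", "exposure")
  )
}

#' Run the sensitivity matrix over a synthetic scenario
#'
#' For each configuration, isolates fire-originated PM2.5 with the
#' configured surface and background, runs the Monte Carlo assessment for
#' each outcome, and records window totals with CIs alongside the exposure
#' summary statistics (population-weighted mean/sd, spatial mean/sd, 95th
#' percentile) of the point-estimate exposure. All rows share the same
#' Monte Carlo seed, so identical configurations give identical rows.
#'
#' @param scenario a \code{fire_scenario} from
#'   \code{\link{generate_scenario}}.
#' @param configs list of \code{\link{assessment_config}} (default: the
#'   11-row matrix of \code{\link{default_assessment_configs}}).
#' @param outcomes outcomes to assess (all-population CRFs).
#' @param mc an \code{\link{mc_config}} template; its \code{sources} field
#'   is overridden per configuration.
#' @return data.frame, one row per configuration, with admission totals and
#'   CI bounds per outcome plus exposure summary columns; the full
#'   \code{mc_result}s are attached as attribute \code{"results"}.
#' @export
run_sensitivity_matrix <- function(scenario,
                                   configs = default_assessment_configs(),
                                   outcomes = c("respiratory",
                                                "cardiovascular"),
                                   mc = mc_config()) {
  stopifnot(inherits(scenario, "fire_scenario"))
  tables <- list(WF = crf_table("WF"), NF = crf_table("NF"))
  rows <- list()
  all_results <- list()
  for (cfg in configs) {
    x <- scenario$surfaces[[cfg$total_method]]
    if (is.null(x))
      stop("scenario has no surface for method '", cfg$total_method, "'")
    bg <- scenario$backgrounds[[cfg$background_method]]
    dx <- isolate_fire(x, bg)
    es <- exposure_summaries(dx, scenario$pop)
    row <- data.frame(config = cfg$id, total_method = cfg$total_method,
                      background_method = cfg$background_method,
                      crf_type = cfg$crf_type,
                      sources = paste(cfg$sources, collapse = "+"))
    res_cfg <- list()
    for (oc in outcomes) {
      crf <- crf_from_table(tables[[cfg$crf_type]], oc)
      mci <- mc
      mci$sources <- cfg$sources
      r <- monte_carlo_assessment(x, bg, crf, scenario$rp[[oc]], mci)
      row[[paste0(oc, "_total")]] <- r$point
      row[[paste0(oc, "_lo")]] <- r$lower
      row[[paste0(oc, "_hi")]] <- r$upper
      res_cfg[[oc]] <- r
    }
    rows[[cfg$id]] <- cbind(row, es)
    all_results[[cfg$id]] <- res_cfg
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- all_results
  out
}
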