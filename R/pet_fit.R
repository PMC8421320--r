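#' Options for the water single-tissue fit
#'
#' @param fit_ptf,fit_va Fit the perfusable tissue fraction / arterial
#'   blood-volume fraction (default) or hold them at their start values.
#' @param starts_f Multi-start grid for flow, mL/g/min.
#' @param start_ptf,start_va Start values.
#' @param lower,upper Named bounds for `F`, `PTF`, `Va`.
#' @param p Water partition coefficient, mL/g (fixed).
#' @param fit_delay Fit an AIF delay by 1-s grid search over
#'   `+/- delay_range_s` (off by default).
#' @param delay_range_s Half-width of the delay grid, s.
#' @return List of class `pet_fit_options`.
#' @export
pet_fit_options <- function(fit_ptf = TRUE, fit_va = TRUE,
                            starts_f = c(0.5, 1.5, 3.0),
                            start_ptf = 0.7, start_va = 0.2,
                            lower = c(F = 0.05, PTF = 0.01, Va = 0),
                            upper = c(F = 8, PTF = 1, Va = 0.5),
                            p = 0.91,
                            fit_delay = FALSE, delay_range_s = 10) {
  structure(as.list(environment()), class = "pet_fit_options")
}

#' Fit the 15O-water single-tissue model to a time-activity curve
#'
#' Weighted nonlinear least squares of
#' `C(t) = PTF * F * [C_A conv exp(-(F/p) t)] + Va * C_A(t)` with weights
#' `sqrt(frame_duration)` (uniform when the curve carries no durations),
#' multiple flow starts, and optional AIF delay fitting by grid search.
#'
#' @param tac Tissue [sampled_curve()] (>= 10 frames).
#' @param aif Arterial input [sampled_curve()] on a compatible support.
#' @param options A [pet_fit_options()].
#' @return A list of class `pet_fit_result`: `F`, `PTF`, `Va`, `p`,
#'   `delay_s`, `rss`, `param_se` (named), `converged`, `at_bound`.
#' @export
fit_water_1tcm <- function(tac, aif, options = pet_fit_options()) {
  stopifnot(is_sampled_curve(tac), is_sampled_curve(aif),
            inherits(options, "pet_fit_options"))
  if (length(tac$times) < 10)
    stop("need at least 10 frames to fit the water model", call. = FALSE)
  if (tac$times[1] < aif$times[1] - 1e-9 ||
      max(tac$times) > max(aif$times) + 1e-9)
    stop("tac and aif supports are incompatible", call. = FALSE)
  w <- if (!is.null(tac$frame_durations)) sqrt(tac$frame_durations)
       else rep(1, length(tac$times))

  fit_at_delay <- function(aif_d) {
    free <- c(TRUE, options$fit_ptf, options$fit_va)
    resid <- function(par) {
      full <- c(F = NA, PTF = options$start_ptf, Va = options$start_va)
      full[free] <- par
      m <- water_1tcm_forward(
        water_params(full[["F"]], PTF = full[["PTF"]], Va = full[["Va"]],
                     p = options$p),
        aif_d, tac$times)
      w * (tac$values - m$values)
    }
    starts <- lapply(options$starts_f, function(f)
      c(F = f, PTF = options$start_ptf, Va = options$start_va)[free])
    fit_nls_multistart(resid, starts, options$lower[free], options$upper[free])
  }

  delays <- if (options$fit_delay)
    seq(-options$delay_range_s, options$delay_range_s, by = 1) else 0
  best <- NULL
  best_delay <- 0
  for (d in delays) {
    f <- fit_at_delay(aif_shift(aif, d))
    if (is.null(best) || (!is.na(f$rss) && f$rss < best$rss)) {
      best <- f
      best_delay <- d
    }
  }
  par <- c(F = NA_real_, PTF = options$start_ptf, Va = options$start_va)
  se <- c(F = NA_real_, PTF = NA_real_, Va = NA_real_)
  free <- c(TRUE, options$fit_ptf, options$fit_va)
  par[free] <- best$par
  se[free] <- best$se
  structure(list(F = par[["F"]], PTF = par[["PTF"]], Va = par[["Va"]],
                 p = options$p, delay_s = best_delay, rss = best$rss,
                 param_se = se, converged = best$converged,
                 at_bound = best$at_bound),
            class = "pet_fit_result")
}

#' @export
print.pet_fit_result <- function(x, ...) {
  cat(sprintf("<pet_fit> F = %.3f mL/g/min (PTF %.3f, Va %.3f), rss %.3g%s\n",
              x$F, x$PTF, x$Va, x$rss,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

# Region curve sets for one scan record: global + coronary territories
# (equal-weighted means of member segment curves) + the 17 segments.
pet_region_curves <- function(pet, level) {
  out <- list()
  if (level %in% c("all", "global")) out$global <- pet$global
  have_segs <- length(pet$segments) > 0
  if (have_segs && level %in% c("all", "territory")) {
    seg_ids <- as.integer(sub("seg", "", names(pet$segments)))
    terr <- territory_of(seg_ids)
    for (tr in c("LAD", "RCA", "LCx"))
      out[[tr]] <- average_curves(pet$segments[terr == tr])
  }
  if (have_segs && level %in% c("all", "segment"))
    out <- c(out, pet$segments)
  out
}

#' Fit the water model across a cohort
#'
#' Fits every subject/condition at the requested aggregation levels:
#' `"global"`, the three coronary `"territory"` curves (equal-weighted means
#' of member segment curves, fitted after averaging), and the 17
#' `"segment"` curves. Fits use the noisy AIF variant (identical to the
#' noise-free one when simulation noise is off). A region whose curve is
#' missing or whose fit errors yields a row of NAs with `converged = FALSE`;
#' the run continues.
#'
#' @param cohort A `perfusion_cohort` or a cohort directory path.
#' @param level `"all"`, `"global"`, `"territory"` or `"segment"`.
#' @param options A [pet_fit_options()].
#' @return data.frame: subject, condition, region, F, PTF, Va, delay_s, rss,
#'   converged, at_bound.
#' @export
fit_cohort_pet <- function(cohort, level = "all",
                           options = pet_fit_options()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "perfusion_cohort"))
  level <- match.arg(level, c("all", "global", "territory", "segment"))
  rows <- list()
  for (rec in cohort$records) {
    curves <- pet_region_curves(rec$pet, level)
    for (nm in names(curves)) {
      fit <- tryCatch(fit_water_1tcm(curves[[nm]], rec$pet$aif_noisy, options),
                      error = function(e) NULL)
      rows[[length(rows) + 1L]] <- if (is.null(fit))
        data.frame(subject = rec$subject, condition = rec$condition,
                   region = nm, F = NA_real_, PTF = NA_real_, Va = NA_real_,
                   delay_s = NA_real_, rss = NA_real_, converged = FALSE,
                   at_bound = NA)
      else
        data.frame(subject = rec$subject, condition = rec$condition,
                   region = nm, F = fit$F, PTF = fit$PTF, Va = fit$Va,
                   delay_s = fit$delay_s, rss = fit$rss,
                   converged = fit$converged, at_bound = fit$at_bound)
    }
  }
  do.call(rbind, rows)
}
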