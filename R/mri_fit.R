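#' Options for the gadolinium kinetic fits
#'
#' @param starts_k1 Multi-start K1 grid for the plain fit, mL/g/min.
#' @param starts_f,starts_ps Multi-start grids for the flow/permeability fit.
#' @param start_ve,start_vb Start values.
#' @param lower_plain,upper_plain Named bounds for (K1, Ve, vb).
#' @param lower_ps,upper_ps Named bounds for (F, PS, Ve, vb).
#' @param rel_se_max Reliability threshold on the relative SE of the
#'   perfusion parameter (fits above it are flagged unreliable).
#' @return List of class `mri_fit_options`.
#' @export
mri_fit_options <- function(starts_k1 = c(0.3, 1, 2),
                            starts_f = c(0.5, 1.5, 3),
                            starts_ps = c(1.5, 3),
                            start_ve = 0.3, start_vb = 0.1,
                            lower_plain = c(K1 = 0.01, Ve = 0.05, vb = 0),
                            upper_plain = c(K1 = 4, Ve = 1, vb = 0.3),
                            lower_ps = c(F = 0.05, PS = 0.5, Ve = 0.05, vb = 0),
                            upper_ps = c(F = 8, PS = 6, Ve = 1, vb = 0.3),
                            rel_se_max = 0.5) {
  structure(as.list(environment()), class = "mri_fit_options")
}

mri_result <- function(model_tag, par, se, rss, converged, at_bound,
                       opts) {
  se_full <- stats::setNames(rep(NA_real_, length(par)), names(par))
  se_full[names(se)] <- se
  rel <- se_full / ifelse(abs(par) > 0, abs(par), NA_real_)
  key <- if ("F" %in% names(par)) "F" else "K1"
  reliable <- isTRUE(converged) && !isTRUE(at_bound) &&
    is.finite(rel[[key]]) && rel[[key]] <= opts$rel_se_max
  structure(list(model_tag = model_tag, params = as.list(par),
                 rss = rss, param_rel_se = rel, converged = converged,
                 at_bound = at_bound, reliable = reliable),
            class = "mri_fit_result")
}

#' @export
print.mri_fit_result <- function(x, ...) {
  p <- x$params
  key <- if (!is.null(p$F)) sprintf("F = %.3f", p$F) else sprintf("K1 = %.3f", p$K1)
  cat(sprintf("<mri_fit %s> %s mL/g/min, rss %.3g%s\n", x$model_tag, key,
              x$rss, if (!x$reliable) " [unreliable]" else ""))
  invisible(x)
}

#' Plain one-tissue fit of a gadolinium concentration curve
#'
#' Fits `C_T = K1 * [C_A conv exp(-(K1/Ve) t)] + vb * C_A` and returns K1 as
#' the perfusion-related parameter — no extraction correction, so K1
#' increasingly underestimates flow above ~1 mL/g/min where the Gd-DOTA
#' extraction fraction drops.
#'
#' @param conc_tac Tissue concentration [sampled_curve()] (mmol/L).
#' @param conc_aif Arterial concentration [sampled_curve()] (mmol/L).
#' @param options An [mri_fit_options()].
#' @return An `mri_fit_result` with `model_tag = "plain_1tcm"`; `params`
#'   holds K1, Ve, vb.
#' @export
fit_gd_plain_1tcm <- function(conc_tac, conc_aif,
                              options = mri_fit_options()) {
  stopifnot(is_sampled_curve(conc_tac), is_sampled_curve(conc_aif),
            inherits(options, "mri_fit_options"))
  resid <- function(par) {
    m <- gd_1tcm_forward(gd_params(K1 = par[["K1"]], Ve = par[["Ve"]],
                                   vb = par[["vb"]]),
                         conc_aif, conc_tac$times, mode = "plain")
    conc_tac$values - m$values
  }
  starts <- lapply(options$starts_k1, function(k)
    c(K1 = k, Ve = options$start_ve, vb = options$start_vb))
  fit <- fit_nls_multistart(resid, starts, options$lower_plain,
                            options$upper_plain)
  names(fit$se) <- names(fit$par)
  mri_result("plain_1tcm", fit$par, fit$se, fit$rss, fit$converged,
             fit$at_bound, options)
}

#' Extraction-fraction correction of measured K1 values
#'
#' Converts influx rates to flow by inverting the Renkin-Crone relation at a
#' fixed (population-calibrated) PS, and reports the first-order noise
#' amplification factor dF/dK1. K1 values at or above PS are unrecoverable
#' (the extraction asymptote) and return NA with `recoverable = FALSE` —
#' the failure mode that degrades this route at hyperaemic flows.
#'
#' @param K1 Measured influx rate(s), mL/g/min.
#' @param PS_population Calibrated population PS, mL/g/min.
#' @param flag_amplification Amplification above which the corrected value is
#'   flagged noisy.
#' @return data.frame: K1, F, amplification, recoverable, noisy.
#' @export
apply_extraction_correction <- function(K1, PS_population,
                                        flag_amplification = 10) {
  if (any(K1 < 0)) stop("`K1` must be nonnegative", call. = FALSE)
  stopifnot(PS_population > 0)
  ok <- K1 < PS_population
  F_out <- rep(NA_real_, length(K1))
  F_out[ok] <- renkin_crone_invert(K1[ok], PS_population)
  amp <- rep(NA_real_, length(K1))
  pos <- ok & F_out > 0
  amp[pos] <- renkin_crone_amplification(F_out[pos], PS_population)
  amp[ok & F_out == 0] <- 1
  data.frame(K1 = K1, F = F_out, amplification = amp, recoverable = ok,
             noisy = !is.na(amp) & amp > flag_amplification)
}

#' Calibrate a population permeability-surface-area product
#'
#' Least-squares fit of the Renkin-Crone relation
#' `K1 = F * (1 - exp(-PS/F))` over paired (K1, F) observations — typically
#' MRI influx rates against simultaneous PET flows spanning rest and stress.
#' A single scalar PS is returned.
#'
#' @param K1 Measured influx rates, mL/g/min (length >= 2 for a per-subject
#'   calibration, >= 5 recommended for a population one).
#' @param F_ref Reference flows, mL/g/min, same length.
#' @param lower,upper Search bounds for PS, mL/g/min.
#' @return List: `PS`, `rss`, `at_upper` (TRUE when the optimum pins at the
#'   upper bound, e.g. K1 == F exactly, where extraction ~ 1 leaves PS
#'   unidentified), `at_bound` (either bound active), `ill_conditioned`
#'   (TRUE when the flows span < 0.5 mL/g/min, with a warning).
#' @export
calibrate_population_ps <- function(K1, F_ref, lower = 1e-6, upper = 50) {
  stopifnot(length(K1) == length(F_ref), length(K1) >= 2)
  if (any(K1 < 0) || any(F_ref <= 0))
    stop("K1 must be >= 0 and reference flows > 0", call. = FALSE)
  ill <- diff(range(F_ref)) < 0.5
  if (ill)
    warning("reference flows span < 0.5 mL/g/min; PS calibration is ill-conditioned",
            call. = FALSE)
  obj <- function(ps) sum((K1 - renkin_crone_k1(F_ref, ps))^2)
  opt <- stats::optimize(obj, c(lower, upper), tol = 1e-10)
  at_upper <- opt$minimum > 0.99 * upper
  at_bound <- at_upper || opt$minimum < lower + 0.01 * (upper - lower)
  if (at_upper)
    warning("PS pinned at the search bound (extraction ~ 1 is unidentifiable)",
            call. = FALSE)
  list(PS = opt$minimum, rss = opt$objective, at_upper = at_upper,
       at_bound = at_bound, ill_conditioned = ill)
}

#' Flow/permeability fit of a gadolinium concentration curve
#'
#' Fits the one-tissue model with the influx tied to the Renkin-Crone
#' relation, `K1 = F * (1 - exp(-PS/F))`, so flow is estimated directly
#' instead of a lumped K1.
#'
#' With `ps = "free"` both F and PS are fitted — but a single tissue curve
#' determines only (K1, Ve, vb), so (F, PS) lie on an exact ridge: the fit
#' reports a valid K1 decomposition, huge relative SEs on F, and
#' `reliable = FALSE`. Supplying a numeric `ps` (per-subject or population
#' calibrated, see [estimate_subject_ps()]) removes the ridge and makes F
#' identifiable.
#'
#' @inheritParams fit_gd_plain_1tcm
#' @param ps `"free"` or a fixed numeric PS in mL/g/min.
#' @return An `mri_fit_result` with `model_tag = "1tcm_ps"`; `params` holds
#'   F, PS, K1 (derived), Ve, vb.
#' @export
fit_gd_1tcm_ps <- function(conc_tac, conc_aif, options = mri_fit_options(),
                           ps = "free") {
  stopifnot(is_sampled_curve(conc_tac), is_sampled_curve(conc_aif),
            inherits(options, "mri_fit_options"))
  ps_free <- identical(ps, "free")
  if (!ps_free && (!is.numeric(ps) || ps <= 0))
    stop("`ps` must be \"free\" or a positive number", call. = FALSE)
  resid <- function(par) {
    ps_val <- if (ps_free) par[["PS"]] else ps
    m <- gd_1tcm_forward(gd_params(F_flow = par[["F"]], PS = ps_val,
                                   Ve = par[["Ve"]], vb = par[["vb"]]),
                         conc_aif, conc_tac$times, mode = "ps_embedded")
    conc_tac$values - m$values
  }
  if (ps_free) {
    starts <- unlist(lapply(options$starts_f, function(f)
      lapply(options$starts_ps, function(p)
        c(F = f, PS = p, Ve = options$start_ve, vb = options$start_vb))),
      recursive = FALSE)
    lower <- options$lower_ps
    upper <- options$upper_ps
  } else {
    keep <- names(options$lower_ps) != "PS"
    starts <- lapply(options$starts_f, function(f)
      c(F = f, Ve = options$start_ve, vb = options$start_vb))
    lower <- options$lower_ps[keep]
    upper <- options$upper_ps[keep]
  }
  fit <- fit_nls_multistart(resid, starts, lower, upper)
  names(fit$se) <- names(fit$par)
  par <- fit$par
  if (!ps_free) par <- c(par, PS = ps)
  par <- c(par, K1 = renkin_crone_k1(par[["F"]], par[["PS"]]))
  mri_result("1tcm_ps", par, fit$se[names(fit$par)], fit$rss, fit$converged,
             fit$at_bound, options)
}

#' Per-subject PS from paired rest/stress K1 and reference flow
#'
#' The direct-estimation route of the dual-modality design: a subject's PS is
#' the Renkin-Crone least-squares solution over that subject's rest and
#' stress (K1_MRI, F_PET) pairs. Two flow states give two equations for the
#' single PS, which is what makes the per-subject estimate well defined
#' (a single condition leaves PS on the F-PS ridge).
#'
#' The estimate is searched within the same PS box the direct fit declares
#' (default 0.5-6 mL/g/min); an estimate pinned at a bound is an unreliable
#' fit and is returned as NA so downstream aggregation excludes that
#' subject, mirroring how unreliable direct fits are excluded.
#'
#' @param K1 Rest and stress MRI influx rates, mL/g/min (length >= 2).
#' @param F_ref Matching reference (PET) flows, mL/g/min.
#' @param bounds PS search interval, mL/g/min.
#' @return The per-subject PS, mL/g/min, or NA when unidentified.
#' @export
estimate_subject_ps <- function(K1, F_ref, bounds = c(0.5, 6)) {
  cal <- suppressWarnings(
    calibrate_population_ps(K1, F_ref, lower = bounds[1], upper = bounds[2]))
  if (cal$at_bound) return(NA_real_)
  cal$PS
}

# Signal-domain preprocessing shared by the cohort MRI fits: convert blood
# and tissue signal curves to concentration with their own T10.
mri_conc_curves <- function(mri, level, baseline_frames = 5) {
  aif <- signal_to_concentration(mri$blood_signal, mri$blood_params,
                                 baseline_frames)
  conv <- function(cu) signal_to_concentration(cu, mri$tissue_params,
                                               baseline_frames)
  out <- list()
  if (level %in% c("all", "global")) out$global <- conv(mri$global_signal)
  have_segs <- length(mri$segment_signals) > 0
  if (have_segs && level %in% c("all", "territory")) {
    seg_ids <- as.integer(sub("seg", "", names(mri$segment_signals)))
    terr <- territory_of(seg_ids)
    for (tr in c("LAD", "RCA", "LCx"))
      out[[tr]] <- conv(average_curves(mri$segment_signals[terr == tr]))
  }
  if (have_segs && level %in% c("all", "segment"))
    out <- c(out, lapply(mri$segment_signals, conv))
  list(aif = aif, regions = out)
}

#' Fit the MRI kinetic models across a cohort
#'
#' Converts every signal curve to gadolinium concentration (blood-pool curve
#' with the blood T10 as the AIF) and runs one of the three analysis routes:
#'
#' * `"plain_1tcm"` — free-K1 one-tissue fits; K1 is the perfusion-related
#'   parameter.
#' * `"ef_corrected"` — plain fits followed by Renkin-Crone inversion at a
#'   population PS (`ps_population`, required).
#' * `"1tcm_ps"` — direct flow estimation: per subject, PS is first estimated
#'   from the rest+stress global K1 against the matching reference flows in
#'   `pet_table` (required), then every region is refitted with PS fixed at
#'   the subject's value.
#'
#' Unreliable fits (relative SE above threshold or active box constraint)
#' carry `reliable = FALSE` and are excluded by downstream agreement
#' analysis.
#'
#' @param cohort A `perfusion_cohort` or cohort directory path.
#' @param model One of `"plain_1tcm"`, `"ef_corrected"`, `"1tcm_ps"`.
#' @param level `"all"`, `"global"`, `"territory"` or `"segment"`.
#' @param options An [mri_fit_options()].
#' @param ps_population Population PS for `"ef_corrected"`, mL/g/min.
#' @param pet_table Global PET fit table (from
#'   `fit_cohort_pet(..., level = "global")`) for `"1tcm_ps"`.
#' @param baseline_frames Pre-contrast frames for the signal conversion.
#' @return data.frame: subject, condition, region, F, PS, K1, Ve, vb, rss,
#'   rel_se_F, reliable. For `"plain_1tcm"`, F is NA and K1 carries the
#'   perfusion parameter.
#' @export
fit_cohort_mri <- function(cohort,
                           model = c("plain_1tcm", "ef_corrected", "1tcm_ps"),
                           level = "all", options = mri_fit_options(),
                           ps_population = NULL, pet_table = NULL,
                           baseline_frames = 5) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "perfusion_cohort"))
  model <- match.arg(model)
  level <- match.arg(level, c("all", "global", "territory", "segment"))
  if (model == "ef_corrected" && is.null(ps_population))
    stop("`ef_corrected` requires `ps_population`", call. = FALSE)
  if (model == "1tcm_ps" && is.null(pet_table))
    stop("`1tcm_ps` requires `pet_table` (reference flows for per-subject PS)",
         call. = FALSE)

  # Plain K1 fits for every record/region; basis of all three routes.
  plain <- list()
  concs <- list()
  for (key in names(cohort$records)) {
    rec <- cohort$records[[key]]
    lv <- if (model == "1tcm_ps" && level != "global") "all" else level
    cc <- mri_conc_curves(rec$mri, if (model == "1tcm_ps") lv else level,
                          baseline_frames)
    concs[[key]] <- cc
    plain[[key]] <- lapply(cc$regions, function(cu)
      tryCatch(fit_gd_plain_1tcm(cu, cc$aif, options),
               error = function(e) NULL))
  }

  # Per-subject PS for the direct route: rest+stress global K1 vs PET F.
  subj_ps <- NULL
  if (model == "1tcm_ps") {
    pet_glob <- pet_table[pet_table$region == "global", ]
    subs <- unique(vapply(cohort$records, function(r) r$subject, ""))
    subj_ps <- vapply(subs, function(s) {
      k1 <- vapply(c("rest", "stress"), function(cond) {
        f <- plain[[paste(s, cond, sep = "_")]]$global
        if (is.null(f)) NA_real_ else f$params$K1
      }, numeric(1))
      fr <- vapply(c("rest", "stress"), function(cond) {
        i <- which(pet_glob$subject == s & pet_glob$condition == cond)
        if (length(i)) pet_glob$F[i[1]] else NA_real_
      }, numeric(1))
      ok <- is.finite(k1) & is.finite(fr)
      if (sum(ok) < 2) return(NA_real_)
      estimate_subject_ps(k1[ok], fr[ok])
    }, numeric(1))
  }

  rows <- list()
  for (key in names(cohort$records)) {
    rec <- cohort$records[[key]]
    cc <- concs[[key]]
    region_names <- names(cc$regions)
    if (model == "1tcm_ps" && level != "all") {
      keep <- switch(level,
        global = region_names == "global",
        territory = region_names %in% c("LAD", "RCA", "LCx"),
        segment = grepl("^seg", region_names))
      region_names <- region_names[keep]
    }
    for (nm in region_names) {
      pf <- plain[[key]][[nm]]
      row <- data.frame(subject = rec$subject, condition = rec$condition,
                        region = nm, F = NA_real_, PS = NA_real_,
                        K1 = NA_real_, Ve = NA_real_, vb = NA_real_,
                        rss = NA_real_, rel_se_F = NA_real_, reliable = FALSE)
      if (model == "plain_1tcm") {
        if (!is.null(pf)) {
          row$K1 <- pf$params$K1; row$Ve <- pf$params$Ve; row$vb <- pf$params$vb
          row$rss <- pf$rss; row$rel_se_F <- pf$param_rel_se[["K1"]]
          row$reliable <- pf$reliable
        }
      } else if (model == "ef_corrected") {
        if (!is.null(pf)) {
          ec <- apply_extraction_correction(pf$params$K1, ps_population)
          row$K1 <- pf$params$K1; row$Ve <- pf$params$Ve; row$vb <- pf$params$vb
          row$F <- ec$F; row$PS <- ps_population; row$rss <- pf$rss
          row$rel_se_F <- pf$param_rel_se[["K1"]] *
            ifelse(is.na(ec$amplification), Inf, ec$amplification)
          row$reliable <- pf$reliable && ec$recoverable && !ec$noisy
        }
      } else {                                  # 1tcm_ps
        ps_s <- subj_ps[[rec$subject]]
        if (is.finite(ps_s)) {
          fit <- tryCatch(fit_gd_1tcm_ps(cc$regions[[nm]], cc$aif, options,
                                         ps = ps_s),
                          error = function(e) NULL)
          if (!is.null(fit)) {
            row$F <- fit$params$F; row$PS <- ps_s; row$K1 <- fit$params$K1
            row$Ve <- fit$params$Ve; row$vb <- fit$params$vb
            row$rss <- fit$rss; row$rel_se_F <- fit$param_rel_se[["F"]]
            row$reliable <- fit$reliable
          }
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
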