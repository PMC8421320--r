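#' Synthetic cohort configuration
#'
#' Study-level knobs for the synthetic rest/stress cohort. Defaults emulate
#' the acquisition the pipeline targets: a 6-min dynamic PET scan after a
#' 400 MBq 15O-water bolus and a 65-heartbeat, saturation-prepared DCE-MRI
#' scan after a 0.05 mmol/kg Gd-DOTA bolus, with cohort flow and
#' permeability moments set to the reference rest/stress distributions
#' (rest MBF 1.02 +/- 0.28, stress 3.13 +/- 1.16, PS 2.91 +/- 0.37, all
#' mL/g/min). Relaxation/relaxivity and tissue-fraction constants are
#' conventional 3 T literature values and are configuration, not estimates.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Integer RNG seed; the cohort is fully determined by it.
#' @param rest_mbf_mean,rest_mbf_sd Rest MBF truth distribution, mL/g/min
#'   (truncated normal, lower bound 0.3).
#' @param stress_mbf_mean,stress_mbf_sd Stress MBF truth distribution,
#'   mL/g/min (truncated normal, lower bound 1.0).
#' @param ps_mean,ps_sd Permeability-surface-area truth distribution,
#'   mL/g/min (truncated normal, lower bound 0.5); one PS per subject, shared
#'   across rest and stress.
#' @param segment_heterogeneity_cv Coefficient of variation of the lognormal
#'   segment-to-segment flow multipliers (renormalised so the weighted
#'   segment mean equals the subject's global flow exactly).
#' @param pet_noise_scale Scale of the PET frame noise, whose SD is
#'   `pet_noise_scale * sqrt(value / frame_duration)`; 0 disables noise.
#' @param mri_snr Baseline signal-to-noise ratio of the MRI signal
#'   (Gaussian, SD = baseline / SNR); `Inf` disables noise.
#' @param pet_duration_s PET acquisition length, s.
#' @param mri_n_beats Number of MRI frames (one per heartbeat, >= 10).
#' @param heart_rate_rest,heart_rate_stress Heart rate, bpm.
#' @param pet_dose_mbq Injected water activity, MBq (scales AIF amplitude
#'   linearly).
#' @param pet_aif_peak_kbq AIF peak at the reference 400 MBq dose, kBq/mL.
#' @param gd_dose_mmol_kg,body_weight_kg,first_pass_volume_l Gd dose and the
#'   nominal mixing volume that set the arterial concentration peak
#'   (dose * weight / volume).
#' @param Ve,vb Gd distribution volume (mL/g) and vascular fraction.
#' @param PTF,Va,p Water-model perfusable tissue fraction, arterial
#'   blood-volume fraction and partition coefficient (mL/g).
#' @param t10_blood_s,t10_tissue_s,r1_relaxivity,prep_delay_s MRI signal
#'   model constants (s, s, L/(mmol s), s).
#' @param simulate_segments If `FALSE`, only global curves are generated
#'   (faster for subject-level studies).
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 12,
                          seed = 1L,
                          rest_mbf_mean = 1.02, rest_mbf_sd = 0.28,
                          stress_mbf_mean = 3.13, stress_mbf_sd = 1.16,
                          ps_mean = 2.91, ps_sd = 0.37,
                          segment_heterogeneity_cv = 0.10,
                          pet_noise_scale = 1.0,
                          mri_snr = 20,
                          pet_duration_s = 360,
                          mri_n_beats = 65,
                          heart_rate_rest = 66, heart_rate_stress = 82,
                          pet_dose_mbq = 400,
                          pet_aif_peak_kbq = 110,
                          gd_dose_mmol_kg = 0.05,
                          body_weight_kg = 75,
                          first_pass_volume_l = 0.9,
                          Ve = 0.35, vb = 0.08,
                          PTF = 0.7, Va = 0.25, p = 0.91,
                          t10_blood_s = 1.66, t10_tissue_s = 1.2,
                          r1_relaxivity = 3.6, prep_delay_s = 0.12,
                          simulate_segments = TRUE) {
  cfg <- as.list(environment())
  errs <- character(0)
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(n_subjects >= 2, "`n_subjects` must be >= 2")
  chk(all(c(rest_mbf_sd, stress_mbf_sd, ps_sd) >= 0), "SDs must be >= 0")
  chk(all(c(rest_mbf_mean, stress_mbf_mean, ps_mean) > 0), "means must be > 0")
  chk(segment_heterogeneity_cv >= 0, "`segment_heterogeneity_cv` must be >= 0")
  chk(pet_noise_scale >= 0, "`pet_noise_scale` must be >= 0")
  chk(mri_snr > 0, "`mri_snr` must be > 0")
  chk(mri_n_beats >= 10, "`mri_n_beats` must be >= 10")
  chk(pet_duration_s > 0, "`pet_duration_s` must be > 0")
  chk(heart_rate_rest > 0 && heart_rate_stress > 0, "heart rates must be > 0")
  if (length(errs)) stop(paste(errs, collapse = "; "), call. = FALSE)
  structure(cfg, class = "cohort_config")
}

# Inverse-CDF truncated-normal sampler; sd = 0 degenerates to the mean.
rtrunc_norm <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

#' Draw the cohort ground truth
#'
#' Per subject: rest and stress global flows from truncated normals (lower
#' bounds 0.3 and 1.0 mL/g/min), one PS shared across conditions (lower bound
#' 0.5), and per-condition lognormal segment multipliers renormalised so the
#' equal-weighted mean of the 17 segmental flows equals the global flow
#' exactly. Fully determined by `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A list of class `ground_truth` with data.frames `subjects`
#'   (subject, condition, F, PS, Ve, vb, PTF, Va, noise_seed) and `segments`
#'   (subject, condition, segment, weight, F).
#' @export
sample_ground_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  rest_f <- rtrunc_norm(n, config$rest_mbf_mean, config$rest_mbf_sd, 0.3)
  stress_f <- rtrunc_norm(n, config$stress_mbf_mean, config$stress_mbf_sd, 1.0)
  ps <- rtrunc_norm(n, config$ps_mean, config$ps_sd, 0.5)
  subjects <- data.frame(
    subject = rep(sprintf("S%02d", seq_len(n)), times = 2),
    condition = rep(c("rest", "stress"), each = n),
    F = c(rest_f, stress_f),
    PS = rep(ps, 2),
    Ve = config$Ve, vb = config$vb,
    PTF = config$PTF, Va = config$Va,
    noise_seed = sample.int(.Machine$integer.max - 1L, 2 * n)
  )
  seg <- aha_segments()
  cv <- config$segment_heterogeneity_cv
  sdlog <- sqrt(log(1 + cv^2))
  seg_list <- lapply(seq_len(nrow(subjects)), function(i) {
    m <- if (cv == 0) rep(1, 17) else stats::rlnorm(17, -sdlog^2 / 2, sdlog)
    m <- m / sum(seg$weight * m)      # weighted mean multiplier == 1 exactly
    data.frame(subject = subjects$subject[i],
               condition = subjects$condition[i],
               segment = seg$segment, weight = seg$weight,
               F = subjects$F[i] * m)
  })
  structure(list(config = config, subjects = subjects,
                 segments = do.call(rbind, seg_list)),
            class = "ground_truth")
}

# Default PET frame schedule: short early frames through the bolus, longer
# late frames; 24x5 + 12x10 + 6x20 = 360 s at the default duration.
pet_frame_schedule <- function(duration_s = 360) {
  base <- c(rep(5, 24), rep(10, 12), rep(20, 6))
  durs <- base * duration_s / 360
  ends <- cumsum(durs)
  data.frame(mid = ends - durs / 2, duration = durs)
}

pet_aif_params <- function(config) {
  aif_params(t0 = 15, alpha = 3, beta = 4,
             amplitude = config$pet_aif_peak_kbq * config$pet_dose_mbq / 400,
             recirc_fraction = 0.15, recirc_tau = 40)
}

mri_aif_params <- function(config) {
  peak <- config$gd_dose_mmol_kg * config$body_weight_kg /
    config$first_pass_volume_l
  aif_params(t0 = 8, alpha = 2.5, beta = 2, amplitude = peak,
             recirc_fraction = 0.2, recirc_tau = 25)
}

add_pet_noise <- function(curve, scale) {
  if (scale == 0) return(curve)
  sd <- scale * sqrt(pmax(curve$values, 0) / curve$frame_durations)
  sampled_curve(curve$times, curve$values + stats::rnorm(length(sd), 0, sd),
                unit = curve$unit, frame_durations = curve$frame_durations)
}

#' Simulate the PET scan of one subject/condition
#'
#' Generates the arterial input on the default frame schedule (gamma-variate
#' bolus, amplitude proportional to injected dose), the global and segmental
#' tissue curves through the water single-tissue forward model, and adds
#' frame noise with SD `pet_noise_scale * sqrt(value / duration)`. The noisy
#' and noise-free AIF are both returned.
#'
#' @param truth_row One row of `ground_truth$subjects`.
#' @param seg_rows Matching rows of `ground_truth$segments` (may be NULL).
#' @param config The [cohort_config()].
#' @return List with `aif`, `aif_noisy`, `global`, and `segments` (a named
#'   list of [sampled_curve()]s, possibly empty).
#' @export
simulate_pet_scan <- function(truth_row, seg_rows, config) {
  sched <- pet_frame_schedule(config$pet_duration_s)
  aif <- gamma_variate_aif(pet_aif_params(config), sched$mid, unit = "kBq/mL")
  aif$frame_durations <- sched$duration
  set.seed(truth_row$noise_seed)
  aif_noisy <- add_pet_noise(aif, config$pet_noise_scale)
  make_tac <- function(f) {
    wp <- water_params(f, PTF = truth_row$PTF, Va = truth_row$Va, p = config$p)
    tac <- water_1tcm_forward(wp, aif, frame_durations = sched$duration)
    add_pet_noise(tac, config$pet_noise_scale)
  }
  glob <- make_tac(truth_row$F)
  segs <- list()
  if (!is.null(seg_rows) && nrow(seg_rows)) {
    segs <- lapply(seq_len(nrow(seg_rows)), function(i) make_tac(seg_rows$F[i]))
    names(segs) <- sprintf("seg%02d", seg_rows$segment)
  }
  list(aif = aif, aif_noisy = aif_noisy, global = glob, segments = segs)
}

#' Simulate the DCE-MRI scan of one subject/condition
#'
#' One frame per heartbeat for `mri_n_beats` beats. The arterial gadolinium
#' concentration is a gamma-variate bolus whose peak follows from the dose
#' and nominal mixing volume; tissue concentration follows the one-tissue
#' forward model with the Renkin-Crone influx implied by the subject's true
#' F and PS. Blood and tissue concentrations are converted to signal with
#' their own T10, and Gaussian noise with SD = baseline/SNR is added.
#'
#' @inheritParams simulate_pet_scan
#' @return List with `blood_signal`, `global_signal`, `segment_signals`
#'   (named list), the noise-free `aif_conc`, and the `blood_params` /
#'   `tissue_params` [signal_params()] used.
#' @export
simulate_mri_scan <- function(truth_row, seg_rows, config) {
  hr <- if (truth_row$condition == "stress") config$heart_rate_stress
        else config$heart_rate_rest
  times <- (seq_len(config$mri_n_beats) - 1) * 60 / hr
  aif_conc <- gamma_variate_aif(mri_aif_params(config), times, unit = "mmol/L")
  blood_par <- signal_params(S0 = 100, T10 = config$t10_blood_s,
                             r1 = config$r1_relaxivity, TD = config$prep_delay_s)
  tissue_par <- signal_params(S0 = 100, T10 = config$t10_tissue_s,
                              r1 = config$r1_relaxivity, TD = config$prep_delay_s)
  set.seed(truth_row$noise_seed + 1L)
  add_noise <- function(sig, par) {
    if (!is.finite(config$mri_snr)) return(sig)
    base <- mri_signal_model(0, par)
    sig + stats::rnorm(length(sig), 0, base / config$mri_snr)
  }
  blood_sig <- add_noise(mri_signal_model(aif_conc$values, blood_par), blood_par)
  make_sig <- function(f) {
    gp <- gd_params(F_flow = f, PS = truth_row$PS, Ve = truth_row$Ve,
                    vb = truth_row$vb)
    conc <- gd_1tcm_forward(gp, aif_conc, mode = "ps_embedded")
    add_noise(mri_signal_model(conc$values, tissue_par), tissue_par)
  }
  glob <- make_sig(truth_row$F)
  segs <- list()
  if (!is.null(seg_rows) && nrow(seg_rows)) {
    segs <- lapply(seq_len(nrow(seg_rows)), function(i)
      sampled_curve(times, make_sig(seg_rows$F[i]), unit = "a.u."))
    names(segs) <- sprintf("seg%02d", seg_rows$segment)
  }
  list(blood_signal = sampled_curve(times, blood_sig, unit = "a.u."),
       global_signal = sampled_curve(times, glob, unit = "a.u."),
       segment_signals = segs,
       aif_conc = aif_conc,
       blood_params = blood_par, tissue_params = tissue_par)
}

#' Simulate a full dual-modality rest/stress cohort
#'
#' Draws the ground truth and simulates paired PET and MRI scans for every
#' subject and condition. Deterministic given the config (including its
#' seed).
#'
#' @param config A [cohort_config()].
#' @return A list of class `perfusion_cohort`: `config`, `truth`, and
#'   `records` — one entry per subject x condition (named e.g. `"S01_rest"`)
#'   holding `pet` and `mri` scan simulations.
#' @export
simulate_cohort <- function(config) {
  truth <- sample_ground_truth(config)
  records <- lapply(seq_len(nrow(truth$subjects)), function(i) {
    row <- truth$subjects[i, ]
    segs <- if (config$simulate_segments)
      truth$segments[truth$segments$subject == row$subject &
                       truth$segments$condition == row$condition, ]
    else NULL
    list(subject = row$subject, condition = row$condition,
         pet = simulate_pet_scan(row, segs, config),
         mri = simulate_mri_scan(row, segs, config))
  })
  names(records) <- paste(truth$subjects$subject, truth$subjects$condition,
                          sep = "_")
  structure(list(config = config, truth = truth, records = records),
            class = "perfusion_cohort")
}

#' @export
print.perfusion_cohort <- function(x, ...) {
  cat(sprintf("<perfusion_cohort> %d subjects x rest/stress, seed %d\n",
              x$config$n_subjects, x$config$seed))
  invisible(x)
}

#' Write a cohort as a directory tree of CSV curves
#'
#' Layout: `config.yaml`, `ground_truth.json`, then one directory per
#' subject/condition containing `pet_aif.csv`, `pet_aif_noisy.csv`,
#' `pet_global.csv`, `pet_segNN.csv`, `mri_blood.csv`, `mri_global.csv`,
#' `mri_segNN.csv` (each with its JSON sidecar) and `mri_meta.json` with the
#' signal-model constants.
#'
#' @param cohort A `perfusion_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "perfusion_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cohort$config), file.path(dir, "config.yaml"))
  jsonlite::write_json(list(subjects = cohort$truth$subjects,
                            segments = cohort$truth$segments),
                       file.path(dir, "ground_truth.json"),
                       digits = NA, dataframe = "columns")
  for (rec in cohort$records) {
    d <- file.path(dir, rec$subject, rec$condition)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_curve(rec$pet$aif, file.path(d, "pet_aif.csv"))
    write_curve(rec$pet$aif_noisy, file.path(d, "pet_aif_noisy.csv"))
    write_curve(rec$pet$global, file.path(d, "pet_global.csv"))
    for (nm in names(rec$pet$segments))
      write_curve(rec$pet$segments[[nm]], file.path(d, paste0("pet_", nm, ".csv")))
    write_curve(rec$mri$blood_signal, file.path(d, "mri_blood.csv"))
    write_curve(rec$mri$global_signal, file.path(d, "mri_global.csv"))
    for (nm in names(rec$mri$segment_signals))
      write_curve(rec$mri$segment_signals[[nm]], file.path(d, paste0("mri_", nm, ".csv")))
    jsonlite::write_json(list(blood_params = unclass(rec$mri$blood_params),
                              tissue_params = unclass(rec$mri$tissue_params)),
                         file.path(d, "mri_meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Cohort directory.
#' @return A `perfusion_cohort` (without the noise-free MRI concentration
#'   curves, which are simulation-internal).
#' @export
read_cohort <- function(dir) {
  cfg_list <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg_list$mri_snr <- as.numeric(cfg_list$mri_snr)   # ".inf" round trip
  config <- do.call(cohort_config, cfg_list)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  truth <- structure(list(config = config,
                          subjects = as.data.frame(gt$subjects),
                          segments = as.data.frame(gt$segments)),
                     class = "ground_truth")
  records <- lapply(seq_len(nrow(truth$subjects)), function(i) {
    row <- truth$subjects[i, ]
    d <- file.path(dir, row$subject, row$condition)
    meta <- jsonlite::read_json(file.path(d, "mri_meta.json"),
                                simplifyVector = TRUE)
    seg_files <- list.files(d, pattern = "^pet_seg[0-9]+\\.csv$")
    pet_segs <- lapply(seg_files, function(f) read_curve(file.path(d, f)))
    names(pet_segs) <- sub("^pet_(seg[0-9]+)\\.csv$", "\\1", seg_files)
    mseg_files <- list.files(d, pattern = "^mri_seg[0-9]+\\.csv$")
    mri_segs <- lapply(mseg_files, function(f) read_curve(file.path(d, f)))
    names(mri_segs) <- sub("^mri_(seg[0-9]+)\\.csv$", "\\1", mseg_files)
    list(subject = row$subject, condition = row$condition,
         pet = list(aif = read_curve(file.path(d, "pet_aif.csv")),
                    aif_noisy = read_curve(file.path(d, "pet_aif_noisy.csv")),
                    global = read_curve(file.path(d, "pet_global.csv")),
                    segments = pet_segs),
         mri = list(blood_signal = read_curve(file.path(d, "mri_blood.csv")),
                    global_signal = read_curve(file.path(d, "mri_global.csv")),
                    segment_signals = mri_segs,
                    blood_params = do.call(signal_params, meta$blood_params),
                    tissue_params = do.call(signal_params, meta$tissue_params)))
  })
  names(records) <- paste(truth$subjects$subject, truth$subjects$condition,
                          sep = "_")
  structure(list(config = config, truth = truth, records = records),
            class = "perfusion_cohort")
}
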