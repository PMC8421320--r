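# Shared fixtures: small cohorts built in code, memoised per test run.

.fixture_env <- new.env(parent = emptyenv())

# Noiseless 2-subject cohort with heterogeneous truths (global curves only).
noiseless_cohort <- function() {
  if (is.null(.fixture_env$noiseless)) {
    cfg <- cohort_config(n_subjects = 2, seed = 7, pet_noise_scale = 0,
                         mri_snr = Inf, simulate_segments = FALSE)
    .fixture_env$noiseless <- simulate_cohort(cfg)
  }
  .fixture_env$noiseless
}

# Noiseless homogeneous 2-subject cohort with all 17 segments.
noiseless_seg_cohort <- function() {
  if (is.null(.fixture_env$noiseless_seg)) {
    cfg <- cohort_config(n_subjects = 2, seed = 5, pet_noise_scale = 0,
                         mri_snr = Inf, segment_heterogeneity_cv = 0,
                         rest_mbf_sd = 0, stress_mbf_sd = 0, ps_sd = 0)
    .fixture_env$noiseless_seg <- simulate_cohort(cfg)
  }
  .fixture_env$noiseless_seg
}

truth_row <- function(cohort, subject, condition) {
  s <- cohort$truth$subjects
  s[s$subject == subject & s$condition == condition, ]
}

# Global concentration curves for one record (blood AIF + tissue).
conc_of <- function(rec) {
  aif <- signal_to_concentration(rec$mri$blood_signal, rec$mri$blood_params)
  tac <- signal_to_concentration(rec$mri$global_signal, rec$mri$tissue_params)
  list(aif = aif, tac = tac)
}

# A smooth gamma-variate test AIF on a 1 Hz grid.
test_aif <- function(duration = 180, dt = 1) {
  gamma_variate_aif(aif_params(t0 = 12, alpha = 3, beta = 4, amplitude = 80,
                               recirc_fraction = 0.15, recirc_tau = 40),
                    seq(0, duration, by = dt))
}
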