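test_that("noiseless plain fits recover the Renkin-Crone influx, not the flow", {
  co <- noiseless_cohort()
  for (key in c("S01_rest", "S01_stress")) {
    rec <- co$records[[key]]
    tr <- truth_row(co, rec$subject, rec$condition)
    cc <- conc_of(rec)
    fit <- fit_gd_plain_1tcm(cc$tac, cc$aif)
    k1_true <- renkin_crone_k1(tr$F, tr$PS)
    expect_equal(fit$params$K1, k1_true, tolerance = 1e-3)
    expect_equal(fit$params$Ve, tr$Ve, tolerance = 1e-3)
    expect_equal(fit$params$vb, tr$vb, tolerance = 1e-3)
    expect_true(fit$reliable)
    # underestimation: K1 < F always, nearly complete extraction at low flow
    expect_lt(fit$params$K1, tr$F)
  }
})

test_that("extraction is near-complete at low flow and saturates at high flow", {
  # K1/F at F = 0.5 with the calibrated PS is ~0.994
  expect_equal(renkin_crone_k1(0.5, 2.6) / 0.5, 0.994, tolerance = 1e-3)
  # K1 at stress-level flow is far below flow (the underestimation regime)
  k1_stress <- renkin_crone_k1(3.19, 2.6)
  expect_lt(k1_stress / 3.19, 0.6)
  expect_equal(k1_stress, 3.19 * (1 - exp(-2.6 / 3.19)), tolerance = 1e-12)
})

test_that("a blood-only curve pins K1 at its lower bound and is flagged", {
  aif <- test_aif(120, 1)
  aif <- sampled_curve(aif$times, aif$values / 20, unit = "mmol/L")
  tac <- sampled_curve(aif$times, 0.05 * aif$values, unit = "mmol/L")
  fit <- fit_gd_plain_1tcm(tac, aif)
  expect_equal(fit$params$K1, 0.01, tolerance = 1e-6)
  expect_true(fit$at_bound)
  expect_false(fit$reliable)
})

test_that("extraction correction inverts K1 and reports its noise amplification", {
  out <- apply_extraction_correction(c(0.92573, 0.1, 2.59), 2.6)
  expect_equal(out$F[1], 1.0, tolerance = 1e-4)
  expect_equal(out$F[2], 0.1, tolerance = 5e-4)    # negligible at low flow
  expect_true(out$recoverable[3])
  expect_gt(out$amplification[3], 50)               # near-asymptote blow-up
  expect_true(out$noisy[3])
  expect_false(out$noisy[1])
  # at/above the asymptote: unrecoverable, NA flow
  bad <- apply_extraction_correction(c(2.6, 3.0), 2.6)
  expect_false(any(bad$recoverable))
  expect_true(all(is.na(bad$F)))
})

test_that("amplification factor matches a finite-difference derivative of the inversion", {
  for (f in c(1, 3)) {
    k1 <- renkin_crone_k1(f, 2.6)
    h <- 1e-6
    fd <- (renkin_crone_invert(k1 + h, 2.6) - renkin_crone_invert(k1 - h, 2.6)) /
      (2 * h)
    expect_equal(renkin_crone_amplification(f, 2.6), fd, tolerance = 1e-4)
  }
})

test_that("population PS calibration recovers the generating value", {
  F_true <- seq(0.5, 4, length.out = 24)
  K1 <- renkin_crone_k1(F_true, 2.6)
  cal <- calibrate_population_ps(K1, F_true)
  expect_equal(cal$PS, 2.6, tolerance = 1e-4)
  expect_false(cal$at_upper)
  # K1 == F exactly: extraction ~ 1, PS runs to the search bound
  expect_warning(deg <- calibrate_population_ps(F_true, F_true),
                 "unidentifiable")
  expect_true(deg$at_upper)
  # flows clustered at one value: ill-conditioned warning
  expect_warning(calibrate_population_ps(K1[1:5] + 0, rep(0.9, 5)),
                 "ill-conditioned")
})

test_that("calibration under 5% noise lands within 0.2 of truth (median over seeds)", {
  med <- sapply(1:30, function(s) {
    set.seed(s)
    F_true <- runif(24, 0.5, 4)
    K1 <- renkin_crone_k1(F_true, 2.6) * (1 + rnorm(24, 0, 0.05))
    Fn <- F_true * (1 + rnorm(24, 0, 0.05))
    suppressWarnings(calibrate_population_ps(pmax(K1, 0), pmax(Fn, 0.01))$PS)
  })
  expect_lt(abs(median(med) - 2.6), 0.2)
})

test_that("flow fits with a fixed PS recover the generating flow to 1e-3", {
  co <- noiseless_cohort()
  for (key in names(co$records)) {
    rec <- co$records[[key]]
    tr <- truth_row(co, rec$subject, rec$condition)
    cc <- conc_of(rec)
    fit <- fit_gd_1tcm_ps(cc$tac, cc$aif, ps = tr$PS)
    expect_equal(fit$params$F, tr$F, tolerance = 1e-3)
    expect_true(fit$reliable)
  }
})

test_that("the free flow/permeability fit sits on the K1 ridge and says so", {
  co <- noiseless_cohort()
  rec <- co$records[["S01_stress"]]
  tr <- truth_row(co, "S01", "stress")
  cc <- conc_of(rec)
  fit <- fit_gd_1tcm_ps(cc$tac, cc$aif, ps = "free")
  # the identifiable combination is recovered exactly ...
  expect_equal(fit$params$K1, renkin_crone_k1(tr$F, tr$PS), tolerance = 1e-3)
  expect_lt(fit$rss, 1e-10)
  # ... but flow itself is on a flat ridge: huge relative SE, not reliable
  expect_false(fit$reliable)
  expect_true(!is.finite(fit$param_rel_se[["F"]]) ||
                fit$param_rel_se[["F"]] > 0.5)
})

test_that("per-subject PS from rest+stress pairs against reference flows is exact", {
  ps_true <- 2.91
  f <- c(0.97, 3.19)
  k1 <- renkin_crone_k1(f, ps_true)
  expect_equal(estimate_subject_ps(k1, f), ps_true, tolerance = 1e-4)
})

test_that("route equivalence: extraction-corrected K1 equals the PS-fixed flow fit", {
  co <- noiseless_cohort()
  rec <- co$records[["S02_rest"]]
  tr <- truth_row(co, "S02", "rest")
  cc <- conc_of(rec)
  plain <- fit_gd_plain_1tcm(cc$tac, cc$aif)
  f_ef <- apply_extraction_correction(plain$params$K1, tr$PS)$F
  f_ps <- fit_gd_1tcm_ps(cc$tac, cc$aif, ps = tr$PS)$params$F
  expect_equal(f_ef, f_ps, tolerance = 1e-4)
  expect_equal(f_ef, tr$F, tolerance = 1e-3)
})

test_that("cohort MRI fits: all three routes run, direct route recovers truth noiselessly", {
  co <- noiseless_cohort()
  pet <- fit_cohort_pet(co, level = "global")
  plain <- fit_cohort_mri(co, "plain_1tcm", level = "global")
  expect_true(all(plain$reliable))
  ef <- fit_cohort_mri(co, "ef_corrected", level = "global",
                       ps_population = mean(co$truth$subjects$PS))
  expect_true(all(is.finite(ef$F)))
  ps <- fit_cohort_mri(co, "1tcm_ps", level = "global", pet_table = pet)
  m <- merge(ps, co$truth$subjects, by = c("subject", "condition"))
  expect_true(all(abs(m$F.x - m$F.y) / m$F.y < 1e-3))
  expect_true(all(abs(m$PS.x - m$PS.y) / m$PS.y < 1e-3))
  expect_identical(sum(!ps$reliable), 0L)
  # determinism
  expect_identical(ps, fit_cohort_mri(co, "1tcm_ps", level = "global",
                                      pet_table = pet))
  # missing prerequisites are explicit errors
  expect_error(fit_cohort_mri(co, "ef_corrected", level = "global"),
               "ps_population")
  expect_error(fit_cohort_mri(co, "1tcm_ps", level = "global"), "pet_table")
})

test_that("very low SNR raises the unreliable-fit rate", {
  count_unreliable <- function(snr, seeds) {
    n <- 0
    for (s in seeds) {
      cfg <- cohort_config(n_subjects = 2, seed = s, mri_snr = snr,
                           simulate_segments = FALSE)
      co <- simulate_cohort(cfg)
      rec <- co$records[["S01_rest"]]
      cc <- suppressWarnings(conc_of(rec))
      fit <- suppressWarnings(
        fit_gd_1tcm_ps(cc$tac, cc$aif,
                       ps = truth_row(co, "S01", "rest")$PS))
      n <- n + !fit$reliable
    }
    n
  }
  seeds <- 101:112
  expect_gte(count_unreliable(2, seeds), count_unreliable(30, seeds))
  expect_gt(count_unreliable(2, seeds), 0)
})

test_that("noise on the corrected flow grows much faster at stress than rest", {
  # fixed 5% relative noise on K1; Monte-Carlo SD of the corrected flow
  set.seed(9)
  sd_at <- function(f_true) {
    k1 <- renkin_crone_k1(f_true, 2.6)
    k1n <- pmin(k1 * (1 + rnorm(400, 0, 0.05)), 2.6 * 0.999)
    sd(renkin_crone_invert(pmax(k1n, 0), 2.6))
  }
  expect_gt(sd_at(3) / sd_at(1), 2)
})
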