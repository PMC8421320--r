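test_that("gamma-variate AIF is zero pre-arrival, peaks at amplitude, scales linearly", {
  ap <- aif_params(t0 = 10, alpha = 3, beta = 4, amplitude = 100)
  tt <- seq(0, 120, by = 0.01)
  g <- gamma_variate_aif(ap, tt)
  expect_true(all(g$values[tt <= 10] == 0))
  expect_true(all(g$values >= 0))
  # calculus maximum: amplitude at t0 + alpha*beta, verified on a fine grid
  expect_equal(max(g$values), 100, tolerance = 1e-8)
  expect_equal(tt[which.max(g$values)], 10 + 3 * 4, tolerance = 1e-3)
  ap2 <- aif_params(t0 = 10, alpha = 3, beta = 4, amplitude = 200,
                    recirc_fraction = 0.2)
  g1 <- gamma_variate_aif(aif_params(10, 3, 4, 100, 0.2), tt)
  g2 <- gamma_variate_aif(ap2, tt)
  expect_equal(g2$values, 2 * g1$values, tolerance = 1e-12)
  expect_error(gamma_variate_aif(ap, c(3, 2, 1)), "increasing")
})

test_that("Renkin-Crone forward map matches its closed form and limits", {
  expect_equal(renkin_crone_k1(1.0, 2.6), 1 - exp(-2.6), tolerance = 1e-12)
  expect_equal(renkin_crone_k1(1.0, 2.6), 0.92573, tolerance = 1e-5)
  expect_equal(renkin_crone_k1(c(0, 2), 0), c(0, 0))
  expect_equal(renkin_crone_k1(0, 3), 0)
  expect_equal(renkin_crone_k1(1e6, 2.6), 2.6, tolerance = 1e-4)
  expect_error(renkin_crone_k1(-1, 2), "nonnegative")
})

test_that("Renkin-Crone map is monotone with extraction falling in flow", {
  f <- seq(0.2, 6, length.out = 40)
  k_f <- renkin_crone_k1(f, 2.6)
  expect_true(all(diff(k_f) > 0))                 # increasing in F
  ps <- seq(0.5, 6, length.out = 40)
  k_ps <- renkin_crone_k1(1.5, ps)
  expect_true(all(diff(k_ps) > 0))                # increasing in PS
  expect_true(all(k_f < pmin(f, 2.6)))            # K1 < min(F, PS)
  E <- k_f / f
  expect_true(all(E > 0 & E < 1))
  expect_true(all(diff(E) < 0))                   # extraction falls with flow
})

test_that("Renkin-Crone inversion round-trips and rejects the asymptote", {
  expect_equal(renkin_crone_invert(1 - exp(-2.6), 2.6), 1.0, tolerance = 1e-6)
  expect_equal(renkin_crone_invert(0, 2.6), 0)
  for (f in c(0.1, 0.97, 3.19, 7)) {
    k1 <- renkin_crone_k1(f, 2.91)
    f_back <- renkin_crone_invert(k1, 2.91)
    expect_lt(abs(renkin_crone_k1(f_back, 2.91) - k1), 1e-10)
    expect_equal(f_back, f, tolerance = 1e-8)
  }
  expect_error(renkin_crone_invert(2.6, 2.6), "no solution")
  expect_error(renkin_crone_invert(3.0, 2.6), "no solution")
  expect_error(renkin_crone_invert(-0.1, 2.6), "nonnegative")
})

test_that("expconv reproduces the step-input closed form and the running integral", {
  t <- seq(0, 100, by = 2.5)
  cu <- sampled_curve(t, rep(3, length(t)))
  k <- 0.07
  expect_equal(expconv(cu, k)$values, 3 * (1 - exp(-k * t)) / k,
               tolerance = 1e-12)
  expect_equal(expconv(cu, 0)$values, 3 * t, tolerance = 1e-12)
  zero <- sampled_curve(t, rep(0, length(t)))
  expect_equal(expconv(zero, k)$values, rep(0, length(t)))
  expect_error(expconv(cu, -0.1), ">= 0")
})

test_that("expconv matches a dense-grid brute-force convolution on a bolus input", {
  aif <- test_aif(duration = 180, dt = 1)     # 1 Hz sampling
  k <- 0.04
  y <- expconv(aif, k)$values
  # oracle: trapezoidal convolution of the piecewise-linear input on dt = 0.01
  tf <- seq(0, 180, by = 0.01)
  vf <- approx(aif$times, aif$values, xout = tf)$y
  oracle <- sapply(seq(11, length(tf), by = 500), function(i) {
    s <- tf[1:i]
    sum_tr <- function(g) sum((g[-1] + g[-length(g)]) / 2) * 0.01
    sum_tr(vf[1:i] * exp(-k * (tf[i] - s)))
  })
  idx <- match(tf[seq(11, length(tf), by = 500)], aif$times)
  keep <- !is.na(idx)
  expect_true(all(abs(y[idx[keep]] - oracle[keep]) /
                    pmax(oracle[keep], 1e-8) < 1e-5))
})

test_that("water forward model has the stated degenerate and closed forms", {
  aif <- test_aif()
  # F = 0 reduces to pure spillover
  out0 <- water_1tcm_forward(water_params(0, PTF = 0.7, Va = 0.1), aif)
  expect_equal(out0$values, 0.1 * aif$values, tolerance = 1e-12)
  # constant AIF: tissue term PTF * p * c * (1 - exp(-F t / p)) (F in 1/s)
  t <- seq(0, 300, by = 5)
  const <- sampled_curve(t, rep(10, length(t)))
  p <- 0.91
  out <- water_1tcm_forward(water_params(1.2, PTF = 0.6, Va = 0, p = p), const)
  expect_equal(out$values, 0.6 * p * 10 * (1 - exp(-(1.2 / 60) * t / p)),
               tolerance = 1e-10)
  # linear in PTF: doubling PTF doubles the tissue term only
  lo <- water_1tcm_forward(water_params(2, PTF = 0.4, Va = 0.2), aif)
  hi <- water_1tcm_forward(water_params(2, PTF = 0.8, Va = 0.2), aif)
  tissue_lo <- lo$values - 0.2 * aif$values
  tissue_hi <- hi$values - 0.2 * aif$values
  expect_equal(tissue_hi, 2 * tissue_lo, tolerance = 1e-10)
})

test_that("gadolinium forward model composes with the Renkin-Crone map", {
  aif <- test_aif()
  aif <- sampled_curve(aif$times, aif$values / 20, unit = "mmol/L")
  out0 <- gd_1tcm_forward(gd_params(K1 = 0, vb = 0.05), aif, mode = "plain")
  expect_equal(out0$values, 0.05 * aif$values, tolerance = 1e-12)
  # ps_embedded(F, PS) equals plain(K1 = renkin_crone_k1(F, PS)) pointwise
  k1 <- renkin_crone_k1(1.0, 2.6)
  emb <- gd_1tcm_forward(gd_params(F_flow = 1.0, PS = 2.6, Ve = 0.3, vb = 0.07),
                         aif, mode = "ps_embedded")
  pl <- gd_1tcm_forward(gd_params(K1 = k1, Ve = 0.3, vb = 0.07), aif,
                        mode = "plain")
  expect_equal(emb$values, pl$values, tolerance = 1e-9)
  # F -> Inf converges to plain with K1 = PS
  emb_inf <- gd_1tcm_forward(gd_params(F_flow = 1e7, PS = 2.6, Ve = 0.3,
                                       vb = 0.07), aif, mode = "ps_embedded")
  pl_ps <- gd_1tcm_forward(gd_params(K1 = 2.6, Ve = 0.3, vb = 0.07), aif,
                           mode = "plain")
  expect_equal(emb_inf$values, pl_ps$values, tolerance = 1e-6)
  # constant AIF closed form: Ve * c * (1 - exp(-K1 t / Ve))
  t <- seq(0, 120, by = 2)
  const <- sampled_curve(t, rep(2, length(t)), unit = "mmol/L")
  out <- gd_1tcm_forward(gd_params(K1 = 1.5, Ve = 0.4, vb = 0), const,
                         mode = "plain")
  expect_equal(out$values, 0.4 * 2 * (1 - exp(-(1.5 / 60) * t / 0.4)),
               tolerance = 1e-10)
  expect_error(gd_1tcm_forward(gd_params(Ve = 0.3), aif, mode = "plain"),
               "K1")
})

test_that("minute/second unit handling is exact", {
  # route A: package convention (times s, rates mL/g/min converted inside)
  aif <- test_aif()
  out <- water_1tcm_forward(water_params(1.7, PTF = 0.65, Va = 0.2), aif)
  # route B: everything hand-converted to per-second rates
  f_s <- 1.7 / 60
  tissue <- 0.65 * f_s * expconv(aif, f_s / 0.91)$values
  expect_equal(out$values, tissue + 0.2 * aif$values, tolerance = 1e-12)
})
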