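#' Gamma-variate arterial input function parameters
#'
#' Parametric bolus model used by the simulator in place of a measured
#' arterial curve: a peak-normalised gamma variate plus an optional
#' recirculation tail.
#'
#' @param t0 Bolus arrival time, s (>= 0).
#' @param alpha Gamma-variate shape (> 0), dimensionless.
#' @param beta Gamma-variate time scale (> 0), s.
#' @param amplitude Peak value, in the units of the output curve (> 0).
#' @param recirc_fraction Recirculation fraction in [0, 1); 0 disables the
#'   tail.
#' @param recirc_tau Recirculation time constant, s (> 0).
#' @return A list of class `aif_params`.
#' @export
aif_params <- function(t0, alpha, beta, amplitude,
                       recirc_fraction = 0, recirc_tau = 30) {
  stopifnot(t0 >= 0, alpha > 0, beta > 0, amplitude > 0,
            recirc_fraction >= 0, recirc_fraction < 1, recirc_tau > 0)
  structure(list(t0 = t0, alpha = alpha, beta = beta, amplitude = amplitude,
                 recirc_fraction = recirc_fraction, recirc_tau = recirc_tau),
            class = "aif_params")
}

#' Simulated arterial input function
#'
#' Evaluates the peak-normalised gamma variate
#' `amplitude * ((t - t0) / (alpha*beta))^alpha * exp(alpha - (t - t0)/beta)`
#' (zero before `t0`, maximum `amplitude` at `t0 + alpha*beta`), plus a
#' recirculation term: the first-pass curve convolved with
#' `exp(-t/recirc_tau)/recirc_tau` and scaled by `recirc_fraction`, so that
#' `recirc_fraction` is the dimensionless steady-state fraction of the
#' first-pass input carried by the tail.
#'
#' @param params An [aif_params()] object.
#' @param times Nonnegative, strictly increasing sample times, s.
#' @param unit Unit tag for the output curve.
#' @return A [sampled_curve()].
#' @export
gamma_variate_aif <- function(params, times, unit = "kBq/mL") {
  stopifnot(inherits(params, "aif_params"))
  times <- as.numeric(times)
  if (any(times < 0) || any(diff(times) <= 0))
    stop("`times` must be nonnegative and strictly increasing", call. = FALSE)
  x <- (times - params$t0) / (params$alpha * params$beta)
  fp <- ifelse(x <= 0, 0,
               params$amplitude * x^params$alpha *
                 exp(params$alpha - (times - params$t0) / params$beta))
  values <- fp
  if (params$recirc_fraction > 0) {
    fp_curve <- sampled_curve(times, fp, unit = unit)
    tail <- expconv(fp_curve, 1 / params$recirc_tau)
    values <- fp + params$recirc_fraction * tail$values / params$recirc_tau
  }
  sampled_curve(times, values, unit = unit)
}

#' Renkin-Crone influx rate
#'
#' Maps flow and permeability-surface-area product to the unidirectional
#' influx rate K1 = F * (1 - exp(-PS/F)). The extraction fraction
#' E = K1/F = 1 - exp(-PS/F) falls with increasing flow, which is why a
#' low-permeability tracer such as Gd-DOTA underestimates perfusion at
#' hyperaemic flows when K1 is read as flow.
#'
#' @param F_flow Blood flow, mL/g/min (>= 0); vectorised.
#' @param PS Permeability-surface-area product, mL/g/min (>= 0); vectorised.
#' @return K1 in mL/g/min. `F = 0` maps to 0.
#' @export
renkin_crone_k1 <- function(F_flow, PS) {
  if (any(F_flow < 0) || any(PS < 0))
    stop("`F_flow` and `PS` must be nonnegative", call. = FALSE)
  out <- ifelse(F_flow == 0, 0, F_flow * -expm1(-PS / F_flow))
  as.numeric(out)
}

#' Invert the Renkin-Crone relation for flow
#'
#' Finds the unique F with `renkin_crone_k1(F, PS) == K1` by monotone root
#' finding. Because K1 -> PS as F -> Inf, the inversion only exists for
#' K1 < PS; near that asymptote the derivative dF/dK1 blows up, amplifying
#' any measurement noise on K1.
#'
#' @param K1 Influx rate, mL/g/min (0 <= K1 < PS); vectorised.
#' @param PS Permeability-surface-area product, mL/g/min (> 0).
#' @param tol Root-finding tolerance on K1 (default 1e-12).
#' @return Flow F in mL/g/min with round-trip error below `tol`.
#' @export
renkin_crone_invert <- function(K1, PS, tol = 1e-12) {
  if (any(K1 < 0)) stop("`K1` must be nonnegative", call. = FALSE)
  if (any(K1 >= PS))
    stop("no solution: K1 >= PS (flow unbounded at the extraction asymptote)",
         call. = FALSE)
  vapply(K1, function(k1) {
    if (k1 == 0) return(0)
    # K1 <= F always, so F = k1 brackets from below; expand upper bound
    # until the residual changes sign (guaranteed since K1 -> PS < infinity).
    lo <- k1
    hi <- max(2 * k1, 1)
    while (renkin_crone_k1(hi, PS) < k1) hi <- hi * 2
    stats::uniroot(function(f) renkin_crone_k1(f, PS) - k1,
                   lower = lo, upper = hi, tol = tol / 10)$root
  }, numeric(1))
}

#' Error amplification of the extraction correction
#'
#' First-order factor dF/dK1 = 1 / (1 - (1 + PS/F) * exp(-PS/F)) by which
#' measurement noise on K1 is magnified when inverted to flow; grows without
#' bound as K1 approaches PS.
#'
#' @param F_flow Flow, mL/g/min (> 0); vectorised.
#' @param PS Permeability-surface-area product, mL/g/min (> 0).
#' @return Amplification factor (> 1).
#' @export
renkin_crone_amplification <- function(F_flow, PS) {
  stopifnot(all(F_flow > 0), all(PS > 0))
  r <- PS / F_flow
  1 / (1 - (1 + r) * exp(-r))
}

#' Convolution with a decaying exponential
#'
#' Computes `(curve %convolve% exp(-rate * t))(t_i)` at the curve's own sample
#' times, treating the input as piecewise linear between samples (and constant
#' at its first value over `[0, t_1]`). The update from one sample to the next
#' uses the closed-form integral of a linear segment against the exponential
#' kernel, so the recursion is exact for piecewise-linear inputs on arbitrary
#' nonuniform grids — no fine regridding and no FFT. `rate = 0` degenerates to
#' the running time-integral of the curve.
#'
#' @param curve A [sampled_curve()].
#' @param rate Decay rate of the kernel, 1/s (>= 0).
#' @return A [sampled_curve()] on the same times; units are input units * s.
#' @export
expconv <- function(curve, rate) {
  stopifnot(is_sampled_curve(curve))
  if (!is.finite(rate) || rate < 0) stop("`rate` must be >= 0", call. = FALSE)
  t <- curve$times
  v <- curve$values
  n <- length(t)
  y <- numeric(n)
  y[1] <- segment_conv(v[1], v[1], t[1], rate)
  if (n > 1) {
    dt <- diff(t)
    E <- exp(-rate * dt)
    for (i in seq_len(n - 1)) {
      y[i + 1] <- y[i] * E[i] + segment_conv(v[i], v[i + 1], dt[i], rate)
    }
  }
  sampled_curve(t, y, unit = curve$unit, frame_durations = curve$frame_durations)
}

# Integral over one segment of a linear input c(s) = c0 + (c1-c0)*s/dt against
# exp(-rate*(dt - s)), s in [0, dt]. Series fallback keeps small rate*dt stable.
segment_conv <- function(c0, c1, dt, rate) {
  if (dt == 0) return(0)
  x <- rate * dt
  if (x < 1e-6) {
    # Taylor expansion in x of the exact expressions below
    return(c0 * dt * (1 - x / 2 + x^2 / 6) +
             (c1 - c0) * dt * (0.5 - x / 3 + x^2 / 8))
  }
  e1 <- -expm1(-x)            # 1 - exp(-x)
  i0 <- e1 / rate             # int exp(-rate*(dt-s)) ds
  i1 <- (dt - i0) / rate      # int s * exp(-rate*(dt-s)) ds
  c0 * i0 + (c1 - c0) / dt * i1
}

#' Kinetic parameters of the 15O-water single-tissue model
#'
#' @param F_flow Myocardial blood flow, mL/g/min (>= 0).
#' @param PTF Perfusable tissue fraction, g/mL, in (0, 1].
#' @param Va Arterial blood-volume (spillover) fraction in [0, 1).
#' @param p Water partition coefficient, mL/g; fixed, not fitted.
#' @return A list of class `water_params`.
#' @export
water_params <- function(F_flow, PTF = 0.7, Va = 0.25, p = 0.91) {
  stopifnot(F_flow >= 0, PTF > 0, PTF <= 1, Va >= 0, Va < 1, p > 0)
  structure(list(F_flow = F_flow, PTF = PTF, Va = Va, p = p),
            class = "water_params")
}

#' Forward single-tissue model for 15O-water PET
#'
#' `C_PET(t) = PTF * F * [C_A conv exp(-(F/p) t)] + Va * C_A(t)`, with F in
#' mL/g/min converted to 1/s at the model boundary. Water is freely
#' diffusible, so the washout rate F/p carries the flow information that makes
#' F identifiable from a single curve.
#'
#' @param params A [water_params()] object.
#' @param aif Arterial input [sampled_curve()] covering `times`.
#' @param times Output sample times, s (default: the AIF times).
#' @param frame_durations Optional frame durations attached to the output.
#' @return A [sampled_curve()] in the AIF's units.
#' @export
water_1tcm_forward <- function(params, aif, times = aif$times,
                               frame_durations = NULL) {
  stopifnot(inherits(params, "water_params"), is_sampled_curve(aif))
  ca <- curve_interp(aif, times)
  ca_curve <- sampled_curve(times, ca, unit = aif$unit)
  f_s <- params$F_flow / 60                     # mL/g/min -> mL/g/s
  k2 <- f_s / params$p                          # 1/s
  tissue <- params$PTF * f_s * expconv(ca_curve, k2)$values
  sampled_curve(times, tissue + params$Va * ca, unit = aif$unit,
                frame_durations = frame_durations)
}

#' Kinetic parameters of the gadolinium one-tissue models
#'
#' For the plain model only `K1` is needed; the flow/permeability
#' parameterisation ties `K1 = renkin_crone_k1(F, PS)`.
#'
#' @param F_flow Flow, mL/g/min, or NA in plain mode.
#' @param PS Permeability-surface-area product, mL/g/min, or NA in plain mode.
#' @param K1 Influx rate, mL/g/min, or NA when derived from (F, PS).
#' @param Ve Extravascular distribution volume, mL/g (> 0).
#' @param vb Vascular (blood-volume) fraction in [0, 1).
#' @return A list of class `gd_params`.
#' @export
gd_params <- function(F_flow = NA_real_, PS = NA_real_, K1 = NA_real_,
                      Ve = 0.35, vb = 0.08) {
  stopifnot(Ve > 0, vb >= 0, vb < 1)
  if (!is.na(F_flow) && !is.na(PS) && !is.na(K1)) {
    if (abs(K1 - renkin_crone_k1(F_flow, PS)) > 1e-8)
      stop("inconsistent K1: must equal renkin_crone_k1(F, PS)", call. = FALSE)
  }
  structure(list(F_flow = F_flow, PS = PS, K1 = K1, Ve = Ve, vb = vb),
            class = "gd_params")
}

#' Forward one-tissue model for gadolinium concentration
#'
#' `C_T(t) = K1 * [C_A conv exp(-(K1/Ve) t)] + vb * C_A(t)` in mmol/L. In
#' `"plain"` mode K1 is a free parameter; in `"ps_embedded"` mode it is
#' derived as `renkin_crone_k1(F, PS)`. Note that the curve depends on (F, PS)
#' only through K1: the pair is not separately identifiable from a single
#' tissue curve (see the methods vignette).
#'
#' @param params A [gd_params()] object.
#' @param aif Arterial concentration [sampled_curve()] (mmol/L).
#' @param times Output sample times, s (default: the AIF times).
#' @param mode `"plain"` (uses `K1`) or `"ps_embedded"` (uses `F`, `PS`).
#' @return A [sampled_curve()] in mmol/L.
#' @export
gd_1tcm_forward <- function(params, aif, times = aif$times,
                            mode = c("plain", "ps_embedded")) {
  stopifnot(inherits(params, "gd_params"), is_sampled_curve(aif))
  mode <- match.arg(mode)
  K1 <- if (mode == "plain") {
    if (is.na(params$K1)) stop("plain mode requires `K1`", call. = FALSE)
    params$K1
  } else {
    if (is.na(params$F_flow) || is.na(params$PS))
      stop("ps_embedded mode requires `F_flow` and `PS`", call. = FALSE)
    renkin_crone_k1(params$F_flow, params$PS)
  }
  ca <- curve_interp(aif, times)
  ca_curve <- sampled_curve(times, ca, unit = "mmol/L")
  k1_s <- K1 / 60                               # mL/g/min -> mL/g/s
  k2 <- k1_s / params$Ve                        # 1/s
  tissue <- k1_s * expconv(ca_curve, k2)$values
  sampled_curve(times, tissue + params$vb * ca, unit = "mmol/L")
}
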