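# Shared nonlinear least-squares machinery for the kinetic fits:
# box-constrained Levenberg-Marquardt (minpack.lm) with multiple starts and
# Gauss-Newton standard errors from a forward-difference Jacobian.

fit_nls_multistart <- function(resid_fn, starts, lower, upper) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ok <- fit$info %in% 1:4
    rss <- fit$deviance
    if (is.null(best) || (ok && !best$ok) || (ok == best$ok && rss < best$rss))
      best <- list(par = fit$par, rss = rss, ok = ok, niter = fit$niter)
  }
  if (is.null(best))
    return(list(par = lower * NA, rss = NA_real_, converged = FALSE,
                se = lower * NA, at_bound = FALSE))
  se <- gauss_newton_se(resid_fn, best$par, best$rss, upper)
  span <- upper - lower
  at_bound <- any((best$par - lower) < 0.01 * span |
                    (upper - best$par) < 0.01 * span)
  list(par = best$par, rss = best$rss, converged = best$ok, se = se,
       at_bound = at_bound)
}

# Approximate parameter SEs from the residual Jacobian at the solution:
# cov = s2 * (J'J)^-1. A singular J'J (e.g. a flat identifiability ridge)
# yields Inf SEs rather than an error.
gauss_newton_se <- function(resid_fn, par, rss, upper = rep(Inf, length(par))) {
  r0 <- resid_fn(par)
  n <- length(r0)
  p <- length(par)
  if (n <= p) return(rep(Inf, p))
  J <- matrix(0, n, p)
  h <- pmax(abs(par), 1e-3) * 1e-6
  h <- ifelse(par + h > upper, -h, h)   # step inward at an active upper bound
  for (j in seq_len(p)) {
    pj <- par
    pj[j] <- pj[j] + h[j]
    J[, j] <- (resid_fn(pj) - r0) / h[j]
  }
  s2 <- rss / (n - p)
  cov <- tryCatch(solve(crossprod(J)) * s2, error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) < 0))
    return(rep(Inf, p))
  sqrt(diag(cov))
}

# AIF shifted by `delay` seconds (positive = arrives later), evaluated on its
# own time grid; values before the shifted support are zero, beyond it are
# held at the last sample.
aif_shift <- function(aif, delay) {
  if (delay == 0) return(aif)
  v <- stats::approx(aif$times + delay, aif$values, xout = aif$times,
                     yleft = 0, yright = aif$values[length(aif$values)])$y
  sampled_curve(aif$times, v, unit = aif$unit,
                frame_durations = aif$frame_durations)
}

# Weighted (default equal) pointwise mean of curves on a common grid, used to
# build territory and global curves from member segments.
average_curves <- function(curves, weights = NULL) {
  stopifnot(length(curves) >= 1)
  if (is.null(weights)) weights <- rep(1, length(curves))
  weights <- weights / sum(weights)
  tref <- curves[[1]]$times
  for (cu in curves)
    if (!isTRUE(all.equal(cu$times, tref)))
      stop("curves must share a common time grid", call. = FALSE)
  vals <- Reduce(`+`, Map(function(cu, w) w * cu$values, curves, weights))
  sampled_curve(tref, vals, unit = curves[[1]]$unit,
                frame_durations = curves[[1]]$frame_durations)
}
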