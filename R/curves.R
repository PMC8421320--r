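#' Sampled time-course curve
#'
#' Container for one region's dynamic measurement: a vector of sample times
#' (seconds from injection; PET frame midpoints) and the measured value at
#' each time. PET curves carry frame durations; the unit tag distinguishes
#' activity concentration (kBq/mL), gadolinium concentration (mmol/L) and raw
#' MRI signal (a.u.).
#'
#' @param times Numeric vector, seconds from injection, strictly increasing,
#'   all >= 0.
#' @param values Numeric vector of measurements, same length as `times`,
#'   finite.
#' @param unit One of `"kBq/mL"`, `"mmol/L"`, `"a.u."`.
#' @param frame_durations Optional numeric vector of frame durations in
#'   seconds (PET only); positive, same length as `times`.
#' @return An object of class `sampled_curve`.
#' @export
sampled_curve <- function(times, values, unit = c("kBq/mL", "mmol/L", "a.u."),
                          frame_durations = NULL) {
  unit <- match.arg(unit)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("`times` and `values` must have the same length", call. = FALSE)
  if (length(times) < 1L) stop("curve must have at least one sample", call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0))
    stop("`times` must be finite and nonnegative", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (any(!is.finite(values)))
    stop("`values` must be finite", call. = FALSE)
  if (!is.null(frame_durations)) {
    frame_durations <- as.numeric(frame_durations)
    if (length(frame_durations) != length(times))
      stop("`frame_durations` must match `times` in length", call. = FALSE)
    if (any(!is.finite(frame_durations)) || any(frame_durations <= 0))
      stop("`frame_durations` must be positive", call. = FALSE)
  }
  structure(list(times = times, values = values, unit = unit,
                 frame_durations = frame_durations),
            class = "sampled_curve")
}

#' @export
print.sampled_curve <- function(x, ...) {
  cat(sprintf("<sampled_curve> %d samples, %.1f-%.1f s, unit %s\n",
              length(x$times), min(x$times), max(x$times), x$unit))
  invisible(x)
}

#' @export
length.sampled_curve <- function(x) length(x$times)

is_sampled_curve <- function(x) inherits(x, "sampled_curve")

#' Linear interpolation of a curve onto new times
#'
#' Requested times must lie within the sampled support; the curve is treated
#' as piecewise linear between samples (the same convention the convolution
#' recursion assumes).
#'
#' @param curve A [sampled_curve()].
#' @param times Target times in seconds.
#' @return Numeric vector of interpolated values.
#' @export
curve_interp <- function(curve, times) {
  stopifnot(is_sampled_curve(curve))
  tol <- 1e-9
  if (min(times) < curve$times[1] - tol || max(times) > max(curve$times) + tol)
    stop(sprintf(
      "requested times [%g, %g] outside curve support [%g, %g] (extrapolation)",
      min(times), max(times), curve$times[1], max(curve$times)), call. = FALSE)
  stats::approx(curve$times, curve$values, xout = pmin(pmax(times, curve$times[1]),
                                                       max(curve$times)))$y
}

#' Write a curve as CSV with a JSON sidecar
#'
#' Serialises a curve as a two-column CSV (`time_s`, `value`) next to a JSON
#' sidecar (same path with `.json` extension) carrying the unit tag and, for
#' PET, the frame durations.
#'
#' @param curve A [sampled_curve()].
#' @param path CSV file path (the sidecar replaces the extension with .json).
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(is_sampled_curve(curve))
  utils::write.csv(data.frame(time_s = curve$times, value = curve$values),
                   path, row.names = FALSE)
  side <- list(unit = curve$unit)
  if (!is.null(curve$frame_durations)) side$frame_durations <- curve$frame_durations
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a curve written by [write_curve()]
#' @param path CSV file path.
#' @return A [sampled_curve()].
#' @export
read_curve <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  sampled_curve(df$time_s, df$value, unit = side$unit,
                frame_durations = side$frame_durations)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)
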