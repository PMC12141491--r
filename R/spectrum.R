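#' Emission spectrum container
#'
#' Wraps a wavelength-indexed fluorescence emission spectrum (typically a
#' 77 K chlorophyll fluorescence measurement) together with its sample
#' metadata. Wavelengths must be strictly increasing and intensities finite.
#'
#' @param wavelength_nm Numeric vector of wavelengths in nm, strictly
#'   increasing, length >= 2.
#' @param intensity Numeric vector of fluorescence counts (a.u.), same length.
#' @param meta Named list of sample metadata. Conventional fields:
#'   `sample_id`, `species`, `treatment` (e.g. light-state label or salinity),
#'   `dilution_percent` (100, 50, 25, ...), `replicate`.
#' @return An object of class `emission_spectrum`: a list with elements
#'   `wavelength_nm`, `intensity`, `meta`, and a `provenance` character vector
#'   recording the processing steps applied so far.
#' @export
emission_spectrum <- function(wavelength_nm, intensity, meta = list()) {
  wavelength_nm <- as.numeric(wavelength_nm)
  intensity <- as.numeric(intensity)
  if (length(wavelength_nm) < 2L)
    stop("an emission spectrum needs at least 2 points")
  if (length(intensity) != length(wavelength_nm))
    stop("wavelength_nm and intensity lengths differ")
  if (any(!is.finite(wavelength_nm)) || any(!is.finite(intensity)))
    stop("wavelengths and intensities must be finite")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(
    list(wavelength_nm = wavelength_nm, intensity = intensity,
         meta = as.list(meta), provenance = character()),
    class = "emission_spectrum"
  )
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("<emission_spectrum> %d points, %.1f-%.1f nm\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm)))
  if (length(x$provenance))
    cat("  processed:", paste(x$provenance, collapse = " -> "), "\n")
  if (!is.null(x$meta$sample_id)) cat("  sample:", x$meta$sample_id, "\n")
  invisible(x)
}

is_uniform_grid <- function(w, tol = 1e-8) {
  d <- diff(w)
  max(d) - min(d) <= tol * mean(d)
}

#' Resample a spectrum onto a uniform wavelength grid
#'
#' Linear interpolation within the original wavelength range only; the
#' resampled grid starts at the first original wavelength and never
#' extrapolates, so the last grid point lies within one step of the original
#' endpoint.
#'
#' @param s An [emission_spectrum()].
#' @param step_nm Grid step in nm, > 0.
#' @return An `emission_spectrum` on the uniform grid, with `"resample"`
#'   appended to its provenance.
#' @export
resample_uniform <- function(s, step_nm = 0.5) {
  stopifnot(inherits(s, "emission_spectrum"))
  if (!is.numeric(step_nm) || length(step_nm) != 1L || step_nm <= 0)
    stop("step_nm must be a single positive number")
  w0 <- s$wavelength_nm
  grid <- seq(w0[1L], w0[length(w0)], by = step_nm)
  if (max(grid) > max(w0) + 1e-12)
    stop("resampling grid extends beyond the measured range")
  y <- approx(w0, s$intensity, xout = grid, method = "linear")$y
  out <- s
  out$wavelength_nm <- grid
  out$intensity <- y
  out$provenance <- c(s$provenance, "resample")
  out
}

#' Smooth a spectrum with a centered running average
#'
#' Centered moving mean over all points within `window_nm / 2` of each
#' wavelength (inclusive at the window edge). At the spectrum edges the
#' window is truncated to the available points. Requires a uniform grid.
#'
#' @param s An [emission_spectrum()] on a uniform grid.
#' @param window_nm Full window width in nm; must be at least the grid step.
#' @return The smoothed spectrum, provenance `"smooth"` appended.
#' @export
smooth_running_average <- function(s, window_nm = 4) {
  stopifnot(inherits(s, "emission_spectrum"))
  w <- s$wavelength_nm
  if (!is_uniform_grid(w))
    stop("smoothing requires a uniform grid; call resample_uniform() first")
  step <- (w[length(w)] - w[1L]) / (length(w) - 1L)
  if (window_nm < step - 1e-9)
    stop("window_nm is smaller than the grid step")
  half <- window_nm / 2
  k <- floor(half / step + 1e-9)            # points on each side of center
  y <- s$intensity
  n <- length(y)
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  out <- s
  out$intensity <- sm
  out$provenance <- c(s$provenance, "smooth")
  out
}

#' Subtract the long-wavelength baseline
#'
#' Sets the zero level by subtracting the mean intensity over a small window
#' around a reference wavelength (default 800 nm, the region where
#' chlorophyll fluorescence has decayed to the instrument baseline) from the
#' whole spectrum. Negative values that result are kept (not clamped) and
#' flagged.
#'
#' @param s An [emission_spectrum()].
#' @param ref_nm Reference wavelength in nm (default 800); must be covered
#'   by the grid.
#' @param half_width_nm Half-width of the averaging window in nm (default 2,
#'   i.e. 798-802 nm). The window is truncated to the measured range when
#'   the grid stops inside it.
#' @return The baseline-subtracted spectrum; provenance `"baseline"`
#'   appended; the subtracted level is stored in `$baseline_level` and a
#'   logical `$has_negatives` flag records whether any value went negative.
#' @export
subtract_baseline <- function(s, ref_nm = 800, half_width_nm = 2) {
  stopifnot(inherits(s, "emission_spectrum"))
  if ("normalize" %in% s$provenance)
    stop("baseline subtraction must precede normalization")
  w <- s$wavelength_nm
  if (min(w) > ref_nm - half_width_nm || max(w) < ref_nm)
    stop(sprintf("spectrum does not cover the %g nm baseline region", ref_nm))
  sel <- w >= ref_nm - half_width_nm & w <= ref_nm + half_width_nm
  level <- mean(s$intensity[sel])
  out <- s
  out$intensity <- s$intensity - level
  out$baseline_level <- level
  out$has_negatives <- any(out$intensity < 0)
  out$provenance <- c(s$provenance, "baseline")
  out
}

#' Normalize a spectrum to its PSII emission peak
#'
#' Divides the whole spectrum by the maximum intensity within the PSII
#' emission window (default 680-690 nm), so the PSII peak becomes exactly 1.
#' Must run after baseline subtraction (enforced through provenance). Ties in
#' the window maximum are broken toward the shorter wavelength.
#'
#' @param s A baseline-subtracted [emission_spectrum()].
#' @param window Numeric length-2, the PSII window in nm (default
#'   `c(680, 690)`).
#' @return An object of class `processed_spectrum` (inherits
#'   `emission_spectrum`) with `$psii_peak` (a list: `wavelength_nm`,
#'   `raw_height`) recording the normalization factor.
#' @export
normalize_to_psii <- function(s, window = c(680, 690)) {
  stopifnot(inherits(s, "emission_spectrum"))
  if (!"baseline" %in% s$provenance)
    stop("normalization requires prior baseline subtraction")
  w <- s$wavelength_nm
  sel <- which(w >= window[1L] & w <= window[2L])
  if (!length(sel))
    stop("spectrum does not cover the PSII window")
  m <- max(s$intensity[sel])
  if (m <= 0)
    stop("PSII window maximum is not positive (dead or empty sample?)")
  peak_i <- sel[which.max(s$intensity[sel])]   # first index: shorter-lambda tie-break
  out <- s
  out$intensity <- s$intensity / m
  out$psii_peak <- list(wavelength_nm = w[peak_i], raw_height = m)
  out$provenance <- c(s$provenance, "normalize")
  class(out) <- c("processed_spectrum", "emission_spectrum")
  out
}

#' Normalized PSI fluorescence statistic
#'
#' The maximum of the PSII-normalized spectrum within the PSI emission window
#' (default 710-730 nm). Some samples lack a distinct PSI emission peak; the
#' window maximum is still returned in that case, with `no_local_peak = TRUE`
#' so downstream analyses can flag it.
#'
#' @param p A `processed_spectrum` from [normalize_to_psii()].
#' @param window Numeric length-2, PSI window in nm (default `c(710, 730)`).
#' @param at_nm Optional fixed wavelength: if given, the statistic is the
#'   normalized intensity at the grid point nearest `at_nm` instead of the
#'   window maximum.
#' @return A list: `value` (the statistic), `wavelength_nm` (where it was
#'   taken), `no_local_peak` (TRUE if the window maximum is not an interior
#'   local maximum of the spectrum).
#' @export
psi_statistic <- function(p, window = c(710, 730), at_nm = NULL) {
  if (!inherits(p, "processed_spectrum"))
    stop("psi_statistic() expects a normalized spectrum (see normalize_to_psii)")
  w <- p$wavelength_nm
  y <- p$intensity
  if (!is.null(at_nm)) {
    i <- which.min(abs(w - at_nm))
    return(list(value = y[i], wavelength_nm = w[i], no_local_peak = NA))
  }
  sel <- which(w >= window[1L] & w <= window[2L])
  if (!length(sel))
    stop("spectrum does not cover the PSI window")
  i <- sel[which.max(y[sel])]
  interior <- i > 1L && i < length(y)
  is_local <- interior && y[i] >= y[i - 1L] && y[i] >= y[i + 1L] &&
    i != sel[1L] && i != sel[length(sel)]
  list(value = y[i], wavelength_nm = w[i], no_local_peak = !is_local)
}

#' Full 77 K spectrum processing pipeline
#'
#' Convenience wrapper applying the fixed processing order:
#' resample (if the grid is non-uniform or a step is requested), 4 nm running
#' average, 800 nm baseline subtraction, PSII-peak normalization.
#'
#' @param s An [emission_spectrum()].
#' @param step_nm Uniform grid step for resampling; `NULL` (default) keeps an
#'   already-uniform grid untouched and otherwise resamples at the median
#'   native step.
#' @param window_nm Running-average window (default 4 nm).
#' @param baseline_nm Baseline reference wavelength (default 800).
#' @param psii_window PSII normalization window (default `c(680, 690)`).
#' @return A `processed_spectrum`.
#' @export
process_spectrum <- function(s, step_nm = NULL, window_nm = 4,
                             baseline_nm = 800, psii_window = c(680, 690)) {
  stopifnot(inherits(s, "emission_spectrum"))
  if (is.null(step_nm)) {
    if (!is_uniform_grid(s$wavelength_nm)) {
      step_nm <- median(diff(s$wavelength_nm))
      s <- resample_uniform(s, step_nm)
    }
  } else {
    s <- resample_uniform(s, step_nm)
  }
  s <- smooth_running_average(s, window_nm = window_nm)
  s <- subtract_baseline(s, ref_nm = baseline_nm)
  normalize_to_psii(s, window = psii_window)
}
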