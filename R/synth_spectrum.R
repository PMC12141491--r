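#' Synthetic chlorophyll-like absorption profile
#'
#' Relative absorbance profile used by the self-absorption model of
#' [gen_spectrum()]: a main red band peaking at 678 nm with a vibronic
#' shoulder, decaying to ~0 beyond 710 nm. The profile is a synthetic
#' stand-in shaped like an in-vivo chlorophyll red absorption band (shipped
#' as `extdata/chl_absorption_synthetic.csv`), adequate for reproducing the
#' qualitative distortion of concentrated samples: emission at 680-690 nm is
#' re-absorbed far more strongly than emission at 710-730 nm.
#'
#' @param wavelength_nm Wavelengths at which to evaluate (linear
#'   interpolation; 0 outside the tabulated 640-810 nm range).
#' @return Relative absorbance in `[0, 1]`.
#' @export
chl_absorption <- function(wavelength_nm) {
  tab <- chl_absorption_table()
  out <- approx(tab$wavelength_nm, tab$absorbance_rel, xout = wavelength_nm,
                method = "linear", rule = 1)$y
  out[is.na(out)] <- 0
  out
}

chl_absorption_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "chl_absorption_synthetic.csv",
                          package = "fluoroplast", mustWork = TRUE)
      cache <<- read.csv(path)
    }
    cache
  }
})

#' Configuration for the synthetic 77 K spectrum generator
#'
#' The emission model is a sum of Gaussian bands: two PSII bands (defaults
#' 685 and 695 nm) and one PSI band (default 715 nm) whose amplitude is the
#' light-state-dependent quantity. Concentration-dependent self-absorption is
#' modelled as attenuation by `exp(-c * A(lambda))` with `A` the
#' [chl_absorption()] profile and `c = self_absorption_strength`.
#'
#' @param band_centers_nm Band centers (nm); exactly one must lie in the PSI
#'   region 700-740 nm.
#' @param band_sigmas_nm Gaussian sigmas (nm), > 0.
#' @param band_amplitudes Nonnegative amplitudes (counts).
#' @param baseline_offset Additive constant counts (detector offset).
#' @param noise_sd Gaussian noise SD in counts.
#' @param self_absorption_strength Nonnegative attenuation scalar `c`.
#' @param grid `c(start_nm, stop_nm, step_nm)`; must span at least
#'   650-800 nm so the 800 nm baseline region exists.
#' @param state2_factor Multiplier (> 1) applied to the PSI band amplitude in
#'   state 2 (default 2).
#' @param seed RNG seed (NULL leaves the RNG state alone).
#' @return A list of class `spectrum_gen_config`.
#' @export
spectrum_gen_config <- function(band_centers_nm = c(685, 695, 715),
                                band_sigmas_nm = c(6, 5, 10),
                                band_amplitudes = c(1000, 600, 550),
                                baseline_offset = 50,
                                noise_sd = 0,
                                self_absorption_strength = 0,
                                grid = c(650, 810, 0.5),
                                state2_factor = 2,
                                seed = NULL) {
  stopifnot(length(band_centers_nm) == length(band_sigmas_nm),
            length(band_centers_nm) == length(band_amplitudes))
  if (any(band_amplitudes < 0)) stop("amplitudes must be >= 0")
  if (any(band_sigmas_nm <= 0)) stop("sigmas must be > 0")
  if (length(grid) != 3L || grid[3L] <= 0)
    stop("grid must be c(start_nm, stop_nm, step_nm) with step > 0")
  if (grid[1L] > 650 || grid[2L] < 800)
    stop("grid must span at least 650-800 nm (the 800 nm baseline region)")
  if (self_absorption_strength < 0)
    stop("self_absorption_strength must be >= 0")
  psi_band <- which(band_centers_nm >= 700 & band_centers_nm <= 740)
  if (length(psi_band) != 1L)
    stop("exactly one band center must lie in the PSI region 700-740 nm")
  if (state2_factor <= 1) stop("state2_factor must be > 1")
  structure(list(band_centers_nm = band_centers_nm,
                 band_sigmas_nm = band_sigmas_nm,
                 band_amplitudes = band_amplitudes,
                 baseline_offset = baseline_offset,
                 noise_sd = noise_sd,
                 self_absorption_strength = self_absorption_strength,
                 grid = grid, state2_factor = state2_factor,
                 psi_band = psi_band, seed = seed),
            class = "spectrum_gen_config")
}

band_sum <- function(wl, centers, sigmas, amps) {
  y <- numeric(length(wl))
  for (i in seq_along(centers))
    y <- y + amps[i] * exp(-(wl - centers[i])^2 / (2 * sigmas[i]^2))
  y
}

#' Generate a synthetic 77 K emission spectrum with ground truth
#'
#' Evaluates the Gaussian band sum on the configured grid, attenuates the
#' emitted (band) signal by the self-absorption model, adds the baseline
#' offset and Gaussian noise. In `state2` the PSI band amplitude is
#' multiplied by `cfg$state2_factor`, emulating light-harvesting antenna
#' migration to PSI. The ground truth records the pre-distortion (no
#' self-absorption, no offset, no noise) normalized PSI statistic: the
#' band-sum maximum on 710-730 nm divided by the maximum on 680-690 nm,
#' evaluated on the same grid.
#'
#' @param cfg A [spectrum_gen_config()].
#' @param state `"state1"`, `"state2"`, or `"custom"` (use amplitudes as
#'   given).
#' @param meta Extra metadata stored on the spectrum (e.g. `sample_id`,
#'   `dilution_percent`).
#' @return A list: `spectrum` (an [emission_spectrum()]), `truth` (a list
#'   with `psi_over_psii`, the per-band amplitudes actually used, and the
#'   noise-free distorted intensities).
#' @export
gen_spectrum <- function(cfg, state = c("state1", "state2", "custom"),
                         meta = list()) {
  stopifnot(inherits(cfg, "spectrum_gen_config"))
  state <- match.arg(state)
  amps <- cfg$band_amplitudes
  if (state == "state2")
    amps[cfg$psi_band] <- amps[cfg$psi_band] * cfg$state2_factor
  wl <- seq(cfg$grid[1L], cfg$grid[2L], by = cfg$grid[3L])
  clean <- band_sum(wl, cfg$band_centers_nm, cfg$band_sigmas_nm, amps)
  atten <- exp(-cfg$self_absorption_strength * chl_absorption(wl))
  distorted <- clean * atten + cfg$baseline_offset
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  y <- distorted
  if (cfg$noise_sd > 0) y <- y + rnorm(length(wl), sd = cfg$noise_sd)
  in_win <- function(lo, hi) wl >= lo & wl <= hi
  truth_ratio <- max(clean[in_win(710, 730)]) / max(clean[in_win(680, 690)])
  meta$state <- state
  list(spectrum = emission_spectrum(wl, y, meta = meta),
       truth = list(psi_over_psii = truth_ratio,
                    band_amplitudes = amps,
                    noise_free = distorted,
                    wavelength_nm = wl))
}

#' Generate a self-absorption dilution series
#'
#' Emulates the quartz-powder dilution protocol: at dilution `d` percent the
#' band amplitudes scale by `d/100` and the self-absorption strength is
#' `c100 * d/100` (re-absorption is proportional to chromophore
#' concentration). All members share a sample id and carry
#' `meta$dilution_percent`.
#'
#' @param cfg A [spectrum_gen_config()]; its `self_absorption_strength` is
#'   ignored in favour of `c100`.
#' @param dilutions Dilution percentages, most concentrated first (default
#'   `c(100, 50, 25)`).
#' @param c100 Self-absorption strength of the undiluted (100%) sample.
#' @param state Light-state label passed to [gen_spectrum()].
#' @param sample_id Shared sample id.
#' @return A [dilution_series()] of the generated spectra; each spectrum's
#'   truth is attached as attribute `truth` on the series.
#' @export
gen_dilution_series <- function(cfg, dilutions = c(100, 50, 25), c100 = 2,
                                state = "state1", sample_id = "synthetic") {
  stopifnot(inherits(cfg, "spectrum_gen_config"))
  out <- lapply(dilutions, function(d) {
    ci <- cfg
    ci$band_amplitudes <- cfg$band_amplitudes * d / 100
    ci$self_absorption_strength <- c100 * d / 100
    if (!is.null(cfg$seed)) ci$seed <- cfg$seed + as.integer(d)
    gen_spectrum(ci, state = state,
                 meta = list(sample_id = sample_id, dilution_percent = d))
  })
  ser <- dilution_series(lapply(out, `[[`, "spectrum"))
  attr(ser, "truth") <- lapply(out, `[[`, "truth")
  ser
}
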