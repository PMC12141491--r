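#' Maximum quantum yield of PSII, Fv/Fm
#'
#' `(Fm - F0) / Fm` from the minimal (`F0`) and maximal (`Fm`) fluorescence
#' of a dark-acclimated sample.
#'
#' @param F0 Dark minimal fluorescence, > 0.
#' @param Fm Dark maximal fluorescence, > 0.
#' @return Fv/Fm in `[0, 1)`.
#' @export
fv_over_fm <- function(F0, Fm) {
  if (any(Fm <= 0)) stop("Fm must be positive")
  if (any(F0 > Fm)) stop("F0 exceeds Fm")
  (Fm - F0) / Fm
}

#' Non-photochemical quenching
#'
#' `NPQ = Fm / Fm' - 1`. A light-acclimated pulse maximum `Fm'` above the
#' dark `Fm` yields a negative NPQ; this is returned as-is with a
#' `"negative_npq"` flag attribute rather than clipped, since it usually
#' signals an imperfect dark reference.
#'
#' @param Fm Dark maximal fluorescence.
#' @param Fm_prime Light-acclimated pulse maximum, > 0.
#' @return NPQ (vectorized); attribute `flag` is a logical vector marking
#'   negative values.
#' @export
npq <- function(Fm, Fm_prime) {
  if (any(Fm_prime <= 0)) stop("Fm' must be positive")
  out <- Fm / Fm_prime - 1
  attr(out, "flag") <- out < 0
  out
}

#' Light-acclimated minimal fluorescence F0'
#'
#' The standard estimate `F0' = F0 / (Fv/Fm + F0 / Fm')`. When `Fm' = Fm`
#' this reduces algebraically to `F0` (dark limit), and `F0' <= F0` whenever
#' `Fm' <= Fm`.
#'
#' @param F0 Dark minimal fluorescence.
#' @param FvFm Dark maximum PSII yield, see [fv_over_fm()].
#' @param Fm_prime Light-acclimated pulse maximum.
#' @return F0'.
#' @export
f0_prime <- function(F0, FvFm, Fm_prime) {
  den <- FvFm + F0 / Fm_prime
  if (any(den <= 0)) stop("nonpositive denominator in F0' estimate")
  F0 / den
}

#' Fraction of open PSII reaction centers, qL
#'
#' `qL = ((Fm' - F) / (Fm' - F0')) * (F0' / F)`. qL is 1 when the transient
#' fluorescence `F` equals `F0'` (all centers open, QA fully oxidized) and 0
#' when `F` equals `Fm'` (all centers closed, QA fully reduced). Values
#' outside `[0, 1]` arise from noisy level estimates; by default they are
#' returned raw with a flag, optionally clipped to the boundary.
#'
#' @param F Transient (steady-state) fluorescence in the light, > 0.
#' @param Fm_prime Pulse maximum, must exceed `F0_prime`.
#' @param F0_prime Light-acclimated minimal fluorescence, see [f0_prime()].
#' @param clip If `TRUE`, map out-of-range values to the nearest boundary
#'   (still flagged). Default `FALSE`.
#' @return qL (vectorized); attribute `flag` marks values outside `[0, 1]`
#'   before any clipping.
#' @export
ql <- function(F, Fm_prime, F0_prime, clip = FALSE) {
  if (any(Fm_prime <= F0_prime)) stop("Fm' must exceed F0'")
  if (any(F0_prime <= 0)) stop("F0' must be positive")
  if (any(F <= 0)) stop("F must be positive")
  out <- ((Fm_prime - F) / (Fm_prime - F0_prime)) * (F0_prime / F)
  bad <- out < 0 | out > 1
  if (clip) out <- pmin(pmax(out, 0), 1)
  attr(out, "flag") <- bad
  out
}

#' Relative electron transport rate
#'
#' `rETR = absorption_factor * PhiPSII * PPFD`, with `PhiPSII =
#' (Fm' - F)/Fm'` the effective PSII yield. The default absorption factor
#' 0.42 is the conventional plant-based estimate of the fraction of incident
#' photons absorbed by PSII and is deliberately a named, configurable
#' constant.
#'
#' @param phi_psii Effective PSII quantum yield in `[0, 1]`.
#' @param ppfd Photosynthetic photon flux density, umol m^-2 s^-1, >= 0.
#' @param absorption_factor Fraction of incident photons reaching PSII
#'   (default 0.42).
#' @return rETR in umol m^-2 s^-1 (vectorized).
#' @export
retr <- function(phi_psii, ppfd, absorption_factor = 0.42) {
  if (any(phi_psii < 0 | phi_psii > 1)) stop("phi_psii must be in [0, 1]")
  if (any(ppfd < 0)) stop("ppfd must be >= 0")
  absorption_factor * phi_psii * ppfd
}
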