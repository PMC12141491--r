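#' Fluorescence trace container
#'
#' A PAM fluorometer trace: time-stamped fluorescence with a saturating-pulse
#' channel and the actinic light schedule.
#'
#' @param time_s Strictly increasing time in seconds.
#' @param fluorescence Fluorescence (a.u.).
#' @param is_pulse Logical, TRUE while a saturating pulse is firing.
#' @param ppfd Actinic photon flux at each sample, >= 0.
#' @param light_label Character label of the light phase at each sample
#'   (conventionally one of `dark`, `low`, `PSII-red`, `PSI-far-red`,
#'   `actinic-step`).
#' @param meta Named list (sample id, species, ...).
#' @return A data frame of class `fluorescence_trace` with a `meta`
#'   attribute.
#' @export
fluorescence_trace <- function(time_s, fluorescence, is_pulse, ppfd,
                               light_label, meta = list()) {
  if (any(diff(time_s) <= 0)) stop("time must be strictly increasing")
  if (any(ppfd < 0)) stop("ppfd must be >= 0")
  df <- data.frame(time_s = as.numeric(time_s),
                   fluorescence = as.numeric(fluorescence),
                   is_pulse = as.logical(is_pulse),
                   ppfd = as.numeric(ppfd),
                   light_label = as.character(light_label),
                   stringsAsFactors = FALSE)
  attr(df, "meta") <- as.list(meta)
  class(df) <- c("fluorescence_trace", "data.frame")
  df
}

#' Extract per-pulse fluorescence levels from a trace
#'
#' For each saturating pulse (a maximal run of `is_pulse`), the steady-state
#' fluorescence `F` is the mean over `pre_window_s` immediately before pulse
#' onset (non-pulse samples only) and the pulse maximum `Fm'` is the maximum
#' over `peak_window_s` from onset. The first pulse fired in a `dark` segment
#' is the dark reference defining `F0` (its pre-pulse mean) and `Fm` (its
#' peak).
#'
#' @param trace A [fluorescence_trace()].
#' @param pre_window_s Pre-pulse averaging window in s (default 2).
#' @param peak_window_s Peak search window from pulse onset in s (default 1).
#' @return A data frame of class `pulse_record`: columns `time_s`, `F`,
#'   `Fm_prime`, `ppfd`, `light_label`, `is_dark_reference`, `flag_inverted`
#'   (peak below pre-pulse mean).
#' @export
extract_pulses <- function(trace, pre_window_s = 2, peak_window_s = 1) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  if (pre_window_s <= 0 || peak_window_s <= 0)
    stop("windows must be positive")
  p <- trace$is_pulse
  if (!any(p)) stop("trace contains no pulse annotations")
  onset <- which(p & !c(FALSE, p[-length(p)]))
  rec <- lapply(onset, function(i) {
    t0 <- trace$time_s[i]
    pre <- trace$time_s >= t0 - pre_window_s & trace$time_s < t0 & !p
    pk <- trace$time_s >= t0 & trace$time_s <= t0 + peak_window_s
    if (!any(pre))
      stop("no pre-pulse samples within pre_window_s of pulse at t=", t0)
    Fv <- mean(trace$fluorescence[pre])
    Fmv <- max(trace$fluorescence[pk])
    data.frame(time_s = t0, F = Fv, Fm_prime = Fmv,
               ppfd = trace$ppfd[i],
               light_label = trace$light_label[i],
               flag_inverted = Fmv < Fv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rec)
  dark <- which(out$light_label == "dark")
  if (!length(dark))
    stop("no dark reference: no pulse fired in a 'dark' segment")
  out$is_dark_reference <- seq_len(nrow(out)) == dark[1L]
  class(out) <- c("pulse_record", "data.frame")
  out
}

#' Photosynthetic parameter time series from a trace
#'
#' Applies the dark reference once (Fv/Fm from the first dark pulse), then
#' computes NPQ, F0', qL, effective PSII yield and rETR for every pulse,
#' keeping the light-phase labels for kinetic plots.
#'
#' @param trace A [fluorescence_trace()].
#' @param pre_window_s,peak_window_s See [extract_pulses()].
#' @param absorption_factor Passed to [retr()] (default 0.42).
#' @return A data frame of class `photo_params`: per pulse `time_s`, `ppfd`,
#'   `light_label`, `F`, `Fm_prime`, `F0_prime`, `npq`, `ql`, `phi_psii`,
#'   `retr`, plus flags `flag_npq` (negative NPQ) and `flag_ql` (qL outside
#'   `[0, 1]`). Attributes `F0`, `Fm`, `fv_fm` carry the dark reference.
#' @export
trace_timecourse <- function(trace, pre_window_s = 2, peak_window_s = 1,
                             absorption_factor = 0.42) {
  pr <- extract_pulses(trace, pre_window_s, peak_window_s)
  ref <- pr[pr$is_dark_reference, ]
  F0 <- ref$F
  Fm <- ref$Fm_prime
  fvfm <- fv_over_fm(F0, Fm)
  npq_v <- npq(Fm, pr$Fm_prime)
  f0p <- f0_prime(F0, fvfm, pr$Fm_prime)
  ql_v <- ql(pr$F, pr$Fm_prime, f0p)
  phi <- (pr$Fm_prime - pr$F) / pr$Fm_prime
  out <- data.frame(
    time_s = pr$time_s, ppfd = pr$ppfd, light_label = pr$light_label,
    F = pr$F, Fm_prime = pr$Fm_prime, F0_prime = f0p,
    npq = as.numeric(npq_v), ql = as.numeric(ql_v), phi_psii = phi,
    retr = retr(pmin(pmax(phi, 0), 1), pr$ppfd, absorption_factor),
    flag_npq = attr(npq_v, "flag"), flag_ql = attr(ql_v, "flag"),
    is_dark_reference = pr$is_dark_reference,
    stringsAsFactors = FALSE)
  attr(out, "F0") <- F0
  attr(out, "Fm") <- Fm
  attr(out, "fv_fm") <- fvfm
  class(out) <- c("photo_params", "data.frame")
  out
}

#' Assemble rapid light curves with group truncation
#'
#' Replicate rETR values measured on a shared ladder of actinic light steps
#' are combined into a group curve. Following the convention that a group
#' curve is only shown down to the light intensity where rETR was above zero
#' in all replicates, the group curve is truncated before the first PPFD step
#' at which any replicate's rETR is not positive; per-replicate curves are
#' kept in full.
#'
#' @param records Data frame with columns `replicate`, `ppfd`, `retr`; every
#'   replicate must contain the same strictly increasing PPFD ladder.
#' @return A list of class `light_curve_set`: `group` (data frame `ppfd`,
#'   `retr_mean`, `retr_sd`, truncated), `replicates` (the input, untouched),
#'   `truncation_ppfd` (last retained step, or `NA` if nothing retained),
#'   `truncated` (logical).
#' @export
build_light_curve <- function(records) {
  need <- c("replicate", "ppfd", "retr")
  if (!is.data.frame(records) || !all(need %in% names(records)) ||
      !nrow(records))
    stop("records must be a non-empty data frame with replicate, ppfd, retr")
  reps <- split(records, records$replicate)
  ladder <- sort(unique(reps[[1L]]$ppfd))
  if (any(duplicated(reps[[1L]]$ppfd)))
    stop("duplicate PPFD steps within a replicate")
  same <- vapply(reps, function(r) length(r$ppfd) == length(ladder) &&
                   all(sort(r$ppfd) == ladder), logical(1))
  if (!all(same)) stop("replicates were not measured on the same PPFD ladder")
  mat <- vapply(reps, function(r) r$retr[order(r$ppfd)],
                numeric(length(ladder)))
  mat <- matrix(mat, nrow = length(ladder))
  all_pos <- apply(mat > 0, 1L, all)
  first_bad <- which(!all_pos)
  keep <- if (length(first_bad)) seq_len(first_bad[1L] - 1L)
          else seq_along(ladder)
  group <- data.frame(ppfd = ladder[keep],
                      retr_mean = if (length(keep)) rowMeans(mat[keep, , drop = FALSE]) else numeric(),
                      retr_sd = if (length(keep)) apply(mat[keep, , drop = FALSE], 1L, sd) else numeric())
  structure(list(group = group, replicates = records,
                 truncation_ppfd = if (length(keep)) ladder[max(keep)] else NA_real_,
                 truncated = length(first_bad) > 0L),
            class = "light_curve_set")
}
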