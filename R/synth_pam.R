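#' Configuration for the synthetic PAM trace generator
#'
#' The generator inverts the saturating-pulse analysis formulas: given
#' requested time courses NPQ(t) and qL(t) it constructs the fluorescence
#' levels that an ideal fluorometer would record, so the analysis side can be
#' tested by exact round-trip. At each pulse time t:
#' `Fm'(t) = Fm / (1 + NPQ(t))`, `F0'(t) = F0 / (Fv/Fm + F0/Fm'(t))`, and
#' the steady-state `F(t)` is the unique solution in `(F0', Fm']` of the qL
#' definition: `F = Fm' F0' / (qL (Fm' - F0') + F0')`.
#'
#' @param F0 Dark minimal fluorescence (a.u.), > 0.
#' @param Fm Dark maximal fluorescence, > F0.
#' @param npq_course Function of time (s) returning NPQ(t) >= 0 (small
#'   negative values are tolerated with a warning flag).
#' @param ql_course Function of time (s) returning qL(t) in `[0, 1]`.
#' @param light_schedule Data frame `duration_s`, `ppfd`, `label`; the first
#'   segment must be labelled `dark` (it defines F0 and Fm).
#' @param pulse_interval_s Seconds between saturating pulses (default 30).
#' @param noise_sd Gaussian noise SD added to the finished trace.
#' @param sample_hz Sampling rate of the trace (default 1).
#' @param pulse_duration_s Width of each saturating pulse (default 1).
#' @param seed RNG seed.
#' @return A list of class `trace_gen_config`.
#' @export
trace_gen_config <- function(F0 = 400, Fm = 2000,
                             npq_course = function(t) rep(0, length(t)),
                             ql_course = function(t) rep(1, length(t)),
                             light_schedule = default_light_schedule(),
                             pulse_interval_s = 30,
                             noise_sd = 0,
                             sample_hz = 1,
                             pulse_duration_s = 1,
                             seed = NULL) {
  if (!(Fm > F0 && F0 > 0)) stop("need Fm > F0 > 0")
  if (pulse_interval_s <= 0) stop("pulse_interval_s must be > 0")
  ls <- as.data.frame(light_schedule)
  if (!all(c("duration_s", "ppfd", "label") %in% names(ls)))
    stop("light_schedule needs duration_s, ppfd, label")
  if (any(ls$duration_s <= 0)) stop("schedule durations must be > 0")
  if (ls$label[1L] != "dark")
    stop("the first schedule segment must be 'dark' (defines F0 and Fm)")
  structure(list(F0 = F0, Fm = Fm, npq_course = npq_course,
                 ql_course = ql_course, light_schedule = ls,
                 pulse_interval_s = pulse_interval_s, noise_sd = noise_sd,
                 sample_hz = sample_hz, pulse_duration_s = pulse_duration_s,
                 seed = seed),
            class = "trace_gen_config")
}

#' Default light schedule for synthetic PAM traces
#'
#' A dark reference segment followed by alternating PSII-specific red and
#' PSI-specific far-red phases at moderate intensity, the sequence used to
#' probe plastoquinone-pool redox kinetics.
#'
#' @param segment_s Duration of each light phase in seconds (default 900,
#'   i.e. 15 min).
#' @param dark_s Duration of the initial dark segment (default 120).
#' @param ppfd Photon flux of the colored phases (default 50).
#' @return A data frame `duration_s`, `ppfd`, `label`.
#' @export
default_light_schedule <- function(segment_s = 900, dark_s = 120, ppfd = 50) {
  data.frame(
    duration_s = c(dark_s, segment_s, segment_s, segment_s),
    ppfd = c(0, ppfd, ppfd, ppfd),
    label = c("dark", "PSII-red", "PSI-far-red", "PSII-red"),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic PAM trace with per-pulse ground truth
#'
#' See [trace_gen_config()] for the construction. The trace interleaves
#' steady-state samples `F(t)` with saturating-pulse peaks `Fm'(t)`; noise is
#' added after construction. During the initial dark segment NPQ and qL are
#' forced to their dark values (0 and 1), so the first pulse records exactly
#' `F0` and `Fm`.
#'
#' @param cfg A [trace_gen_config()].
#' @return A list: `trace` (a [fluorescence_trace()]) and `truth`, a data
#'   frame with one row per pulse: `time_s`, `npq`, `ql`, `F`, `Fm_prime`,
#'   `F0_prime`, `phi_psii`, `retr` (absorption factor 0.42), `ppfd`,
#'   `light_label`. The truth of a seeded config is reproducible
#'   bit-identically.
#' @export
gen_pam_trace <- function(cfg) {
  stopifnot(inherits(cfg, "trace_gen_config"))
  sched <- cfg$light_schedule
  t_end <- sum(sched$duration_s)
  dt <- 1 / cfg$sample_hz
  time <- seq(0, t_end - dt, by = dt)
  seg_end <- cumsum(sched$duration_s)
  seg_of <- findInterval(time, c(0, seg_end), rightmost.closed = TRUE)
  seg_of[seg_of > nrow(sched)] <- nrow(sched)
  ppfd <- sched$ppfd[seg_of]
  label <- sched$label[seg_of]
  dark_end <- seg_end[1L]

  pulse_times <- seq(cfg$pulse_interval_s, t_end - cfg$pulse_duration_s,
                     by = cfg$pulse_interval_s)
  fvfm <- (cfg$Fm - cfg$F0) / cfg$Fm

  level_at <- function(tt) {
    dark <- tt < dark_end
    npq_t <- ifelse(dark, 0, cfg$npq_course(tt))
    ql_t <- ifelse(dark, 1, cfg$ql_course(tt))
    if (any(ql_t < 0 | ql_t > 1))
      stop("ql_course must stay within [0, 1]")
    fmprime <- cfg$Fm / (1 + npq_t)
    f0prime <- cfg$F0 / (fvfm + cfg$F0 / fmprime)
    f <- fmprime * f0prime / (ql_t * (fmprime - f0prime) + f0prime)
    list(npq = npq_t, ql = ql_t, fmprime = fmprime, f0prime = f0prime, f = f)
  }

  # Steady-state fluorescence is held constant over each inter-pulse
  # interval at the level belonging to the *next* pulse, so the pre-pulse
  # window reads exactly the per-pulse ground truth.
  plev <- level_at(pulse_times)
  done <- findInterval(time, pulse_times + cfg$pulse_duration_s)
  nxt <- pmin(done + 1L, length(pulse_times))
  fluor <- plev$f[nxt]
  is_pulse <- rep(FALSE, length(time))
  for (k in seq_along(pulse_times)) {
    idx <- which(time >= pulse_times[k] &
                   time < pulse_times[k] + cfg$pulse_duration_s)
    fluor[idx] <- plev$fmprime[k]
    is_pulse[idx] <- TRUE
  }

  tl <- plev
  if (any(tl$npq < 0))
    warning("npq_course returned negative values; flagged in truth")
  phi <- (tl$fmprime - tl$f) / tl$fmprime
  pseg <- findInterval(pulse_times, c(0, seg_end), rightmost.closed = TRUE)
  pseg[pseg > nrow(sched)] <- nrow(sched)
  truth <- data.frame(
    time_s = pulse_times, npq = tl$npq, ql = tl$ql, F = tl$f,
    Fm_prime = tl$fmprime, F0_prime = tl$f0prime, phi_psii = phi,
    retr = 0.42 * phi * sched$ppfd[pseg],
    ppfd = sched$ppfd[pseg], light_label = sched$label[pseg],
    flag_npq = tl$npq < 0,
    stringsAsFactors = FALSE)

  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (cfg$noise_sd > 0)
    fluor <- fluor + rnorm(length(fluor), sd = cfg$noise_sd)

  list(trace = fluorescence_trace(time, fluor, is_pulse, ppfd, label,
                                  meta = list(F0 = cfg$F0, Fm = cfg$Fm)),
       truth = truth)
}
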