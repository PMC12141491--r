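test_that("Fv/Fm arithmetic and preconditions", {
  expect_equal(fv_over_fm(400, 2000), 0.8)
  expect_equal(fv_over_fm(1500, 1500), 0)
  expect_error(fv_over_fm(400, 0), "positive")
  expect_error(fv_over_fm(2100, 2000), "exceeds")
})

test_that("NPQ arithmetic, zero at Fm' = Fm, flagged when negative", {
  expect_equal(as.numeric(npq(2000, 2000)), 0)
  expect_equal(as.numeric(npq(3000, 1500)), 1)
  v <- npq(2000, 2500)
  expect_lt(as.numeric(v), 0)
  expect_true(attr(v, "flag"))
  expect_error(npq(2000, 0), "positive")
})

test_that("F0' reduces to F0 in the dark limit and shrinks with Fm'", {
  fvfm <- fv_over_fm(400, 2000)
  expect_equal(f0_prime(400, fvfm, 2000), 400, tolerance = 1e-12)
  expect_equal(f0_prime(400, 0.8, 1000), 400 / 1.2, tolerance = 1e-12)
  # limit Fm' -> 0+: F0' -> 0+
  small <- vapply(10^-(1:6), function(e) f0_prime(400, 0.8, e), numeric(1))
  expect_true(all(diff(small) < 0))
  expect_lt(small[6], 1e-3)
  expect_error(f0_prime(400, -0.5, 1000), "denominator")
})

test_that("qL hits its boundary identities machine-exactly and matches hand
           arithmetic in between", {
  f0p <- f0_prime(400, 0.8, 1000)
  expect_identical(as.numeric(ql(f0p, 1000, f0p)), 1)
  expect_identical(as.numeric(ql(1000, 1000, f0p)), 0)
  expect_equal(as.numeric(ql(600, 1000, f0p)),
               ((1000 - 600) / (1000 - f0p)) * (f0p / 600),
               tolerance = 1e-12)
  expect_equal(as.numeric(ql(600, 1000, f0p)), 1 / 3, tolerance = 1e-9)
  out <- ql(150, 1000, 400 / 1.2)          # F below F0' -> qL > 1, flagged
  expect_true(attr(out, "flag"))
  expect_gt(as.numeric(out), 1)
  expect_error(ql(600, 300, 400), "exceed")
})

test_that("qL decreases in F and NPQ decreases in Fm'", {
  f0p <- 300
  fs <- seq(310, 990, by = 20)
  qls <- as.numeric(ql(fs, 1000, f0p))
  expect_true(all(diff(qls) < 0))
  fmps <- seq(500, 2000, by = 100)
  npqs <- as.numeric(npq(2000, fmps))
  expect_true(all(diff(npqs) < 0))
})

test_that("rETR is the absorption factor times yield times PPFD", {
  expect_equal(retr(0, 500), 0)
  expect_equal(retr(1, 1), 0.42)
  expect_equal(retr(0.5, 100), 21)
  expect_equal(retr(1, 1, absorption_factor = 0.5), 0.5)
  expect_error(retr(1.2, 10), "\\[0, 1\\]")
  expect_error(retr(0.5, -1), ">= 0")
})

test_that("pulses are extracted from a hand-built square waveform", {
  # 0..19 s steady 400; pulse at 10 s (2 s wide, 1800); second segment
  # steady 500 with pulse at 30 s peaking 1500
  tm <- 0:39
  f <- c(rep(400, 10), 1800, 1800, rep(400, 8),
         rep(500, 10), 1500, 1500, rep(500, 8))
  pulse <- tm %in% c(10, 11, 30, 31)
  lab <- rep(c("dark", "PSII-red"), each = 20)
  tr <- fluorescence_trace(tm, f, pulse, rep(c(0, 50), each = 20), lab)
  pr <- extract_pulses(tr, pre_window_s = 2, peak_window_s = 2)
  expect_equal(nrow(pr), 2)
  expect_equal(pr$F, c(400, 500))
  expect_equal(pr$Fm_prime, c(1800, 1500))
  expect_true(pr$is_dark_reference[1])
  expect_false(pr$is_dark_reference[2])
})

test_that("a trace without a dark segment has no reference and errors", {
  tm <- 0:19
  f <- c(rep(500, 10), 1500, 1500, rep(500, 8))
  tr <- fluorescence_trace(tm, f, tm %in% c(10, 11),
                           rep(50, 20), rep("PSII-red", 20))
  expect_error(extract_pulses(tr), "no dark reference")
})

test_that("an inverted pulse is flagged, not dropped", {
  tm <- 0:19
  f <- c(rep(400, 5), 1800, rep(400, 8), 300, 300, rep(400, 4))
  tr <- fluorescence_trace(tm, f, tm %in% c(5, 14, 15), rep(0, 20),
                           rep("dark", 20))
  pr <- extract_pulses(tr, pre_window_s = 2, peak_window_s = 1)
  expect_equal(nrow(pr), 2)
  expect_true(pr$flag_inverted[2])
})

test_that("noise-free timecourse recovers the generator courses exactly", {
  cfg <- trace_gen_config(
    F0 = 400, Fm = 2000,
    npq_course = function(t) 1.5 * (1 - exp(-(t - 120) / 200)),
    ql_course = function(t) 0.3 + 0.6 * exp(-(t - 120) / 300),
    light_schedule = data.frame(duration_s = c(120, 600), ppfd = c(0, 50),
                                label = c("dark", "PSII-red")),
    pulse_interval_s = 30)
  g <- gen_pam_trace(cfg)
  tt <- trace_timecourse(g$trace)
  expect_equal(tt$npq, g$truth$npq, tolerance = 1e-9)
  expect_equal(tt$ql, g$truth$ql, tolerance = 1e-9)
  expect_equal(tt$retr, g$truth$retr, tolerance = 1e-9)
  expect_equal(attr(tt, "fv_fm"), 0.8, tolerance = 1e-12)
})

test_that("constant-fluorescence pulses give qL = 0 via F = Fm'", {
  tm <- 0:29
  f <- c(rep(400, 10), 1800, rep(400, 9), rep(700, 5), 700, rep(700, 4))
  pulse <- tm %in% c(10, 25)
  tr <- fluorescence_trace(tm, f, pulse, rep(c(0, 50), each = 20)[1:30],
                           c(rep("dark", 20), rep("PSII-red", 10)))
  tt <- trace_timecourse(tr)
  expect_equal(tt$ql[2], 0)
})

test_that("with noise the mean absolute qL error stays within its
           Monte-Carlo bound over 50 pulses", {
  cfg <- trace_gen_config(
    F0 = 400, Fm = 2000,
    npq_course = function(t) rep(0.5, length(t)),
    ql_course = function(t) rep(0.6, length(t)),
    light_schedule = data.frame(duration_s = c(120, 1600), ppfd = c(0, 50),
                                label = c("dark", "PSII-red")),
    pulse_interval_s = 30, noise_sd = 5, seed = 19)
  g <- gen_pam_trace(cfg)
  tt <- trace_timecourse(g$trace)
  sel <- tt$light_label == "PSII-red"
  expect_gte(sum(sel), 50)
  err <- tt$ql[sel] - g$truth$ql[g$truth$light_label == "PSII-red"]
  se <- sqrt(var(err) / length(err) + (3 * 5 / 1333)^2)
  expect_lt(abs(mean(err)), 3 * se)
  expect_lt(mean(abs(err)), 0.05)
})

test_that("light curves truncate where any replicate's rETR hits zero", {
  ladder <- seq(25, 225, by = 25)             # 9 steps
  mk <- function(rep_id, retr) data.frame(replicate = rep_id, ppfd = ladder,
                                          retr = retr)
  ok <- rbind(mk("r1", seq(5, 45, by = 5)), mk("r2", seq(4, 44, by = 5)))
  lc <- build_light_curve(ok)
  expect_false(lc$truncated)
  expect_equal(nrow(lc$group), 9)

  r3 <- seq(5, 45, by = 5); r3[7] <- 0
  tr <- build_light_curve(rbind(ok, mk("r3", r3)))
  expect_true(tr$truncated)
  expect_equal(nrow(tr$group), 6)
  expect_equal(tr$truncation_ppfd, ladder[6])
  expect_equal(nrow(tr$replicates), 27)        # per-replicate data untouched

  expect_error(build_light_curve(data.frame()), "non-empty")
  bad <- rbind(mk("r1", seq(5, 45, by = 5)),
               data.frame(replicate = "r2", ppfd = ladder + 1,
                          retr = seq(5, 45, by = 5)))
  expect_error(build_light_curve(bad), "same PPFD ladder")
})
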