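# fluoroplast

Phenotyping of photosynthetic light acclimation and chloroplast morphology
in green algae and kleptoplastic sea slugs, from three standard assays:

* **77 K chlorophyll fluorescence spectra** — state transitions (the
  migration of mobile LHCII antenna between the photosystems) are read out
  as the *normalized PSI fluorescence*: after smoothing (4 nm running
  average), 800 nm baseline subtraction and normalization to the PSII peak
  on 680–690 nm, the statistic is the spectrum maximum on 710–730 nm.
  Dilution-series QC guards against self-absorption in concentrated
  samples.
* **PAM saturating-pulse fluorometry** — the standard parameters per
  pulse: `Fv/Fm = (Fm−F0)/Fm`, `ΦPSII = (Fm′−F)/Fm′`,
  `NPQ = Fm/Fm′ − 1`, `F0′ = F0/(Fv/Fm + F0/Fm′)`,
  `qL = ((Fm′−F)/(Fm′−F0′))·(F0′/F)`, and
  `rETR = 0.42·ΦPSII·PPFD`, plus rapid light curves with the
  all-replicates-positive truncation rule.
* **Chloroplast shape from fluorescence micrographs** — classical
  segmentation (threshold + distance-transform watershed), per-object area
  and sub-pixel perimeter, circularity `4π·Area/Perimeter²` (1 = perfect
  circle), and per-replicate median aggregation.

Treatment groups are compared through a gated decision tree
(Shapiro–Wilk + Levene → Student's *t* / one-way ANOVA + Tukey, otherwise
Kruskal–Wallis + Dunn with Holm adjustment), the replicate being the unit
of analysis.

A first-class synthetic-data module (`gen_spectrum()`, `gen_pam_trace()`,
`gen_chloroplast_image()`) generates all three data types with analytic
ground truth — Gaussian emission bands with optional self-absorption
distortion, pulse trains built by inverting the parameter formulas, and
ellipse fields with exact Ramanujan-perimeter circularities — so the whole
pipeline is testable offline.

## Worked example

Detect a state-1 → state-2 transition from synthetic spectra (PSI band
amplitude doubled in state 2, 5% noise, five replicates per light
treatment):

```r
library(fluoroplast)

psi <- function(cfg, state)
  psi_statistic(process_spectrum(gen_spectrum(cfg, state)$spectrum))$value
red     <- sapply(1:5, function(i)
  psi(spectrum_gen_config(noise_sd = 50, seed = 600 + i), "state2"))
far_red <- sapply(1:5, function(i)
  psi(spectrum_gen_config(noise_sd = 50, seed = 500 + i), "state1"))
round(far_red, 3)
#> [1] 0.489 0.479 0.525 0.495 0.475
round(red, 3)
#> [1] 0.959 0.950 0.974 0.990 0.940
compare_states(red, far_red, names = c("red", "far-red"))
#> <group_comparison> parametric branch: Student t
#>   statistic = 37.72, p = 2.678e-10 (significant at alpha = 0.05)
```

The red-light (PSII-favoring) treatment roughly doubles the normalized PSI
fluorescence — antenna has migrated to PSI (state 2) — and the gated test
declares the difference significant.

PAM kinetics from a synthetic trace (dark reference then red light; NPQ
rises, qL falls as the plastoquinone pool reduces):

```r
tc <- trace_gen_config(
  npq_course = function(t) 0.8 * (1 - exp(-(t - 120) / 300)),
  ql_course  = function(t) 0.35 + 0.5 * exp(-(t - 120) / 400),
  light_schedule = data.frame(duration_s = c(120, 600), ppfd = c(0, 50),
                              label = c("dark", "PSII-red")),
  pulse_interval_s = 60)
tt <- trace_timecourse(gen_pam_trace(tc)$trace)
head(tt[, c("time_s", "light_label", "npq", "ql", "retr")], 5)
#>  time_s light_label   npq    ql   retr
#>      60        dark 0.000 1.000  0.000
#>     120    PSII-red 0.000 0.850 16.227
#>     180    PSII-red 0.145 0.780 15.364
#>     240    PSII-red 0.264 0.720 14.598
#>     300    PSII-red 0.361 0.669 13.919
```

Shape recovery on a generated scene of 20 ellipses (axis ratio 1.4):

```r
sc <- gen_chloroplast_image(image_gen_config(n_objects = 20,
                                             axis_ratio = 1.4, seed = 11))
mo <- measure_objects(segment_objects(sc$image), sc$pixel_size_um)
median(mo$circularity)            # 0.962, measured through the pipeline
median(sc$truth$circularity)      # 0.959, analytic ground truth
ellipse_circularity(2, 1)         # 0.841, the 2:1 reference value
```

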