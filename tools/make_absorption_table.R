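# Regenerates inst/extdata/chl_absorption_synthetic.csv: a synthetic
# chlorophyll-like red absorption profile (main band at 678 nm, sigma 11 nm,
# plus a vibronic shoulder) used by the self-absorption model of the
# spectrum generator. Values are relative absorbance, max-normalized.
wl <- seq(640, 810, by = 2)
a <- exp(-(wl - 678)^2 / (2 * 11^2)) + 0.35 * exp(-(wl - 628)^2 / (2 * 16^2))
a <- a / max(a)
write.csv(data.frame(wavelength_nm = wl, absorbance_rel = round(a, 6)),
          file.path("inst", "extdata", "chl_absorption_synthetic.csv"),
          row.names = FALSE)
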