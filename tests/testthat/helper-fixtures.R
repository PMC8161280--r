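# shared fixture builders (all fixtures are generated in code)

flat_spectrum <- function(value = 0, axis = default_axis())
  ev_spectrum(axis, rep(value, length(axis)))

ramp_spectrum <- function(axis = default_axis(), slope = 1, intercept = 0)
  ev_spectrum(axis, intercept + slope * axis)

# minimal JCAMP-DX writer used only as a test fixture (the package reader
# is read-only by design)
write_jcamp_fixture <- function(spec, path, yfactor = 1) {
  w <- spec$wavenumber
  y <- round(spec$intensity / yfactor)
  n <- length(w)
  lines <- c("##TITLE=fixture", "##JCAMP-DX=4.24", "##DATA TYPE=RAMAN SPECTRUM",
             "##XUNITS=1/CM", "##YUNITS=ARBITRARY UNITS",
             sprintf("##FIRSTX=%g", w[1]), sprintf("##LASTX=%g", w[n]),
             sprintf("##NPOINTS=%d", n), sprintf("##YFACTOR=%g", yfactor),
             "##XYDATA=(X++(Y..Y))")
  per_line <- 6
  i <- 1
  while (i <= n) {
    j <- min(i + per_line - 1, n)
    lines <- c(lines, paste(c(sprintf("%g", w[i]), sprintf("%g", y[i:j])),
                            collapse = " "))
    i <- j + 1
  }
  writeLines(c(lines, "##END="), path)
  invisible(path)
}

# preprocessed group summary of one synthetic cell
preprocessed_cell <- function(modality, fraction, group, seeds,
                              axis = default_axis(),
                              noise_sigma = NULL, jitter_sd = NULL) {
  prof <- spectrum_profile(modality, fraction, group)
  cfg <- if (modality == "SERS") preprocess_config(norm_mode = "none")
    else preprocess_config(norm_mode = "ch_1448")
  average_spectra(lapply(seeds, function(s)
    preprocess_spectrum(simulate_spectrum(prof, axis, seed = s,
                                          noise_sigma = noise_sigma,
                                          jitter_sd = jitter_sd),
                        cfg)))
}

noiseless_diff <- function(modality, fraction) {
  a <- preprocessed_cell(modality, fraction, "POOL_A", seeds = 1,
                         noise_sigma = 0, jitter_sd = 0)
  b <- preprocessed_cell(modality, fraction, "CONTROL", seeds = 1,
                         noise_sigma = 0, jitter_sd = 0)
  difference_spectrum(a, b)
}
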