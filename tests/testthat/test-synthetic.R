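test_that("pseudo-Voigt profiles honor height, FWHM and shape limits", {
  ax <- seq(900, 1100, by = 0.5)
  for (eta in c(0, 0.3, 0.7, 1)) {
    y <- pseudo_voigt(ax, 1000, 12.5, 14, eta)
    expect_equal(y[ax == 1000], 12.5)
    # half maximum at center +/- FWHM/2 for every eta (both components
    # share the FWHM)
    expect_equal(y[ax == 1007], 6.25, tolerance = 1e-9)
    expect_equal(y[ax == 993], 6.25, tolerance = 1e-9)
  }
  # eta = 1 matches the textbook Lorentzian pointwise
  lor <- 10 * (14 / 2)^2 / ((ax - 1000)^2 + (14 / 2)^2)
  expect_equal(pseudo_voigt(ax, 1000, 10, 14, 1), lor)
  # eta = 0 matches the Gaussian
  gau <- 10 * exp(-4 * log(2) * (ax - 1000)^2 / 14^2)
  expect_equal(pseudo_voigt(ax, 1000, 10, 14, 0), gau)
  expect_error(pseudo_voigt(ax, 1000, -1), ">= 0")
  expect_error(pseudo_voigt(ax, 1000, 1, 0), "> 0")
  expect_error(pseudo_voigt(ax, 1000, 1, 14, 2), "\\[0, 1\\]")
})

test_that("simulated spectra are seeded and reduce to the closed form", {
  ax <- default_axis()
  prof <- spectrum_profile("SERS", "EV12", "POOL_A")
  s1 <- simulate_spectrum(prof, ax, seed = 42)
  s2 <- simulate_spectrum(prof, ax, seed = 42)
  expect_identical(s1$intensity, s2$intensity)
  expect_false(identical(s1$intensity,
                         simulate_spectrum(prof, ax, seed = 43)$intensity))
  clean <- simulate_spectrum(prof, ax, noise_sigma = 0, jitter_sd = 0)
  expect_equal(clean$intensity, profile_intensity(prof, ax))
  expect_equal(clean$meta$fraction, "EV12")
  # baseline-only profile: pure closed-form background
  flat_prof <- prof
  flat_prof$bands <- flat_prof$bands[0, ]
  flat_clean <- simulate_spectrum(flat_prof, ax, noise_sigma = 0,
                                  jitter_sd = 0)
  expect_equal(flat_clean$intensity,
               prof$baseline$offset + prof$baseline$exp_amplitude *
                 exp(-(ax - 300) / prof$baseline$exp_scale))
})

test_that("noiseless cancer-control profile differences have the marker signs", {
  ax <- default_axis()
  cancer <- profile_intensity(spectrum_profile("SERS", "EV12", "POOL_A"), ax)
  control <- profile_intensity(spectrum_profile("SERS", "EV12", "CONTROL"), ax)
  d <- cancer - control
  for (ctr in builtin_band_panel("cancer_sers_positive")$center)
    expect_gt(d[which.min(abs(ax - ctr))], 0)
  for (ctr in c(477, 656))
    expect_lt(d[which.min(abs(ax - ctr))], 0)
})

test_that("profile band sets are consistent with the marker panels", {
  near_band <- function(prof, center, tol = 6)
    any(abs(prof$bands$center - center) <= tol)
  for (fr in c("EV5", "EV12", "EV120")) {
    cancer <- spectrum_profile("SERS", fr, "POOL_A")
    for (ctr in builtin_band_panel("cancer_sers_positive")$center)
      expect_true(near_band(cancer, ctr),
                  label = sprintf("cancer %s band near %g", fr, ctr))
    control <- spectrum_profile("SERS", fr, "CONTROL")
    for (ctr in builtin_band_panel("control_sers_negative")$center)
      expect_true(near_band(control, ctr),
                  label = sprintf("control band near %g", ctr))
    raman <- spectrum_profile("RAMAN", fr, "POOL_B")
    for (ctr in builtin_band_panel("raman_diff")$center)
      expect_true(near_band(raman, ctr),
                  label = sprintf("raman band near %g", ctr))
  }
})

test_that("simulated maps scale signal by the film mask", {
  prof <- spectrum_profile("SERS", "EV12", "POOL_A")
  # mask covering every pixel: homogeneous up to noise
  m_all <- simulate_map(prof, 4, 4, mask_radius = 100, seed = 2,
                        noise_sigma = 0)
  ints <- vapply(m_all$spectra, function(s) s$intensity[200], numeric(1))
  expect_lt(diff(range(ints)), 1e-9)
  expect_true(all(attr(m_all, "inside")))
  # noiseless map: top-|inside| selection recovers exactly the film pixels
  m <- simulate_map(prof, 8, 8, seed = 3, noise_sigma = 0)
  inside <- attr(m, "inside")
  expect_true(any(inside) && !all(inside))
  sel <- select_top(m, k = sum(inside))
  key <- function(specs) sort(vapply(specs, function(s)
    paste(s$meta$position, collapse = ","), character(1)))
  expect_equal(key(sel), key(m$spectra[inside]))
  # seeded determinism
  m2 <- simulate_map(prof, 8, 8, seed = 3, noise_sigma = 0)
  expect_identical(m$spectra[[10]]$intensity, m2$spectra[[10]]$intensity)
  expect_error(simulate_map(prof, 1, 4), "2x2")
})

test_that("cohorts enumerate every cell deterministically", {
  cfg <- cohort_config(n_replicates = 1, seed = 7,
                       axis = default_axis(1000, 1200, 2))
  co <- simulate_cohort(cfg)
  # 4 fractions x 3 groups x 2 modalities x 1 replicate
  expect_equal(length(co$spectra), 24)
  expect_equal(nrow(co$manifest), 24)
  expect_equal(nrow(unique(co$manifest[c("modality", "fraction", "group")])),
               24)
  co2 <- simulate_cohort(cfg)
  expect_identical(co$manifest, co2$manifest)
  for (i in seq_along(co$spectra))
    expect_identical(co$spectra[[i]]$intensity, co2$spectra[[i]]$intensity)
  expect_equal(nrow(co$metrics), 12)
  # manifest metadata matches the spectra
  i <- sample(seq_len(24), 1)
  expect_equal(co$spectra[[i]]$meta$fraction, co$manifest$fraction[i])
  expect_equal(co$spectra[[i]]$meta$group, co$manifest$group[i])
})

test_that("FC fractions carry no cancer-marker signal", {
  # noiseless: the cancer-panel score of the FC difference is ~ 0
  d0 <- noiseless_diff("SERS", "FC")
  panel <- builtin_band_panel("cancer_sers_positive")
  expect_lt(abs(positive_difference_score(d0, panel)), 60)
  # at default noise, |score| stays within 3 propagated noise SDs
  ok <- vapply(1:10, function(r) {
    ca <- preprocessed_cell("SERS", "FC", "POOL_A", seeds = r * 100 + 1:5)
    co <- preprocessed_cell("SERS", "FC", "CONTROL", seeds = r * 100 + 11:15)
    d <- difference_spectrum(ca, co)
    sigma <- attr(call_band_signs(d, builtin_band_panel("sers_diff")),
                  "noise_sigma")
    abs(positive_difference_score(d, panel)) <
      3 * score_noise_sd(d$wavenumber, panel, sigma)
  }, logical(1))
  expect_gte(sum(ok), 9)
})
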