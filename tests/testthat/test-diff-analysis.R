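test_that("difference spectra subtract control from cancer on a shared axis", {
  ax <- default_axis()
  base <- ev_spectrum(ax, 10 + pseudo_voigt(ax, 1450, 5))
  gs <- function(s) group_summary(s, flat_spectrum(0, ax), 3)
  expect_true(all(difference_spectrum(gs(base), gs(base))$intensity == 0))
  bump <- ev_spectrum(ax, base$intensity + pseudo_voigt(ax, 1393, 4, 12, 0))
  d <- difference_spectrum(gs(bump), gs(base))
  expect_lt(max(abs(d$intensity - pseudo_voigt(ax, 1393, 4, 12, 0))), 1e-9)
  # antisymmetry under group swap
  d2 <- difference_spectrum(gs(base), gs(bump))
  expect_equal(d2$intensity, -d$intensity)
})

test_that("chord-baselined band integration matches closed forms", {
  ax <- seq(1300, 1500, by = 1)
  expect_equal(integrate_band(flat_spectrum(7, ax), 1400, 10), 0)
  # linear ramp: the chord equals the spectrum
  expect_equal(integrate_band(ramp_spectrum(ax, 0.3, -5), 1400, 10), 0,
               tolerance = 1e-9)
  # triangular peak height 10 over a 20 cm-1 window with zero endpoints
  tri <- ev_spectrum(ax, pmax(0, 10 - abs(ax - 1400)))
  expect_equal(integrate_band(tri, 1400, 10), 100)
  expect_error(integrate_band(tri, 1300, 10), "beyond")
  # linearity and invariance to a global linear function
  set.seed(3)
  y1 <- rnorm(length(ax)); y2 <- rnorm(length(ax))
  a1 <- integrate_band(ev_spectrum(ax, y1), 1400, 10)
  a2 <- integrate_band(ev_spectrum(ax, y2), 1400, 10)
  expect_equal(integrate_band(ev_spectrum(ax, y1 + y2), 1400, 10), a1 + a2)
  lin <- 3 + 0.2 * ax
  expect_equal(integrate_band(ev_spectrum(ax, y1 + lin), 1400, 10), a1,
               tolerance = 1e-9)
})

test_that("band ratios compare window-maximum heights", {
  # half-integer axis so both band centers sit on grid points
  ax <- default_axis(step = 0.5)
  equal_peaks <- ev_spectrum(ax, pseudo_voigt(ax, 1393, 5) +
                               pseudo_voigt(ax, 1450, 5))
  expect_equal(band_ratio(equal_peaks), 1, tolerance = 0.02)
  double <- ev_spectrum(ax, pseudo_voigt(ax, 1393, 10, 12, 0) +
                          pseudo_voigt(ax, 1450, 5, 12, 0))
  expect_equal(band_ratio(double), 2, tolerance = 0.02)
  expect_error(band_ratio(flat_spectrum(0, ax)), "non-positive")
})

test_that("sign calls are thresholded, antisymmetric and band-specific", {
  ax <- default_axis()
  panel <- builtin_band_panel("sers_diff")
  zero <- flat_spectrum(0, ax)
  expect_true(all(call_band_signs(zero, panel)$sign_call == "NEUTRAL"))
  # a single seeded band at 713, 10x the noise level
  set.seed(21)
  d <- ev_spectrum(ax, pseudo_voigt(ax, 713, 20, 12, 0) +
                     rnorm(length(ax), 0, 2))
  calls <- call_band_signs(d, panel)
  expect_equal(calls$sign_call[calls$center == 713], "POSITIVE")
  expect_true(all(calls$sign_call[calls$center != 713] == "NEUTRAL"))
  # negation flips every non-neutral call
  neg <- ev_spectrum(ax, -d$intensity)
  flipped <- call_band_signs(neg, panel)
  expect_equal(flipped$sign_call[calls$sign_call == "POSITIVE"], "NEGATIVE")
  expect_equal(flipped$area, -calls$area)
  expect_error(call_band_signs(d, panel, noise_regions = list(c(700, 720))),
               "overlaps")
})

test_that("noiseless synthetic cohorts reproduce the published sign tables", {
  for (fr in c("EV5", "EV12", "EV120")) {
    sers <- call_band_signs(noiseless_diff("SERS", fr),
                            builtin_band_panel("sers_diff"))
    expect_equal(sers$sign_call, sers$expected_sign,
                 label = paste("SERS signs for", fr))
    expect_equal(sum(sers$sign_call == "POSITIVE"), 11)
    expect_equal(sum(sers$sign_call == "NEGATIVE"), 2)
    raman <- call_band_signs(noiseless_diff("RAMAN", fr),
                             builtin_band_panel("raman_diff"))
    expect_equal(raman$sign_call, raman$expected_sign,
                 label = paste("Raman signs for", fr))
  }
})

test_that("positive-difference scores are additive and zero on null input", {
  ax <- default_axis()
  panel <- builtin_band_panel("cancer_sers_positive")
  expect_equal(positive_difference_score(flat_spectrum(0, ax), panel), 0)
  set.seed(8)
  y1 <- rnorm(length(ax)); y2 <- rnorm(length(ax))
  s1 <- positive_difference_score(ev_spectrum(ax, y1), panel)
  s2 <- positive_difference_score(ev_spectrum(ax, y2), panel)
  s12 <- positive_difference_score(ev_spectrum(ax, y1 + y2), panel)
  expect_equal(s12, s1 + s2, tolerance = 1e-9)
})

test_that("score noise propagation matches a Monte-Carlo estimate", {
  ax <- default_axis()
  panel <- builtin_band_panel("cancer_sers_positive")
  sigma <- 2.5
  predicted <- score_noise_sd(ax, panel, sigma)
  set.seed(31)
  draws <- replicate(400, positive_difference_score(
    ev_spectrum(ax, rnorm(length(ax), 0, sigma)), panel))
  expect_lt(abs(sd(draws) / predicted - 1), 0.15)
})

test_that("diff reports bundle the fraction readouts", {
  cancer <- preprocessed_cell("SERS", "EV12", "POOL_A", seeds = 1:5)
  control <- preprocessed_cell("SERS", "EV12", "CONTROL", seeds = 11:15)
  rep <- diff_report(cancer, control, fraction = "EV12")
  expect_s3_class(rep, "diff_report")
  expect_equal(rep$fraction, "EV12")
  expect_gt(rep$positive_score, 0)
  expect_gt(rep$ratio_1393_1450, 2)
  expect_gt(rep$noise_sigma, 0)
  pos_sum <- sum(rep$band_integrals$area[
    rep$band_integrals$expected_sign == "POSITIVE"])
  expect_equal(rep$positive_score, pos_sum, tolerance = 1e-9)
  expect_output(print(rep), "positive-marker score")
})
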