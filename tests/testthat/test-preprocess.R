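test_that("Savitzky-Golay smoothing preserves low-order polynomials and cuts noise", {
  ax <- default_axis()
  # degree <= polyorder is reproduced exactly at interior points
  poly <- ev_spectrum(ax, 2 + 0.01 * ax + 1e-5 * ax^2 - 1e-9 * ax^3)
  sm <- smooth_savgol(poly, 11, 3)
  interior <- 6:(length(ax) - 5)
  expect_lt(max(abs(sm$intensity[interior] - poly$intensity[interior])),
            1e-6 * max(abs(poly$intensity)))
  const <- flat_spectrum(5, ax)
  expect_equal(smooth_savgol(const, 11, 3)$intensity, const$intensity,
               tolerance = 1e-10)
  # variance reduction on white noise, 100 seeded draws
  reduced <- vapply(1:100, function(i) {
    set.seed(i)
    y <- rnorm(length(ax))
    var(smooth_savgol(ev_spectrum(ax, y), 11, 3)$intensity) < var(y)
  }, logical(1))
  expect_true(all(reduced))
  expect_error(smooth_savgol(const, 10, 3), "odd")
  expect_error(smooth_savgol(ev_spectrum(1:5, 1:5), 7, 3), "length")
  expect_error(smooth_savgol(const, 11, 11), "polyorder")
})

test_that("ALS baseline handles flat, ramp and peak-on-background inputs", {
  ax <- default_axis()
  flat <- flat_spectrum(0, ax)
  res <- baseline_als(flat)
  expect_lt(max(abs(res$baseline$intensity)), 1e-6)
  expect_lt(max(abs(res$corrected$intensity)), 1e-6)
  # corrected = spec - baseline pointwise, always
  set.seed(2)
  s <- ev_spectrum(ax, 100 + rnorm(length(ax)))
  r2 <- baseline_als(s)
  expect_equal(r2$corrected$intensity,
               s$intensity - r2$baseline$intensity)
  # peak-free linear ramp is absorbed into the baseline
  ramp <- ramp_spectrum(ax, slope = 0.5, intercept = 10)
  rr <- baseline_als(ramp, 1e5, 0.01)
  amp <- diff(range(ramp$intensity))
  expect_lt(max(abs(rr$corrected$intensity)), 0.01 * amp)
  # single peak on the generator's exponential background: area within 5%
  peak <- pseudo_voigt(ax, 1004, 100, 12, 0.7)
  bg <- 30 + 300 * exp(-(ax - 300) / 350)
  corr <- baseline_als(ev_spectrum(ax, peak + bg))$corrected
  win <- ax >= 974 & ax <= 1034
  tz <- function(y) sum(diff(ax[win]) * (head(y[win], -1) + tail(y[win], -1)) / 2)
  expect_lt(abs(tz(corr$intensity) / tz(peak) - 1), 0.05)
  expect_error(baseline_als(ev_spectrum(1:5, 1:5)), "at least 10")
  expect_error(baseline_als(flat, p = 1.5), "in \\(0, 1\\)")
})

test_that("ALS solution solves the converged penalized least-squares system", {
  # direct dense solve oracle at the returned weights, random instances
  for (i in 1:20) {
    set.seed(i)
    n <- 120
    w_ax <- seq(400, 400 + 2 * (n - 1), by = 2)
    y <- 50 * exp(-(w_ax - 400) / 300) +
      pseudo_voigt(w_ax, sample(450:550, 1), runif(1, 20, 80), 14, 0.7) +
      rnorm(n, 0, 1)
    lam <- 10^runif(1, 4, 6)
    res <- baseline_als(ev_spectrum(w_ax, y), lam, 0.01, iters = 50)
    wts <- attr(res$baseline, "weights")
    D <- diff(diag(n), differences = 2)
    z_direct <- solve(diag(wts) + lam * crossprod(D), wts * y)
    expect_lt(max(abs(z_direct - res$baseline$intensity)), 1e-6)
  }
})

test_that("band normalization is idempotent, scale-invariant and exact", {
  ax <- default_axis()
  s <- ev_spectrum(ax, 1 + pseudo_voigt(ax, 1660, 10) +
                     pseudo_voigt(ax, 1450, 6))
  n1 <- normalize_to_band(s, 1660, 15)
  win <- ax >= 1645 & ax <= 1675
  expect_equal(max(n1$intensity[win]), 1)
  # idempotent and scale invariant
  expect_equal(normalize_to_band(n1, 1660, 15)$intensity, n1$intensity)
  scaled <- ev_spectrum(ax, 7.3 * s$intensity)
  expect_equal(normalize_to_band(scaled, 1660, 15)$intensity, n1$intensity)
  # hand computation: peaks 2 @ 1660 and 3 @ 1450, CH normalization
  two <- ev_spectrum(ax, pseudo_voigt(ax, 1660, 2) + pseudo_voigt(ax, 1450, 3))
  ch <- normalize_to_band(two, 1448, 15)
  expect_equal(max(ch$intensity[ax >= 1645 & ax <= 1675]), 2 / 3,
               tolerance = 1e-3)
  expect_equal(max(ch$intensity[ax >= 1433 & ax <= 1463]), 1)
  neg <- flat_spectrum(-1, ax)
  expect_error(normalize_to_band(neg, 1660, 15), "non-positive")
  expect_error(normalize_to_band(s, 5000, 15), "does not overlap")
})

test_that("the preprocessing chain is deterministic and meets its contract", {
  ax <- default_axis()
  cfg_noop <- preprocess_config(norm_mode = "none")
  flatish <- flat_spectrum(3, ax)
  out <- preprocess_spectrum(flatish, cfg_noop)
  expect_lt(max(abs(out$intensity)), 1e-6)
  # determinism: identical inputs and config give identical output
  s <- simulate_spectrum(spectrum_profile("SERS", "EV12", "POOL_A"), ax,
                         seed = 9)
  o1 <- preprocess_spectrum(s, cfg_noop)
  o2 <- preprocess_spectrum(s, cfg_noop)
  expect_identical(o1$intensity, o2$intensity)
  expect_true(any(grepl("als", o1$meta$steps)))
  # noiseless control Raman: amide-I window max 1, signal-free median ~ 0
  raman <- simulate_spectrum(spectrum_profile("RAMAN", "EV12", "CONTROL"),
                             ax, noise_sigma = 0, jitter_sd = 0)
  proc <- preprocess_spectrum(raman, preprocess_config(norm_mode = "amide_i_1660"))
  win <- proc$wavenumber >= 1645 & proc$wavenumber <= 1675
  expect_equal(max(proc$intensity[win]), 1)
  idx <- unlist(lapply(default_noise_regions(), function(r)
    which(proc$wavenumber >= r[1] & proc$wavenumber <= r[2])))
  expect_lt(abs(median(proc$intensity[idx])), 0.01)
  expect_error(preprocess_config(sg_window = 10), "odd")
  expect_error(preprocess_config(baseline_p = 1), "\\(0, 1\\)")
})
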