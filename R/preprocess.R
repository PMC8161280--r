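#' Preprocessing configuration
#'
#' Bundles the parameters of the standard processing chain
#' crop -> smooth -> baseline -> normalize applied to every spectrum before
#' comparison. Defaults follow field practice for 785 nm fingerprint
#' spectra: Savitzky-Golay window 11 points / order 3, asymmetric least
#' squares with smoothness 1e5 and asymmetry 0.01.
#'
#' @param crop_lo,crop_hi fingerprint-region crop bounds in cm^-1.
#' @param sg_window Savitzky-Golay window length in points (odd,
#'   > `sg_polyorder`).
#' @param sg_polyorder Savitzky-Golay polynomial order.
#' @param baseline_lambda ALS smoothness penalty on the second difference of
#'   the baseline; larger values give stiffer baselines.
#' @param baseline_p ALS asymmetry weight in (0, 1): points above the
#'   baseline (peaks) get weight `p`, points below get `1 - p`.
#' @param baseline_iters maximum ALS reweighting iterations.
#' @param norm_mode intensity normalization: `"amide_i_1660"` (protein amide
#'   I band, used for spontaneous Raman comparison), `"ch_1448"` (CH
#'   deformation band, used before Raman difference scoring) or `"none"`
#'   (the default for SERS spectra, which are baseline-corrected but never
#'   normalized).
#' @param norm_half_window half width (cm^-1) of the window searched for the
#'   normalization band maximum; tolerates small calibration shifts.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(crop_lo = 300, crop_hi = 1800,
                              sg_window = 11, sg_polyorder = 3,
                              baseline_lambda = 1e5, baseline_p = 0.01,
                              baseline_iters = 20,
                              norm_mode = c("none", "amide_i_1660", "ch_1448"),
                              norm_half_window = 15) {
  norm_mode <- match.arg(norm_mode)
  if (sg_window %% 2 != 1 || sg_window <= sg_polyorder)
    stop("sg_window must be odd and greater than sg_polyorder")
  if (!(baseline_p > 0 && baseline_p < 1)) stop("baseline_p must be in (0, 1)")
  if (norm_half_window <= 0) stop("norm_half_window must be > 0")
  structure(list(crop_lo = crop_lo, crop_hi = crop_hi, sg_window = sg_window,
                 sg_polyorder = sg_polyorder,
                 baseline_lambda = baseline_lambda, baseline_p = baseline_p,
                 baseline_iters = baseline_iters, norm_mode = norm_mode,
                 norm_half_window = norm_half_window),
            class = "preprocess_config")
}

#' Normalization band centers
#'
#' Protein amide I (backbone C=O stretch) near 1660 cm^-1 and the CH
#' deformation band near 1448 cm^-1.
#' @format named numeric vector.
#' @export
NORMALIZATION_BANDS <- c(AMIDE_I = 1660, CH = 1448)

#' Savitzky-Golay smoothing
#'
#' Local polynomial least-squares smoothing of the intensity trace; the axis
#' is unchanged. Delegates to [signal::sgolayfilt()].
#'
#' @param x an `ev_spectrum`.
#' @param window filter window length in points (odd, <= spectrum length,
#'   > `polyorder`).
#' @param polyorder polynomial order.
#' @return the smoothed `ev_spectrum`.
#' @export
smooth_savgol <- function(x, window = 11, polyorder = 3) {
  validate_spectrum(x)
  n <- length(x$intensity)
  if (window %% 2 != 1) stop("window must be odd")
  if (window > n) stop("window exceeds spectrum length")
  if (window <= polyorder) stop("window must exceed polyorder")
  y <- signal::sgolayfilt(x$intensity, p = polyorder, n = window)
  ev_spectrum(x$wavenumber, y, meta = x$meta)
}

#' Asymmetric-least-squares baseline correction
#'
#' Estimates a smooth fluorescence-like baseline by iteratively reweighted
#' penalized least squares (Eilers-style ALS): the baseline `z` minimizes
#' `sum(w * (y - z)^2) + lambda * sum(diff(z, differences = 2)^2)` where
#' points above the current baseline get weight `p` and points below get
#' `1 - p`. With small `p`, peaks are ignored and the baseline follows the
#' smooth background.
#'
#' @param x an `ev_spectrum` with at least 10 points.
#' @param lambda smoothness penalty (default 1e5).
#' @param p asymmetry weight in (0, 1) (default 0.01).
#' @param iters maximum reweighting iterations (default 20). If the weights
#'   have not stabilized after `iters` iterations a warning is issued and
#'   the last iterate is returned.
#' @return a list with elements `corrected` (spectrum minus baseline) and
#'   `baseline`, both `ev_spectrum` objects; the final ALS weights are
#'   attached to `baseline` as attribute `"weights"`.
#' @export
baseline_als <- function(x, lambda = 1e5, p = 0.01, iters = 20) {
  validate_spectrum(x)
  if (!(p > 0 && p < 1)) stop("p must be in (0, 1)")
  y <- x$intensity
  n <- length(y)
  if (n < 10) stop("baseline correction needs at least 10 points")
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  converged <- FALSE
  for (it in seq_len(iters)) {
    A <- P + Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(A, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (all(w_new == w)) { converged <- TRUE; break }
    w <- w_new
  }
  if (!converged)
    warning(sprintf("ALS baseline did not converge in %d iterations; returning last iterate",
                    iters))
  baseline <- ev_spectrum(x$wavenumber, z, meta = x$meta)
  attr(baseline, "weights") <- w
  corrected <- ev_spectrum(x$wavenumber, y - z, meta = x$meta)
  list(corrected = corrected, baseline = baseline)
}

#' Normalize a spectrum to a band maximum
#'
#' Divides all intensities by the maximum intensity found in the window
#' `center +/- half_window`, so the band height becomes exactly 1. Used for
#' equal-intensity scaling on the protein amide I band (1660 cm^-1) or the
#' CH band (1448 cm^-1).
#'
#' @param x an `ev_spectrum` (normally baseline-corrected first).
#' @param center band center in cm^-1.
#' @param half_window search half width in cm^-1 (default 15).
#' @return the normalized `ev_spectrum`.
#' @export
normalize_to_band <- function(x, center, half_window = 15) {
  validate_spectrum(x)
  inwin <- x$wavenumber >= center - half_window &
    x$wavenumber <= center + half_window
  if (!any(inwin))
    stop(sprintf("normalization window %g +/- %g does not overlap the axis",
                 center, half_window))
  m <- max(x$intensity[inwin])
  if (m <= 0)
    stop(sprintf("non-positive maximum in the %g cm-1 normalization window (baseline failure?)",
                 center))
  ev_spectrum(x$wavenumber, x$intensity / m, meta = x$meta)
}

#' Standard preprocessing chain
#'
#' Applies, in order: crop to the fingerprint region, Savitzky-Golay
#' smoothing, ALS baseline correction and (optionally) band-maximum
#' normalization. Smoothing precedes baseline estimation so that noise does
#' not destabilize the ALS weights. Each step is appended to
#' `meta$steps` for provenance.
#'
#' @param x an `ev_spectrum`.
#' @param cfg a [preprocess_config()].
#' @return the processed `ev_spectrum`.
#' @export
preprocess_spectrum <- function(x, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  s <- crop_spectrum(x, cfg$crop_lo, cfg$crop_hi)
  s <- smooth_savgol(s, cfg$sg_window, cfg$sg_polyorder)
  s <- baseline_als(s, cfg$baseline_lambda, cfg$baseline_p,
                    cfg$baseline_iters)$corrected
  if (cfg$norm_mode == "amide_i_1660")
    s <- normalize_to_band(s, NORMALIZATION_BANDS[["AMIDE_I"]],
                           cfg$norm_half_window)
  else if (cfg$norm_mode == "ch_1448")
    s <- normalize_to_band(s, NORMALIZATION_BANDS[["CH"]],
                           cfg$norm_half_window)
  s$meta$steps <- c(x$meta$steps,
                    sprintf("crop[%g,%g]", cfg$crop_lo, cfg$crop_hi),
                    sprintf("savgol(%d,%d)", cfg$sg_window, cfg$sg_polyorder),
                    sprintf("als(%g,%g,%d)", cfg$baseline_lambda,
                            cfg$baseline_p, cfg$baseline_iters),
                    sprintf("norm(%s)", cfg$norm_mode))
  s
}
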