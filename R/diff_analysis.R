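#' Cancer-minus-control difference spectrum
#'
#' Pointwise difference of the group mean spectra, cancer minus control, so
#' that bands elevated in the cancer fractions appear positive.
#'
#' @param cancer,control [group_summary()] objects on identical axes.
#' @return an `ev_spectrum`.
#' @export
difference_spectrum <- function(cancer, control) {
  stopifnot(inherits(cancer, "group_summary"),
            inherits(control, "group_summary"))
  subtract_spectra(cancer$mean, control$mean)
}

band_window_points <- function(x, center, half_window) {
  lo <- center - half_window
  hi <- center + half_window
  idx <- which(x$wavenumber >= lo & x$wavenumber <= hi)
  if (length(idx) < 2)
    stop(sprintf("band window [%g, %g] outside the axis range", lo, hi))
  if (min(x$wavenumber) > lo || max(x$wavenumber) < hi)
    stop(sprintf("band window [%g, %g] extends beyond the axis", lo, hi))
  idx
}

#' Chord-baselined band integration
#'
#' Trapezoidal integral of the intensity over the closed window
#' `center +/- half_window`, minus the integral of the chord (the straight
#' line joining the intensities at the window endpoints). Chord subtraction
#' makes the area invariant to any globally linear function of wavenumber,
#' i.e. to offsets and tilts. The result is signed.
#'
#' @param x an `ev_spectrum`.
#' @param center band center in cm^-1.
#' @param half_window integration half width in cm^-1 (default 10).
#' @return signed band area in intensity * cm^-1.
#' @export
integrate_band <- function(x, center, half_window = 10) {
  validate_spectrum(x)
  idx <- band_window_points(x, center, half_window)
  w <- x$wavenumber[idx]
  y <- x$intensity[idx]
  chord_area <- (y[1] + y[length(y)]) / 2 * (w[length(w)] - w[1])
  trapz(w, y) - chord_area
}

#' Height ratio of two bands
#'
#' Ratio of the window-maximum intensities at two band positions, e.g. the
#' 1393 / 1450 cm^-1 ratio that is close to one for control EV fractions
#' and elevated (maximal for EV12) in cancer fractions.
#'
#' @param x an `ev_spectrum` (normally baseline-corrected).
#' @param numerator_center,denominator_center band centers in cm^-1.
#' @param half_window search half width in cm^-1 (default 8).
#' @return dimensionless ratio.
#' @export
band_ratio <- function(x, numerator_center = 1393, denominator_center = 1450,
                       half_window = 8) {
  validate_spectrum(x)
  peak <- function(center) {
    idx <- band_window_points(x, center, half_window)
    max(x$intensity[idx])
  }
  den <- peak(denominator_center)
  if (den <= 0)
    stop(sprintf("non-positive maximum in the %g cm-1 denominator window",
                 denominator_center))
  peak(numerator_center) / den
}

#' Default signal-free wavenumber regions
#'
#' Regions of the default synthetic-spectrum geometry that carry no band
#' intensity, used for robust noise estimation on difference spectra.
#' @return list of length-2 numeric vectors (cm^-1 intervals).
#' @export
default_noise_regions <- function()
  list(c(360, 370), c(740, 750), c(1700, 1750))

noise_sigma_mad <- function(x, noise_regions) {
  if (length(noise_regions) == 0) stop("need at least one noise region")
  idx <- unlist(lapply(noise_regions, function(r)
    which(x$wavenumber >= r[1] & x$wavenumber <= r[2])))
  if (length(idx) < 3) stop("noise regions contain too few axis points")
  stats::mad(x$intensity[idx], center = stats::median(x$intensity[idx]))
}

# standard deviation of the chord-subtracted trapezoidal area of i.i.d.
# noise with unit sigma over the window points (exact linear functional)
band_area_noise_factor <- function(w) {
  n <- length(w)
  tw <- numeric(n)
  dw <- diff(w)
  tw[-n] <- tw[-n] + dw / 2
  tw[-1] <- tw[-1] + dw / 2
  width <- w[n] - w[1]
  tw[1] <- tw[1] - width / 2
  tw[n] <- tw[n] - width / 2
  sqrt(sum(tw^2))
}

#' Call marker-band signs on a difference spectrum
#'
#' Integrates every band of the panel (chord-baselined) and calls it
#' POSITIVE, NEGATIVE or NEUTRAL against a noise threshold. The noise level
#' `sigma` is the robust SD (1.4826 x median absolute deviation) of the
#' difference intensities over the signal-free `noise_regions`; the
#' per-band threshold is `3 * sigma * f_w`, where `f_w` is the exact noise
#' propagation factor of the chord-subtracted trapezoidal area over the
#' band's window (a window-width equivalent). A band is NEUTRAL iff its
#' absolute area is below the threshold.
#'
#' @param diff a difference `ev_spectrum`.
#' @param panel a [band_panel()]; windows must not intersect the noise
#'   regions.
#' @param noise_regions list of cm^-1 intervals free of band signal.
#' @return a data frame (one row per band) with columns `label`, `center`,
#'   `half_window`, `expected_sign`, `area`, `threshold`, `sign_call`, plus
#'   attribute `"noise_sigma"`.
#' @export
call_band_signs <- function(diff, panel,
                            noise_regions = default_noise_regions()) {
  stopifnot(inherits(panel, "band_panel"))
  for (r in noise_regions) {
    overlap <- panel$center + panel$half_window >= r[1] &
      panel$center - panel$half_window <= r[2]
    if (any(overlap))
      stop(sprintf("noise region [%g, %g] overlaps a panel band window",
                   r[1], r[2]))
  }
  sigma <- noise_sigma_mad(diff, noise_regions)
  out <- as.data.frame(panel)
  out$area <- NA_real_
  out$threshold <- NA_real_
  for (i in seq_len(nrow(panel))) {
    idx <- band_window_points(diff, panel$center[i], panel$half_window[i])
    out$area[i] <- integrate_band(diff, panel$center[i], panel$half_window[i])
    out$threshold[i] <- 3 * sigma * band_area_noise_factor(diff$wavenumber[idx])
  }
  out$sign_call <- ifelse(out$area > out$threshold, "POSITIVE",
                          ifelse(out$area < -out$threshold, "NEGATIVE",
                                 "NEUTRAL"))
  attr(out, "noise_sigma") <- sigma
  out
}

#' Summed positive-marker band area
#'
#' Sum of the chord-baselined areas of the panel's POSITIVE-expected bands
#' on a difference spectrum: the scalar used to rank the discriminatory
#' power of EV fractions.
#'
#' @param diff a difference `ev_spectrum`.
#' @param panel a [band_panel()] (default the 11-band cancer SERS panel).
#' @return the summed signed area.
#' @export
positive_difference_score <- function(diff,
                                      panel = builtin_band_panel("cancer_sers_positive")) {
  stopifnot(inherits(panel, "band_panel"))
  pos <- panel[panel$expected_sign == "POSITIVE", , drop = FALSE]
  if (nrow(pos) == 0) stop("panel has no POSITIVE-expected bands")
  sum(vapply(seq_len(nrow(pos)), function(i)
    integrate_band(diff, pos$center[i], pos$half_window[i]), numeric(1)))
}

#' Noise SD of the positive-difference score
#'
#' Exact propagation of i.i.d. per-point noise with SD `sigma` through the
#' summed chord-subtracted trapezoidal areas of the panel's POSITIVE bands:
#' the per-point weights of all positive-band windows are accumulated on
#' the axis (so overlapping windows are handled exactly) and the returned
#' value is `sigma * ||w||_2`.
#'
#' @param axis wavenumber axis of the difference spectrum.
#' @param panel a [band_panel()].
#' @param sigma per-point noise SD of the difference spectrum.
#' @return SD of the score under pure noise.
#' @export
score_noise_sd <- function(axis, panel, sigma) {
  stopifnot(inherits(panel, "band_panel"))
  wtot <- numeric(length(axis))
  pos <- panel[panel$expected_sign == "POSITIVE", , drop = FALSE]
  for (i in seq_len(nrow(pos))) {
    idx <- which(axis >= pos$center[i] - pos$half_window[i] &
                   axis <= pos$center[i] + pos$half_window[i])
    w <- axis[idx]
    n <- length(w)
    tw <- numeric(n)
    dw <- diff(w)
    tw[-n] <- tw[-n] + dw / 2
    tw[-1] <- tw[-1] + dw / 2
    width <- w[n] - w[1]
    tw[1] <- tw[1] - width / 2
    tw[n] <- tw[n] - width / 2
    wtot[idx] <- wtot[idx] + tw
  }
  sigma * sqrt(sum(wtot^2))
}

#' Full difference-spectrum report for one fraction
#'
#' Computes the cancer-minus-control difference of the two group summaries
#' and derives the marker readouts: per-band chord areas and sign calls,
#' the summed positive-marker score, the 1393/1450 cm^-1 height ratio of
#' the cancer mean, and the robust noise SD of the difference.
#'
#' @param cancer,control [group_summary()] objects on identical axes.
#' @param panel a [band_panel()] (default the combined SERS difference
#'   panel).
#' @param noise_regions signal-free cm^-1 intervals for noise estimation.
#' @param fraction optional fraction label carried into the report.
#' @return an object of class `diff_report`: a list with elements
#'   `fraction`, `difference`, `band_integrals`, `positive_score`,
#'   `ratio_1393_1450`, `noise_sigma`, `n_cancer`, `n_control`.
#' @export
diff_report <- function(cancer, control,
                        panel = builtin_band_panel("sers_diff"),
                        noise_regions = default_noise_regions(),
                        fraction = cancer$mean$meta$fraction) {
  d <- difference_spectrum(cancer, control)
  calls <- call_band_signs(d, panel, noise_regions)
  structure(list(
    fraction = fraction,
    difference = d,
    band_integrals = calls,
    positive_score = positive_difference_score(d, panel),
    ratio_1393_1450 = band_ratio(cancer$mean),
    noise_sigma = attr(calls, "noise_sigma"),
    n_cancer = cancer$n, n_control = control$n), class = "diff_report")
}

#' @export
print.diff_report <- function(x, ...) {
  cat(sprintf("<diff_report>%s  n = %d cancer vs %d control\n",
              if (!is.null(x$fraction)) paste0(" fraction ", x$fraction) else "",
              x$n_cancer, x$n_control))
  cat(sprintf("  positive-marker score: %.4g\n", x$positive_score))
  cat(sprintf("  1393/1450 height ratio (cancer mean): %.3f\n",
              x$ratio_1393_1450))
  cat(sprintf("  noise sigma (robust): %.4g\n", x$noise_sigma))
  tab <- x$band_integrals
  cat(sprintf("  bands: %d called, %d POSITIVE, %d NEGATIVE, %d NEUTRAL\n",
              nrow(tab), sum(tab$sign_call == "POSITIVE"),
              sum(tab$sign_call == "NEGATIVE"),
              sum(tab$sign_call == "NEUTRAL")))
  invisible(x)
}

#' @export
summary.diff_report <- function(object, ...) {
  print(object)
  print.data.frame(object$band_integrals, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
plot.diff_report <- function(x, ...) {
  plot(x$difference, main = sprintf("Difference spectrum%s",
       if (!is.null(x$fraction)) paste0(" (", x$fraction, ")") else ""), ...)
  graphics::abline(h = 0, lty = 3)
  tab <- x$band_integrals
  called <- tab[tab$sign_call != "NEUTRAL", , drop = FALSE]
  if (nrow(called) > 0)
    graphics::abline(v = called$center, lty = 2,
                     col = ifelse(called$sign_call == "POSITIVE",
                                  "red", "blue"))
  invisible(x)
}
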