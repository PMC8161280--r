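#' Construct a spectrum
#'
#' A spectrum couples a strictly increasing wavenumber axis (cm^-1) with an
#' intensity trace (detector counts, arbitrary units) and acquisition
#' metadata. All downstream operations (preprocessing, map selection,
#' difference analysis) work on this container.
#'
#' @param wavenumber numeric vector of Raman shifts in cm^-1; strictly
#'   increasing, finite, length >= 2. A strictly decreasing axis is accepted
#'   and reversed (together with `intensity`) so that the stored axis is
#'   always ascending.
#' @param intensity numeric vector of intensities, same length as
#'   `wavenumber`, all finite.
#' @param meta list of acquisition metadata; recognised fields are
#'   `modality` (`"SERS"` or `"RAMAN"`), `fraction` (`"EV5"`, `"EV12"`,
#'   `"EV120"`, `"FC"`), `group` (`"CONTROL"`, `"POOL_A"`, `"POOL_B"`),
#'   `replicate_id`, `position` (length-2 numeric, micrometres) and `steps`
#'   (processing provenance, managed by the pipeline).
#'
#' @return an object of class `ev_spectrum`.
#' @export
#' @examples
#' s <- ev_spectrum(c(1000, 1001, 1002), c(1, 2, 3))
#' s
ev_spectrum <- function(wavenumber, intensity, meta = list()) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) >= 2 && all(diff(wavenumber) < 0)) {
    wavenumber <- rev(wavenumber)
    intensity <- rev(intensity)
  }
  x <- structure(list(wavenumber = wavenumber, intensity = intensity,
                      meta = meta), class = "ev_spectrum")
  validate_spectrum(x)
  x
}

MODALITIES <- c("SERS", "RAMAN")
FRACTIONS <- c("EV5", "EV12", "EV120", "FC")
GROUPS <- c("CONTROL", "POOL_A", "POOL_B")

validate_spectrum <- function(x) {
  if (!inherits(x, "ev_spectrum")) stop("not an ev_spectrum")
  w <- x$wavenumber
  y <- x$intensity
  if (length(w) < 2) stop("spectrum must have at least 2 points")
  if (!all(is.finite(w))) stop("non-finite wavenumbers")
  if (any(diff(w) <= 0)) stop("wavenumber axis must be strictly increasing")
  if (length(y) != length(w)) stop("intensity length differs from axis length")
  if (!all(is.finite(y))) stop("non-finite intensities")
  m <- x$meta
  check_enum <- function(value, allowed, what) {
    if (!is.null(value) && !value %in% allowed)
      stop(sprintf("invalid %s '%s' (allowed: %s)", what, value,
                   paste(allowed, collapse = ", ")))
  }
  check_enum(m$modality, MODALITIES, "modality")
  check_enum(m$fraction, FRACTIONS, "fraction")
  check_enum(m$group, GROUPS, "group")
  invisible(x)
}

axes_identical <- function(a, b, tol = 1e-9) {
  length(a$wavenumber) == length(b$wavenumber) &&
    max(abs(a$wavenumber - b$wavenumber)) <=
      tol * max(1, max(abs(a$wavenumber)))
}

#' Resample a spectrum onto a new wavenumber axis
#'
#' Linear interpolation of the intensity trace onto `target_axis`. The target
#' axis must lie within the source axis range: extrapolation is refused so
#' that subtraction of resampled spectra never silently invents data.
#'
#' @param x an `ev_spectrum`.
#' @param target_axis strictly increasing numeric vector within the range of
#'   `x`'s axis.
#' @return an `ev_spectrum` on `target_axis`; metadata is preserved.
#' @export
resample_spectrum <- function(x, target_axis) {
  validate_spectrum(x)
  target_axis <- as.numeric(target_axis)
  if (length(target_axis) < 2 || any(diff(target_axis) <= 0))
    stop("target axis must be strictly increasing with >= 2 points")
  rng <- range(x$wavenumber)
  if (min(target_axis) < rng[1] || max(target_axis) > rng[2])
    stop(sprintf("target axis [%g, %g] extends beyond source range [%g, %g]",
                 min(target_axis), max(target_axis), rng[1], rng[2]))
  yi <- stats::approx(x$wavenumber, x$intensity, xout = target_axis,
                      method = "linear", ties = "ordered")$y
  ev_spectrum(target_axis, yi, meta = x$meta)
}

#' Subtract one spectrum from another
#'
#' Pointwise `a - b`. Both spectra must share an identical axis; resample
#' explicitly first if they do not, so that interpolation is always a visible
#' processing step.
#'
#' @param a,b `ev_spectrum` objects on identical axes.
#' @return an `ev_spectrum` holding `a$intensity - b$intensity`; the metadata
#'   records both parents under `meta$parents`.
#' @export
subtract_spectra <- function(a, b) {
  validate_spectrum(a)
  validate_spectrum(b)
  if (!axes_identical(a, b))
    stop("axis mismatch: spectra must share an identical wavenumber axis ",
         "(resample_spectrum() first)")
  meta <- a$meta
  meta$parents <- list(a = a$meta, b = b$meta)
  ev_spectrum(a$wavenumber, a$intensity - b$intensity, meta = meta)
}

#' Crop a spectrum to a wavenumber interval
#'
#' Retains exactly the axis points in the closed interval `[lo, hi]`.
#'
#' @param x an `ev_spectrum`.
#' @param lo,hi interval bounds in cm^-1, `lo < hi`.
#' @return the cropped `ev_spectrum`.
#' @export
crop_spectrum <- function(x, lo, hi) {
  validate_spectrum(x)
  if (!(lo < hi)) stop("crop requires lo < hi")
  keep <- x$wavenumber >= lo & x$wavenumber <= hi
  if (sum(keep) < 2)
    stop(sprintf("crop to [%g, %g] leaves fewer than 2 axis points", lo, hi))
  ev_spectrum(x$wavenumber[keep], x$intensity[keep], meta = x$meta)
}

#' @export
print.ev_spectrum <- function(x, ...) {
  m <- x$meta
  tag <- paste(Filter(Negate(is.null),
                      list(m$modality, m$fraction, m$group, m$replicate_id)),
               collapse = "/")
  cat(sprintf("<ev_spectrum> %d points, %g-%g cm-1%s\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              if (nzchar(tag)) paste0(" [", tag, "]") else ""))
  invisible(x)
}

#' @export
plot.ev_spectrum <- function(x, ..., xlab = expression(paste(
                               "Raman shift (", cm^-1, ")")),
                             ylab = "Intensity (a.u.)", type = "l") {
  graphics::plot(x$wavenumber, x$intensity, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Construct a spectral map (Raman image)
#'
#' A grid-positioned collection of spectra sharing one wavenumber axis, as
#' acquired when imaging the margin of a dried sample film.
#'
#' @param spectra list of `ev_spectrum` objects with identical axes, in
#'   row-major order (rows are y, columns are x).
#' @param n_rows,n_cols grid dimensions; `n_rows * n_cols` must equal
#'   `length(spectra)`.
#' @param step grid step in micrometres (default 10, the acquisition step).
#' @return an object of class `ev_map`.
#' @export
ev_map <- function(spectra, n_rows, n_cols, step = 10) {
  if (length(spectra) == 0) stop("map needs at least one spectrum")
  lapply(spectra, validate_spectrum)
  if (n_rows * n_cols != length(spectra))
    stop(sprintf("grid %dx%d does not hold %d spectra", n_rows, n_cols,
                 length(spectra)))
  ref <- spectra[[1]]
  for (s in spectra[-1])
    if (!axes_identical(ref, s)) stop("all map spectra must share one axis")
  structure(list(spectra = spectra, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), step = step),
            class = "ev_map")
}

#' @export
print.ev_map <- function(x, ...) {
  cat(sprintf("<ev_map> %dx%d grid (%d spectra), step %g um, %d points/spectrum\n",
              x$n_rows, x$n_cols, length(x$spectra), x$step,
              length(x$spectra[[1]]$wavenumber)))
  invisible(x)
}

#' Summarise replicate spectra as mean and standard deviation
#'
#' @param mean,sd `ev_spectrum` objects on identical axes; `sd` intensities
#'   must be non-negative.
#' @param n replicate count.
#' @return an object of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  validate_spectrum(mean)
  validate_spectrum(sd)
  if (!axes_identical(mean, sd)) stop("mean and sd axes differ")
  if (any(sd$intensity < 0)) stop("sd intensities must be >= 0")
  if (n < 1) stop("n must be >= 1")
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> n = %d replicates, %d points\n", x$n,
              length(x$mean$wavenumber)))
  invisible(x)
}

# trapezoidal integral over the full vector
trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

#' Default fingerprint-region axis
#'
#' The fingerprint region (about 300-1800 cm^-1) carries the biomolecular
#' band structure; 2 cm^-1 sampling gives 751 points. This is a package
#' configuration choice, overridable everywhere an axis is taken.
#'
#' @param lo,hi,step axis bounds and sampling interval in cm^-1.
#' @return numeric wavenumber vector.
#' @export
default_axis <- function(lo = 300, hi = 1800, step = 2) seq(lo, hi, by = step)
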