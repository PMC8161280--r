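#' Score map spectra by integrated intensity
#'
#' The intensity criterion for picking spectra from a Raman image of a dried
#' sample film: each member spectrum is scored by the trapezoidal integral
#' of its intensity over `region`. Integration is robust to single hot
#' pixels, unlike a max-intensity criterion.
#'
#' @param map an [ev_map()].
#' @param region length-2 numeric, integration region in cm^-1 (default the
#'   600-1750 cm^-1 fingerprint core).
#' @param baseline_correct if `TRUE`, score ALS-baseline-corrected copies of
#'   the spectra (the originals are untouched).
#' @return numeric vector of scores, one per spectrum in storage (row-major)
#'   order.
#' @export
score_map <- function(map, region = c(600, 1750), baseline_correct = FALSE) {
  stopifnot(inherits(map, "ev_map"))
  w <- map$spectra[[1]]$wavenumber
  keep <- w >= region[1] & w <= region[2]
  if (sum(keep) < 2)
    stop(sprintf("scoring region [%g, %g] does not overlap the map axis",
                 region[1], region[2]))
  vapply(map$spectra, function(s) {
    if (baseline_correct) s <- baseline_als(s)$corrected
    trapz(s$wavenumber[keep], s$intensity[keep])
  }, numeric(1))
}

#' Select the most intense spectra of a map
#'
#' Returns the `k` highest-scoring spectra (or the top fraction `q` of
#' them, `k = ceiling(q * N)`). Ties are broken by ascending row-major grid
#' index, so the selected set is independent of storage shuffling.
#'
#' @param map an [ev_map()].
#' @param k number of spectra to select (exactly one of `k`/`q`).
#' @param q fraction in (0, 1] of spectra to select (default 0.25 when
#'   neither is given).
#' @param region scoring region passed to [score_map()].
#' @param baseline_correct passed to [score_map()]; scoring on
#'   baseline-corrected copies (default `TRUE`) makes the score reflect band
#'   intensity rather than fluorescence background.
#' @return list of the selected `ev_spectrum` objects, in row-major order.
#' @export
select_top <- function(map, k = NULL, q = NULL, region = c(600, 1750),
                       baseline_correct = TRUE) {
  stopifnot(inherits(map, "ev_map"))
  n <- length(map$spectra)
  if (!is.null(k) && !is.null(q)) stop("give exactly one of k or q")
  if (is.null(k)) {
    if (is.null(q)) q <- 0.25
    if (!(q > 0 && q <= 1)) stop("q must be in (0, 1]")
    k <- ceiling(q * n)
  }
  if (k < 1 || k > n)
    stop(sprintf("k = %d outside 1..%d", k, n))
  scores <- score_map(map, region, baseline_correct)
  # ties fall back to ascending row-major grid index (from position metadata
  # when present, storage order otherwise), so the selected set is invariant
  # to storage shuffling
  pos <- lapply(map$spectra, function(s) s$meta$position)
  gidx <- if (!any(vapply(pos, is.null, logical(1)))) {
    xs <- vapply(pos, `[`, numeric(1), 1)
    ys <- vapply(pos, `[`, numeric(1), 2)
    order(order(ys, xs))
  } else seq_len(n)
  sel <- order(-scores, gidx)[seq_len(k)]
  map$spectra[sel[order(gidx[sel])]]
}

#' Average replicate spectra
#'
#' Pointwise mean and sample standard deviation (n - 1 denominator,
#' appropriate for the small replicate counts of droplet measurements; the
#' SD is zero when n = 1).
#'
#' @param specs non-empty list of `ev_spectrum` objects on identical axes.
#' @return a [group_summary()].
#' @export
average_spectra <- function(specs) {
  if (length(specs) == 0) stop("need at least one spectrum")
  lapply(specs, validate_spectrum)
  ref <- specs[[1]]
  for (s in specs[-1])
    if (!axes_identical(ref, s)) stop("axis mismatch across replicates")
  mat <- vapply(specs, function(s) s$intensity,
                numeric(length(ref$wavenumber)))
  mat <- matrix(mat, nrow = length(ref$wavenumber))
  mu <- rowMeans(mat)
  sdv <- if (ncol(mat) > 1) apply(mat, 1, stats::sd) else
    rep(0, nrow(mat))
  meta <- ref$meta
  meta$replicate_id <- NULL
  group_summary(ev_spectrum(ref$wavenumber, mu, meta = meta),
                ev_spectrum(ref$wavenumber, sdv, meta = meta),
                n = length(specs))
}
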