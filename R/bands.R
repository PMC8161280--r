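#' Construct a marker-band panel
#'
#' A band panel is a named list of marker bands, each defined by a center
#' (cm^-1), a half window (cm^-1) and the sign the band is expected to take
#' in a cancer-minus-control difference spectrum.
#'
#' @param name panel name.
#' @param label character vector of unique band labels.
#' @param center numeric vector of band centers (cm^-1, > 0).
#' @param half_window half width of the integration window (cm^-1, > 0);
#'   recycled. Default 10, i.e. a +/-10 cm^-1 window.
#' @param expected_sign `"POSITIVE"`, `"NEGATIVE"` or `"NEUTRAL"`; recycled.
#' @return a `band_panel`: a data frame with columns `label`, `center`,
#'   `half_window`, `expected_sign` and a `name` attribute.
#' @export
#' @examples
#' band_panel("demo", c("b1393", "b1450"), c(1393, 1450))
band_panel <- function(name, label, center, half_window = 10,
                       expected_sign = "NEUTRAL") {
  label <- as.character(label)
  center <- as.numeric(center)
  n <- length(center)
  if (n == 0) stop("band panel must contain at least one band")
  if (length(label) != n) stop("label and center lengths differ")
  if (anyDuplicated(label)) stop("duplicate band labels in panel")
  half_window <- rep_len(as.numeric(half_window), n)
  expected_sign <- rep_len(as.character(expected_sign), n)
  if (any(center <= 0)) stop("band centers must be > 0")
  if (any(half_window <= 0)) stop("half windows must be > 0")
  if (!all(expected_sign %in% c("POSITIVE", "NEGATIVE", "NEUTRAL")))
    stop("expected_sign must be POSITIVE, NEGATIVE or NEUTRAL")
  structure(data.frame(label = label, center = center,
                       half_window = half_window,
                       expected_sign = expected_sign,
                       stringsAsFactors = FALSE),
            name = name, class = c("band_panel", "data.frame"))
}

#' Built-in marker-band panels
#'
#' Panels of the reproducible difference bands between cancer and control
#' EV-enriched plasma fractions:
#' \describe{
#'   \item{`cancer_sers_positive`}{the 11 SERS bands consistently elevated in
#'     cancer fractions: 382, 394, 600, 713, 854, 1004, 1132, 1238, 1393,
#'     1560, 1589 cm^-1.}
#'   \item{`control_sers_negative`}{the SERS bands elevated in controls
#'     (negative in the cancer-minus-control difference): 477, 656 cm^-1.}
#'   \item{`sers_diff`}{union of the two SERS panels (13 bands).}
#'   \item{`raman_diff`}{spontaneous-Raman difference bands: positive 510,
#'     935, 1315, 1652; negative 879, 1242, 1554, 1672 cm^-1.}
#' }
#'
#' @param name one of `"cancer_sers_positive"`, `"control_sers_negative"`,
#'   `"sers_diff"`, `"raman_diff"`.
#' @param half_window integration half window in cm^-1 (default 10).
#' @return a [band_panel()].
#' @export
builtin_band_panel <- function(name = c("cancer_sers_positive",
                                        "control_sers_negative",
                                        "sers_diff", "raman_diff"),
                               half_window = 10) {
  name <- match.arg(name)
  sers_pos <- c(382, 394, 600, 713, 854, 1004, 1132, 1238, 1393, 1560, 1589)
  sers_neg <- c(477, 656)
  raman_pos <- c(510, 935, 1315, 1652)
  raman_neg <- c(879, 1242, 1554, 1672)
  mk <- function(centers, signs)
    band_panel(name, paste0("b", centers), centers, half_window, signs)
  switch(name,
    cancer_sers_positive = mk(sers_pos, "POSITIVE"),
    control_sers_negative = mk(sers_neg, "NEGATIVE"),
    sers_diff = mk(c(sers_pos, sers_neg),
                   rep(c("POSITIVE", "NEGATIVE"),
                       c(length(sers_pos), length(sers_neg)))),
    raman_diff = mk(c(raman_pos, raman_neg),
                    rep(c("POSITIVE", "NEGATIVE"),
                        c(length(raman_pos), length(raman_neg)))))
}

#' @export
print.band_panel <- function(x, ...) {
  cat(sprintf("<band_panel> '%s': %d bands\n", attr(x, "name"), nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
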