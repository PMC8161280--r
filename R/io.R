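split_fields <- function(line) {
  # delimiter auto-detection limited to tab / comma / whitespace
  if (grepl("\t", line)) strsplit(line, "\t", fixed = TRUE)[[1]]
  else if (grepl(",", line)) strsplit(line, ",", fixed = TRUE)[[1]]
  else strsplit(trimws(line), "[[:space:]]+")[[1]]
}

parse_header_meta <- function(lines) {
  meta <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    if (grepl("=", body, fixed = TRUE)) {
      kv <- strsplit(body, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      if (key %in% c("modality", "fraction", "group", "replicate_id"))
        meta[[key]] <- val
    }
  }
  meta
}

#' Read a two-column spectrum file
#'
#' Expects delimited text (tab, comma or whitespace separated) with two
#' numeric columns: wavenumber (cm^-1) and intensity. Lines starting with
#' `#` are comments; `# key = value` header lines with keys `modality`,
#' `fraction`, `group` or `replicate_id` are read into the metadata.
#' Descending axes are reversed; duplicate wavenumbers are an error.
#'
#' @param path file path.
#' @return an [ev_spectrum()].
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  is_comment <- grepl("^\\s*#", lines)
  meta <- parse_header_meta(lines[is_comment])
  data_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (length(data_idx) < 2)
    stop(sprintf("%s: fewer than 2 data rows", path))
  n <- length(data_idx)
  w <- numeric(n); y <- numeric(n)
  for (i in seq_len(n)) {
    f <- split_fields(lines[data_idx[i]])
    if (length(f) < 2)
      stop(sprintf("%s: line %d: expected 2 columns", path, data_idx[i]))
    vals <- suppressWarnings(as.numeric(f[1:2]))
    if (any(is.na(vals)))
      stop(sprintf("%s: line %d: non-numeric row '%s'", path, data_idx[i],
                   lines[data_idx[i]]))
    w[i] <- vals[1]; y[i] <- vals[2]
  }
  if (anyDuplicated(w))
    stop(sprintf("%s: duplicate wavenumbers", path))
  if (all(diff(w) < 0)) { w <- rev(w); y <- rev(y) }
  ev_spectrum(w, y, meta = meta)
}

#' Write a spectrum as tab-separated text
#'
#' Inverse of [read_spectrum()]; metadata fields are written as
#' `# key = value` header lines.
#'
#' @param x an `ev_spectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  validate_spectrum(x)
  hdr <- character(0)
  for (key in c("modality", "fraction", "group", "replicate_id")) {
    if (!is.null(x$meta[[key]]))
      hdr <- c(hdr, sprintf("# %s = %s", key, x$meta[[key]]))
  }
  rows <- sprintf("%.10g\t%.10g", x$wavenumber, x$intensity)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a Raman map from a wide table
#'
#' First column is the wavenumber axis; every further column is one spectrum.
#' The header row encodes the grid position of each spectrum as `x:y` (in
#' micrometres). The grid must be complete (every combination of the unique
#' x and y values present exactly once); spectra are stored row-major with
#' rows ordered by y and columns by x.
#'
#' @param path file path.
#' @param meta metadata list applied to every member spectrum.
#' @return an [ev_map()].
#' @export
read_spectral_map <- function(path, meta = list()) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) < 3) stop(sprintf("%s: too few rows for a map", path))
  hdr <- split_fields(lines[1])
  pos <- hdr[-1]
  xy <- lapply(strsplit(pos, ":", fixed = TRUE), function(p) {
    v <- suppressWarnings(as.numeric(p))
    if (length(v) != 2 || any(is.na(v)))
      stop(sprintf("%s: header position '%s' is not 'x:y'", path,
                   paste(p, collapse = ":")))
    v
  })
  xs <- vapply(xy, `[`, numeric(1), 1)
  ys <- vapply(xy, `[`, numeric(1), 2)
  ncolspec <- length(pos)
  dat <- matrix(NA_real_, nrow = length(lines) - 1, ncol = ncolspec + 1)
  for (i in 2:length(lines)) {
    f <- suppressWarnings(as.numeric(split_fields(lines[i])))
    if (length(f) != ncolspec + 1 || any(is.na(f)))
      stop(sprintf("%s: line %d: ragged or non-numeric row", path, i))
    dat[i - 1, ] <- f
  }
  ux <- sort(unique(xs)); uy <- sort(unique(ys))
  if (length(ux) * length(uy) != ncolspec || anyDuplicated(paste(xs, ys)))
    stop(sprintf("%s: positions do not form a complete rectangular grid", path))
  w <- dat[, 1]
  ord <- order(match(ys, uy), match(xs, ux))  # row-major: y rows, x columns
  step <- if (length(ux) > 1) min(diff(ux)) else if (length(uy) > 1)
    min(diff(uy)) else 10
  spectra <- lapply(ord, function(j) {
    m <- meta
    m$position <- c(xs[j], ys[j])
    ev_spectrum(w, dat[, j + 1], meta = m)
  })
  ev_map(spectra, n_rows = length(uy), n_cols = length(ux), step = step)
}

#' Write a Raman map as a wide table
#'
#' @param map an `ev_map` with per-spectrum `position` metadata (filled in by
#'   [read_spectral_map()] and [simulate_map()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectral_map <- function(map, path) {
  pos <- vapply(map$spectra, function(s) {
    p <- s$meta$position
    if (is.null(p)) stop("map spectra lack position metadata")
    sprintf("%g:%g", p[1], p[2])
  }, character(1))
  w <- map$spectra[[1]]$wavenumber
  mat <- vapply(map$spectra, function(s) s$intensity, numeric(length(w)))
  hdr <- paste(c("wavenumber", pos), collapse = "\t")
  rows <- apply(cbind(w, mat), 1, function(r)
    paste(sprintf("%.10g", r), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a JCAMP-DX spectrum (uncompressed XYDATA subset)
#'
#' Minimal reader for JCAMP-DX files with `##XYDATA=(X++(Y..Y))` in AFFN
#' (plain decimal) form. The axis is reconstructed from `##FIRSTX`,
#' `##LASTX` and `##NPOINTS`; intensities are scaled by `##YFACTOR`.
#' Compressed ordinate forms (DIF/DUP/SQZ/PAC letter codes) are refused.
#'
#' @param path file path.
#' @return an [ev_spectrum()].
#' @export
read_jcamp <- function(path) {
  lines <- readLines(path)
  get_field <- function(key) {
    hit <- grep(sprintf("^##%s=", key), lines, value = TRUE)
    if (length(hit) == 0) return(NULL)
    trimws(sub(sprintf("^##%s=", key), "", hit[1]))
  }
  npoints <- as.numeric(get_field("NPOINTS"))
  firstx <- as.numeric(get_field("FIRSTX"))
  lastx <- as.numeric(get_field("LASTX"))
  yfactor <- get_field("YFACTOR")
  yfactor <- if (is.null(yfactor)) 1 else as.numeric(yfactor)
  if (is.null(npoints) || is.na(npoints) || is.na(firstx) || is.na(lastx))
    stop(sprintf("%s: missing FIRSTX/LASTX/NPOINTS", path))
  start <- grep("^##XYDATA=", lines)
  if (length(start) == 0) stop(sprintf("%s: no XYDATA block", path))
  form <- sub("^##XYDATA=", "", lines[start[1]])
  if (!grepl("X\\+\\+\\(Y\\.\\.Y\\)", form))
    stop(sprintf("%s: unsupported XYDATA form '%s'", path, form))
  body <- lines[(start[1] + 1):length(lines)]
  end <- grep("^##", body)
  if (length(end) > 0) body <- body[seq_len(end[1] - 1)]
  ys <- numeric(0)
  for (ln in body) {
    toks <- strsplit(trimws(ln), "[[:space:],]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) < 2) next
    if (!all(grepl("^[+-]?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?$", toks)))
      stop(sprintf("%s: compressed ordinate encoding (DIF/DUP/SQZ) is not supported",
                   path))
    ys <- c(ys, as.numeric(toks[-1]))
  }
  if (length(ys) != npoints)
    stop(sprintf("%s: NPOINTS=%d but %d ordinates found", path, npoints,
                 length(ys)))
  w <- seq(firstx, lastx, length.out = npoints)
  y <- ys * yfactor
  if (all(diff(w) < 0)) { w <- rev(w); y <- rev(y) }
  ev_spectrum(w, y)
}

#' Read a band panel from a YAML document
#'
#' The document has a top-level `name` and a `bands` list; each band is a
#' mapping with keys `label`, `center`, `half_window` (optional, default 10)
#' and `sign` (optional, default NEUTRAL). Unknown keys are rejected.
#'
#' @param path file path.
#' @return a [band_panel()].
#' @export
read_band_panel <- function(path) {
  doc <- yaml::read_yaml(path)
  unknown <- setdiff(names(doc), c("name", "bands"))
  if (length(unknown) > 0)
    stop(sprintf("%s: unknown keys: %s", path, paste(unknown, collapse = ", ")))
  if (is.null(doc$bands) || length(doc$bands) == 0)
    stop(sprintf("%s: panel defines no bands", path))
  get <- function(b, key, default = NULL) {
    bad <- setdiff(names(b), c("label", "center", "half_window", "sign"))
    if (length(bad) > 0)
      stop(sprintf("%s: unknown band keys: %s", path, paste(bad, collapse = ", ")))
    if (is.null(b[[key]])) default else b[[key]]
  }
  band_panel(
    name = if (is.null(doc$name)) basename(path) else doc$name,
    label = vapply(doc$bands, function(b)
      as.character(get(b, "label", stop(sprintf("%s: band without label", path)))),
      character(1)),
    center = vapply(doc$bands, function(b) as.numeric(get(b, "center")),
                    numeric(1)),
    half_window = vapply(doc$bands, function(b)
      as.numeric(get(b, "half_window", 10)), numeric(1)),
    expected_sign = vapply(doc$bands, function(b)
      as.character(get(b, "sign", "NEUTRAL")), character(1)))
}

#' Write a band panel as a YAML document
#'
#' @param panel a `band_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_band_panel <- function(panel, path) {
  doc <- list(name = attr(panel, "name"),
              bands = lapply(seq_len(nrow(panel)), function(i)
                list(label = panel$label[i], center = panel$center[i],
                     half_window = panel$half_window[i],
                     sign = panel$expected_sign[i])))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a fraction-metrics table
#'
#' Delimited table with columns `fraction`, `group`, `particle_count`
#' (NTA particle number, units of 1e9 particles/mL) and `diameter` (DLS
#' hydrodynamic diameter, nm). `(fraction, group)` pairs must be unique and
#' counts/diameters positive.
#'
#' @param path file path.
#' @return a data frame with the four validated columns.
#' @export
read_fraction_metrics <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("fraction", "group", "particle_count", "diameter")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: need columns %s", path, paste(need, collapse = ", ")))
  df <- df[need]
  if (any(!df$fraction %in% FRACTIONS)) stop(sprintf("%s: invalid fraction", path))
  if (any(!df$group %in% GROUPS)) stop(sprintf("%s: invalid group", path))
  if (any(df$particle_count <= 0)) stop(sprintf("%s: particle_count must be > 0", path))
  if (any(df$diameter <= 0)) stop(sprintf("%s: diameter must be > 0", path))
  if (anyDuplicated(paste(df$fraction, df$group)))
    stop(sprintf("%s: duplicate (fraction, group) pair", path))
  df
}

#' NTA/DLS metrics of the plasma EV fractions
#'
#' The published particle numbers (NTA, 1e9/mL) and approximated diameters
#' (DLS, nm) for the EV5, EV12, EV120 and free-circulating (fc) fractions of
#' the control pool and the two prostate-cancer pools. The fc diameter,
#' reported only as an upper bound (< 50 nm), is evaluated at 50 nm.
#'
#' @return a data frame with columns `fraction`, `group`, `particle_count`,
#'   `diameter`.
#' @export
#' @examples
#' compute_fraction_metrics(table1_metrics())
table1_metrics <- function() {
  read_fraction_metrics(system.file("extdata", "table1_metrics.tsv",
                                    package = "sersev", mustWork = TRUE))
}
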