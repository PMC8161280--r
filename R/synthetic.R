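#' Pseudo-Voigt band profile
#'
#' Height-normalized linear mixture of a Lorentzian and a Gaussian sharing
#' one FWHM: `eta * L + (1 - eta) * G`, scaled so the value at the center
#' equals `amplitude`.
#'
#' @param axis wavenumber axis (cm^-1).
#' @param center band center (cm^-1).
#' @param amplitude peak height (>= 0).
#' @param fwhm full width at half maximum (cm^-1, > 0).
#' @param eta Lorentzian fraction in `[0, 1]` (0 = Gaussian,
#'   1 = Lorentzian).
#' @return intensity trace along `axis`.
#' @export
pseudo_voigt <- function(axis, center, amplitude = 1, fwhm = 12, eta = 0.7) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (fwhm <= 0) stop("fwhm must be > 0")
  if (eta < 0 || eta > 1) stop("eta must be in [0, 1]")
  hw <- fwhm / 2
  d2 <- (axis - center)^2
  lor <- hw^2 / (d2 + hw^2)
  gau <- exp(-4 * log(2) * d2 / fwhm^2)
  amplitude * (eta * lor + (1 - eta) * gau)
}

#' Default cancer-marker enhancement per fraction
#'
#' Relative scaling of the cancer SERS marker-band amplitudes across
#' EV-enriched fractions, taken from the ratios of the reported integrated
#' positive-difference intensities (EV12 and EV120 relative to EV5:
#' 4.39 and 1.89).
#' @return named numeric vector.
#' @export
default_fraction_enhancement <- function()
  c(EV5 = 1, EV12 = 672261 / 153163, EV120 = 290069 / 153163)

#' Default Raman difference-feature scaling per fraction
#'
#' Relative scaling of the spontaneous-Raman difference features across
#' fractions, from the ratios of the reported CH-normalized difference
#' integrals (EV12 and EV120 relative to EV5: 1.93 and 2.39).
#' @return named numeric vector.
#' @export
default_raman_delta <- function()
  c(EV5 = 1, EV12 = 13908 / 7205, EV120 = 17251 / 7205)

SERS_FWHM <- 12
RAMAN_FWHM <- 16
PV_ETA <- 0.7

bands_df <- function(center, amplitude, fwhm, eta = PV_ETA)
  data.frame(center = center, amplitude = amplitude, fwhm = fwhm, eta = eta)

# SERS band positions of control EV-enriched fractions
CONTROL_SERS_CENTERS <- c(478, 656, 803, 899, 1003, 1030, 1132, 1223, 1343,
                          1393, 1450, 1589, 1615, 1653)
# SERS marker bands elevated in cancer EV-enriched fractions
CANCER_SERS_MARKERS <- c(382, 394, 600, 713, 854, 1004, 1132, 1238, 1393,
                         1560, 1589)

control_sers_bands <- function() {
  bands_df(CONTROL_SERS_CENTERS, 50, SERS_FWHM)
}

cancer_sers_bands <- function(enh = 1) {
  # markers at 2.4x the control level before fraction enhancement, the
  # stable CH band at 1450, and weak counterparts of the control-elevated
  # bands (those not coinciding with a marker)
  weak <- setdiff(CONTROL_SERS_CENTERS, c(1003, 1132, 1393, 1450, 1589))
  rbind(bands_df(CANCER_SERS_MARKERS, 50 * 2.4 * enh, SERS_FWHM),
        bands_df(1450, 50, SERS_FWHM),
        bands_df(weak, 10, SERS_FWHM))
}

# protein bands of the EV-depleted free-circulating fraction: Tyr
# (643/826/850), Phe (622/1003/1209), peptide backbone (940/1300/1655),
# aliphatic/aromatic (1340/1450); carotenoids (1157/1523) in controls only
fc_sers_bands <- function(group) {
  b <- bands_df(c(643, 826, 850, 622, 1003, 1209, 940, 1300, 1655,
                  1340, 1450), 30, SERS_FWHM)
  if (group == "CONTROL")
    b <- rbind(b, bands_df(c(1157, 1523), 20, SERS_FWHM))
  b
}

# protein-dominated spontaneous Raman signature shared by control and
# cancer EV-enriched fractions
control_raman_bands <- function() {
  centers <- c(505, 538, 621, 643, 758, 828, 851, 878, 937, 1003, 1044,
               1125, 1157, 1207, 1243, 1315, 1337, 1448, 1528, 1552,
               1606, 1661, 1672)
  amps <- c(30, 25, 45, 40, 35, 40, 40, 50, 50, 70, 25,
            40, 40, 35, 50, 40, 45, 70, 40, 50,
            35, 80, 30)
  bands_df(centers, amps, RAMAN_FWHM)
}

cancer_raman_bands <- function(delta = 1) {
  b <- control_raman_bands()
  # cancer-elevated local features (alpha-helix / disulfide side of the
  # spec's sign convention) ...
  extra <- bands_df(c(510, 935, 1652), c(15, 13, 13) * delta, RAMAN_FWHM)
  # ... and reduced Trp / amide III / beta-sheet features
  b$amplitude[b$center == 878] <- 50 - 12 * delta
  b$amplitude[b$center == 1243] <- 50 - 12 * delta
  b$amplitude[b$center == 1552] <- 50 - 12 * delta
  b$amplitude[b$center == 1672] <- 30 - 8 * delta
  b$amplitude[b$center == 1315] <- 40 + 10 * delta
  if (any(b$amplitude < 0)) stop("raman delta multiplier too large")
  rbind(b, extra)
}

fc_raman_bands <- function(group) {
  bands_df(c(622, 643, 826, 850, 940, 1003, 1209, 1254, 1300, 1340,
             1450, 1655), 25, RAMAN_FWHM)
}

#' Synthetic spectrum profile for a fraction/group/modality cell
#'
#' Returns the generative model of one measurement condition: a pseudo-Voigt
#' band list at the characteristic positions of that cell, a smooth
#' fluorescence-like exponential baseline, an additive-noise SD and a
#' replicate-to-replicate amplitude jitter SD. Cancer SERS marker amplitudes
#' are scaled per fraction by `fraction_enhancement`; the Raman
#' difference-feature amplitudes by `raman_delta`. The free-circulating
#' (FC) fraction carries protein bands only, identical across groups except
#' for carotenoid bands present in controls, so its cancer-marker score is
#' null by construction.
#'
#' @param modality `"SERS"` or `"RAMAN"`.
#' @param fraction `"EV5"`, `"EV12"`, `"EV120"` or `"FC"`.
#' @param group `"CONTROL"`, `"POOL_A"` or `"POOL_B"`.
#' @param fraction_enhancement named multipliers for the cancer SERS marker
#'   amplitudes (see [default_fraction_enhancement()]).
#' @param raman_delta named multipliers for the Raman difference features
#'   (see [default_raman_delta()]).
#' @return a `spectrum_profile` list with elements `name`, `bands` (data
#'   frame: center, amplitude, fwhm, eta), `baseline` (offset,
#'   exp_amplitude, exp_scale), `noise_sigma`, `jitter_sd`.
#' @export
spectrum_profile <- function(modality = c("SERS", "RAMAN"),
                             fraction = c("EV12", "EV5", "EV120", "FC"),
                             group = c("CONTROL", "POOL_A", "POOL_B"),
                             fraction_enhancement = default_fraction_enhancement(),
                             raman_delta = default_raman_delta()) {
  modality <- match.arg(modality)
  fraction <- match.arg(fraction)
  group <- match.arg(group)
  cancer <- group != "CONTROL"
  if (fraction == "FC") {
    bands <- if (modality == "SERS") fc_sers_bands(group) else
      fc_raman_bands(group)
    baseline <- list(offset = 20, exp_amplitude = 150, exp_scale = 350)
  } else if (modality == "SERS") {
    bands <- if (cancer) cancer_sers_bands(fraction_enhancement[[fraction]])
      else control_sers_bands()
    baseline <- list(offset = 30, exp_amplitude = 300, exp_scale = 350)
  } else {
    bands <- if (cancer) cancer_raman_bands(raman_delta[[fraction]])
      else control_raman_bands()
    baseline <- list(offset = 40, exp_amplitude = 400, exp_scale = 450)
  }
  structure(list(name = paste(modality, fraction, group, sep = "_"),
                 modality = modality, fraction = fraction, group = group,
                 bands = bands, baseline = baseline,
                 noise_sigma = 4, jitter_sd = 0.05),
            class = "spectrum_profile")
}

#' Noiseless intensity of a profile
#'
#' Closed-form sum of the profile's pseudo-Voigt bands plus its exponential
#' baseline `offset + A * exp(-(nu - nu_lo) / scale)` along `axis`.
#'
#' @param profile a [spectrum_profile()].
#' @param axis wavenumber axis (cm^-1).
#' @return intensity trace.
#' @export
profile_intensity <- function(profile, axis) {
  b <- profile$bands
  y <- profile$baseline$offset + profile$baseline$exp_amplitude *
    exp(-(axis - min(axis)) / profile$baseline$exp_scale)
  for (i in seq_len(nrow(b)))
    y <- y + pseudo_voigt(axis, b$center[i], b$amplitude[i], b$fwhm[i],
                          b$eta[i])
  y
}

#' Simulate one spectrum
#'
#' Draws one replicate from a profile: band sum scaled by a per-replicate
#' amplitude factor `1 + N(0, jitter_sd)`, plus the baseline, plus i.i.d.
#' Gaussian noise. Deterministic for a fixed seed.
#'
#' @param profile a [spectrum_profile()].
#' @param axis wavenumber axis (default [default_axis()]).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param noise_sigma,jitter_sd overrides of the profile defaults; set both
#'   to 0 for the noiseless spectrum.
#' @param replicate_id optional identifier stored in the metadata.
#' @return an [ev_spectrum()] with modality/fraction/group metadata.
#' @export
simulate_spectrum <- function(profile, axis = default_axis(), seed = NULL,
                              noise_sigma = NULL, jitter_sd = NULL,
                              replicate_id = NULL) {
  stopifnot(inherits(profile, "spectrum_profile"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_sigma)) noise_sigma <- profile$noise_sigma
  if (is.null(jitter_sd)) jitter_sd <- profile$jitter_sd
  f <- if (jitter_sd > 0) max(0.2, 1 + stats::rnorm(1, 0, jitter_sd)) else 1
  base <- profile$baseline$offset + profile$baseline$exp_amplitude *
    exp(-(axis - min(axis)) / profile$baseline$exp_scale)
  y <- base + f * (profile_intensity(profile, axis) - base)
  if (noise_sigma > 0) y <- y + stats::rnorm(length(axis), 0, noise_sigma)
  ev_spectrum(axis, y, meta = list(modality = profile$modality,
                                   fraction = profile$fraction,
                                   group = profile$group,
                                   replicate_id = replicate_id))
}

#' Simulate a Raman map of a dried sample film
#'
#' Pixels within `mask_radius` (in pixel units) of the grid center carry
#' the full band amplitude of the profile; pixels outside (substrate only)
#' carry 5% of it. Baseline and noise are present everywhere.
#'
#' @param profile a [spectrum_profile()].
#' @param n_rows,n_cols grid dimensions (>= 2 each).
#' @param step grid step in micrometres.
#' @param mask_radius film radius in pixel units (default
#'   `0.45 * min(n_rows, n_cols)`).
#' @param axis wavenumber axis.
#' @param seed integer seed.
#' @param noise_sigma override of the profile noise SD.
#' @return an [ev_map()]; the film mask is attached as attribute
#'   `"inside"` (logical, row-major).
#' @export
simulate_map <- function(profile, n_rows = 8, n_cols = 8, step = 10,
                         mask_radius = NULL, axis = default_axis(),
                         seed = NULL, noise_sigma = NULL) {
  stopifnot(inherits(profile, "spectrum_profile"))
  if (n_rows < 2 || n_cols < 2) stop("map grid must be at least 2x2")
  if (is.null(mask_radius)) mask_radius <- 0.45 * min(n_rows, n_cols)
  if (is.null(noise_sigma)) noise_sigma <- profile$noise_sigma
  if (!is.null(seed)) set.seed(seed)
  cy <- (n_rows + 1) / 2
  cx <- (n_cols + 1) / 2
  base <- profile$baseline$offset + profile$baseline$exp_amplitude *
    exp(-(axis - min(axis)) / profile$baseline$exp_scale)
  signal <- profile_intensity(profile, axis) - base
  spectra <- vector("list", n_rows * n_cols)
  inside <- logical(n_rows * n_cols)
  k <- 0
  for (r in seq_len(n_rows)) {
    for (c in seq_len(n_cols)) {
      k <- k + 1
      inside[k] <- sqrt((r - cy)^2 + (c - cx)^2) <= mask_radius
      amp <- if (inside[k]) 1 else 0.05
      y <- base + amp * signal
      if (noise_sigma > 0) y <- y + stats::rnorm(length(axis), 0, noise_sigma)
      spectra[[k]] <- ev_spectrum(axis, y, meta = list(
        modality = profile$modality, fraction = profile$fraction,
        group = profile$group, position = c((c - 1) * step, (r - 1) * step)))
    }
  }
  m <- ev_map(spectra, n_rows, n_cols, step)
  attr(m, "inside") <- inside
  m
}

#' Cohort configuration
#'
#' @param n_replicates replicates per (fraction, group, modality) cell
#'   (default 5, the droplet replicate count).
#' @param axis wavenumber axis.
#' @param seed integer master seed for the cohort.
#' @param fractions,groups,modalities cells to generate.
#' @param fraction_enhancement,raman_delta see [spectrum_profile()].
#' @param noise_sigma,jitter_sd overrides applied to every cell (`NULL` =
#'   profile defaults).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_replicates = 5, axis = default_axis(), seed = 1,
                          fractions = c("EV5", "EV12", "EV120", "FC"),
                          groups = c("CONTROL", "POOL_A", "POOL_B"),
                          modalities = c("SERS", "RAMAN"),
                          fraction_enhancement = default_fraction_enhancement(),
                          raman_delta = default_raman_delta(),
                          noise_sigma = NULL, jitter_sd = NULL) {
  structure(list(n_replicates = n_replicates, axis = axis,
                 seed = as.integer(seed), fractions = fractions,
                 groups = groups, modalities = modalities,
                 fraction_enhancement = fraction_enhancement,
                 raman_delta = raman_delta, noise_sigma = noise_sigma,
                 jitter_sd = jitter_sd),
            class = "cohort_config")
}

# counter scheme: the k-th spectrum of the enumeration (modality, fraction,
# group, replicate, in the order given by the config) gets sub-seed
# (seed + 7919 * k) mod 2^31-1, independent of generation order
cohort_subseed <- function(seed, k) (seed + 7919 * k) %% 2147483647

#' Simulate a full cohort
#'
#' Generates `n_replicates` seeded spectra for every
#' (modality, fraction, group) cell of the configuration, together with a
#' manifest mapping each spectrum to its metadata and sub-seed, and the
#' fraction metrics table. Per-spectrum sub-seeds are derived from the
#' master seed by a fixed counter scheme, so the cohort is bit-identical
#' for a fixed configuration regardless of generation order.
#'
#' @param cfg a [cohort_config()].
#' @return an `ev_cohort`: list with elements `spectra` (list of
#'   [ev_spectrum()]), `manifest` (data frame: index, modality, fraction,
#'   group, replicate_id, seed), `metrics` (the fraction metrics with
#'   derived concentrations) and `config`.
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  spectra <- list()
  rows <- list()
  k <- 0
  for (modality in cfg$modalities) {
    for (fraction in cfg$fractions) {
      for (group in cfg$groups) {
        prof <- spectrum_profile(modality, fraction, group,
                                 cfg$fraction_enhancement, cfg$raman_delta)
        for (rep in seq_len(cfg$n_replicates)) {
          k <- k + 1
          sub <- cohort_subseed(cfg$seed, k)
          rid <- sprintf("%s_%s_%s_r%d", modality, fraction, group, rep)
          spectra[[k]] <- simulate_spectrum(prof, cfg$axis, seed = sub,
                                            noise_sigma = cfg$noise_sigma,
                                            jitter_sd = cfg$jitter_sd,
                                            replicate_id = rid)
          rows[[k]] <- data.frame(index = k, modality = modality,
                                  fraction = fraction, group = group,
                                  replicate_id = rid, seed = sub,
                                  stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(spectra = spectra, manifest = do.call(rbind, rows),
                 metrics = compute_fraction_metrics(table1_metrics()),
                 config = cfg),
            class = "ev_cohort")
}

#' @export
print.ev_cohort <- function(x, ...) {
  cat(sprintf("<ev_cohort> %d spectra (%d x %d x %d cells x %d replicates), seed %d\n",
              length(x$spectra), length(x$config$modalities),
              length(x$config$fractions), length(x$config$groups),
              x$config$n_replicates, x$config$seed))
  invisible(x)
}

#' Extract and summarise one cohort cell
#'
#' Preprocesses the replicates of one (modality, fraction, group) cell and
#' averages them. The default preprocessing follows modality convention:
#' SERS spectra are baseline-corrected but not normalized; Raman spectra
#' are additionally normalized to the CH band at 1448 cm^-1 (the
#' convention used before Raman difference scoring).
#'
#' @param cohort an `ev_cohort`.
#' @param modality,fraction,group cell selector; `group` may be a vector
#'   (e.g. both cancer pools, which are then pooled).
#' @param cfg a [preprocess_config()]; `NULL` selects the modality default.
#' @return a [group_summary()].
#' @export
cohort_cell_summary <- function(cohort, modality, fraction, group,
                                cfg = NULL) {
  stopifnot(inherits(cohort, "ev_cohort"))
  if (is.null(cfg)) {
    cfg <- if (modality == "SERS") preprocess_config(norm_mode = "none")
      else preprocess_config(norm_mode = "ch_1448")
  }
  m <- cohort$manifest
  idx <- m$index[m$modality == modality & m$fraction == fraction &
                   m$group %in% group]
  if (length(idx) == 0) stop("no spectra match the requested cell")
  average_spectra(lapply(cohort$spectra[idx], preprocess_spectrum, cfg = cfg))
}
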