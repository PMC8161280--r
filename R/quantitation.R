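#' Sphere volume from a diameter in nanometres
#'
#' `V = (4/3) * pi * r^3` with `r = diameter / 2`, converted to cm^3
#' (1 nm = 1e-7 cm). EVs are assumed spherical, as supported by DLS and
#' TEM.
#'
#' @param diameter_nm particle diameter in nm (> 0).
#' @return volume in cm^3.
#' @export
#' @examples
#' sphere_volume_cm3(100)  # 5.236e-16 cm^3
sphere_volume_cm3 <- function(diameter_nm) {
  if (any(diameter_nm <= 0)) stop("diameter must be > 0")
  (4 / 3) * pi * (diameter_nm / 2 * 1e-7)^3
}

#' EV mass concentration from NTA count and DLS diameter
#'
#' Approximates the mass concentration of a fraction as
#' `N * V(d) * rho`: particle number concentration (NTA) times the volume
#' of a sphere at the DLS diameter times the particle density. The default
#' density of 1 g/cm^3 is the standard approximation for EVs (close to
#' water/lipid).
#'
#' @param particle_count_1e9_per_ml NTA particle number in units of
#'   1e9 particles/mL.
#' @param diameter_nm DLS diameter in nm.
#' @param density_g_cm3 particle density in g/cm^3 (default 1).
#' @return mass concentration in mg/mL. Zero counts give zero.
#' @export
#' @examples
#' mass_concentration(414, 500)   # ~27.1 mg/mL
#' mass_concentration(1494, 200)  # ~6.26 mg/mL
mass_concentration <- function(particle_count_1e9_per_ml, diameter_nm,
                               density_g_cm3 = 1) {
  if (any(particle_count_1e9_per_ml < 0)) stop("particle count must be >= 0")
  if (any(density_g_cm3 <= 0)) stop("density must be > 0")
  # (1e9 / mL) * cm^3 * (g / cm^3) = 1e9 g / mL; * 1e9 * 1e3 -> mg/mL
  particle_count_1e9_per_ml * 1e9 *
    sphere_volume_cm3(diameter_nm) * density_g_cm3 * 1e3
}

#' Round to significant figures for table display
#'
#' Round-half-even at `digits` significant figures (R's [signif()]), the
#' convention used when comparing derived concentrations against their
#' two-significant-figure printed form.
#'
#' @param x numeric.
#' @param digits significant figures (default 2).
#' @return rounded numeric.
#' @export
round_sigfig <- function(x, digits = 2) signif(x, digits)

#' Derive mass concentrations for a metrics table
#'
#' @param metrics data frame as returned by [read_fraction_metrics()] or
#'   [table1_metrics()].
#' @param density_g_cm3 particle density in g/cm^3.
#' @return the input with two added columns: `mass_concentration` (mg/mL)
#'   and `printed` (rounded to 2 significant figures).
#' @export
compute_fraction_metrics <- function(metrics, density_g_cm3 = 1) {
  need <- c("fraction", "group", "particle_count", "diameter")
  if (!all(need %in% names(metrics)))
    stop("metrics must have columns ", paste(need, collapse = ", "))
  metrics$mass_concentration <- mass_concentration(
    metrics$particle_count, metrics$diameter, density_g_cm3)
  metrics$printed <- round_sigfig(metrics$mass_concentration, 2)
  metrics
}

#' Solve EV / AgNP mixing volumes
#'
#' Given the EV fraction concentration and the aggregated silver
#' nanoparticle concentration, solves for the two volumes that realize a
#' fixed EV:AgNP mass ratio in a fixed final droplet volume:
#' `v_ev * c_ev = ratio * v_agnp * c_agnp` with `v_ev + v_agnp = total`.
#' The closed form is
#' `v_ev = total * ratio * c_agnp / (c_ev + ratio * c_agnp)`.
#'
#' @param ev_concentration EV mass concentration in mg/mL (> 0).
#' @param agnp_concentration AgNP concentration in mg/mL after KCl-induced
#'   aggregation (default 0.05: 0.1 mg/mL diluted 1:1 with KCl).
#' @param mass_ratio target EV:AgNP mass ratio (default 20).
#' @param total_volume final droplet volume in uL (default 10).
#' @return an object of class `mixing_plan` with the inputs plus the solved
#'   `ev_volume` and `agnp_volume` (uL).
#' @export
#' @examples
#' mixing_volumes(1.0)   # 5 uL EV + 5 uL AgNP
#' mixing_volumes(27)    # ~0.357 uL of the concentrated EV5 fraction
mixing_volumes <- function(ev_concentration, agnp_concentration = 0.05,
                           mass_ratio = 20, total_volume = 10) {
  if (ev_concentration <= 0) stop("ev_concentration must be > 0")
  if (agnp_concentration <= 0) stop("agnp_concentration must be > 0")
  if (mass_ratio <= 0 || total_volume <= 0)
    stop("mass_ratio and total_volume must be > 0")
  v_ev <- total_volume * mass_ratio * agnp_concentration /
    (ev_concentration + mass_ratio * agnp_concentration)
  v_agnp <- total_volume - v_ev
  if (!(v_ev > 0 && v_ev < total_volume))
    stop(sprintf("infeasible plan: required EV volume %.3g uL not in (0, %g)",
                 v_ev, total_volume))
  structure(list(ev_concentration = ev_concentration,
                 agnp_concentration = agnp_concentration,
                 mass_ratio = mass_ratio, total_volume = total_volume,
                 ev_volume = v_ev, agnp_volume = v_agnp),
            class = "mixing_plan")
}

#' @export
print.mixing_plan <- function(x, ...) {
  cat(sprintf("<mixing_plan> %.4g uL EV (%.4g mg/mL) + %.4g uL AgNP (%.4g mg/mL)\n",
              x$ev_volume, x$ev_concentration, x$agnp_volume,
              x$agnp_concentration))
  cat(sprintf("  total %.4g uL, EV:AgNP mass ratio %.4g:1\n",
              x$total_volume, x$mass_ratio))
  invisible(x)
}

#' Concentration after volumetric dilution
#'
#' `c0 / (1 + added_volume_ratio)`: e.g. adding an equal volume of KCl
#' solution (ratio 1) halves the AgNP concentration from 0.1 to
#' 0.05 mg/mL.
#'
#' @param c0 initial concentration in mg/mL (>= 0).
#' @param added_volume_ratio volume added per unit initial volume (>= 0).
#' @return diluted concentration in mg/mL.
#' @export
dilution <- function(c0, added_volume_ratio) {
  if (any(c0 < 0) || any(added_volume_ratio < 0))
    stop("concentration and volume ratio must be >= 0")
  c0 / (1 + added_volume_ratio)
}
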