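#' Polychromatic X-ray source spectrum
#'
#' Builds a parametric bremsstrahlung (Kramers-type) spectrum filtered by an
#' aluminium slab, sampled on a uniform energy grid up to the tube voltage.
#' The shape is \eqn{S(E) \propto (kVp - E)/E \cdot e^{-\mu_{Al}(E) t}}, with
#' the total fluence normalised to `fluence` photons per pixel per second so
#' that downstream expected counts scale linearly with exposure time.
#'
#' @param kvp Tube voltage in kV (maximum photon energy, keV). Must be > 0.
#' @param filtration_mm_al Aluminium filtration thickness in mm (>= 0).
#' @param fluence Total open-beam fluence in photons per pixel per second,
#'   integrated over the whole spectrum.
#' @param energy_step Energy grid spacing in keV.
#' @param energy_min Lower end of the energy grid in keV.
#' @return An object of class `source_spectrum`: a list with `energy` (keV
#'   grid) and `fluence` (photons / keV / pixel / s), plus `kvp` and
#'   `filtration_mm_al`.
#' @examples
#' s <- source_spectrum(50, 0.5)
#' plot(s$energy, s$fluence, type = "l", xlab = "keV", ylab = "fluence")
#' @export
source_spectrum <- function(kvp, filtration_mm_al = 0.5, fluence = 1e4,
                            energy_step = 0.5, energy_min = 1) {
  if (!is.finite(kvp) || kvp <= 0) stop("kvp must be a positive number")
  if (filtration_mm_al < 0) stop("filtration must be non-negative")
  energy <- seq(energy_min, kvp, by = energy_step)
  if (energy[length(energy)] < kvp) energy <- c(energy, kvp)
  raw <- pmax(kvp - energy, 0) / energy
  mu_al <- mu_aluminium(energy)           # 1/mm
  s <- raw * exp(-mu_al * filtration_mm_al)
  total <- trapz(energy, s)
  if (total <= 0) stop("spectrum has no fluence; check kvp/filtration")
  s <- s * fluence / total
  structure(
    list(energy = energy, fluence = s, kvp = kvp,
         filtration_mm_al = filtration_mm_al),
    class = "source_spectrum"
  )
}

#' @export
print.source_spectrum <- function(x, ...) {
  cat(sprintf(
    "<source_spectrum> %g kVp, %.2f mm Al, %d energy samples (%.1f-%.1f keV)\n",
    x$kvp, x$filtration_mm_al, length(x$energy),
    min(x$energy), max(x$energy)))
  cat(sprintf("  total fluence %.4g photons/pixel/s\n",
              trapz(x$energy, x$fluence)))
  invisible(x)
}

# Effective beam-filtration attenuation (1/mm): photoelectric E^-3 term +
# Compton floor. This is an effective model of filter plus detector energy
# response, calibrated so that exposure-balanced open-beam counts across the
# default threshold ladder reproduce the proportions of the acquisition
# exposure table; it is softer at low energy than bulk aluminium.
mu_aluminium <- function(energy_kev) 300 / energy_kev^3 + 0.04

#' Attenuating material
#'
#' A material is described by a two-term linear attenuation model
#' \eqn{\mu(E) = p / E^3 + c} (1/mm, E in keV): a photoelectric term falling
#' as \eqn{E^{-3}} plus an approximately energy-independent Compton term.
#' An optional K-edge multiplies the photoelectric term by a jump factor at
#' and above the edge energy.
#'
#' @param name Material name.
#' @param photo Photoelectric coefficient `p` (keV^3 / mm).
#' @param compton Compton coefficient `c` (1/mm).
#' @param kedge_kev Optional K-edge energy (keV).
#' @param kedge_jump Multiplicative jump of the photoelectric term at the
#'   edge (> 1), used only when `kedge_kev` is given.
#' @return An object of class `material_spec`.
#' @seealso [attenuation()], [materials()], [make_iodine_solution()]
#' @export
material <- function(name, photo, compton, kedge_kev = NULL,
                     kedge_jump = NULL) {
  if (photo < 0 || compton < 0) stop("attenuation coefficients must be >= 0")
  if (!is.null(kedge_kev) && (is.null(kedge_jump) || kedge_jump <= 1))
    stop("a K-edge requires kedge_jump > 1")
  structure(
    list(name = name, photo = photo, compton = compton,
         kedge_kev = kedge_kev, kedge_jump = kedge_jump),
    class = "material_spec"
  )
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material_spec> %s: mu(30 keV) = %.4f /mm%s\n", x$name,
              attenuation(x, 30),
              if (is.null(x$kedge_kev)) ""
              else sprintf(", K-edge at %.1f keV", x$kedge_kev)))
  invisible(x)
}

#' Linear attenuation coefficient of a material
#'
#' @param mat A `material_spec`.
#' @param energy_kev Vector of energies (keV).
#' @return Linear attenuation in 1/mm at each energy.
#' @export
attenuation <- function(mat, energy_kev) UseMethod("attenuation")

#' @export
attenuation.material_spec <- function(mat, energy_kev) {
  photo <- mat$photo / energy_kev^3
  if (!is.null(mat$kedge_kev))
    photo <- photo * ifelse(energy_kev >= mat$kedge_kev, mat$kedge_jump, 1)
  photo + mat$compton
}

#' Built-in material library
#'
#' Plausible two-term attenuation models for the plastics, fluids and air
#' used in the insert phantom. Coefficients are chosen to give realistic
#' magnitudes and ordering of diagnostic-energy attenuation (e.g. water
#' ~0.037/mm at 30 keV, PTFE densest, air negligible); they are not traced
#' to any tabulation and are configurable through [material()].
#'
#' @return Named list of `material_spec` objects: water, oil, pmma, pc,
#'   peek, pom, ptfe, pla, air.
#' @export
materials <- function() {
  list(
    water = material("water", 515, 0.0180),
    oil   = material("oil",   260, 0.0165),
    pmma  = material("pmma",  390, 0.0195),
    pc    = material("pc",    330, 0.0190),
    peek  = material("peek",  420, 0.0210),
    pom   = material("pom",   520, 0.0225),
    ptfe  = material("ptfe", 1100, 0.0300),
    pla   = material("pla",   420, 0.0200),
    air   = material("air",  0.60, 2.2e-5)
  )
}

#' Iodine solution in water
#'
#' Water plus a concentration-proportional iodine term whose photoelectric
#' component jumps upward at the iodine K-edge (33.2 keV). At zero
#' concentration the material is identical to water.
#'
#' @param concentration_mg_ml Iodine concentration in mg/mL (>= 0).
#' @param kedge_kev K-edge energy in keV.
#' @param kedge_jump Photoelectric jump factor at the edge.
#' @return A `material_spec` whose attenuation adds the iodine contribution
#'   on top of water.
#' @examples
#' iod <- make_iodine_solution(135)
#' attenuation(iod, 33.5) > attenuation(iod, 33.0)  # K-edge jump
#' @export
make_iodine_solution <- function(concentration_mg_ml, kedge_kev = 33.2,
                                 kedge_jump = 5.4) {
  if (concentration_mg_ml < 0) stop("concentration must be >= 0")
  w <- materials()$water
  # iodine mass attenuation modelled as A * (E / kedge)^-3 below the edge,
  # jumping by kedge_jump at the edge; A in cm^2/g at the edge energy.
  A <- 5.6
  conc_g_cm3 <- concentration_mg_ml / 1000
  # photoelectric coefficient in (1/mm) * keV^3: mu = coeff / E^3
  photo_iod <- A * conc_g_cm3 / 10 * kedge_kev^3
  structure(
    list(name = sprintf("iodine_%gmgml", concentration_mg_ml),
         photo = w$photo + photo_iod, compton = w$compton,
         kedge_kev = if (concentration_mg_ml > 0) kedge_kev else NULL,
         kedge_jump = if (concentration_mg_ml > 0) kedge_jump else NULL,
         # only the iodine share of the photoelectric term jumps at the edge
         photo_base = w$photo, photo_jumping = photo_iod),
    class = c("iodine_solution", "material_spec")
  )
}

#' @export
attenuation.iodine_solution <- function(mat, energy_kev) {
  photo <- mat$photo_base / energy_kev^3
  if (!is.null(mat$kedge_kev)) {
    jump <- ifelse(energy_kev >= mat$kedge_kev, mat$kedge_jump, 1)
    photo <- photo + mat$photo_jumping * jump / energy_kev^3
  }
  photo + mat$compton
}

# trapezoid rule on an irregular grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}
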