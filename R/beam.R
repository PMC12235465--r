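#' Beam and detector geometry for a scanning SAXS experiment
#'
#' Bundles the quantities needed to map detector pixels to scattering vectors
#' and to compute the radiation dose delivered per exposure. Lengths are kept
#' in the units beamline users quote them in (keV, mm, um) and converted
#' internally where SI is required.
#'
#' @param energy_kev Photon energy in keV.
#' @param distance_mm Sample-to-detector distance in mm.
#' @param pixel_um Detector pixel pitch in micrometres.
#' @param center Beam center as `c(row, col)` in pixel units (may be
#'   fractional; 1-based like R matrix indices).
#' @param photon_flux Incident flux in photons/s (used by dosimetry only).
#' @param exposure_time Exposure time per frame in seconds.
#' @param spot_area_um2 Focal spot area in um^2 (used by dosimetry only).
#' @param mass_attenuation_cm2g Mass attenuation coefficient mu/rho in
#'   cm^2/g at `energy_kev` (used by dosimetry only).
#' @return An object of class `beam_geometry`.
#' @examples
#' beam <- beam_geometry(energy_kev = 20.129, distance_mm = 2250,
#'                       pixel_um = 172, center = c(32.5, 32.5))
#' wavelength_angstrom(beam)
#' @export
beam_geometry <- function(energy_kev, distance_mm, pixel_um, center,
                          photon_flux = 1e13, exposure_time = 0.05,
                          spot_area_um2 = 2500, mass_attenuation_cm2g = 0.56) {
  stopifnot(is.numeric(energy_kev), energy_kev > 0,
            is.numeric(distance_mm), distance_mm > 0,
            is.numeric(pixel_um), pixel_um > 0,
            length(center) == 2, all(is.finite(center)))
  if (photon_flux <= 0 || exposure_time < 0 || spot_area_um2 <= 0 ||
      mass_attenuation_cm2g <= 0)
    stop("dosimetry fields of a beam_geometry must be positive")
  structure(list(
    energy_kev = energy_kev,
    distance_mm = distance_mm,
    pixel_um = pixel_um,
    center = as.numeric(center),
    photon_flux = photon_flux,
    exposure_time = exposure_time,
    spot_area_um2 = spot_area_um2,
    mass_attenuation_cm2g = mass_attenuation_cm2g
  ), class = "beam_geometry")
}

#' X-ray wavelength from photon energy
#'
#' lambda[A] = 12.398 / E[keV].
#'
#' @param beam A [beam_geometry()] or a numeric energy in keV.
#' @return Wavelength in Angstrom.
#' @export
wavelength_angstrom <- function(beam) {
  e <- if (inherits(beam, "beam_geometry")) beam$energy_kev else beam
  12.398 / e
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("beam_geometry: %.4g keV (lambda %.5f A), Dsd %.5g mm, pixel %.4g um, center (%.4g, %.4g)\n",
              x$energy_kev, wavelength_angstrom(x), x$distance_mm,
              x$pixel_um, x$center[1], x$center[2]))
  invisible(x)
}

# keV -> J
.KEV_J <- 1.602176634e-16

#' Radiation dose delivered by a single exposure
#'
#' Surface dose for a thin sample fully intercepting the focused beam,
#' D = flux x E x t / A x (mu/rho), with internal conversion of keV to J,
#' um^2 to m^2 and cm^2/g to m^2/kg. Transmission and sample thickness are
#' deliberately not modelled (thin-sample surface-dose approximation).
#'
#' @param beam A [beam_geometry()] carrying `photon_flux`, `energy_kev`,
#'   `exposure_time`, `spot_area_um2` and `mass_attenuation_cm2g`.
#' @return Dose in gray (J/kg).
#' @examples
#' b <- beam_geometry(20.129, 2250, 172, c(32.5, 32.5),
#'                    photon_flux = 1e13, exposure_time = 0.05,
#'                    spot_area_um2 = 50 * 50, mass_attenuation_cm2g = 0.56)
#' dose_per_exposure(b) / 1e3   # kGy
#' @export
dose_per_exposure <- function(beam) {
  stopifnot(inherits(beam, "beam_geometry"))
  if (beam$spot_area_um2 <= 0) stop("focal spot area must be positive")
  energy_j <- beam$energy_kev * .KEV_J
  area_m2 <- beam$spot_area_um2 * 1e-12
  mu_rho_m2kg <- beam$mass_attenuation_cm2g * 1e-4 / 1e-3
  beam$photon_flux * energy_j * beam$exposure_time / area_m2 * mu_rho_m2kg
}

#' Cone-beam micro-CT geometry
#'
#' @param source_detector_cm Source-to-detector distance (SDD) in cm.
#' @param source_object_cm Source-to-rotation-center distance (SOD) in cm.
#' @param detector_pixel_um Physical detector pixel size in um.
#' @return An object of class `ct_geometry`.
#' @examples
#' g <- ct_geometry(92, 16, 16)
#' magnification(g)          # 5.75
#' effective_voxel(g)        # 2.78 um
#' effective_propagation(g)  # 13.2 cm
#' @export
ct_geometry <- function(source_detector_cm, source_object_cm, detector_pixel_um) {
  stopifnot(is.numeric(source_detector_cm), is.numeric(source_object_cm),
            is.numeric(detector_pixel_um), detector_pixel_um > 0)
  if (!(source_object_cm > 0 && source_object_cm < source_detector_cm))
    stop("require 0 < SOD < SDD")
  structure(list(source_detector_cm = source_detector_cm,
                 source_object_cm = source_object_cm,
                 detector_pixel_um = detector_pixel_um),
            class = "ct_geometry")
}

#' @rdname ct_geometry
#' @param geom A [ct_geometry()].
#' @return `magnification()`: dimensionless M = SDD/SOD.
#' @export
magnification <- function(geom) {
  stopifnot(inherits(geom, "ct_geometry"))
  geom$source_detector_cm / geom$source_object_cm
}

#' @rdname ct_geometry
#' @return `effective_voxel()`: demagnified voxel size in um.
#' @export
effective_voxel <- function(geom) {
  geom$detector_pixel_um / magnification(geom)
}

#' @rdname ct_geometry
#' @return `effective_propagation()`: effective free-space propagation
#'   distance SOD x (SDD - SOD) / SDD in cm, governing the near-field phase
#'   contrast fringes.
#' @export
effective_propagation <- function(geom) {
  stopifnot(inherits(geom, "ct_geometry"))
  sod <- geom$source_object_cm
  sdd <- geom$source_detector_cm
  sod * (sdd - sod) / sdd
}

#' Total acquisition time of a mesh scan
#'
#' @param mesh_shape `c(rows, cols)` of the scan grid.
#' @param exposure_time Exposure per point in seconds.
#' @param overhead_per_point Motor settle / readout overhead per point in
#'   seconds (default 0).
#' @return Total time in seconds.
#' @examples
#' scan_time(c(100, 100), 0.05) / 60   # ~8.3 min
#' @export
scan_time <- function(mesh_shape, exposure_time, overhead_per_point = 0) {
  stopifnot(length(mesh_shape) == 2, all(mesh_shape >= 1),
            exposure_time > 0, overhead_per_point >= 0)
  prod(mesh_shape) * (exposure_time + overhead_per_point)
}

#' Round-number geometry report
#'
#' Formats the cone-beam geometry figures at the precision they are usually
#' quoted at (magnification to 1 decimal, voxel to 2, propagation to the cm).
#'
#' @param geom A [ct_geometry()].
#' @return A named character vector.
#' @export
geometry_report <- function(geom) {
  c(magnification = sprintf("%.1f", magnification(geom)),
    effective_voxel_um = sprintf("%.2f", effective_voxel(geom)),
    effective_propagation_cm = sprintf("%.0f", effective_propagation(geom)))
}
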