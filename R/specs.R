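#' Probe bead specification
#'
#' Describes a spherical probe bead. The bead radius `a = diameter / 2` and
#' mass `m = (4/3) * pi * a^3 * density` enter the oscillating-sphere
#' equation of motion, and the refractive index enters the Mie scattering
#' coefficients of the radiation-force model.
#'
#' @param diameter Bead diameter in metres.
#' @param density Bead material density in kg/m^3. Defaults: polystyrene
#'   1050, melamine resin 1510.
#' @param refractive_index Bead refractive index (>= 1) at the pump
#'   wavelength. Defaults: polystyrene 1.58, melamine resin 1.68 at 789 nm.
#' @param material Label, one of `"melamine"`, `"polystyrene"` or a free
#'   string. When `density`/`refractive_index` are missing they are filled
#'   from the material defaults.
#' @return An object of class `bead_spec`.
#' @export
bead_spec <- function(diameter, density = NULL, refractive_index = NULL,
                      material = "melamine") {
  defaults <- list(
    melamine    = list(density = 1510, refractive_index = 1.68),
    polystyrene = list(density = 1050, refractive_index = 1.58)
  )
  if (material %in% names(defaults)) {
    if (is.null(density)) density <- defaults[[material]]$density
    if (is.null(refractive_index)) {
      refractive_index <- defaults[[material]]$refractive_index
    }
  }
  stopifnot(is.numeric(diameter), length(diameter) == 1, diameter > 0)
  stopifnot(is.numeric(density), density > 0)
  stopifnot(is.numeric(refractive_index), refractive_index >= 1)
  structure(
    list(diameter = diameter, density = density,
         refractive_index = refractive_index, material = material),
    class = "bead_spec"
  )
}

#' @rdname bead_spec
#' @param bead A `bead_spec`.
#' @export
bead_radius <- function(bead) bead$diameter / 2

#' @rdname bead_spec
#' @export
bead_mass <- function(bead) (4 / 3) * pi * bead_radius(bead)^3 * bead$density

#' Embedding-medium specification
#'
#' Physical properties of the medium surrounding the probe beads. For
#' viscous-fluid force calibration set `viscosity`; for viscoelastic media a
#' complex shear modulus may be recorded. The density enters the complex
#' shear wavenumber k* = omega * sqrt(rho / G*) of the oscillating-sphere
#' model.
#'
#' @param refractive_index Medium refractive index (>= 1). Water 1.33;
#'   10% w/w glycerol-water 1.3469.
#' @param density Medium density in kg/m^3 (default 1000, aqueous hydrogels).
#' @param viscosity Dynamic viscosity in Pa s (fluid media; default 0).
#' @param complex_shear_modulus Optional complex G* in Pa for viscoelastic
#'   media; `Re(G*) >= 0` required when given.
#' @return An object of class `medium_spec`.
#' @export
medium_spec <- function(refractive_index = 1.33, density = 1000,
                        viscosity = 0, complex_shear_modulus = NULL) {
  stopifnot(refractive_index >= 1, density > 0, viscosity >= 0)
  if (!is.null(complex_shear_modulus)) {
    stopifnot(Re(complex_shear_modulus) >= 0)
  }
  structure(
    list(refractive_index = refractive_index, density = density,
         viscosity = viscosity, complex_shear_modulus = complex_shear_modulus),
    class = "medium_spec"
  )
}

#' Complex mechanical response of a bead
#'
#' Amplitude and phase (with respect to the drive waveform) of a bead's
#' displacement at the modulation frequency.
#'
#' @param amplitude Oscillation amplitude in metres (>= 0).
#' @param phase_shift Phase shift in radians, wrapped to (-pi, pi].
#' @param angular_frequency Angular modulation frequency omega in rad/s.
#' @return An object of class `complex_response`.
#' @export
complex_response <- function(amplitude, phase_shift, angular_frequency) {
  stopifnot(amplitude >= 0, angular_frequency > 0)
  phase_shift <- wrap_phase(phase_shift)
  structure(
    list(amplitude = amplitude, phase_shift = phase_shift,
         angular_frequency = angular_frequency),
    class = "complex_response"
  )
}

#' Light-sheet pump beam
#'
#' An astigmatic (elliptical) Gaussian beam focused by a cylindrical lens:
#' nearly collimated along the long axis and tightly focused along the short
#' axis. Widths are full-width-half-maximum of intensity at the focal plane.
#'
#' @param wavelength Vacuum wavelength in metres (default 789 nm).
#' @param power Total beam power in watts (default 120 mW).
#' @param fwhm_long Long-axis intensity FWHM at focus in metres (default 80 um).
#' @param fwhm_short Short-axis intensity FWHM at focus in metres
#'   (default 1.4 um). Must be smaller than `fwhm_long`.
#' @param modulation_frequency Power-modulation frequency in Hz (default 20).
#' @return An object of class `light_sheet_beam`.
#' @export
light_sheet_beam <- function(wavelength = 789e-9, power = 0.120,
                             fwhm_long = 80e-6, fwhm_short = 1.4e-6,
                             modulation_frequency = 20) {
  stopifnot(wavelength > 0, power >= 0, fwhm_long > 0, fwhm_short > 0,
            modulation_frequency > 0, fwhm_long > fwhm_short)
  structure(
    list(wavelength = wavelength, power = power, fwhm_long = fwhm_long,
         fwhm_short = fwhm_short,
         modulation_frequency = modulation_frequency),
    class = "light_sheet_beam"
  )
}

#' BM-mode acquisition plan
#'
#' Acquisition parameters of the phase-sensitive OCT detection: BM-mode
#' frame rate and frame count per slow-axis position, transverse sampling,
#' slow-axis scan, and the OCT operating point used for sensitivity
#' estimates.
#'
#' @param frame_rate BM-mode frame rate in Hz (default 425).
#' @param n_frames Frames per slow-axis position (default 6400).
#' @param fast_range Fast-axis scan range in metres (default 90 um).
#' @param pixel_size Transverse pixel pitch in metres (default 0.75 um).
#' @param slow_range Slow-axis scan range in metres (default 350 um).
#' @param slow_step Slow-axis step in metres (default 0.75 um).
#' @param wait_time Stage settling time per slow position in seconds
#'   (default 6).
#' @param oct_wavelength OCT centre wavelength in metres (default 1300 nm).
#' @param medium_index Refractive index seen by the OCT beam (default 1.34).
#' @param snr_db OCT signal-to-noise ratio in dB at the operating point
#'   (default 28).
#' @param depth_range Imaged depth extent in metres (default 80 um).
#' @return An object of class `acquisition_plan`.
#' @export
acquisition_plan <- function(frame_rate = 425, n_frames = 6400,
                             fast_range = 90e-6, pixel_size = 0.75e-6,
                             slow_range = 350e-6, slow_step = 0.75e-6,
                             wait_time = 6, oct_wavelength = 1300e-9,
                             medium_index = 1.34, snr_db = 28,
                             depth_range = 80e-6) {
  stopifnot(frame_rate > 0, n_frames >= 1, fast_range > 0, pixel_size > 0,
            slow_range >= 0, wait_time >= 0, oct_wavelength > 0,
            medium_index >= 1, depth_range > 0)
  if (slow_range > 0) stopifnot(slow_step > 0, slow_step <= slow_range)
  structure(
    list(frame_rate = frame_rate, n_frames = n_frames,
         fast_range = fast_range, pixel_size = pixel_size,
         slow_range = slow_range, slow_step = slow_step,
         wait_time = wait_time, oct_wavelength = oct_wavelength,
         medium_index = medium_index, snr_db = snr_db,
         depth_range = depth_range),
    class = "acquisition_plan"
  )
}

#' 2D radiation-pressure force profile
#'
#' Axial radiation-pressure force magnitude `F_rad(x, z)` sampled on a
#' regular grid spanning the light-sheet long axis (x) and depth (z).
#'
#' @param grid_x Strictly increasing lateral grid in metres.
#' @param grid_z Strictly increasing depth grid in metres.
#' @param force Matrix `length(grid_x) x length(grid_z)` of non-negative
#'   forces in newtons; `NA` marks missing cells.
#' @param provenance `"simulated"` or `"measured"`.
#' @return An object of class `force_profile`.
#' @export
force_profile <- function(grid_x, grid_z, force,
                          provenance = c("simulated", "measured")) {
  provenance <- match.arg(provenance)
  stopifnot(all(diff(grid_x) > 0) || length(grid_x) == 1,
            all(diff(grid_z) > 0) || length(grid_z) == 1)
  force <- as.matrix(force)
  stopifnot(nrow(force) == length(grid_x), ncol(force) == length(grid_z))
  if (any(force[is.finite(force)] < 0)) {
    stop("force values must be non-negative")
  }
  structure(
    list(grid_x = grid_x, grid_z = grid_z, force = force,
         provenance = provenance),
    class = "force_profile"
  )
}

# wrap angle(s) to (-pi, pi]
wrap_phase <- function(phi) {
  w <- (phi + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# run expr with a temporary RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
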