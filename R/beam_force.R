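# Light-sheet optics, GLMT radiation force, and acquisition planning.

# 1/e^2 intensity radius from intensity FWHM
fwhm_to_waist <- function(fwhm) fwhm / sqrt(2 * log(2))

# beam widths (long, short) at depth z from the focus
beam_widths <- function(beam, z, medium_index) {
  w0x <- fwhm_to_waist(beam$fwhm_long)
  w0y <- fwhm_to_waist(beam$fwhm_short)
  zrx <- pi * w0x^2 * medium_index / beam$wavelength
  zry <- pi * w0y^2 * medium_index / beam$wavelength
  list(w0x = w0x, w0y = w0y,
       wx = w0x * sqrt(1 + (z / zrx)^2),
       wy = w0y * sqrt(1 + (z / zry)^2))
}

#' Light-sheet intensity profile
#'
#' Elliptical-Gaussian focus with the stated intensity FWHMs at `z = 0` and
#' independent Gaussian-beam divergence along each transverse axis. The
#' transverse plane integral equals the beam power at every depth.
#'
#' @param beam A [light_sheet_beam()].
#' @param x,y,z Position in metres: `x` along the long axis, `y` along the
#'   short axis, `z` along propagation (focus at the origin). Vectorised.
#' @param medium_index Refractive index of the propagation medium
#'   (default 1.33); sets the Rayleigh ranges.
#' @return Intensity in W/m^2.
#' @export
lightsheet_intensity <- function(beam, x, y, z, medium_index = 1.33) {
  w <- beam_widths(beam, z, medium_index)
  2 * beam$power / (pi * w$wx * w$wy) *
    exp(-2 * x^2 / w$wx^2 - 2 * y^2 / w$wy^2)
}

# Localized-approximation beam-shape coefficients for the astigmatic sheet:
# azimuthal average of the normalised field amplitude on rings of radius
# rho_n = (n + 1/2)/k centred on the bead axis.
glmt_gn <- function(beam, x0, y0, z, k, nmax, medium_index, n_phi = 64) {
  w <- beam_widths(beam, z, medium_index)
  # amplitude envelope relative to the focal on-axis peak
  pref <- sqrt(w$w0x * w$w0y / (w$wx * w$wy))
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  cphi <- cos(phi); sphi <- sin(phi)
  n <- seq_len(nmax)
  rho <- (n + 0.5) / k
  xs <- outer(rho, cphi) + x0   # nmax x n_phi
  ys <- outer(rho, sphi) + y0
  amp <- pref * exp(-xs^2 / w$wx^2 - ys^2 / w$wy^2)
  rowMeans(amp)
}

#' GLMT radiation force of the light sheet on a probe bead
#'
#' Axial radiation-pressure force from generalized Lorenz-Mie theory. The
#' sheet is represented by beam-shape coefficients in the localized
#' approximation (field amplitude averaged azimuthally over the ring
#' `rho_n = (n + 1/2)/k` about the bead axis), and the axial force is the
#' on-axis GLMT radiation-pressure cross-section
#' \deqn{C_{pr,z} = \frac{2\pi}{k^2}\Big[\sum_n \frac{n(n+2)}{n+1}
#'   g_n g_{n+1}\,\mathrm{Re}(a_n + a_{n+1}^* - 2 a_n a_{n+1}^* +
#'   b_n + b_{n+1}^* - 2 b_n b_{n+1}^*) +
#'   \sum_n \frac{2n+1}{n(n+1)} g_n^2\,
#'   \mathrm{Re}(a_n + b_n - 2 a_n b_n^*)\Big]}
#' applied as `F_z = n_med I_peak C_pr,z / c`, which reduces exactly to
#' `Q_pr = Q_ext - g Q_sca` for a plane wave (`g_n = 1`). Transverse
#' components are reported at dipole (gradient-force) order and are
#' negligible for the weakly focused long axis.
#'
#' @param beam A [light_sheet_beam()].
#' @param bead A [bead_spec()].
#' @param medium A [medium_spec()]; `medium$refractive_index` must be below
#'   the bead index.
#' @param position Numeric length-3 `(x, y, z)` in metres (bead centre
#'   relative to the focus).
#' @param nmax Optional partial-wave count override.
#' @return Numeric length-3 force vector `(Fx, Fy, Fz)` in newtons.
#' @export
glmt_force <- function(beam, bead, medium, position = c(0, 0, 0),
                       nmax = NULL) {
  stopifnot(length(position) == 3)
  n_med <- medium$refractive_index
  if (bead$refractive_index <= n_med) {
    stop("bead index must exceed the medium index")
  }
  if (beam$power == 0) return(c(0, 0, 0))
  a <- bead_radius(bead)
  k <- 2 * pi * n_med / beam$wavelength
  x <- k * a
  m <- bead$refractive_index / n_med
  ab <- mie_ab(x, m, nmax)
  an <- ab$a; bn <- ab$b
  nmx <- ab$nmax
  gn <- glmt_gn(beam, position[1], position[2], position[3], k, nmx + 1,
                n_med)
  g <- gn[1:nmx]; g1 <- gn[2:(nmx + 1)]
  n <- 1:nmx
  a1 <- c(an[-1], 0); b1 <- c(bn[-1], 0)
  s_cross <- sum(n * (n + 2) / (n + 1) * g * g1 *
                 Re(an + Conj(a1) - 2 * an * Conj(a1) +
                    bn + Conj(b1) - 2 * bn * Conj(b1)))
  s_diag <- sum((2 * n + 1) / (n * (n + 1)) * g^2 *
                Re(an + bn - 2 * an * Conj(bn)))
  c_pr <- (2 * pi / k^2) * (s_cross + s_diag)
  i_peak <- 2 * beam$power /
    (pi * fwhm_to_waist(beam$fwhm_long) * fwhm_to_waist(beam$fwhm_short))
  c_light <- 299792458
  fz <- n_med * i_peak * c_pr / c_light
  # dipole-order transverse gradient force
  alpha <- (m^2 - 1) / (m^2 + 2)
  h <- 1e-8
  gx <- (lightsheet_intensity(beam, position[1] + h, position[2],
                              position[3], n_med) -
         lightsheet_intensity(beam, position[1] - h, position[2],
                              position[3], n_med)) / (2 * h)
  gy <- (lightsheet_intensity(beam, position[1], position[2] + h,
                              position[3], n_med) -
         lightsheet_intensity(beam, position[1], position[2] - h,
                              position[3], n_med)) / (2 * h)
  fgrad <- 2 * pi * n_med * a^3 * alpha / c_light
  c(fgrad * gx, fgrad * gy, fz)
}

#' Sample the axial GLMT force on an (x, z) grid
#'
#' Evaluates the axial component of [glmt_force()] at `y = 0` on a regular
#' grid spanning the light-sheet long axis and depth.
#'
#' @inheritParams glmt_force
#' @param grid_x,grid_z Strictly increasing grids in metres.
#' @return A [force_profile()] with `provenance = "simulated"`.
#' @export
force_profile_from_model <- function(beam, bead, medium, grid_x, grid_z) {
  f <- matrix(0, length(grid_x), length(grid_z))
  for (j in seq_along(grid_z)) {
    for (i in seq_along(grid_x)) {
      f[i, j] <- glmt_force(beam, bead, medium,
                            c(grid_x[i], 0, grid_z[j]))[3]
    }
  }
  force_profile(grid_x, grid_z, pmax(f, 0), provenance = "simulated")
}

#' Shot-noise-limited displacement sensitivity
#'
#' The smallest detectable displacement amplitude supported by `N` temporal
#' frames at a given OCT SNR:
#' `dz = lambda0 / (4 pi n sqrt(2 N SNR))`, the single-quadrature standard
#' deviation of the N-sample complex mean of the per-frame phase noise
#' converted to displacement.
#'
#' @param plan An [acquisition_plan()] (uses `oct_wavelength`,
#'   `medium_index`, `n_frames`, `snr_db`).
#' @return Displacement sensitivity in metres.
#' @export
displacement_sensitivity <- function(plan) {
  stopifnot(inherits(plan, "acquisition_plan"), plan$n_frames >= 2,
            is.finite(plan$snr_db))
  snr <- 10^(plan$snr_db / 10)
  plan$oct_wavelength /
    (4 * pi * plan$medium_index * sqrt(2 * plan$n_frames * snr))
}

#' Maximum measurable shear elastic modulus
#'
#' The stiffest medium in which a bead response is still detectable: the
#' response amplitude must exceed `snr_factor` times the displacement
#' sensitivity, giving
#' `G'_max = F / (6 pi a snr_factor sensitivity)`.
#'
#' @param force_peak Peak radiation force in newtons.
#' @param radius Bead radius in metres.
#' @param sensitivity Displacement sensitivity in metres.
#' @param snr_factor Minimum amplitude-to-sensitivity ratio (default 4).
#' @return Modulus bound in Pa.
#' @export
max_measurable_modulus <- function(force_peak, radius, sensitivity,
                                   snr_factor = 4) {
  stopifnot(force_peak > 0, radius > 0, sensitivity > 0, snr_factor > 0)
  force_peak / (6 * pi * radius * snr_factor * sensitivity)
}

#' Acquisition-time arithmetic
#'
#' @param plan An [acquisition_plan()].
#' @param with_wait Also include the per-position stage wait time.
#' @return List with `per_position` (s), `n_positions`,
#'   `total_without_wait` (s) and `total_with_wait` (s).
#' @export
acquisition_times <- function(plan, with_wait = TRUE) {
  stopifnot(inherits(plan, "acquisition_plan"), plan$frame_rate > 0)
  per <- plan$n_frames / plan$frame_rate
  n_pos <- if (plan$slow_range == 0) 1L else {
    if (plan$slow_step == 0) stop("slow_step must be > 0 when slow_range > 0")
    as.integer(ceiling(plan$slow_range / plan$slow_step))
  }
  list(per_position = per, n_positions = n_pos,
       total_without_wait = per * n_pos,
       total_with_wait = (per + plan$wait_time) * n_pos)
}

#' Bead volume fraction from mean edge-to-edge spacing
#'
#' Converts a mean nearest-neighbour edge-to-edge spacing into a volume
#' fraction via the Poisson nearest-neighbour relation
#' `r_centre = 0.554 n^(-1/3)` with `r_centre = spacing + diameter`,
#' then `phi = n (pi/6) d^3`.
#'
#' @param diameter Bead diameter in metres.
#' @param mean_edge_spacing Mean edge-to-edge nearest-neighbour spacing in
#'   metres (> 0).
#' @return Dimensionless volume fraction.
#' @export
bead_volume_fraction <- function(diameter, mean_edge_spacing) {
  stopifnot(diameter > 0, mean_edge_spacing > 0)
  r_centre <- mean_edge_spacing + diameter
  n_dens <- (0.554 / r_centre)^3
  n_dens * pi / 6 * diameter^3
}

#' Full width at half maximum of a sampled profile
#'
#' Linear-interpolation FWHM of a single-peaked profile.
#'
#' @param x Grid (strictly increasing).
#' @param y Values.
#' @return FWHM in the units of `x`.
#' @export
profile_fwhm <- function(x, y) {
  stopifnot(length(x) == length(y), all(diff(x) > 0))
  imax <- which.max(y)
  half <- y[imax] / 2
  left <- NA_real_; right <- NA_real_
  if (imax > 1) {
    for (i in seq(imax - 1, 1)) {
      if (y[i] <= half) {
        left <- x[i] + (x[i + 1] - x[i]) * (half - y[i]) / (y[i + 1] - y[i])
        break
      }
    }
  }
  if (imax < length(y)) {
    for (i in seq(imax + 1, length(y))) {
      if (y[i] <= half) {
        right <- x[i - 1] +
          (x[i] - x[i - 1]) * (y[i - 1] - half) / (y[i - 1] - y[i])
        break
      }
    }
  }
  right - left
}
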