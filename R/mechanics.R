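#' Effective modulus of an oscillating sphere in a viscoelastic medium
#'
#' Oestreicher's model relates the apparent (effective) modulus sensed by a
#' rigid sphere oscillating at angular frequency omega to the true complex
#' shear modulus of the surrounding medium:
#' `G_eff = G* (1 - i k a - (k a)^2 / 9)` with complex shear wavenumber
#' `k = omega * sqrt(rho / G*)`. The principal square root (`Re(k) >= 0`) is
#' used, with an `exp(+i omega t)` time convention so that the purely
#' viscous limit `G* = i omega eta` reproduces Stokes drag.
#'
#' @param g_star Complex shear modulus G* in Pa (non-zero).
#' @param omega Angular frequency in rad/s (> 0).
#' @param radius Sphere radius in metres (> 0).
#' @param rho Medium density in kg/m^3 (>= 0); `rho = 0` gives
#'   `G_eff = G*` exactly.
#' @return Complex effective modulus in Pa.
#' @export
oestreicher_geff <- function(g_star, omega, radius, rho = 1000) {
  g_star <- as.complex(g_star)
  if (any(Mod(g_star) == 0)) stop("g_star must be non-zero (k* undefined)")
  stopifnot(omega > 0, radius > 0, rho >= 0)
  k <- omega * sqrt(as.complex(rho) / g_star)
  k <- ifelse(Re(k) < 0, -k, k)  # principal branch
  g_star * (1 - 1i * k * radius - (k * radius)^2 / 9)
}

#' Invert the oscillating-sphere relation for G*
#'
#' Recovers the true complex shear modulus from the effective modulus by
#' fixed-point iteration `G_{n+1} = G_eff / (1 - i k_n a - (k_n a)^2 / 9)`
#' starting from `G_0 = G_eff`. Because `|k a| << 1` at the 20-Hz operating
#' point, the map is strongly contractive and converges in a few iterations.
#'
#' @inheritParams oestreicher_geff
#' @param g_eff Complex effective modulus in Pa (non-zero).
#' @param tol Relative convergence tolerance (default 1e-12).
#' @param max_iter Iteration cap (default 200).
#' @return Complex G* in Pa such that
#'   `oestreicher_geff(G*, omega, radius, rho)` equals `g_eff` within `tol`.
#' @export
invert_geff <- function(g_eff, omega, radius, rho = 1000, tol = 1e-12,
                        max_iter = 200) {
  g_eff <- as.complex(g_eff)
  if (Mod(g_eff) == 0) stop("g_eff must be non-zero")
  stopifnot(tol > 0)
  if (rho == 0) return(g_eff)
  g <- g_eff
  for (it in seq_len(max_iter)) {
    k <- omega * sqrt(as.complex(rho) / g)
    if (Re(k) < 0) k <- -k
    g_new <- g_eff / (1 - 1i * k * radius - (k * radius)^2 / 9)
    rel <- Mod(g_new - g) / Mod(g_new)
    g <- g_new
    if (rel < tol) return(g)
  }
  stop(sprintf(
    "invert_geff did not converge in %d iterations (last G* = %s, relative change %.3e)",
    max_iter, format(g), rel))
}

#' Complex shear modulus from a measured bead response
#'
#' Solves the harmonically forced oscillating-sphere equation of motion for
#' the effective modulus,
#' `G_eff = (F + m omega^2 A e^{i phi}) / (6 pi a A e^{i phi})`,
#' then inverts the Oestreicher relation to obtain
#' `G* = G' + i G''`.
#'
#' @param force Radiation-pressure force amplitude at the bead in newtons
#'   (> 0).
#' @param response A [complex_response()] with the bead's displacement
#'   amplitude and phase shift w.r.t. the drive waveform.
#' @param bead A [bead_spec()]; supplies radius and (if inertia is kept)
#'   mass.
#' @param medium_rho Medium density in kg/m^3 used in the inversion
#'   (default 1000).
#' @param include_inertia Keep the `m omega^2` inertial term? At 20 Hz the
#'   term is ~1e-9 of the drag term and may be dropped (default TRUE).
#' @return A list with `g_star` (complex Pa), `g_prime`, `g_double_prime`,
#'   `loss_ratio` (= G''/G'), and the intermediate `g_eff`.
#' @export
modulus_from_response <- function(force, response, bead, medium_rho = 1000,
                                  include_inertia = TRUE) {
  stopifnot(inherits(response, "complex_response"), inherits(bead, "bead_spec"))
  if (response$amplitude <= 0) stop("no detectable mechanical response")
  stopifnot(force > 0)
  a <- bead_radius(bead)
  m <- if (include_inertia) bead_mass(bead) else 0
  omega <- response$angular_frequency
  p <- response$amplitude * exp(1i * response$phase_shift)
  g_eff <- (force + m * omega^2 * p) / (6 * pi * a * p)
  g_star <- invert_geff(g_eff, omega, a, medium_rho)
  list(g_star = g_star,
       g_prime = Re(g_star),
       g_double_prime = Im(g_star),
       loss_ratio = Im(g_star) / Re(g_star),
       g_eff = g_eff)
}

#' Forward bead response from a known modulus
#'
#' The forward companion of [modulus_from_response()]: given the local G*,
#' force and bead, returns the complex displacement phasor
#' `A e^{i phi} = F / (6 pi a G_eff - m omega^2)` predicted by the
#' oscillating-sphere model.
#'
#' @inheritParams modulus_from_response
#' @param g_star Complex shear modulus in Pa.
#' @param omega Angular frequency in rad/s.
#' @return A [complex_response()].
#' @export
response_from_modulus <- function(g_star, force, omega, bead,
                                  medium_rho = 1000, include_inertia = TRUE) {
  a <- bead_radius(bead)
  m <- if (include_inertia) bead_mass(bead) else 0
  g_eff <- oestreicher_geff(g_star, omega, a, medium_rho)
  p <- force / (6 * pi * a * g_eff - m * omega^2)
  complex_response(Mod(p), Arg(p), omega)
}

#' Integrate the 1D axial equation of motion of a bead in viscous fluid
#'
#' Solves `m z'' = F(z) - 6 pi eta a z' + g (4/3) pi a^3 (rho_b - rho_f)`
#' (the last term only when `gravity = TRUE`) with deSolve's stiff-capable
#' `lsoda` integrator. The momentum relaxation time
#' `tau = m / (6 pi eta a)` is sub-microsecond for micron beads, so the
#' motion is heavily overdamped.
#'
#' @param force_profile A function `F(z)` returning force in newtons, or a
#'   single number for a constant force.
#' @param bead A [bead_spec()].
#' @param fluid A [medium_spec()] with `viscosity > 0`.
#' @param z0 Initial depth in metres.
#' @param duration Integration time in seconds.
#' @param dt Output sampling interval in seconds.
#' @param gravity Include the gravity/buoyancy term (default FALSE).
#' @param v0 Initial velocity in m/s (default 0).
#' @return A data.frame with columns `t`, `z`, `v`.
#' @export
integrate_bead_eom <- function(force_profile, bead, fluid, z0, duration, dt,
                               gravity = FALSE, v0 = 0) {
  stopifnot(inherits(bead, "bead_spec"), inherits(fluid, "medium_spec"),
            fluid$viscosity > 0, duration > 0, dt > 0)
  f_of_z <- if (is.function(force_profile)) {
    force_profile
  } else {
    fv <- force_profile
    function(z) rep(fv, length(z))
  }
  a <- bead_radius(bead)
  m <- bead_mass(bead)
  drag <- 6 * pi * fluid$viscosity * a
  f_buoy <- if (gravity) {
    9.80665 * (4 / 3) * pi * a^3 * (bead$density - fluid$density)
  } else 0
  deriv <- function(t, y, parms) {
    fz <- f_of_z(y[1])
    if (!is.finite(fz)) stop("non-finite force value at z = ", y[1])
    list(c(y[2], (fz - drag * y[2] + f_buoy) / m))
  }
  times <- seq(0, duration, by = dt)
  sol <- deSolve::lsoda(c(z = z0, v = v0), times, deriv, parms = NULL,
                        rtol = 1e-10, atol = c(1e-15, 1e-12))
  data.frame(t = sol[, "time"], z = sol[, "z"], v = sol[, "v"])
}
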