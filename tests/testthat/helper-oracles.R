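# Independent oracles and shared fixtures for the test suite.

# Damped complex Newton inversion of the oscillating-sphere relation.
# Independent of the package's fixed-point path: iterates on the analytic
# residual f(G) = G - i a w sqrt(rho G) - w^2 rho a^2 / 9 - g_eff with
# f'(G) = 1 - i k a / 2.
newton_invert_geff <- function(g_eff, omega, radius, rho, tol = 1e-13,
                               max_iter = 100) {
  g <- as.complex(g_eff)
  for (i in seq_len(max_iter)) {
    sq <- sqrt(as.complex(rho * g))
    if (Re(sq) < 0) sq <- -sq
    f <- g - 1i * radius * omega * sq - omega^2 * rho * radius^2 / 9 -
      g_eff
    k <- omega * sqrt(as.complex(rho) / g)
    if (Re(k) < 0) k <- -k
    fp <- 1 - 1i * k * radius / 2
    step <- f / fp
    # damping: halve the step until |G| stays away from zero
    while (Mod(g - step) < 0.1 * Mod(g)) step <- step / 2
    g_new <- g - step
    if (Mod(g_new - g) < tol * Mod(g_new)) return(g_new)
    g <- g_new
  }
  g
}

# Frozen reference values from an independent Mie implementation built on
# scipy.special spherical Bessel functions (spherical_jn / spherical_yn).
mie_reference <- list(
  # x = 2 pi * 1.33 * 0.95e-6 / 789e-9, m = 1.68 / 1.33
  default_bead = list(x = 10.0618563189, m = 1.2631578947,
                      q_ext = 3.1920212497, q_pr = 0.4670134904),
  small = list(x = 5.0, m = 1.2,
               q_ext = 1.7699741857, q_pr = 0.1886877084)
)

# Single-voxel BM-mode stack whose phase encodes the displacement d_t (m),
# with optional per-frame phase noise.
make_voxel_stack <- function(d_t, frame_rate = 425, f_mod = 20,
                             drive_phase = 0, oct_wavelength = 1300e-9,
                             medium_index = 1.34, mag = 100,
                             sigma_phi = 0, n_z = 1, n_x = 1) {
  n_t <- length(d_t)
  phase <- 4 * pi * medium_index / oct_wavelength * d_t
  ph <- matrix(phase, n_t, n_z * n_x)
  if (sigma_phi > 0) {
    ph <- ph + matrix(rnorm(n_t * n_z * n_x, sd = sigma_phi), n_t)
  }
  field <- array(mag * exp(1i * ph), c(n_t, n_z, n_x))
  bm_stack(field, frame_rate, f_mod, drive_phase = drive_phase,
           oct_wavelength = oct_wavelength, medium_index = medium_index,
           noise_level = 1)
}

# Synthetic constant-velocity streak image: Gaussian ridge z = z0 + v t.
make_streak_image <- function(v, n_t = 200, n_z = 80, dt = 1 / 425,
                              dz = 0.5e-6, z0 = 10e-6,
                              psf_sigma = 1.5e-6, noise = 0) {
  tt <- (seq_len(n_t) - 1) * dt
  zs <- (seq_len(n_z) - 0.5) * dz
  ztrue <- z0 + v * tt
  img <- exp(-outer(ztrue, zs, `-`)^2 / (2 * psf_sigma^2))
  if (noise > 0) img <- pmax(img + abs(matrix(rnorm(length(img),
                                                    sd = noise),
                                              n_t)), 0)
  trajectory_image(img, dt, dz)
}

# All permutations of 1..n as a matrix (n! rows), recursive construction.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# Default bead / medium / beam triple used across tests.
default_bead <- function() bead_spec(1.9e-6, material = "melamine")
default_medium <- function() medium_spec(1.33)
glycerol_water <- function() medium_spec(1.3469, 1021, 1.31e-3)
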