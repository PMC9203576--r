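# Forward generators for every input the pipeline consumes, with known
# ground truth. The defaults reproduce the study conditions: 425-Hz
# BM-mode frames, 20-Hz force modulation, 0.75-um pixels, 28-dB bead SNR,
# 1300-nm OCT centre wavelength in a medium of index 1.34.

#' Analytic elliptical-Gaussian force profile
#'
#' A separable stand-in for the full GLMT force map: peak force at the
#' focus with Gaussian lateral (long-axis) and axial fall-offs of the
#' stated FWHMs. Useful as a fast, exactly known `F_rad(x, z)` for
#' synthetic scenes.
#'
#' @param peak Peak force in newtons (default 3 pN).
#' @param fwhm_x Lateral FWHM in metres (default 80 um).
#' @param fwhm_z Axial FWHM in metres (default 80 um).
#' @param grid_x,grid_z Output grids in metres.
#' @param z_focus Depth of the focus in metres (default mid-grid).
#' @return A [force_profile()] with `provenance = "simulated"`.
#' @export
gaussian_force_profile <- function(peak = 3e-12, fwhm_x = 80e-6,
                                   fwhm_z = 80e-6,
                                   grid_x = seq(-60e-6, 60e-6, 2e-6),
                                   grid_z = seq(0, 80e-6, 2e-6),
                                   z_focus = NULL) {
  if (is.null(z_focus)) z_focus <- mean(range(grid_z))
  sx <- fwhm_x / (2 * sqrt(2 * log(2)))
  sz <- fwhm_z / (2 * sqrt(2 * log(2)))
  f <- peak * outer(exp(-grid_x^2 / (2 * sx^2)),
                    exp(-(grid_z - z_focus)^2 / (2 * sz^2)))
  force_profile(grid_x, grid_z, f, provenance = "simulated")
}

#' Ground-truth container for a synthetic scene
#'
#' @param positions Matrix `n x 3` of bead centroids `(x, y, z)` in metres.
#' @param g_star Complex G* per bead in Pa.
#' @param force_map A [force_profile()] giving `F_rad(x, z)`.
#' @param pt_amplitude Photothermal displacement amplitude (m) at the beam
#'   centre and maximum depth; 0 disables the PT field.
#' @param pt_phase PT phase shift w.r.t. the drive waveform in radians.
#' @param pt_depth Depth dependence of the cumulative PT optical path:
#'   `"linear"` (matches the reconstruction model) or `"quadratic"`
#'   (model-mismatch variant).
#' @param snr_bead_db Bead-voxel OCT SNR in dB (default 28).
#' @param snr_bg_db Medium-scatter OCT SNR in dB (default 16).
#' @param seed Integer seed; the scene is reproducible given the seed.
#' @return An object of class `scene_truth`.
#' @export
scene_truth <- function(positions, g_star, force_map,
                        pt_amplitude = 0, pt_phase = 0.5,
                        pt_depth = c("linear", "quadratic"),
                        snr_bead_db = 28, snr_bg_db = 16, seed = 1) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, nrow(positions) == length(g_star))
  structure(
    list(positions = positions, g_star = as.complex(g_star),
         force_map = force_map, pt_amplitude = pt_amplitude,
         pt_phase = pt_phase, pt_depth = match.arg(pt_depth),
         snr_bead_db = snr_bead_db, snr_bg_db = snr_bg_db, seed = seed),
    class = "scene_truth"
  )
}

#' Generate synthetic BM-mode stacks with known ground truth
#'
#' Forward-composes the whole measurement model: each bead's mechanical
#' phasor follows from its true G* and the local radiation force through
#' the oscillating-sphere model; bead reflectors (3x3x3 voxel clusters)
#' modulate the OCT phase accordingly; every voxel additionally carries a
#' depth-cumulative photothermal phase modulation shaped like the
#' light-sheet long-axis intensity; static speckle gives each voxel a
#' random static phase; and per-frame phase noise of standard deviation
#' `1/sqrt(SNR)` emulates the shot-noise limit.
#'
#' @param truth A [scene_truth()].
#' @param plan An [acquisition_plan()]; `n_frames`, `frame_rate`,
#'   `fast_range`, `pixel_size`, `depth_range`, `oct_wavelength`,
#'   `medium_index` are used.
#' @param beam A [light_sheet_beam()]; sets `f_mod` and the PT lateral
#'   shape.
#' @param bead A [bead_spec()].
#' @param medium A [medium_spec()]; density enters the forward response.
#' @param slow_positions Slow-axis positions (m) to simulate; default the
#'   minimal contiguous set covering all beads at `plan$slow_step` pitch.
#' @param drive_phase Drive waveform phase at `t = 0` (default 0).
#' @return List with `stacks` (list of [bm_stack()]) and `truth` (the
#'   input truth augmented with per-bead `force`, `a_mech`, `phi_mech`).
#' @export
gen_bm_stack <- function(truth, plan, beam, bead, medium,
                         slow_positions = NULL, drive_phase = 0) {
  stopifnot(inherits(truth, "scene_truth"),
            inherits(plan, "acquisition_plan"))
  px <- plan$pixel_size
  n_x <- max(3L, round(plan$fast_range / px))
  n_z <- max(3L, round(plan$depth_range / px))
  n_t <- plan$n_frames
  if (is.null(slow_positions)) {
    yr <- range(truth$positions[, 2])
    slow_positions <- seq(yr[1] - px, yr[2] + px, by = px)
  }
  omega <- 2 * pi * beam$modulation_frequency
  n_beads <- nrow(truth$positions)
  f_at <- interp_force(truth$force_map, truth$positions[, 1],
                       truth$positions[, 3])
  if (any(!is.finite(f_at))) stop("bead outside the force map support")
  p_mech <- complex(n_beads)
  for (b in seq_len(n_beads)) {
    resp <- response_from_modulus(truth$g_star[b], f_at[b], omega, bead,
                                  medium$density)
    p_mech[b] <- resp$amplitude * exp(1i * resp$phase_shift)
  }
  lam <- plan$oct_wavelength
  n_med <- plan$medium_index
  phase_per_m <- 4 * pi * n_med / lam
  if (any(Mod(p_mech) + truth$pt_amplitude > lam / (8 * n_med))) {
    warning("bead oscillation amplitude approaches the lambda/4 ",
            "unwrapping margin")
  }
  xs <- (seq_len(n_x) - 0.5) * px
  zs <- (seq_len(n_z) - 0.5) * px
  # PT complex displacement field (z, x), cumulative in depth
  # lateral PT shape follows the sheet long-axis intensity, centred on
  # the grid midpoint
  lshape <- exp(-(xs - mean(xs))^2 /
                  (2 * (beam$fwhm_long / (2 * sqrt(2 * log(2))))^2))
  dshape <- switch(truth$pt_depth,
                   linear = zs / max(zs),
                   quadratic = (zs / max(zs))^2)
  p_pt <- truth$pt_amplitude * exp(1i * truth$pt_phase) *
    outer(dshape, lshape)
  tt <- (seq_len(n_t) - 1) / plan$frame_rate
  cos_t <- cos(omega * tt + drive_phase)
  sin_t <- sin(omega * tt + drive_phase)
  mag_bead <- 10^(truth$snr_bead_db / 20)
  mag_bg <- 10^(truth$snr_bg_db / 20)
  stacks <- with_seed(truth$seed, {
    lapply(slow_positions, function(y0) {
      # per-voxel complex displacement phasor and magnitude
      p_tot <- p_pt
      mag <- matrix(mag_bg, n_z, n_x)
      sel <- which(abs(truth$positions[, 2] - y0) <= px + 1e-12)
      for (b in sel) {
        iz <- round(truth$positions[b, 3] / px + 0.5)
        ix <- round(truth$positions[b, 1] / px + 0.5)
        zi <- max(1, iz - 1):min(n_z, iz + 1)
        xi <- max(1, ix - 1):min(n_x, ix + 1)
        p_tot[zi, xi] <- p_tot[zi, xi] + p_mech[b]
        mag[zi, xi] <- mag_bead
      }
      static <- matrix(stats::runif(n_z * n_x, -pi, pi), n_z, n_x)
      sigma_phi <- 1 / mag  # 1/sqrt(SNR_linear)
      pv <- as.vector(p_tot)
      phase <- outer(cos_t, Re(pv)) - outer(sin_t, Im(pv))
      phase <- phase * phase_per_m
      phase <- sweep(phase, 2, as.vector(static), `+`)
      phase <- phase + matrix(stats::rnorm(n_t * n_z * n_x), n_t) *
        rep(as.vector(sigma_phi), each = n_t)
      field <- array(
        rep(as.vector(mag), each = n_t) * exp(1i * phase),
        c(n_t, n_z, n_x)
      )
      bm_stack(field, plan$frame_rate, beam$modulation_frequency,
               drive_phase = drive_phase, pixel_z = px, pixel_x = px,
               slow_position = y0, oct_wavelength = lam,
               medium_index = n_med, noise_level = 1)
    })
  })
  truth$force <- f_at
  truth$a_mech <- Mod(p_mech)
  truth$phi_mech <- Arg(p_mech)
  list(stacks = stacks, truth = truth)
}

#' Render a space-time trajectory movie of a bead in viscous fluid
#'
#' Integrates the 1D equation of motion under a known force-depth profile
#' and renders the trajectory as a streak with a Gaussian axial point
#' spread function plus additive noise.
#'
#' @param force_fn Function `F(z)` in newtons (or a constant).
#' @param bead A [bead_spec()].
#' @param fluid A [medium_spec()] with `viscosity > 0`.
#' @param z0 Starting depth in metres.
#' @param duration Movie duration in seconds.
#' @param dt Frame interval in seconds (default 1/425).
#' @param dz Depth pixel pitch in metres (default 0.5 um).
#' @param depth_range Rendered depth window in metres (default 80 um).
#' @param psf_sigma Axial PSF standard deviation in metres
#'   (default 1.5 um).
#' @param noise_db Peak-signal-to-noise of the rendering in dB
#'   (default 20).
#' @param gravity Include gravity/buoyancy in the integration
#'   (default TRUE).
#' @param x_position Lateral position tag in metres.
#' @param seed Integer seed.
#' @return List with `image` (a [trajectory_image()]), `kinematics` (the
#'   true sampled `t, z, v`), and `truncated` (TRUE when the bead left the
#'   window).
#' @export
gen_trajectory_movie <- function(force_fn, bead, fluid, z0,
                                 duration = 0.5, dt = 1 / 425,
                                 dz = 0.5e-6, depth_range = 80e-6,
                                 psf_sigma = 1.5e-6, noise_db = 20,
                                 gravity = TRUE, x_position = 0,
                                 seed = 1) {
  kin <- integrate_bead_eom(force_fn, bead, fluid, z0, duration, dt,
                            gravity = gravity)
  n_z <- round(depth_range / dz)
  zs <- (seq_len(n_z) - 0.5) * dz
  truncated <- any(kin$z < 0 | kin$z > depth_range)
  img <- with_seed(seed, {
    I <- exp(-outer(kin$z, zs, `-`)^2 / (2 * psf_sigma^2))
    noise <- abs(matrix(stats::rnorm(length(I), sd = 10^(-noise_db / 20)),
                        nrow(I)))
    pmax(I + noise, 0)
  })
  list(image = trajectory_image(img, dt, dz, x_position),
       kinematics = kin, truncated = truncated)
}

#' Generate a synthetic pericellular stiffness scene
#'
#' A spherical dynamic-speckle cell surrounded by beads at uniform random
#' positions; the true stiffness follows a power law of distance to the
#' cell surface, `G'(r) = G_bg (r / 30 um)^beta` for `r <= 30 um` and
#' `G_bg` beyond, with lognormal multiplicative scatter.
#'
#' @param beta Decay exponent (default -0.19).
#' @param g_background Background storage modulus in Pa (default 150).
#' @param loss_ratio_bg Background loss ratio (default 0.4).
#' @param cell_radius Cell radius in metres (default 15 um).
#' @param n_beads Number of beads (default 400, >= 10).
#' @param r_maxima Outer sampling radius beyond the cell surface in
#'   metres (default 60 um).
#' @param cv Coefficient of variation of the lognormal scatter
#'   (default 0.25).
#' @param pericell_cutoff Power-law domain bound in metres (default
#'   30 um).
#' @param seed Integer seed.
#' @return List with `records` (a `bead_record`-style data.frame with
#'   `r` appended), `cell` (centre + radius) and `truth` (generator
#'   parameters).
#' @export
gen_pericellular_scene <- function(beta = -0.19, g_background = 150,
                                   loss_ratio_bg = 0.4,
                                   cell_radius = 15e-6, n_beads = 400,
                                   r_maxima = 60e-6, cv = 0.25,
                                   pericell_cutoff = 30e-6, seed = 1) {
  stopifnot(n_beads >= 10)
  with_seed(seed, {
    r_out <- cell_radius + r_maxima
    pos <- matrix(NA_real_, 0, 3)
    while (nrow(pos) < n_beads) {
      cand <- matrix(stats::runif(3 * 2 * n_beads, -r_out, r_out), ncol = 3)
      rad <- sqrt(rowSums(cand^2))
      cand <- cand[rad > cell_radius + 1e-6 & rad < r_out, , drop = FALSE]
      pos <- rbind(pos, cand)
    }
    pos <- pos[seq_len(n_beads), , drop = FALSE]
    r <- sqrt(rowSums(pos^2)) - cell_radius
    g_true <- ifelse(r <= pericell_cutoff,
                     g_background * (r / pericell_cutoff)^beta,
                     g_background)
    sdlog <- sqrt(log(1 + cv^2))
    g_obs <- g_true * stats::rlnorm(n_beads, -sdlog^2 / 2, sdlog)
    loss <- loss_ratio_bg * stats::rlnorm(n_beads, -sdlog^2 / 2, sdlog)
    records <- data.frame(id = seq_len(n_beads), xc = pos[, 1],
                          yc = pos[, 2], zc = pos[, 3],
                          a_mech = NA_real_, phi_mech = NA_real_,
                          force = NA_real_, g_prime = g_obs,
                          g_double_prime = g_obs * loss,
                          loss_ratio = loss, n_voxels = NA_integer_,
                          qc = "", r = r)
    list(records = records,
         cell = list(centre = c(0, 0, 0), radius = cell_radius),
         truth = list(beta = beta, g_background = g_background,
                      g_true = g_true, cv = cv, seed = seed))
  })
}

#' Generate a synthetic fibre volume with planted shell metrics
#'
#' Renders straight cylindrical fibres with intensity proportional to
#' their thickness on a dim background, plants beads, and records the
#' per-bead truth (fibre occupancy of each shell) directly from the
#' rendering. With `shell_fraction` set, fibre voxels are instead planted
#' as an exact random fraction of each bead's shell, giving an exactly
#' known fibre volume fraction.
#'
#' @param dims Volume dimensions `(n_z, n_x, n_y)` in voxels
#'   (default `c(40, 40, 40)`).
#' @param voxel_size Isotropic voxel pitch in metres (default 0.75 um).
#' @param n_fibres Number of fibres (default 30).
#' @param fibre_radius Fibre radius in metres (default 0.6 um).
#' @param fibre_snr_db Intensity of fibre voxels in dB over the noise
#'   level; a length-2 range is sampled per fibre in proportion to
#'   thickness (default `c(14, 20)`).
#' @param shell_snr_db Intensity of non-fibre shell voxels in dB
#'   (default 8; above the 6-dB noise floor, below the 14-dB fibre
#'   threshold).
#' @param bg_snr_db Background intensity in dB (default 8, above the
#'   6-dB noise floor as in a weakly scattering matrix).
#' @param n_beads Number of beads (default 20).
#' @param bead_diameter Bead diameter in metres (default 1.9 um).
#' @param shell Shell thickness for the truth bookkeeping (default 3 um).
#' @param shell_fraction Optional exact fibre occupancy of each shell in
#'   `[0, 1]`; overrides the cylinder renderer inside the shells.
#' @param seed Integer seed.
#' @return List with `volume` (intensity array), `centroids`
#'   (data.frame `xc, yc, zc`), `fibre_mask`, `truth` (per-bead shell
#'   fraction and local density), `noise_level`.
#' @export
gen_fibre_volume <- function(dims = c(40, 40, 40), voxel_size = 0.75e-6,
                             n_fibres = 30, fibre_radius = 0.6e-6,
                             fibre_snr_db = c(14, 20), shell_snr_db = 8,
                             bg_snr_db = 8, n_beads = 20,
                             bead_diameter = 1.9e-6, shell = 3e-6,
                             shell_fraction = NULL, seed = 1) {
  with_seed(seed, {
    ext <- dims * voxel_size
    zc <- (seq_len(dims[1]) - 0.5) * voxel_size
    xc <- (seq_len(dims[2]) - 0.5) * voxel_size
    yc <- (seq_len(dims[3]) - 0.5) * voxel_size
    vol <- array(10^(bg_snr_db / 20), dims)
    fibre_mask <- array(FALSE, dims)
    a <- bead_diameter / 2
    margin <- a + shell + voxel_size
    # bead centres with minimum separation 2 * (a + shell)
    cent <- matrix(NA_real_, 0, 3)
    tries <- 0
    while (nrow(cent) < n_beads && tries < 5000) {
      tries <- tries + 1
      p <- stats::runif(3, margin, ext - margin)
      if (nrow(cent) == 0 ||
          min(sqrt(colSums((t(cent) - p)^2))) > 2 * (a + shell)) {
        cent <- rbind(cent, p)
      }
    }
    n_beads <- nrow(cent)
    centroids <- data.frame(zc = cent[, 1], xc = cent[, 2], yc = cent[, 3])
    dist_to <- function(i) {
      sqrt(outer(outer((zc - cent[i, 1])^2, (xc - cent[i, 2])^2, `+`),
                 (yc - cent[i, 3])^2, `+`))
    }
    if (is.null(shell_fraction)) {
      # random cylinders, intensity proportional to thickness
      grid <- expand.grid(z = zc, x = xc, y = yc)
      for (f in seq_len(n_fibres)) {
        p0 <- stats::runif(3, 0, ext)
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        rad <- fibre_radius * stats::runif(1, 0.7, 1.5)
        rel <- cbind(grid$z - p0[1], grid$x - p0[2], grid$y - p0[3])
        proj <- rel %*% dir
        perp2 <- rowSums(rel^2) - proj^2
        inside <- perp2 <= rad^2
        if (!any(inside)) next
        snr <- fibre_snr_db[1] + (fibre_snr_db[2] - fibre_snr_db[1]) *
          (rad - 0.7 * fibre_radius) / (0.8 * fibre_radius)
        vol[inside] <- pmax(vol[inside], 10^(snr / 20))
        fibre_mask[inside] <- TRUE
      }
      truth_frac <- numeric(n_beads)
      for (i in seq_len(n_beads)) {
        di <- dist_to(i)
        in_shell <- di > a & di <= a + shell
        truth_frac[i] <- mean(fibre_mask[in_shell])
      }
    } else {
      truth_frac <- numeric(n_beads)
      for (i in seq_len(n_beads)) {
        di <- dist_to(i)
        in_shell <- which(di > a & di <= a + shell)
        vol[in_shell] <- 10^(shell_snr_db / 20)
        k <- round(shell_fraction * length(in_shell))
        pick <- sample(in_shell, k)
        vol[pick] <- 10^(mean(fibre_snr_db) / 20)
        fibre_mask[pick] <- TRUE
        truth_frac[i] <- k / length(in_shell)
      }
    }
    # plant bright beads
    for (i in seq_len(n_beads)) {
      di <- dist_to(i)
      vol[di <= a] <- 10^(30 / 20)
    }
    list(volume = vol, centroids = centroids, fibre_mask = fibre_mask,
         truth = list(shell_fraction = truth_frac, seed = seed),
         noise_level = 1, voxel_size = rep(voxel_size, 3))
  })
}
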