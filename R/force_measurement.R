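# Radiation-pressure force calibration from space-time bead trajectories.
#
# A bead sedimenting/pushed through viscous fluid traces a streak in the
# (time, depth) intensity image. The local streak slope gives the axial
# velocity; the overdamped equation of motion then yields the force.

#' Space-time trajectory image
#'
#' @param data Non-negative intensity matrix, rows = time samples,
#'   columns = depth pixels.
#' @param dt Frame interval in seconds.
#' @param dz Depth pixel pitch in metres.
#' @param x_position Lateral position of this segment in metres.
#' @return An object of class `trajectory_image`.
#' @export
trajectory_image <- function(data, dt, dz, x_position = 0) {
  data <- as.matrix(data)
  stopifnot(dt > 0, dz > 0, all(data >= 0))
  structure(list(data = data, dt = dt, dz = dz, x_position = x_position),
            class = "trajectory_image")
}

# bilinear sample of matrix W at fractional (row, col); NA outside
bilinear_sample <- function(W, r, c) {
  nr <- nrow(W); nc <- ncol(W)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 <= nr - 1 & c0 <= nc - 1
  out <- rep(NA_real_, length(r))
  if (any(ok)) {
    i00 <- (c0[ok] - 1) * nr + r0[ok]
    v <- (1 - fr[ok]) * (1 - fc[ok]) * W[i00] +
      fr[ok] * (1 - fc[ok]) * W[i00 + 1] +
      (1 - fr[ok]) * fc[ok] * W[i00 + nr] +
      fr[ok] * fc[ok] * W[i00 + nr + 1]
    out[ok] <- v
  }
  out
}

# Radon-style projection variance: rotate the window so a streak of angle
# `theta` (radians, slope = tan(theta) columns per row) becomes parallel to
# the row axis, project by averaging along rows, and return the variance of
# the projection. A straight streak maximises this variance at its own
# angle.
projection_variance <- function(W, theta) {
  nr <- nrow(W); nc <- ncol(W)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  p <- seq_len(nr) - cr                 # along assumed streak direction
  qmax <- floor(min(nr, nc) / 2 * 0.75)
  q <- seq(-qmax, qmax)                 # across streaks
  ct <- cos(theta); st <- sin(theta)
  rr <- outer(p * ct, -q * st, `+`) + cr
  cc2 <- outer(p * st, q * ct, `+`) + cc
  vals <- matrix(bilinear_sample(W, as.vector(rr), as.vector(cc2)),
                 nrow = length(p))
  nvalid <- colSums(!is.na(vals))
  proj <- colMeans(vals, na.rm = TRUE)
  keep <- nvalid >= 0.6 * length(p)
  if (sum(keep) < 3) return(NA_real_)
  stats::var(proj[keep])
}

# slope (columns per row, i.e. depth px per frame) of the dominant streak,
# with parabolic sub-grid refinement of the variance peak; returns slope and
# a [0,1] contrast-based quality
streak_slope <- function(W, angle_grid_deg) {
  th <- angle_grid_deg * pi / 180
  v <- vapply(th, function(t) projection_variance(W, t), numeric(1))
  if (all(!is.finite(v))) return(list(slope = NA_real_, quality = 0))
  i <- which.max(v)
  vmed <- stats::median(v, na.rm = TRUE)
  quality <- if (v[i] > 0) max(0, 1 - vmed / v[i]) else 0
  th_hat <- th[i]
  if (i > 1 && i < length(th) && is.finite(v[i - 1]) && is.finite(v[i + 1])) {
    denom <- v[i - 1] - 2 * v[i] + v[i + 1]
    if (denom < 0) {
      th_hat <- th[i] + 0.5 * (v[i - 1] - v[i + 1]) / denom *
        (th[i + 1] - th[i])
    }
  }
  list(slope = tan(th_hat), quality = quality)
}

#' Extract bead kinematics from a space-time trajectory image
#'
#' Tracks the bead depth by intensity centroid, then estimates the local
#' axial velocity in sliding windows as the Radon-transform
#' maximum-variance projection angle (streak slope). Velocity is smoothed
#' with a Savitzky-Golay filter and acceleration is the analytic derivative
#' of the local quadratic fit.
#'
#' @param img A [trajectory_image()].
#' @param window Integer `(n_t, n_z)`: sliding-window extent in time
#'   samples and depth pixels (default `c(32, 24)`).
#' @param angle_grid Angles in degrees to scan for the streak slope
#'   (default `seq(-80, 80, by = 0.25)`).
#' @param quality_threshold Windows whose Radon peak contrast falls below
#'   this value get quality 0 (default 0.2).
#' @param sg_window Savitzky-Golay window length (odd, default 11).
#' @return A data.frame of class `kinematics` with columns `t`, `z`, `v`,
#'   `accel`, `quality`.
#' @export
extract_kinematics <- function(img, window = c(32, 24),
                               angle_grid = seq(-80, 80, by = 0.25),
                               quality_threshold = 0.2, sg_window = 11) {
  stopifnot(inherits(img, "trajectory_image"))
  W <- img$data
  n_t <- nrow(W); n_z <- ncol(W)
  stopifnot(window[1] <= n_t, window[2] <= n_z)
  Wb <- pmax(W - stats::median(W), 0)
  W2 <- Wb^2
  hz <- window[2] %/% 2
  # depth track: centroid restricted to a window around the per-frame
  # intensity peak, so a uniform noise background cannot pull the track
  # toward the image centre
  pk <- max.col(W2, ties.method = "first")
  pkv <- Wb[cbind(seq_len(n_t), pk)]
  # frames without a clear bead (left the window, or pure noise) and
  # frames whose peak hugs the depth boundary (clipped point spread
  # function) are gated out
  med_pk <- stats::median(pkv[pkv > 0])
  present <- is.finite(med_pk) & pkv > 0.4 * med_pk &
    pk > hz %/% 2 & pk <= n_z - hz %/% 2
  zc <- rep(NA_real_, n_t)
  for (t in seq_len(n_t)) {
    cols <- max(1, pk[t] - hz):min(n_z, pk[t] + hz)
    tot <- sum(W2[t, cols])
    if (tot > 0) zc[t] <- sum(W2[t, cols] * cols) / tot
  }
  zc[!present] <- NA_real_
  if (sum(!is.na(zc)) < 2) {
    zc <- rep((n_z + 1) / 2, n_t)     # featureless image: no streak
    present <- rep(FALSE, n_t)
  } else {
    zc <- stats::approx(seq_len(n_t)[!is.na(zc)], zc[!is.na(zc)],
                        xout = seq_len(n_t), rule = 2)$y
  }
  zc <- stats::runmed(zc, 2 * (min(sg_window, n_t - 2) %/% 2) + 1)
  # sliding Radon windows, 50% overlap
  ht <- window[1] %/% 2
  centers <- unique(pmin(pmax(seq(ht + 1, n_t - ht, by = max(1, ht)),
                              ht + 1), n_t - ht))
  vw <- numeric(length(centers)); qw <- numeric(length(centers))
  for (k in seq_along(centers)) {
    tc <- centers[k]
    rows <- (tc - ht):(tc + ht - 1 + window[1] %% 2)
    if (mean(present[rows]) < 0.8) {
      vw[k] <- NA_real_; qw[k] <- 0
      next
    }
    z0 <- round(zc[tc])
    cols <- max(1, z0 - hz):min(n_z, z0 + hz)
    sub <- Wb[rows, cols, drop = FALSE]
    res <- streak_slope(sub, angle_grid)
    q <- if (is.na(res$slope) || res$quality < quality_threshold) 0 else
      res$quality
    vw[k] <- if (q > 0) res$slope * img$dz / img$dt else NA_real_
    qw[k] <- q
  }
  t_all <- (seq_len(n_t) - 1) * img$dt
  good <- qw > 0
  if (sum(good) >= 2) {
    v <- stats::approx(t_all[centers[good]], vw[good], xout = t_all,
                       rule = 2)$y
    quality <- stats::approx(t_all[centers[good]], qw[good], xout = t_all,
                             rule = 2)$y
  } else if (sum(good) == 1) {
    v <- rep(vw[good], n_t); quality <- rep(qw[good], n_t)
  } else {
    v <- rep(0, n_t); quality <- rep(0, n_t)
  }
  # smooth v and differentiate for acceleration
  n_sg <- min(sg_window, n_t - (1 - n_t %% 2))
  n_sg <- max(5, 2 * (n_sg %/% 2) + 1)
  if (n_t >= n_sg) {
    v <- signal::sgolayfilt(v, p = 2, n = n_sg)
    accel <- signal::sgolayfilt(v, p = 2, n = n_sg, m = 1, ts = img$dt)
  } else {
    accel <- c(0, diff(v)) / img$dt
  }
  quality[!present] <- 0
  structure(
    data.frame(t = t_all, z = (zc - 1) * img$dz, v = v, accel = accel,
               quality = quality),
    class = c("kinematics", "data.frame")
  )
}

#' Recover the axial force profile from bead kinematics
#'
#' Inverts the 1D equation of motion of the bead in viscous fluid,
#' `F_rad(z(t)) = m a(t) + 6 pi eta a v(t) - g (4/3) pi a^3 (rho_b -
#' rho_f)` (gravity term only when requested), and resamples onto a regular
#' depth grid by quality-weighted averaging.
#'
#' @param kin A `kinematics` data.frame from [extract_kinematics()].
#' @param bead A [bead_spec()].
#' @param fluid A [medium_spec()] with `viscosity > 0`; defaults for the
#'   glycerol-water calibration are `medium_spec(1.3469, 1021, 1.31e-3)`.
#' @param gravity Include the gravity/buoyancy term (default TRUE, the
#'   calibration geometry).
#' @param z_grid Optional regular output grid in metres; default 24 bins
#'   spanning the sampled depths.
#' @return A data.frame with columns `z`, `force`, `weight`, `n`.
#' @export
recover_force_profile <- function(kin, bead, fluid, gravity = TRUE,
                                  z_grid = NULL) {
  stopifnot(inherits(kin, "data.frame"), fluid$viscosity > 0)
  if (all(kin$quality <= 0)) stop("trajectory unusable: all-zero quality")
  a <- bead_radius(bead)
  m <- bead_mass(bead)
  drag <- 6 * pi * fluid$viscosity * a
  f_buoy <- if (gravity) {
    9.80665 * (4 / 3) * pi * a^3 * (bead$density - fluid$density)
  } else 0
  f_t <- m * kin$accel + drag * kin$v - f_buoy
  keep <- kin$quality > 0
  if (is.null(z_grid)) {
    zr <- range(kin$z[keep])
    z_grid <- if (diff(zr) > 0) seq(zr[1], zr[2], length.out = 24)
              else zr[1]
  }
  dzg <- if (length(z_grid) > 1) diff(z_grid[1:2]) else 1
  idx <- round((kin$z - z_grid[1]) / dzg) + 1
  idx[!is.finite(idx)] <- 1L
  ok <- keep & idx >= 1 & idx <= length(z_grid)
  wsum <- tapply(kin$quality[ok], idx[ok], sum)
  fsum <- tapply((f_t * kin$quality)[ok], idx[ok], sum)
  nn <- tapply(rep(1, sum(ok)), idx[ok], sum)
  force <- rep(NA_real_, length(z_grid))
  weight <- rep(0, length(z_grid))
  n <- rep(0L, length(z_grid))
  ii <- as.integer(names(wsum))
  force[ii] <- fsum / wsum
  weight[ii] <- wsum
  n[ii] <- as.integer(nn)
  data.frame(z = z_grid, force = force, weight = weight, n = n)
}

#' Assemble per-segment depth profiles into a 2D force map
#'
#' Stacks force-depth profiles measured at different lateral segments into
#' a `F_rad(x, z)` map. All profiles must share one depth grid; missing
#' cells stay `NA`. Negative noise excursions are clipped at zero.
#'
#' @param profiles A list; each element a list with `x` (lateral position,
#'   metres) and `profile` (data.frame from [recover_force_profile()]).
#' @param smooth_x Optional odd window for a lateral running mean
#'   (default 0 = none).
#' @return A [force_profile()] with `provenance = "measured"`.
#' @export
assemble_force_map <- function(profiles, smooth_x = 0) {
  stopifnot(length(profiles) >= 1)
  z <- profiles[[1]]$profile$z
  for (p in profiles) {
    if (length(p$profile$z) != length(z) ||
        any(abs(p$profile$z - z) > 1e-12)) {
      stop("inconsistent depth grids across segments")
    }
  }
  xs <- vapply(profiles, function(p) p$x, numeric(1))
  ord <- order(xs)
  f <- t(vapply(profiles[ord], function(p) p$profile$force,
                numeric(length(z))))
  if (smooth_x >= 3) {
    h <- smooth_x %/% 2
    fs <- f
    for (i in seq_len(nrow(f))) {
      rows <- max(1, i - h):min(nrow(f), i + h)
      fs[i, ] <- colMeans(f[rows, , drop = FALSE], na.rm = TRUE)
    }
    f <- fs
  }
  f[!is.na(f) & f < 0] <- 0
  force_profile(xs[ord], z, f, provenance = "measured")
}
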