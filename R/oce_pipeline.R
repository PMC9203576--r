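# Phase-sensitive OCE reconstruction: demodulation of BM-mode stacks into
# per-voxel phasors, phase registration, segmentation, photothermal (PT)
# reconstruction/compensation, bead clustering, and per-bead modulus
# mapping.

#' BM-mode complex OCT stack at one slow-axis position
#'
#' @param field Complex array `(n_t, n_z, n_x)`: time, depth, fast axis.
#' @param frame_rate BM-mode frame rate in Hz.
#' @param f_mod Radiation-pressure modulation frequency in Hz; must be
#'   below the Nyquist rate.
#' @param drive_phase Phase of the drive waveform at `t = 0` in radians.
#' @param pixel_z,pixel_x Voxel pitch in metres.
#' @param slow_position Slow-axis position in metres.
#' @param oct_wavelength OCT centre wavelength in metres.
#' @param medium_index Refractive index converting phase to displacement.
#' @param noise_level OCT magnitude noise floor (a.u.); when `NULL` it is
#'   estimated from the darkest voxels at demodulation time.
#' @return An object of class `bm_stack`.
#' @export
bm_stack <- function(field, frame_rate, f_mod, drive_phase = 0,
                     pixel_z = 0.75e-6, pixel_x = 0.75e-6,
                     slow_position = 0, oct_wavelength = 1300e-9,
                     medium_index = 1.34, noise_level = NULL) {
  stopifnot(is.complex(field), length(dim(field)) == 3)
  stopifnot(dim(field)[1] >= 2, f_mod < frame_rate / 2, frame_rate > 0)
  structure(
    list(field = field, frame_rate = frame_rate, f_mod = f_mod,
         drive_phase = drive_phase, pixel_z = pixel_z, pixel_x = pixel_x,
         slow_position = slow_position, oct_wavelength = oct_wavelength,
         medium_index = medium_index, noise_level = noise_level),
    class = "bm_stack"
  )
}

#' Demodulate a BM-mode stack into a per-voxel phasor field
#'
#' Per voxel, the temporal phase of the complex OCT signal is unwrapped,
#' converted to optical-path displacement
#' `d(t) = phase(t) * lambda0 / (4 pi n)`, and fit by linear least squares
#' to `A cos(2 pi f_mod t) + B sin(2 pi f_mod t) + C` at the exact
#' modulation frequency (20 Hz is not commensurate with the frame count, so
#' a DFT bin would leak). The reported phase shift is relative to the drive
#' waveform.
#'
#' @param stack A [bm_stack()].
#' @return An object of class `phasor_field`: matrices (`n_z x n_x`)
#'   `amplitude` (m), `phase` (rad, in (-pi, pi]), `mean_mag`, `snr_db`,
#'   `residual_ratio` (amplitude standard error / amplitude), plus grid
#'   metadata.
#' @export
demodulate <- function(stack) {
  stopifnot(inherits(stack, "bm_stack"))
  d <- dim(stack$field)
  n_t <- d[1]; n_z <- d[2]; n_x <- d[3]
  if ((n_t / stack$frame_rate) * stack$f_mod < 2) {
    stop("fewer than 2 modulation cycles in the stack")
  }
  S <- matrix(stack$field, n_t, n_z * n_x)
  tt <- (seq_len(n_t) - 1) / stack$frame_rate
  # frames containing non-finite samples are excluded outright
  bad_rows <- !is.finite(rowSums(Re(S)) + rowSums(Im(S)))
  if (any(bad_rows)) {
    S <- S[!bad_rows, , drop = FALSE]
    tt <- tt[!bad_rows]
    n_t <- nrow(S)
    if (n_t < 4) stop("too few finite frames to demodulate")
  }
  # temporal unwrap via frame-to-frame phase increments
  dphi <- Arg(S[-1, , drop = FALSE] * Conj(S[-n_t, , drop = FALSE]))
  phi <- rbind(0, apply(dphi, 2, cumsum))
  disp <- phi * stack$oct_wavelength / (4 * pi * stack$medium_index)
  w <- 2 * pi * stack$f_mod
  X <- cbind(cos(w * tt), sin(w * tt), 1)
  xtx <- crossprod(X)
  coef <- solve(xtx, crossprod(X, disp))
  p <- complex(real = coef[1, ], imaginary = -coef[2, ])
  amp <- Mod(p)
  resid <- disp - X %*% coef
  # fit-quality metric: standard error of the amplitude estimate (the
  # per-frame residual propagated through the least-squares fit) over the
  # amplitude itself
  sigma_amp <- sqrt(colMeans(resid^2)) * sqrt(2 / n_t)
  rr <- sigma_amp / pmax(amp, .Machine$double.eps)
  amp_se <- matrix(sigma_amp, n_z, n_x)
  mean_mag <- colMeans(Mod(S))
  noise <- stack$noise_level
  if (is.null(noise)) {
    noise <- stats::quantile(mean_mag, 0.1, names = FALSE)
  }
  snr_db <- 20 * log10(pmax(mean_mag, .Machine$double.eps) / noise)
  structure(
    list(amplitude = matrix(amp, n_z, n_x),
         phase = matrix(wrap_phase(Arg(p) - stack$drive_phase), n_z, n_x),
         mean_mag = matrix(mean_mag, n_z, n_x),
         snr_db = matrix(snr_db, n_z, n_x),
         residual_ratio = matrix(rr, n_z, n_x),
         amp_se = amp_se,
         pixel_z = stack$pixel_z, pixel_x = stack$pixel_x,
         slow_position = stack$slow_position,
         f_mod = stack$f_mod, noise_level = noise),
    class = "phasor_field"
  )
}

#' Remove per-frame common-mode phase drift
#'
#' Estimates the common-mode phase of each frame as the argument of the
#' complex mean over reference (static, high-SNR) voxels relative to the
#' first frame, and subtracts it from every voxel of that frame.
#'
#' @param stack A [bm_stack()].
#' @param reference_mask Logical `n_z x n_x` matrix of reference voxels.
#' @return The registered [bm_stack()].
#' @export
register_phase <- function(stack, reference_mask) {
  stopifnot(inherits(stack, "bm_stack"))
  if (!any(reference_mask)) stop("empty reference mask")
  d <- dim(stack$field)
  S <- matrix(stack$field, d[1], d[2] * d[3])
  ref <- as.vector(reference_mask)
  r1 <- Conj(S[1, ref, drop = TRUE])
  theta <- as.vector(Arg(S[, ref, drop = FALSE] %*% r1))
  stack$field <- array(S * exp(-1i * theta), d)
  stack
}

# 2D connected-component labelling (8-connectivity), BFS
label_components_2d <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      r <- (p - 1) %% nr + 1; c <- (p - 1) %/% nr + 1
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          q <- (cc - 1) * nr + rr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

# binary dilation of a 2D mask with a disc of radius r (pixels)
dilate_disc <- function(mask, r) {
  if (r <= 0) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  offs <- expand.grid(dr = -ceiling(r):ceiling(r),
                      dc = -ceiling(r):ceiling(r))
  offs <- offs[offs$dr^2 + offs$dc^2 <= r^2, ]
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(out)
  for (k in seq_len(nrow(offs))) {
    rr <- idx[, 1] + offs$dr[k]
    cc <- idx[, 2] + offs$dc[k]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    out[cbind(rr[ok], cc[ok])] <- TRUE
  }
  out
}

#' Segment a phasor field into bead, photothermal and excluded regions
#'
#' Voxels are assigned by OCT magnitude SNR: bead voxels are connected
#' blobs at or above `bead_snr_db`; PT voxels are medium-scatter voxels
#' inside `pt_snr_window` and outside the dilated bead regions. Bead blobs
#' are excluded (with a reason code) when they touch the image margin, sit
#' closer to a neighbouring blob than the adjacency radius, or fit the
#' drive sinusoid poorly.
#'
#' @param phasors A `phasor_field` from [demodulate()].
#' @param bead_snr_db Bead magnitude threshold in dB (default 28).
#' @param pt_snr_window Two dB values `(lo, hi)` bounding medium-scatter
#'   voxels (default `c(6, 26)`).
#' @param bead_diameter Bead diameter in metres (default 1.9 um); sets the
#'   adjacency radius.
#' @param edge_margin Margin in voxels (default 3).
#' @param dilation_factor Adjacency radius in bead diameters (default 2).
#' @param residual_max Maximum sinusoid-fit residual ratio (default 0.5).
#' @return A list of class `segmentation_masks`: logical matrices `bead`,
#'   `pt`, `excluded`, integer `bead_labels`, and a data.frame `components`
#'   with per-blob centroids (pixels), sizes, and exclusion reasons.
#' @export
segment_stack <- function(phasors, bead_snr_db = 28,
                          pt_snr_window = c(6, 26),
                          bead_diameter = 1.9e-6, edge_margin = 3,
                          dilation_factor = 2, residual_max = 0.5) {
  stopifnot(inherits(phasors, "phasor_field"),
            pt_snr_window[1] < pt_snr_window[2])
  snr <- phasors$snr_db
  cand <- snr >= bead_snr_db - 1e-9   # guard against fp ties at the threshold
  lab <- label_components_2d(cand)
  ncomp <- max(lab)
  n_z <- nrow(snr); n_x <- ncol(snr)
  radius_px <- dilation_factor * bead_diameter /
    min(phasors$pixel_z, phasors$pixel_x)
  comp <- data.frame(id = integer(0), cz = numeric(0), cx = numeric(0),
                     n = integer(0), reason = character(0))
  keep <- rep(TRUE, ncomp)
  reasons <- rep("", ncomp)
  cz <- cx <- nvox <- numeric(ncomp)
  for (i in seq_len(ncomp)) {
    vox <- which(lab == i, arr.ind = TRUE)
    cz[i] <- mean(vox[, 1]); cx[i] <- mean(vox[, 2]); nvox[i] <- nrow(vox)
    if (any(vox[, 1] <= edge_margin | vox[, 1] > n_z - edge_margin |
            vox[, 2] <= edge_margin | vox[, 2] > n_x - edge_margin)) {
      keep[i] <- FALSE; reasons[i] <- "edge"
      next
    }
    med_rr <- stats::median(phasors$residual_ratio[lab == i])
    if (is.finite(med_rr) && med_rr > residual_max) {
      keep[i] <- FALSE; reasons[i] <- "poor_fit"
    }
  }
  if (ncomp >= 2) {
    for (i in seq_len(ncomp - 1)) {
      for (j in (i + 1):ncomp) {
        dd <- sqrt((cz[i] - cz[j])^2 + (cx[i] - cx[j])^2)
        if (dd < radius_px) {
          keep[c(i, j)] <- FALSE
          reasons[c(i, j)] <- "adjacent_bead_overlap"
        }
      }
    }
  }
  bead <- matrix(FALSE, n_z, n_x)
  excluded <- matrix(FALSE, n_z, n_x)
  bead_labels <- matrix(0L, n_z, n_x)
  for (i in seq_len(ncomp)) {
    sel <- lab == i
    if (keep[i]) {
      bead[sel] <- TRUE
      bead_labels[sel] <- i
    } else {
      excluded[sel] <- TRUE
    }
  }
  pt <- snr >= pt_snr_window[1] & snr <= pt_snr_window[2] &
    !dilate_disc(cand, radius_px)
  if (ncomp > 0) {
    comp <- data.frame(id = seq_len(ncomp), cz = cz, cx = cx,
                       n = as.integer(nvox),
                       reason = ifelse(keep, "", reasons))
  }
  structure(list(bead = bead, pt = pt, excluded = excluded,
                 bead_labels = bead_labels, components = comp),
            class = "segmentation_masks")
}

#' Reconstruct the 2D photothermal response field
#'
#' Fits a separable complex surface `PT(x, z) = u(z) * l(x)` to the phasors
#' of the medium-scatter (PT) voxels by alternating least squares: the
#' lateral shape `l(x)` follows the light-sheet long-axis intensity
#' profile, and the depth shape `|u(z)|` is constrained monotone
#' non-decreasing (cumulative optical-path heating) by isotonic
#' regression. When coverslip rows are given, the model is rescaled to
#' match the complex mean of the measured phasors there.
#'
#' @param phasors A `phasor_field`.
#' @param masks A `segmentation_masks` from [segment_stack()].
#' @param coverslip_rows Optional integer depth rows holding the coverslip
#'   cumulative-PT measurement.
#' @param min_pt_voxels Minimum PT voxels required (default 20).
#' @param n_iter ALS iterations (default 10).
#' @param depth_smooth Running-mean window (depth rows) applied to the
#'   depth shape before the monotone projection (default 5).
#' @return A list of class `pt_field` with matrices `amplitude` (m) and
#'   `phase` (rad) on the full `(z, x)` grid.
#' @export
reconstruct_pt <- function(phasors, masks, coverslip_rows = NULL,
                           min_pt_voxels = 20, n_iter = 10,
                           depth_smooth = 5) {
  stopifnot(inherits(phasors, "phasor_field"),
            inherits(masks, "segmentation_masks"))
  if (sum(masks$pt) < min_pt_voxels) {
    stop("insufficient PT voxels: ", sum(masks$pt), " < ", min_pt_voxels)
  }
  P <- phasors$amplitude * exp(1i * phasors$phase)
  M <- masks$pt
  n_z <- nrow(P); n_x <- ncol(P)
  if (all(Mod(P[M]) == 0)) {
    return(structure(list(amplitude = matrix(0, n_z, n_x),
                          phase = matrix(0, n_z, n_x)),
                     class = "pt_field"))
  }
  Pm <- ifelse(M, P, complex(real = 0))
  W <- matrix(as.numeric(M), n_z, n_x)
  # lateral shape init: column means of masked magnitude
  cm <- colSums(Mod(Pm)) / pmax(colSums(W), 1)
  has <- colSums(W) > 0
  l <- stats::approx(which(has), cm[has], xout = seq_len(n_x),
                     rule = 2)$y
  l <- l / max(l)
  u <- complex(n_z)
  for (it in seq_len(n_iter)) {
    u <- as.vector(Pm %*% l) / pmax(as.vector(W %*% l^2),
                                    .Machine$double.eps)
    uscale <- Conj(u) / max(Mod(u))
    lnum <- Mod(as.vector(t(Pm) %*% uscale))
    lden <- as.vector(t(W) %*% (Mod(uscale)^2))
    l <- lnum / pmax(lden, .Machine$double.eps)
    l <- l / max(l)
  }
  # fill depth rows without PT support, then enforce monotone magnitude
  rhas <- rowSums(W) > 0
  if (!all(rhas)) {
    re <- stats::approx(which(rhas), Re(u[rhas]), xout = seq_len(n_z),
                        rule = 2)$y
    im <- stats::approx(which(rhas), Im(u[rhas]), xout = seq_len(n_z),
                        rule = 2)$y
    u <- complex(real = re, imaginary = im)
  }
  sm <- function(x, w) {
    y <- stats::filter(x, rep(1 / w, w), sides = 2)
    y[is.na(y)] <- x[is.na(y)]
    as.vector(y)
  }
  # cumulative heating varies slowly with depth: smooth the depth shape
  # before projecting onto the monotone cone, so that rows whose PT voxels
  # were mostly removed around beads borrow strength from their neighbours
  w <- min(depth_smooth, n_z - (1 - n_z %% 2))
  if (w >= 3) {
    u <- complex(real = sm(Re(u), w), imaginary = sm(Im(u), w))
  }
  mag <- stats::isoreg(seq_len(n_z), Mod(u))$yf
  ph <- Arg(complex(real = sm(Re(u), 5), imaginary = sm(Im(u), 5)))
  u <- mag * exp(1i * ph)
  model <- outer(u, as.complex(l))
  if (!is.null(coverslip_rows)) {
    obs <- mean(P[coverslip_rows, ])
    fit <- mean(model[coverslip_rows, ])
    if (Mod(fit) > 0) model <- model * (obs / fit)
  }
  structure(list(amplitude = Mod(model), phase = Arg(model)),
            class = "pt_field")
}

#' Isolate the mechanical response by complex PT subtraction
#'
#' `A_mech e^{i phi_mech} = A_tot e^{i phi_tot} - A_PT e^{i phi_PT}` at
#' every voxel.
#'
#' @param phasors A `phasor_field` (total response).
#' @param pt A `pt_field` from [reconstruct_pt()], or `NULL` for no
#'   compensation.
#' @return A `phasor_field` with the mechanical amplitude and phase.
#' @export
isolate_mech <- function(phasors, pt = NULL) {
  stopifnot(inherits(phasors, "phasor_field"))
  tot <- phasors$amplitude * exp(1i * phasors$phase)
  mech <- if (is.null(pt)) tot else {
    stopifnot(all(dim(pt$amplitude) == dim(phasors$amplitude)))
    tot - pt$amplitude * exp(1i * pt$phase)
  }
  out <- phasors
  out$amplitude <- Mod(mech)
  out$phase <- Arg(mech)
  out
}

# circular median: sample angle minimising summed angular distance,
# ties broken toward the circular mean
circular_median <- function(phi) {
  if (length(phi) == 1) return(phi)
  cost <- vapply(phi, function(p) sum(abs(wrap_phase(phi - p))), numeric(1))
  best <- which(cost <= min(cost) + 1e-12)
  if (length(best) > 1) {
    cmean <- Arg(sum(exp(1i * phi)))
    best <- best[which.min(abs(wrap_phase(phi[best] - cmean)))]
  }
  phi[best]
}

#' Cluster bead voxels across slow-axis positions into bead records
#'
#' Connected components in 3D (depth, fast axis, slow axis;
#' 26-connectivity, slices adjacent when their slow positions differ by at
#' most 1.5 steps). Per bead: magnitude-weighted centroid, component
#' median of voxel amplitudes and circular median of phases. Because the
#' magnitude of a noisy phasor is biased upward (Rician), each voxel
#' amplitude is first debiased by power subtraction,
#' `sqrt(max(A^2 - 2 se^2, 0))`, using the amplitude standard error
#' propagated by the demodulator.
#'
#' @param mech_list List of mechanical `phasor_field`s, one per slow-axis
#'   position (ordered by position).
#' @param masks_list Matching list of `segmentation_masks`.
#' @param slow_step Nominal slow-axis step in metres; defaults to the
#'   median spacing of the supplied positions.
#' @return A `bead_record` data.frame: `id`, `xc`, `yc`, `zc` (m),
#'   `a_mech` (m), `phi_mech` (rad), `n_voxels`, `qc`, plus `NA` columns
#'   `force`, `g_prime`, `g_double_prime`, `loss_ratio` filled by
#'   [map_modulus()].
#' @export
cluster_beads <- function(mech_list, masks_list, slow_step = NULL) {
  stopifnot(length(mech_list) == length(masks_list),
            length(mech_list) >= 1)
  pos <- vapply(mech_list, function(p) p$slow_position, numeric(1))
  ord <- order(pos)
  mech_list <- mech_list[ord]; masks_list <- masks_list[ord]
  pos <- pos[ord]
  if (is.null(slow_step)) {
    slow_step <- if (length(pos) > 1) stats::median(diff(pos)) else Inf
  }
  vox <- do.call(rbind, lapply(seq_along(mech_list), function(s) {
    m <- masks_list[[s]]$bead
    if (!any(m)) return(NULL)
    idx <- which(m, arr.ind = TRUE)
    amp <- mech_list[[s]]$amplitude[m]
    se <- if (!is.null(mech_list[[s]]$amp_se)) {
      mech_list[[s]]$amp_se[m]
    } else 0
    amp <- sqrt(pmax(amp^2 - 2 * se^2, 0))   # Rician debias
    data.frame(z = idx[, 1], x = idx[, 2], s = s, amp = amp,
               phi = mech_list[[s]]$phase[m],
               w = mech_list[[s]]$mean_mag[m])
  }))
  empty <- data.frame(id = integer(0), xc = numeric(0), yc = numeric(0),
                      zc = numeric(0), a_mech = numeric(0),
                      phi_mech = numeric(0), force = numeric(0),
                      g_prime = numeric(0), g_double_prime = numeric(0),
                      loss_ratio = numeric(0), n_voxels = integer(0),
                      qc = character(0))
  class(empty) <- c("bead_record", "data.frame")
  if (is.null(vox) || nrow(vox) == 0) return(empty)
  # 3D connected components by BFS over the voxel table
  n <- nrow(vox)
  lab <- integer(n)
  cur <- 0L
  key <- paste(vox$z, vox$x, vox$s)
  lookup <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(key[i], i, envir = lookup)
  slice_adj <- function(s1, s2) {
    abs(pos[s1] - pos[s2]) <= 1.5 * slow_step + 1e-15
  }
  for (i in seq_len(n)) {
    if (lab[i] != 0L) next
    cur <- cur + 1L
    queue <- i; lab[i] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      for (dz in -1:1) for (dx in -1:1) for (ds in -1:1) {
        if (dz == 0 && dx == 0 && ds == 0) next
        s2 <- vox$s[p] + ds
        if (s2 < 1 || s2 > length(pos)) next
        if (ds != 0 && !slice_adj(vox$s[p], s2)) next
        k <- paste(vox$z[p] + dz, vox$x[p] + dx, s2)
        j <- mget(k, envir = lookup, ifnotfound = list(NULL))[[1]]
        if (!is.null(j) && lab[j] == 0L) {
          lab[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  px <- mech_list[[1]]$pixel_x; pz <- mech_list[[1]]$pixel_z
  recs <- lapply(seq_len(cur), function(i) {
    v <- vox[lab == i, ]
    wsum <- sum(v$w)
    data.frame(id = i,
               xc = sum((v$x - 0.5) * px * v$w) / wsum,
               yc = sum(pos[v$s] * v$w) / wsum,
               zc = sum((v$z - 0.5) * pz * v$w) / wsum,
               a_mech = stats::median(v$amp),
               phi_mech = circular_median(v$phi),
               force = NA_real_, g_prime = NA_real_,
               g_double_prime = NA_real_, loss_ratio = NA_real_,
               n_voxels = nrow(v), qc = "")
  })
  out <- do.call(rbind, recs)
  class(out) <- c("bead_record", "data.frame")
  out
}

# bilinear interpolation of a force_profile at (x, z); NA outside support
interp_force <- function(fp, x, z) {
  gx <- fp$grid_x; gz <- fp$grid_z
  out <- rep(NA_real_, length(x))
  for (k in seq_along(x)) {
    if (length(gx) == 1) {
      i <- 1; tx <- 0
    } else {
      if (x[k] < gx[1] || x[k] > gx[length(gx)]) next
      i <- max(1, min(length(gx) - 1, findInterval(x[k], gx)))
      tx <- (x[k] - gx[i]) / (gx[i + 1] - gx[i])
    }
    if (length(gz) == 1) {
      j <- 1; tz <- 0
    } else {
      if (z[k] < gz[1] || z[k] > gz[length(gz)]) next
      j <- max(1, min(length(gz) - 1, findInterval(z[k], gz)))
      tz <- (z[k] - gz[j]) / (gz[j + 1] - gz[j])
    }
    f00 <- fp$force[i, j]
    f10 <- if (length(gx) > 1) fp$force[i + 1, j] else f00
    f01 <- if (length(gz) > 1) fp$force[i, j + 1] else f00
    f11 <- if (length(gx) > 1 && length(gz) > 1) fp$force[i + 1, j + 1] else f00
    out[k] <- (1 - tx) * (1 - tz) * f00 + tx * (1 - tz) * f10 +
      (1 - tx) * tz * f01 + tx * tz * f11
  }
  out
}

#' Map bead responses to complex shear moduli
#'
#' Interpolates the radiation force at each bead centroid from the 2D
#' force profile, then recovers `G* = G' + i G''` through the
#' oscillating-sphere model ([modulus_from_response()]). Beads outside the
#' force-map support are flagged and left without moduli.
#'
#' @param records A `bead_record` data.frame from [cluster_beads()].
#' @param force_map A [force_profile()].
#' @param bead A [bead_spec()].
#' @param medium_rho Medium density in kg/m^3 (default 1000).
#' @param omega Angular modulation frequency in rad/s.
#' @param include_inertia Keep the bead inertial term (default TRUE).
#' @return The records with `force`, `g_prime`, `g_double_prime`,
#'   `loss_ratio` filled in.
#' @export
map_modulus <- function(records, force_map, bead, medium_rho = 1000,
                        omega = 2 * pi * 20, include_inertia = TRUE) {
  stopifnot(inherits(force_map, "force_profile"))
  if (nrow(records) == 0) return(records)
  f <- interp_force(force_map, records$xc, records$zc)
  for (i in seq_len(nrow(records))) {
    if (!is.finite(f[i]) || f[i] <= 0 || records$a_mech[i] <= 0) {
      records$qc[i] <- paste0(records$qc[i], "outside_force_map;")
      next
    }
    resp <- complex_response(records$a_mech[i], records$phi_mech[i], omega)
    gg <- modulus_from_response(f[i], resp, bead, medium_rho,
                                include_inertia)
    records$force[i] <- f[i]
    records$g_prime[i] <- gg$g_prime
    records$g_double_prime[i] <- gg$g_double_prime
    records$loss_ratio[i] <- gg$loss_ratio
  }
  records
}

#' Run reconstruction steps 2-6 on a list of BM-mode stacks
#'
#' Convenience wrapper: demodulate each slow-axis stack, segment,
#' reconstruct and subtract the photothermal field, cluster bead voxels in
#' 3D, and map moduli from a force profile.
#'
#' @param stacks List of [bm_stack()]s (one per slow-axis position).
#' @param force_map A [force_profile()].
#' @param bead A [bead_spec()].
#' @param medium_rho Medium density for the modulus inversion.
#' @param pt_compensation Reconstruct and subtract the PT field
#'   (default TRUE).
#' @param ... Passed to [segment_stack()].
#' @return A `bead_record` data.frame with moduli.
#' @export
reconstruct_series <- function(stacks, force_map, bead, medium_rho = 1000,
                               pt_compensation = TRUE, ...) {
  mech_list <- vector("list", length(stacks))
  masks_list <- vector("list", length(stacks))
  omega <- 2 * pi * stacks[[1]]$f_mod
  for (s in seq_along(stacks)) {
    ph <- demodulate(stacks[[s]])
    mk <- segment_stack(ph, bead_diameter = bead$diameter, ...)
    pt <- NULL
    if (pt_compensation && sum(mk$pt) >= 20) {
      pt <- reconstruct_pt(ph, mk)
    }
    mech_list[[s]] <- isolate_mech(ph, pt)
    masks_list[[s]] <- mk
  }
  recs <- cluster_beads(mech_list, masks_list)
  map_modulus(recs, force_map, bead, medium_rho, omega)
}
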