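# Downstream analyses: speckle-contrast cell segmentation, pericellular
# distance profiles and power-law fits, bead-displacement statistics,
# collagen shell metrics, distribution summaries, and hypothesis tests.

#' Segment a cell from temporal speckle contrast
#'
#' Dynamic intracellular scatterers decorrelate the OCT speckle between
#' BM-mode frames while the surrounding matrix stays static. Per voxel the
#' temporal standard deviation of the OCT magnitude, normalised by its
#' temporal mean, is thresholded; after morphological closing the largest
#' connected component is taken as the cell.
#'
#' @param stacks A [bm_stack()] or list of them (one per slow position).
#' @param contrast_threshold Speckle-contrast threshold; voxels above it
#'   are dynamic (default 0.25).
#' @param closing_radius Structuring-disc radius in voxels (default 1).
#' @return Logical array `(n_z, n_x, n_slices)` of class `cell_mask` with
#'   attributes `pixel_z`, `pixel_x`, `slow_positions`.
#' @export
speckle_segment_cell <- function(stacks, contrast_threshold = 0.25,
                                 closing_radius = 1) {
  if (inherits(stacks, "bm_stack")) stacks <- list(stacks)
  stopifnot(length(stacks) >= 1, dim(stacks[[1]]$field)[1] >= 2)
  d <- dim(stacks[[1]]$field)
  mask <- array(FALSE, c(d[2], d[3], length(stacks)))
  for (s in seq_along(stacks)) {
    M <- Mod(stacks[[s]]$field)
    mu <- apply(M, c(2, 3), mean)
    sg <- apply(M, c(2, 3), stats::sd)
    contrast <- sg / pmax(mu, .Machine$double.eps)
    m <- contrast > contrast_threshold
    if (closing_radius > 0) {
      m <- !dilate_disc(!dilate_disc(m, closing_radius), closing_radius)
    }
    mask[, , s] <- m
  }
  if (!any(mask)) {
    warning("no voxel above the speckle-contrast threshold: empty mask")
  } else if (all(mask)) {
    warning("all voxels dynamic: degenerate mask")
  } else {
    lab <- label_components_3d(mask)
    counts <- tabulate(lab[lab > 0])
    mask <- array(lab == which.max(counts), dim(mask))
  }
  structure(mask, class = "cell_mask",
            pixel_z = stacks[[1]]$pixel_z, pixel_x = stacks[[1]]$pixel_x,
            slow_positions = vapply(stacks, function(s) s$slow_position,
                                    numeric(1)))
}

# 3D connected components (26-connectivity) on a logical array
label_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  cur <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      p0 <- p - 1
      i <- p0 %% d[1] + 1
      j <- (p0 %/% d[1]) %% d[2] + 1
      k <- p0 %/% (d[1] * d[2]) + 1
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        ii <- i + di; jj <- j + dj; kk <- k + dk
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
            kk < 1 || kk > d[3]) next
        q <- (kk - 1) * d[1] * d[2] + (jj - 1) * d[1] + ii
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

#' Shortest distance from bead centroids to a cell surface
#'
#' Euclidean distance from each centroid to the nearest cell-mask voxel
#' centre, with anisotropic voxel sizes; beads inside the mask get 0.
#'
#' @param centroids Matrix or data.frame with columns `xc`, `yc`, `zc` in
#'   metres (fast, slow, depth).
#' @param cell_mask A `cell_mask` from [speckle_segment_cell()], or a
#'   logical array with the same attributes.
#' @return Numeric vector of distances in metres.
#' @export
distance_to_cell <- function(centroids, cell_mask) {
  if (!any(cell_mask)) stop("empty cell mask")
  pz <- attr(cell_mask, "pixel_z"); px <- attr(cell_mask, "pixel_x")
  sp <- attr(cell_mask, "slow_positions")
  idx <- which(cell_mask, arr.ind = TRUE)
  vz <- (idx[, 1] - 0.5) * pz
  vx <- (idx[, 2] - 0.5) * px
  vy <- sp[idx[, 3]]
  centroids <- as.data.frame(centroids)
  vapply(seq_len(nrow(centroids)), function(i) {
    d2 <- (vx - centroids$xc[i])^2 + (vy - centroids$yc[i])^2 +
      (vz - centroids$zc[i])^2
    sqrt(min(d2))
  }, numeric(1))
}

#' Distance-binned viscoelasticity profile
#'
#' Groups beads by distance to the cell into fixed-width bins and reports
#' the per-bin mean and Student-t 95% confidence interval of `G'` and the
#' loss ratio `R`, optionally normalised by the mean over the faraway
#' background (`r >= background_cutoff`).
#'
#' @param records A `bead_record` data.frame with `g_prime`, `loss_ratio`.
#' @param r Distance to the cell per bead, metres.
#' @param bin_width Bin width in metres (default 3 um).
#' @param background_cutoff Background distance in metres (default 30 um).
#' @param normalise Divide by the background means (default FALSE).
#' @return A data.frame with one row per non-empty bin: `r` (bin centre),
#'   `n`, `g_prime_mean`, `g_prime_lo`, `g_prime_hi`, `loss_mean`,
#'   `loss_lo`, `loss_hi`.
#' @export
distance_profile <- function(records, r, bin_width = 3e-6,
                             background_cutoff = 30e-6, normalise = FALSE) {
  stopifnot(nrow(records) >= 1, length(r) == nrow(records))
  bin <- floor(r / bin_width)
  ci <- function(x) {
    n <- sum(is.finite(x))
    m <- mean(x, na.rm = TRUE)
    if (n >= 2) {
      hw <- stats::qt(0.975, n - 1) * stats::sd(x, na.rm = TRUE) / sqrt(n)
    } else hw <- NA_real_
    c(m, m - hw, m + hw, n)
  }
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    g <- ci(records$g_prime[sel])
    l <- ci(records$loss_ratio[sel])
    data.frame(r = (b + 0.5) * bin_width, n = g[4],
               g_prime_mean = g[1], g_prime_lo = g[2], g_prime_hi = g[3],
               loss_mean = l[1], loss_lo = l[2], loss_hi = l[3])
  }))
  if (normalise) {
    bg <- r >= background_cutoff
    if (!any(bg)) stop("no background beads beyond the cutoff")
    gb <- mean(records$g_prime[bg], na.rm = TRUE)
    lb <- mean(records$loss_ratio[bg], na.rm = TRUE)
    out[, c("g_prime_mean", "g_prime_lo", "g_prime_hi")] <-
      out[, c("g_prime_mean", "g_prime_lo", "g_prime_hi")] / gb
    out[, c("loss_mean", "loss_lo", "loss_hi")] <-
      out[, c("loss_mean", "loss_lo", "loss_hi")] / lb
  }
  out
}

#' Power-law fit of the pericellular stiffness gradient
#'
#' Degree-1 least squares of `log G'` against `log r` restricted to
#' `r <= r_max`, giving the decay exponent beta with its t-based 95%
#' confidence interval. The log-log space is the only reading under which
#' the exponent is dimensionless.
#'
#' @param r Distances in metres (> 0).
#' @param g_prime Storage moduli in Pa (> 0).
#' @param r_max Fit domain bound in metres (default 30 um).
#' @return List with `beta`, `ci` (length 2), `se`, `intercept`, `n`,
#'   and the `lm` fit.
#' @export
fit_power_law <- function(r, g_prime, r_max = 30e-6) {
  sel <- is.finite(r) & is.finite(g_prime) & r <= r_max
  r <- r[sel]; g_prime <- g_prime[sel]
  if (length(r) < 3) stop("need at least 3 points with r <= r_max")
  if (any(r <= 0) || any(g_prime <= 0)) {
    stop("power-law fit requires positive r and G'")
  }
  fit <- stats::lm(log(g_prime) ~ log(r))
  beta <- unname(stats::coef(fit)[2])
  # noiseless power-law input gives a zero-residual fit; silence lm's
  # "essentially perfect fit" chatter for that legal case
  ci <- suppressWarnings(unname(stats::confint(fit, level = 0.95)[2, ]))
  se <- suppressWarnings(unname(summary(fit)$coefficients[2, 2]))
  list(beta = beta, ci = ci, se = se,
       intercept = unname(stats::coef(fit)[1]), n = length(r), fit = fit)
}

#' Cumulative bead displacements corrected for bulk sample shift
#'
#' Component-wise: the per-step displacement of each bead minus the mean
#' per-step displacement over all beads (the bulk shift), accumulated over
#' time. The first time point is the zero reference.
#'
#' @param positions Numeric array `(n_beads, n_times, 3)` of centroid
#'   coordinates in metres (components x, y, z).
#' @return Array `(n_beads, n_times, 3)` of cumulative displacements;
#'   `[, 1, ] = 0`.
#' @export
cumulative_displacement <- function(positions) {
  d <- dim(positions)
  stopifnot(length(d) == 3, d[3] == 3, d[2] >= 2)
  if (d[1] == 1) {
    warning("single bead: bulk shift equals its own motion, ",
            "displacements are identically zero")
  }
  out <- array(0, d)
  for (n in 2:d[2]) {
    step <- positions[, n, , drop = FALSE] -
      positions[, n - 1, , drop = FALSE]
    bulk <- apply(step, 3, mean)
    out[, n, ] <- out[, n - 1, ] +
      sweep(array(step, c(d[1], 3)), 2, bulk)
  }
  out
}

#' Signed cumulative displacement along the dataset-level major axis
#'
#' The major axis is the component of the normalised absolute displacement
#' vector `(|dx|, |dy|, |dz|) / ||dr||` with the largest average over all
#' beads and time points (zero-norm entries skipped). The signed
#' displacement is the sign of that component times the Euclidean norm.
#'
#' @param disp Array `(n_beads, n_times, 3)` from
#'   [cumulative_displacement()].
#' @return List with `S` (matrix `n_beads x n_times`) and `major_axis`
#'   (1 = x, 2 = y, 3 = z; `NA` when all displacements vanish).
#' @export
signed_displacement <- function(disp) {
  d <- dim(disp)
  stopifnot(length(d) == 3, d[3] == 3)
  nrm <- sqrt(disp[, , 1]^2 + disp[, , 2]^2 + disp[, , 3]^2)
  nz <- nrm > 0
  if (!any(nz)) {
    return(list(S = matrix(0, d[1], d[2]), major_axis = NA_integer_))
  }
  frac <- vapply(1:3, function(k) {
    mean(abs(disp[, , k])[nz] / nrm[nz])
  }, numeric(1))
  axis <- which.max(frac)
  S <- sign(disp[, , axis]) * nrm
  list(S = matrix(S, d[1], d[2]), major_axis = axis)
}

#' Group beads by final matrix deformation
#'
#' Labels each bead `high-negative`, `low`, or `high-positive` from its
#' signed displacement at the final time point. The default threshold is
#' the 67th percentile of `|S|`.
#'
#' @param s_final Signed displacements at the last time point, metres.
#' @param s_hi Threshold in metres; `NULL` (default) uses
#'   `quantile(|S|, 0.67)`.
#' @return Factor with levels `high-negative`, `low`, `high-positive`.
#' @export
group_by_deformation <- function(s_final, s_hi = NULL) {
  stopifnot(all(is.finite(s_final)))
  if (is.null(s_hi)) {
    s_hi <- stats::quantile(abs(s_final), 0.67, names = FALSE)
  }
  lab <- ifelse(s_final <= -s_hi & s_hi > 0, "high-negative",
                ifelse(s_final >= s_hi & s_hi > 0, "high-positive", "low"))
  factor(lab, levels = c("high-negative", "low", "high-positive"))
}

#' Collagen shell metrics around each bead
#'
#' Collects intensity voxels within a spherical shell of the stated
#' thickness around each bead surface (after removing the beads
#' themselves) and reports the 0.95 quantile and mean of intensity plus
#' the fibre volume fraction: voxels at or above the fibre SNR threshold
#' divided by voxels at or above the noise SNR threshold.
#'
#' @param volume 3D intensity array `(n_z, n_x, n_y)` (a.u., beads
#'   present; they are removed by magnitude segmentation + dilation).
#' @param centroids Data.frame with `xc`, `yc`, `zc` in metres.
#' @param voxel_size Length-3 voxel pitch `(z, x, y)` in metres.
#' @param bead_diameter Bead diameter in metres.
#' @param shell Shell thickness in metres (default 3 um; must be > 0).
#' @param noise_level Intensity value corresponding to 0 dB SNR.
#' @param snr_noise Noise-floor threshold in dB (default 6).
#' @param snr_fibre Fibre threshold in dB (default 14).
#' @param dilation Bead-removal dilation in voxels beyond the bead radius
#'   (default 1).
#' @param connectivity Optional data.frame `(id, count)` of manually
#'   counted fibre branches, merged by bead id.
#' @return Data.frame with `id`, `q95_intensity`, `mean_intensity`,
#'   `fibre_volume_fraction`, `n_shell`, `connectivity`, `qc`.
#' @export
shell_metrics <- function(volume, centroids, voxel_size, bead_diameter,
                          shell = 3e-6, noise_level = 1, snr_noise = 6,
                          snr_fibre = 14, dilation = 1,
                          connectivity = NULL) {
  if (shell <= 0) stop("shell thickness must be > 0")
  d <- dim(volume)
  centroids <- as.data.frame(centroids)
  zc <- (seq_len(d[1]) - 0.5) * voxel_size[1]
  xc <- (seq_len(d[2]) - 0.5) * voxel_size[2]
  yc <- (seq_len(d[3]) - 0.5) * voxel_size[3]
  a <- bead_diameter / 2
  remove_r <- a + dilation * min(voxel_size)
  # magnitude convention: SNR(dB) = 20 log10(|I| / noise)
  snr_db <- 20 * log10(pmax(volume, .Machine$double.eps) / noise_level)
  bead_dist2 <- function(i) {
    outer(outer((zc - centroids$zc[i])^2, (xc - centroids$xc[i])^2, `+`),
          (yc - centroids$yc[i])^2, `+`)
  }
  # squared distance of every voxel to its nearest bead centre (for the
  # magnitude-segmentation + dilation bead removal)
  near2 <- array(Inf, d)
  for (j in seq_len(nrow(centroids))) near2 <- pmin(near2, bead_dist2(j))
  outside_beads <- near2 > remove_r^2
  out <- lapply(seq_len(nrow(centroids)), function(i) {
    dist <- sqrt(bead_dist2(i))
    in_shell <- dist > remove_r & dist <= a + shell & outside_beads
    vals <- volume[in_shell]
    snrs <- snr_db[in_shell]
    if (length(vals) == 0) {
      return(data.frame(id = i, q95_intensity = NA_real_,
                        mean_intensity = NA_real_,
                        fibre_volume_fraction = NA_real_, n_shell = 0L,
                        qc = "empty_shell"))
    }
    above_noise <- sum(snrs >= snr_noise)
    frac <- if (above_noise > 0) sum(snrs >= snr_fibre) / above_noise
            else NA_real_
    data.frame(id = i,
               q95_intensity = stats::quantile(vals, 0.95, names = FALSE),
               mean_intensity = mean(vals),
               fibre_volume_fraction = frac,
               n_shell = length(vals), qc = "")
  })
  out <- do.call(rbind, out)
  out$connectivity <- NA_real_
  if (!is.null(connectivity)) {
    m <- match(out$id, connectivity$id)
    out$connectivity <- connectivity$count[m]
  }
  out
}

#' Spearman rank correlation between a shell metric and a modulus
#'
#' Rank correlation with tie-corrected two-tailed p-value; a linear
#' best-fit line is reported for display only.
#'
#' @param metric Per-bead metric values.
#' @param modulus Per-bead `G'` or `R` values.
#' @return List with `rho`, `p_value`, `n`, and `display_fit`
#'   (intercept/slope of the linear fit).
#' @export
correlate_metrics <- function(metric, modulus) {
  sel <- is.finite(metric) & is.finite(modulus)
  metric <- metric[sel]; modulus <- modulus[sel]
  if (length(metric) < 4) stop("need at least 4 paired observations")
  if (stats::sd(metric) == 0 || stats::sd(modulus) == 0) {
    stop("constant input: rank correlation undefined")
  }
  # exact null distribution when untied; tie-corrected normal approximation
  # otherwise (cor.test decides and warns, which we silence)
  ct <- suppressWarnings(
    stats::cor.test(metric, modulus, method = "spearman")
  )
  lf <- stats::lm(modulus ~ metric)
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n = length(metric),
       display_fit = unname(stats::coef(lf)))
}

#' FWHM of a sample distribution
#'
#' Gaussian kernel density estimate (Silverman's rule) whose full width at
#' half the mode is reported as the heterogeneity metric sigma_FWHM.
#'
#' @param samples Numeric vector (>= 10 values for a meaningful KDE).
#' @return FWHM in the units of `samples`; 0 for degenerate input.
#' @export
distribution_fwhm <- function(samples) {
  samples <- samples[is.finite(samples)]
  stopifnot(length(samples) >= 2)
  if (stats::sd(samples) == 0) return(0)
  dd <- stats::density(samples, bw = "nrd0")
  profile_fwhm(dd$x, dd$y)
}

#' Two-group comparison tests
#'
#' Two-sided Welch's t-test for equality of means, Levene's test for
#' equality of variances, and (for equal-length paired samples) Pearson
#' correlation of the paired trend.
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @return List with `welch` (htest), `levene` (data.frame from
#'   [car::leveneTest()]), `pearson` (htest or NULL), and `direction`
#'   (sign of `mean(a) - mean(b)`).
#' @export
group_tests <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  welch <- stats::t.test(a, b, var.equal = FALSE)
  grp <- factor(rep(c("a", "b"), c(length(a), length(b))))
  levene <- car::leveneTest(c(a, b), grp, center = mean)
  pearson <- if (length(a) == length(b) && stats::sd(a) > 0 &&
                 stats::sd(b) > 0) {
    stats::cor.test(a, b, method = "pearson")
  } else NULL
  list(welch = welch, levene = levene, pearson = pearson,
       direction = sign(mean(a) - mean(b)))
}

#' Threshold-and-gamma post-processing of confocal reflectance images
#'
#' Pixels below the stated percentile are zeroed; the remainder is
#' normalised to `[0, 1]` and gamma-corrected.
#'
#' @param image 2D non-negative matrix.
#' @param percentile Threshold percentile (default 80).
#' @param gamma Gamma coefficient (default 0.4).
#' @return Processed matrix in `[0, 1]`.
#' @export
confocal_postprocess <- function(image, percentile = 80, gamma = 0.4) {
  stopifnot(is.matrix(image), all(image >= 0))
  thr <- stats::quantile(image, percentile / 100, names = FALSE)
  out <- image
  out[out < thr] <- 0
  rng <- max(out) - thr
  if (rng <= 0) {
    warning("constant image: all-zero output")
    return(matrix(0, nrow(image), ncol(image)))
  }
  pos <- out >= thr
  out[pos] <- ((out[pos] - thr) / rng)^gamma
  out[!pos] <- 0
  out
}
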