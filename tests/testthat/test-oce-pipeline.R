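# Demodulation, registration, segmentation, PT compensation, clustering
# and modulus mapping.

omega20 <- 2 * pi * 20

test_that("demodulation is exact on a noiseless non-bin sinusoid", {
  tt <- (0:849) / 425
  d_t <- 500e-12 * cos(2 * pi * 20 * tt + 0.3)
  ph <- demodulate(make_voxel_stack(d_t))
  expect_equal(ph$amplitude[1, 1], 500e-12, tolerance = 1e-9)
  expect_equal(ph$phase[1, 1], 0.3, tolerance = 1e-9)
})

test_that("demodulation reports phase relative to the drive waveform", {
  tt <- (0:849) / 425
  d_t <- 400e-12 * cos(2 * pi * 20 * tt + 1.0)
  ph <- demodulate(make_voxel_stack(d_t, drive_phase = 0.4))
  expect_equal(ph$phase[1, 1], 0.6, tolerance = 1e-9)
})

test_that("constant phase demodulates to zero amplitude", {
  ph <- demodulate(make_voxel_stack(rep(0, 400)))
  expect_lt(ph$amplitude[1, 1], 1e-18)
})

test_that("frames with non-finite samples are excluded from the fit", {
  tt <- (0:849) / 425
  d_t <- 500e-12 * cos(2 * pi * 20 * tt + 0.3)
  stk <- make_voxel_stack(d_t)
  stk$field[c(17, 400), 1, 1] <- NA_complex_
  ph <- demodulate(stk)
  expect_equal(ph$amplitude[1, 1], 500e-12, tolerance = 1e-9)
  expect_equal(ph$phase[1, 1], 0.3, tolerance = 1e-9)
})

test_that("stacks shorter than two modulation cycles are rejected", {
  tt <- (0:30) / 425   # < 0.1 s, < 2 cycles of 20 Hz
  expect_error(demodulate(make_voxel_stack(rep(0, 31))), "cycles")
})

test_that("phase registration removes an injected common-mode drift exactly", {
  set.seed(11)
  n_t <- 200; n_z <- 6; n_x <- 5
  base <- array(complex(modulus = 50,
                        argument = runif(n_z * n_x, -pi, pi)),
                c(1, n_z, n_x))[rep(1, n_t), , , drop = FALSE]
  base <- array(base, c(n_t, n_z, n_x))
  drift <- cumsum(rnorm(n_t, sd = 0.05))
  drift <- drift - drift[1]
  drifted <- base * array(rep(exp(1i * drift), n_z * n_x), c(n_t, n_z, n_x))
  stk <- bm_stack(drifted, 425, 20)
  reg <- register_phase(stk, matrix(TRUE, n_z, n_x))
  expect_equal(Arg(reg$field * Conj(base)),
               array(0, c(n_t, n_z, n_x)), tolerance = 1e-10)
  # zero drift: stack unchanged
  stk0 <- bm_stack(base, 425, 20)
  reg0 <- register_phase(stk0, matrix(TRUE, n_z, n_x))
  expect_equal(reg0$field, base, tolerance = 1e-12)
  expect_error(register_phase(stk0, matrix(FALSE, n_z, n_x)), "empty")
})

test_that("bead phasors survive registration of a spatially uniform drift", {
  tt <- (0:599) / 425
  d_t <- 300e-12 * cos(2 * pi * 20 * tt + 0.7)
  stk <- make_voxel_stack(d_t, n_z = 4, n_x = 4)
  # voxel (1,1) carries the oscillation; others static reference
  field <- stk$field
  field[, 2:4, ] <- array(complex(modulus = 80, argument = 0.2),
                          c(600, 3, 4))
  drift <- 0.3 * sin(2 * pi * 3 * tt)
  field <- field * array(rep(exp(1i * drift), 16), c(600, 4, 4))
  stk$field <- field
  ref <- matrix(FALSE, 4, 4); ref[3, ] <- TRUE
  ph <- demodulate(register_phase(stk, ref))
  expect_equal(ph$amplitude[1, 1], 300e-12, tolerance = 1e-6)
  expect_equal(ph$phase[1, 1], 0.7, tolerance = 1e-6)
})

make_planted_phasors <- function(centres_zx, n_z = 40, n_x = 40,
                                 bead_db = 30, bg_db = 10) {
  snr <- matrix(bg_db, n_z, n_x)
  for (k in seq_len(nrow(centres_zx))) {
    z <- centres_zx[k, 1]; x <- centres_zx[k, 2]
    snr[(z - 1):(z + 1), (x - 1):(x + 1)] <- bead_db
  }
  structure(
    list(amplitude = matrix(1e-10, n_z, n_x),
         phase = matrix(0, n_z, n_x),
         mean_mag = 10^(snr / 20), snr_db = snr,
         residual_ratio = matrix(0.05, n_z, n_x),
         pixel_z = 0.75e-6, pixel_x = 0.75e-6, slow_position = 0,
         f_mod = 20, noise_level = 1),
    class = "phasor_field"
  )
}

test_that("planted beads segment into the right number of components", {
  set.seed(3)
  centres <- as.matrix(expand.grid(z = c(10, 20, 30), x = c(10, 20, 30)))
  ph <- make_planted_phasors(centres)
  mk <- segment_stack(ph, bead_snr_db = 28, pt_snr_window = c(6, 26))
  expect_equal(max(mk$bead_labels), 9)
  expect_equal(sum(mk$bead), 9 * 9)
  expect_true(all(!mk$excluded[mk$bead]))
  # PT voxels exist and avoid the bead blobs themselves
  expect_gt(sum(mk$pt), 200)
  expect_false(any(mk$pt & mk$bead))
})

test_that("noise-only fields yield an empty bead mask", {
  ph <- make_planted_phasors(matrix(numeric(0), 0, 2))
  mk <- segment_stack(ph, bead_snr_db = 28)
  expect_equal(sum(mk$bead), 0)
})

test_that("bead pairs closer than the adjacency radius are both excluded", {
  centres <- rbind(c(20, 16), c(20, 21))  # 5 px apart, radius ~5.1 px
  ph <- make_planted_phasors(centres)
  mk <- segment_stack(ph, bead_snr_db = 28)
  expect_equal(sum(mk$bead), 0)
  expect_true(any(mk$components$reason == "adjacent_bead_overlap"))
})

test_that("beads at the image margin are excluded with an edge reason", {
  centres <- rbind(c(3, 20), c(25, 25))
  ph <- make_planted_phasors(centres)
  mk <- segment_stack(ph, bead_snr_db = 28, edge_margin = 3)
  expect_true("edge" %in% mk$components$reason)
  expect_equal(max(mk$bead_labels > 0), 1)
})

test_that("PT reconstruction recovers uniform, separable and zero fields", {
  n_z <- 30; n_x <- 30
  mask_all <- structure(
    list(bead = matrix(FALSE, n_z, n_x), pt = matrix(TRUE, n_z, n_x),
         excluded = matrix(FALSE, n_z, n_x),
         bead_labels = matrix(0L, n_z, n_x),
         components = data.frame()),
    class = "segmentation_masks")
  base <- make_planted_phasors(matrix(numeric(0), 0, 2), n_z, n_x)
  # uniform complex phasor recovered exactly
  ph <- base
  ph$amplitude <- matrix(2e-10, n_z, n_x)
  ph$phase <- matrix(0.4, n_z, n_x)
  pt <- reconstruct_pt(ph, mask_all)
  expect_equal(pt$amplitude, ph$amplitude, tolerance = 1e-9)
  expect_equal(pt$phase, ph$phase, tolerance = 1e-9)
  # separable lateral-intensity x linear-depth truth, noiseless
  xs <- seq_len(n_x); zs <- seq_len(n_z)
  lat <- exp(-(xs - 15.5)^2 / (2 * 12^2))
  truth <- 3e-10 * outer(zs / n_z, lat)
  ph$amplitude <- truth
  ph$phase <- matrix(0.8, n_z, n_x)
  pt <- reconstruct_pt(ph, mask_all)
  expect_lt(max(abs(pt$amplitude - truth)) / max(truth), 0.01)
  expect_equal(pt$phase[truth > 1e-12], rep(0.8, sum(truth > 1e-12)),
               tolerance = 1e-6)
  # zero PT everywhere
  ph$amplitude <- matrix(0, n_z, n_x)
  pt <- reconstruct_pt(ph, mask_all)
  expect_true(all(pt$amplitude == 0))
  # insufficient PT voxels
  small <- mask_all
  small$pt[] <- FALSE
  small$pt[1:3, 1] <- TRUE
  expect_error(reconstruct_pt(ph, small), "insufficient")
})

test_that("mechanical isolation is exact complex subtraction", {
  n_z <- 4; n_x <- 4
  base <- make_planted_phasors(matrix(numeric(0), 0, 2), n_z, n_x)
  base$amplitude <- matrix(500e-12, n_z, n_x)
  base$phase <- matrix(0, n_z, n_x)
  pt <- structure(list(amplitude = matrix(300e-12, n_z, n_x),
                       phase = matrix(pi / 2, n_z, n_x)),
                  class = "pt_field")
  mech <- isolate_mech(base, pt)
  expect_equal(mech$amplitude[1, 1], sqrt(500^2 + 300^2) * 1e-12,
               tolerance = 1e-9)
  expect_equal(mech$phase[1, 1], atan2(-300, 500), tolerance = 1e-9)
  expect_equal(mech$phase[1, 1] * 180 / pi, -31.0, tolerance = 0.01)
  # total equals PT: zero mechanical response
  pt0 <- structure(list(amplitude = base$amplitude, phase = base$phase),
                   class = "pt_field")
  mech0 <- isolate_mech(base, pt0)
  expect_true(all(mech0$amplitude < 1e-18))
  # no PT: mechanical equals total
  mech1 <- isolate_mech(base, NULL)
  expect_equal(mech1$amplitude, base$amplitude)
})

test_that("clustering medians, centroids and invariances behave", {
  n_z <- 20; n_x <- 20
  ph <- make_planted_phasors(rbind(c(10, 10)), n_z, n_x)
  amp <- matrix(0, n_z, n_x)
  amp[9:11, 9:11] <- 3e-12
  amp[10, 9:11] <- c(1, 2, 4) * 1e-12
  amp[10, 10] <- 5e-12
  # 5 voxels of interest carry 1..5 pm; restrict the mask to them
  mask <- structure(
    list(bead = matrix(FALSE, n_z, n_x), pt = matrix(FALSE, n_z, n_x),
         excluded = matrix(FALSE, n_z, n_x),
         bead_labels = matrix(0L, n_z, n_x), components = data.frame()),
    class = "segmentation_masks")
  mask$bead[10, 8:12] <- TRUE
  ph$amplitude <- matrix(0, n_z, n_x)
  ph$amplitude[10, 8:12] <- c(1, 2, 3, 4, 5) * 1e-12
  ph$phase <- matrix(0, n_z, n_x)
  recs <- cluster_beads(list(ph), list(mask))
  expect_equal(nrow(recs), 1)
  expect_equal(recs$a_mech, 3e-12)
  # empty mask: empty record list
  mask0 <- mask; mask0$bead[] <- FALSE
  expect_equal(nrow(cluster_beads(list(ph), list(mask0))), 0)
  # uniform intensity scaling leaves clustering unchanged
  ph2 <- ph; ph2$mean_mag <- 7 * ph$mean_mag
  recs2 <- cluster_beads(list(ph2), list(mask))
  expect_equal(recs2$xc, recs$xc)
  expect_equal(recs2$a_mech, recs$a_mech)
})

test_that("planted multi-bead volume clusters with sub-voxel centroids", {
  set.seed(21)
  n_z <- 36; n_x <- 36
  centres <- as.matrix(expand.grid(z = c(9, 18, 27), x = c(9, 18, 27)))
  slices <- lapply(1:3, function(s) {
    ph <- make_planted_phasors(centres, n_z, n_x)
    ph$slow_position <- (s - 1) * 0.75e-6
    ph$amplitude <- matrix(1e-12, n_z, n_x)
    ph$phase <- matrix(0.2, n_z, n_x)
    ph
  })
  masks <- lapply(slices, function(ph) {
    segment_stack(ph, bead_snr_db = 28)
  })
  recs <- cluster_beads(slices, masks)
  expect_equal(nrow(recs), 9)
  # centroids land on the planted centres within one voxel RMS
  px <- 0.75e-6
  truth <- cbind((centres[, 2] - 0.5) * px, (centres[, 1] - 0.5) * px)
  got <- recs[order(recs$xc, recs$zc), c("xc", "zc")]
  tr <- truth[order(truth[, 1], truth[, 2]), ]
  rms <- sqrt(mean((got$xc - tr[, 1])^2 + (got$zc - tr[, 2])^2))
  expect_lt(rms, px)
})

test_that("modulus mapping interpolates force and flags uncovered beads", {
  recs <- data.frame(id = 1:2, xc = c(0, 5e-3), yc = 0,
                     zc = c(40e-6, 40e-6),
                     a_mech = 4 * 76e-12, phi_mech = 0,
                     force = NA_real_, g_prime = NA_real_,
                     g_double_prime = NA_real_, loss_ratio = NA_real_,
                     n_voxels = 27L, qc = "")
  fmap <- force_profile(seq(-50e-6, 50e-6, 10e-6),
                        seq(0, 80e-6, 10e-6),
                        matrix(3e-12, 11, 9))
  out <- map_modulus(recs, fmap, default_bead(), medium_rho = 0,
                     include_inertia = FALSE)
  expect_equal(out$g_prime[1], 551, tolerance = 0.01)
  expect_true(is.na(out$g_prime[2]))
  expect_match(out$qc[2], "outside_force_map")
})

test_that("circular phase median is robust at the wrap point", {
  phi <- c(3.1, -3.1, 3.0, -3.0, 3.05)
  m <- pfoce:::circular_median(phi)
  expect_gt(abs(m), 2.9)   # near +/- pi, not near 0
})
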