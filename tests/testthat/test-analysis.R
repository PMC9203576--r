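# Cell segmentation, distance profiling, displacement statistics, shell
# metrics, distribution summaries and hypothesis tests.

make_speckle_stack <- function(cell_mask_2d, n_t = 24, slow_position = 0,
                               seed = 5) {
  # static speckle outside the mask, frame-decorrelating speckle inside
  n_z <- nrow(cell_mask_2d); n_x <- ncol(cell_mask_2d)
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    static <- matrix(complex(real = rnorm(n_z * n_x),
                             imaginary = rnorm(n_z * n_x)), n_z, n_x)
    field <- array(0i, c(n_t, n_z, n_x))
    for (t in seq_len(n_t)) {
      dyn <- matrix(complex(real = rnorm(n_z * n_x),
                            imaginary = rnorm(n_z * n_x)), n_z, n_x)
      frame <- ifelse(cell_mask_2d, dyn, static)
      field[t, , ] <- frame
    }
    bm_stack(field, 425, 20, slow_position = slow_position)
  })
}

test_that("static speckle yields an empty cell mask with a warning", {
  m <- matrix(FALSE, 16, 16)
  stk <- make_speckle_stack(m)
  expect_warning(mask <- speckle_segment_cell(stk), "empty")
  expect_false(any(mask))
})

test_that("an all-dynamic volume degenerates to a full mask with a warning", {
  m <- matrix(TRUE, 12, 12)
  stk <- make_speckle_stack(m)
  expect_warning(mask <- speckle_segment_cell(stk, closing_radius = 0),
                 "degenerate")
  expect_true(all(mask))
})

test_that("a planted dynamic ellipsoid is recovered with Dice >= 0.9", {
  n_z <- 30; n_x <- 30
  zz <- outer(seq_len(n_z), rep(1, n_x))
  xx <- outer(rep(1, n_z), seq_len(n_x))
  truth2d <- ((zz - 15)^2 / 9^2 + (xx - 15)^2 / 6^2) <= 1
  stacks <- lapply(1:3, function(s) {
    make_speckle_stack(truth2d, n_t = 32, slow_position = (s - 1) * 0.75e-6,
                       seed = 100 + s)
  })
  mask <- speckle_segment_cell(stacks, contrast_threshold = 0.3)
  truth <- array(rep(truth2d, 3), c(n_z, n_x, 3))
  dice <- 2 * sum(mask & truth) / (sum(mask) + sum(truth))
  expect_gte(dice, 0.9)
})

test_that("distance to a spherical mask matches the analytic distance", {
  n <- 41
  px <- 1e-6
  zz <- outer(outer((seq_len(n) - 0.5), rep(1, n)), rep(1, n))
  xx <- aperm(zz, c(2, 1, 3))
  yy <- aperm(zz, c(3, 2, 1))
  ctr <- 20.5
  mask <- sqrt((zz - ctr)^2 + (xx - ctr)^2 + (yy - ctr)^2) <= 10
  mask <- structure(mask, class = "cell_mask", pixel_z = px, pixel_x = px,
                    slow_positions = (seq_len(n) - 0.5) * px)
  # bead 25 um from the centre: true surface distance 15 um
  cent <- data.frame(xc = (ctr + 25) * px, yc = ctr * px, zc = ctr * px)
  r <- distance_to_cell(cent, mask)
  expect_equal(r, 15e-6, tolerance = sqrt(3) * px / 15e-6)
  # a bead on the surface has distance ~0
  cent0 <- data.frame(xc = (ctr + 9.4) * px, yc = ctr * px, zc = ctr * px)
  expect_lt(distance_to_cell(cent0, mask), px * sqrt(3))
  # beads inside the mask get 0
  centi <- data.frame(xc = ctr * px, yc = ctr * px, zc = ctr * px)
  expect_equal(distance_to_cell(centi, mask), 0)
  expect_error(distance_to_cell(cent, structure(array(FALSE, c(2, 2, 2)),
                                                class = "cell_mask")),
               "empty")
})

test_that("distance profile means, t-CIs and normalisation are correct", {
  recs <- data.frame(g_prime = rep(100, 12), loss_ratio = rep(0.3, 12))
  r <- seq(1e-6, 34e-6, length.out = 12)
  prof <- distance_profile(recs, r)
  expect_true(all(abs(prof$g_prime_mean - 100) < 1e-12))
  ok <- prof$n >= 2
  expect_true(all(prof$g_prime_hi[ok] - prof$g_prime_lo[ok] < 1e-9))
  # hand-checked t CI at n = 5
  x <- c(90, 95, 100, 105, 120)
  recs2 <- data.frame(g_prime = x, loss_ratio = 0.3)
  prof2 <- distance_profile(recs2, rep(1e-6, 5))
  hw <- qt(0.975, 4) * sd(x) / sqrt(5)
  expect_equal(prof2$g_prime_hi - prof2$g_prime_mean, hw,
               tolerance = 1e-12)
  expect_equal(qt(0.975, 4), 2.776, tolerance = 1e-3)
  # background normalisation maps faraway bins to unity
  recs3 <- data.frame(g_prime = c(rep(200, 6), rep(100, 6)),
                      loss_ratio = 0.3)
  r3 <- c(seq(2e-6, 17e-6, length.out = 6),
          seq(31e-6, 46e-6, length.out = 6))
  prof3 <- distance_profile(recs3, r3, normalise = TRUE)
  far <- prof3$r >= 30e-6
  expect_true(all(abs(prof3$g_prime_mean[far] - 1) < 1e-12))
})

test_that("power-law fit recovers exact exponents and rejects bad input", {
  r <- seq(2e-6, 28e-6, length.out = 20)
  g <- 300 * (r / 30e-6)^(-0.19)
  fit <- fit_power_law(r, g)
  expect_equal(fit$beta, -0.19, tolerance = 1e-10)
  # constant data: zero exponent
  fit0 <- fit_power_law(r, rep(150, 20))
  expect_equal(fit0$beta, 0, tolerance = 1e-12)
  expect_error(fit_power_law(r[1:2], g[1:2]), "at least 3")
  expect_error(fit_power_law(r, -g), "positive")
})

test_that("bulk-shift correction cancels any common translation exactly", {
  set.seed(8)
  n_b <- 7; n_t <- 5
  pos <- array(runif(n_b * n_t * 3), c(n_b, n_t, 3))
  disp0 <- cumulative_displacement(pos)
  # apply an arbitrary rigid translation per time point
  shift <- matrix(rnorm(n_t * 3), n_t, 3)
  pos2 <- pos
  for (t in seq_len(n_t)) {
    pos2[, t, ] <- pos[, t, ] +
      matrix(shift[t, ], n_b, 3, byrow = TRUE)
  }
  disp2 <- cumulative_displacement(pos2)
  expect_equal(disp2, disp0, tolerance = 1e-12)
  # all beads translated identically: zero displacement
  pos3 <- array(0, c(2, 4, 3))
  for (t in 1:4) pos3[, t, 1] <- t * 1e-6
  expect_equal(cumulative_displacement(pos3), array(0, c(2, 4, 3)))
})

test_that("equal-and-opposite motion accumulates as +/- (n-1) u", {
  u <- 2e-6; n_t <- 5
  pos <- array(0, c(2, n_t, 3))
  for (t in seq_len(n_t)) {
    pos[1, t, 1] <- (t - 1) * u
    pos[2, t, 1] <- -(t - 1) * u
  }
  disp <- cumulative_displacement(pos)
  for (t in seq_len(n_t)) {
    expect_equal(disp[1, t, 1], (t - 1) * u, tolerance = 1e-15)
    expect_equal(disp[2, t, 1], -(t - 1) * u, tolerance = 1e-15)
  }
})

test_that("signed displacement follows the dataset-level major axis", {
  # single bead moving along +x
  disp <- array(0, c(1, 4, 3))
  disp[1, , 1] <- c(0, 1, 2, 3) * 1e-6
  s <- signed_displacement(disp)
  expect_equal(s$major_axis, 1)
  expect_equal(s$S[1, ], c(0, 1, 2, 3) * 1e-6)
  # mirror symmetry: negating x negates S
  disp2 <- disp; disp2[, , 1] <- -disp2[, , 1]
  s2 <- signed_displacement(disp2)
  expect_equal(s2$S, -s$S)
  # y dominates on average: S takes the sign of the y component even for
  # a bead whose own largest component is x
  disp3 <- array(0, c(3, 2, 3))
  disp3[1, 2, ] <- c(1e-6, 5e-6, 0)
  disp3[2, 2, ] <- c(0, -4e-6, 1e-6)
  disp3[3, 2, ] <- c(3e-6, -2e-6, 0)   # x-dominant bead
  s3 <- signed_displacement(disp3)
  expect_equal(s3$major_axis, 2)
  expect_equal(sign(s3$S[3, 2]), -1)   # sign of its y component
  expect_equal(abs(s3$S[3, 2]), sqrt(9 + 4) * 1e-6)
  # all-zero displacements
  s0 <- signed_displacement(array(0, c(2, 3, 3)))
  expect_true(all(s0$S == 0))
})

test_that("deformation grouping splits by signed threshold", {
  s <- c(-5e-6, -0.1e-6, 4e-6)
  grp <- group_by_deformation(s, s_hi = 1e-6)
  expect_equal(as.character(grp),
               c("high-negative", "low", "high-positive"))
  expect_true(all(group_by_deformation(rep(0, 5), s_hi = 1e-6) == "low"))
  # percentile default reproduces tercile-like splits on a uniform grid
  s_unif <- seq(-1, 1, length.out = 99) * 1e-5
  grp2 <- group_by_deformation(s_unif)
  expect_equal(as.vector(table(grp2)), c(17, 66, 16), tolerance = 0.1)
})

test_that("uniform shells give equal Q95 and mean; empty shells flag", {
  vol <- array(2, c(24, 24, 24))
  cent <- data.frame(xc = 9e-6, yc = 9e-6, zc = 9e-6)
  sm <- shell_metrics(vol, cent, rep(0.75e-6, 3), 1.9e-6)
  expect_equal(sm$q95_intensity, 2)
  expect_equal(sm$mean_intensity, 2)
  expect_true(sm$fibre_volume_fraction %in% c(0, 1))
  expect_error(shell_metrics(vol, cent, rep(0.75e-6, 3), 1.9e-6,
                             shell = 0), "shell thickness")
})

test_that("planted shell occupancy is recovered by the fibre fraction", {
  fv <- gen_fibre_volume(n_beads = 6, shell_fraction = 0.30, seed = 9)
  sm <- shell_metrics(fv$volume, fv$centroids, fv$voxel_size, 1.9e-6,
                      noise_level = fv$noise_level)
  expect_equal(mean(sm$fibre_volume_fraction),
               mean(fv$truth$shell_fraction), tolerance = 0.05)
  expect_true(all(abs(sm$fibre_volume_fraction -
                        fv$truth$shell_fraction) < 0.06))
})

test_that("fibre fraction is invariant to global intensity rescaling", {
  fv <- gen_fibre_volume(n_beads = 4, shell_fraction = 0.4, seed = 12)
  sm1 <- shell_metrics(fv$volume, fv$centroids, fv$voxel_size, 1.9e-6,
                       noise_level = 1)
  sm2 <- shell_metrics(fv$volume * 10, fv$centroids, fv$voxel_size,
                       1.9e-6, noise_level = 10)
  expect_equal(sm1$fibre_volume_fraction, sm2$fibre_volume_fraction)
})

test_that("rank correlation hits the monotone limits and permutation p-values", {
  x <- 1:10
  expect_equal(correlate_metrics(x, x^3)$rho, 1)
  expect_equal(correlate_metrics(x, -sqrt(x))$rho, -1)
  expect_error(correlate_metrics(1:3, 1:3), "at least 4")
  expect_error(correlate_metrics(rep(1, 5), 1:5), "constant")
  # tie-free n = 8 case against the exact permutation distribution
  set.seed(14)
  xs <- rnorm(8); ys <- rnorm(8)
  got <- correlate_metrics(xs, ys)
  rho_obs <- abs(cor(xs, ys, method = "spearman"))
  rx <- rank(xs)
  perms <- all_permutations(8)
  d2 <- rowSums(sweep(perms, 2, rx)^2)
  perm_rhos <- abs(1 - 6 * d2 / (8 * (8^2 - 1)))
  p_exact <- mean(perm_rhos >= rho_obs - 1e-12)
  expect_lt(abs(got$p_value - p_exact), 0.01)
})

test_that("distribution FWHM matches the Gaussian closed form and scales", {
  set.seed(16)
  x <- rnorm(4000, sd = 3)
  f <- distribution_fwhm(x)
  expect_equal(f, 2.3548 * 3, tolerance = 0.05)
  expect_equal(distribution_fwhm(5 * x), 5 * f, tolerance = 0.02)
  expect_equal(distribution_fwhm(rep(2, 50)), 0)
})

test_that("Welch t-test on the toy samples gives t = -3.674 with df = 4", {
  gt <- group_tests(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(gt$welch$statistic), -3.674, tolerance = 1e-3)
  expect_equal(unname(gt$welch$parameter), 4, tolerance = 1e-9)
  # identical samples: p = 1
  gt0 <- group_tests(c(1, 2, 3), c(1, 2, 3))
  expect_equal(gt0$welch$p.value, 1)
  expect_equal(unname(gt0$pearson$estimate), 1)
})

test_that("Levene's test holds its nominal type-I error on equal variances", {
  set.seed(17)
  rej <- replicate(600, {
    gt <- group_tests(rnorm(15), rnorm(15))
    gt$levene[["Pr(>F)"]][1] < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("confocal post-processing thresholds at the 80th percentile and gamma-corrects", {
  img <- matrix(1:100, 10, 10)
  expect_equal(quantile(as.numeric(img), 0.8, names = FALSE), 80.2)
  out <- confocal_postprocess(img)
  expect_equal(sum(out > 0), 20)     # ~20% of pixels retained
  # gamma = 1 keeps monotone order above the threshold
  out1 <- confocal_postprocess(img, gamma = 1)
  kept <- which(out1 > 0)
  expect_true(all(diff(out1[kept]) > 0))
  expect_warning(res <- confocal_postprocess(matrix(3, 5, 5)), "constant")
  expect_true(all(res == 0))
})
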