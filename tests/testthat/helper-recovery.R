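# End-to-end parameter-recovery study: full forward generation at the
# study operating point (6400 frames at 425 Hz, 28 dB bead SNR, 20 Hz
# modulation, 0.75-um pixels) followed by the full reconstruction
# pipeline with photothermal compensation.

recovery_force_map <- function() {
  gaussian_force_profile(grid_x = seq(0, 24e-6, 1e-6),
                         grid_z = seq(0, 24e-6, 1e-6))
}

# One simulated slow-axis triplet holding 6 beads of modulus g_star;
# returns the reconstructed records with the truth attached.
run_recovery_set <- function(g_star, seed, pt_ratio = 5,
                             n_frames = 6400, snr_bead_db = 28) {
  fmap <- recovery_force_map()
  px <- 0.75e-6
  centers <- expand.grid(ix = c(8, 16, 24), iz = c(8, 16))
  pos <- cbind((centers$ix - 0.5) * px, 0.75e-6, (centers$iz - 0.5) * px)
  bead <- bead_spec(1.9e-6)
  n <- nrow(pos)
  amps <- vapply(seq_len(n), function(b) {
    response_from_modulus(g_star, interp_force(fmap, pos[b, 1], pos[b, 3]),
                          2 * pi * 20, bead, 1000)$amplitude
  }, numeric(1))
  truth <- scene_truth(pos, rep(g_star, n), fmap,
                       pt_amplitude = pt_ratio * stats::median(amps),
                       pt_phase = 0.6, snr_bead_db = snr_bead_db,
                       seed = seed)
  plan <- acquisition_plan(n_frames = n_frames, fast_range = 24e-6,
                           depth_range = 24e-6)
  sim <- gen_bm_stack(truth, plan, light_sheet_beam(), bead,
                      medium_spec(),
                      slow_positions = c(0, 0.75e-6, 1.5e-6))
  recs <- reconstruct_series(sim$stacks, fmap, bead)
  recs$g_true <- Re(g_star)
  recs
}

run_recovery_study <- function(g_prime_values = c(50, 200, 500),
                               n_sets_per_group = 9, pt_ratio = 5,
                               seed = 101) {
  out <- list()
  k <- 0
  for (gp in g_prime_values) {
    for (s in seq_len(n_sets_per_group)) {
      k <- k + 1
      out[[k]] <- run_recovery_set(complex(real = gp, imaginary = 0.3 * gp),
                                   seed = seed + k, pt_ratio = pt_ratio)
    }
  }
  do.call(rbind, out)
}
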