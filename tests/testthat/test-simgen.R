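test_that("diffusive generator has the Brownian step variance and honours D = 0", {
  cfg0 <- tiny_diffusive_config(D = 0, n = 10L)
  for (tr in simulate_diffusive(cfg0))
    expect_true(all(tr$positions == tr$positions[1]))

  cfg <- sim_config(seed = 12L, mode = "diffusive", D_true = 6.3e4,
                    frame_interval = 0.1, n_frames = 600L, n_particles = 100L,
                    assoc_time_mean = 40, mt_lengths = 1000)  # no reflection
  steps <- unlist(lapply(simulate_diffusive(cfg),
                         function(tr) diff(tr$positions))) * 1000
  expect_gt(length(steps), 1e4)
  expect_lt(abs(var(steps) / (2 * 6.3e4 * 0.1) - 1), 0.05)
})

test_that("faster-diffusing construct has larger ensemble MSD at 1 s", {
  msd_at_1s <- function(D, seed) {
    cfg <- tiny_diffusive_config(seed = seed, D = D, n = 120L)
    m <- compute_msd(simulate_diffusive(cfg), max_lag = 2)
    m$mean_msd_nm2[which.min(abs(m$lag_s - 1))]
  }
  expect_gt(msd_at_1s(9.4e4, 13L), msd_at_1s(6.3e4, 13L))
})

test_that("diffusive positions stay inside the microtubule", {
  cfg <- tiny_diffusive_config(seed = 14L, D = 2e5, n = 50L)
  for (tr in simulate_diffusive(cfg)) {
    L <- cfg$mt_lengths[tr$mt_id]
    expect_true(all(tr$positions >= 0 & tr$positions <= L))
  }
})

test_that("processive kinematics are exact without stochastic velocity", {
  # one particle at known position moving at 9 um/min = 0.15 um/s with a
  # run longer than the MT must arrive at the minus end at start/0.15
  cfg <- sim_config(seed = 1L, mode = "processive", frame_interval = 1,
                    n_frames = 400L, n_particles = 1L,
                    velocity_mean = 9, velocity_sd = 0,
                    run_length_mean = 1e6, end_dwell_mean = 10,
                    pause_rate = 0, mt_lengths = 20)
  tr <- simulate_processive(cfg)[[1]]
  p <- tr$true_params
  expect_true(p$reached_end)
  arrival <- p$bind_time + p$bind_pos / 0.15
  # position first hits zero at the interpolated arrival time
  idx <- which(tr$positions == 0)[1]
  expect_true(tr$times[idx] >= arrival - 1e-9)
  expect_true(tr$times[idx] - arrival <= 1)      # within one frame
  # exact positions on the approach
  approach <- tr$times < arrival
  expect_equal(tr$positions[approach],
               p$bind_pos - 0.15 * (tr$times[approach] - p$bind_time),
               tolerance = 1e-9)
})

test_that("run lengths and end dwells follow their exponential laws", {
  cfg <- tiny_processive_config(seed = 22L, n = 10000L)
  cfg$end_dwell_mean <- 25
  trs <- simulate_processive(cfg)
  runs <- vapply(trs, function(t) t$true_params$run_target, numeric(1))
  dwells <- vapply(trs, function(t) t$true_params$dwell_target, numeric(1))
  expect_lt(abs(mean(runs) / cfg$run_length_mean - 1), 0.03)
  ks <- suppressWarnings(stats::ks.test(dwells, "pexp", 1 / 25))
  expect_gt(ks$p.value, 0.01)
})

test_that("generator output is bit-identical under the same config and seed", {
  cfg <- tiny_processive_config(seed = 23L, n = 40L)
  expect_identical(simulate_processive(cfg), simulate_processive(cfg))
  cfgd <- tiny_diffusive_config(seed = 24L)
  expect_identical(simulate_diffusive(cfgd), simulate_diffusive(cfgd))
  stk1 <- render_spot_field(c(2000, 4000), optics_config(noise = "gaussian"))
  stk2 <- render_spot_field(c(2000, 4000), optics_config(noise = "gaussian"))
  expect_identical(stk1$channels, stk2$channels)
  cfgm <- sim_config(seed = 29L, mode = "processive", velocity_mean = 9,
                     frame_interval = 1, n_frames = 15L, n_particles = 5L,
                     mt_lengths = c(8, 10), noise_model = "gaussian")
  trm <- simulate_processive(cfgm)
  expect_identical(render_movie(trm, cfgm, field_px = c(48L, 96L))$channels,
                   render_movie(trm, cfgm, field_px = c(48L, 96L))$channels)
})

test_that("adding particles does not perturb earlier particle streams", {
  cfg_small <- tiny_processive_config(seed = 25L, n = 10L)
  cfg_big <- tiny_processive_config(seed = 25L, n = 30L)
  a <- simulate_processive(cfg_small)
  b <- simulate_processive(cfg_big)
  ids_a <- vapply(a, function(t) t$particle_id, numeric(1))
  for (k in seq_along(a))
    expect_identical(a[[k]], b[[which(vapply(b, function(t) t$particle_id,
                                             numeric(1)) == ids_a[k])]])
})

test_that("cluster intensity scales linearly with stoichiometry", {
  cfg <- sim_config(seed = 26L, mode = "diffusive", D_true = 0,
                    n_particles = 0L, maturation_fraction = 1,
                    intensity_mean = 1000, intensity_sd = 150,
                    fluorophores_per_motor = 2L)
  singles <- sample_cluster_intensities(cfg, 10000, "single")
  means <- sapply(c(2L, 4L, 6L), function(k) {
    cfg_k <- cfg
    cfg_k$motors_per_cluster_range <- c(k, k)
    mean(sample_cluster_intensities(cfg_k, 10000, "cluster", unit = "motor"))
  })
  # mean cluster intensity = 2k x single mean (2 tags per motor)
  for (j in seq_along(means))
    expect_lt(abs(means[j] / (2 * c(2, 4, 6)[j] * mean(singles)) - 1), 0.02)
  cfg_bad <- cfg
  cfg_bad$motors_per_cluster_range <- c(5L, 2L)
  expect_error(sample_cluster_intensities(cfg_bad, 5, "cluster", "motor"),
               "range")
})

test_that("photobleaching traces step down and wait geometrically", {
  cfg <- sim_config(seed = 27L, mode = "diffusive", D_true = 0,
                    n_frames = 1500L, n_particles = 0L,
                    photobleach_prob_per_frame = 0.02,
                    maturation_fraction = 1, noise_model = "none",
                    background_mean = 50)
  tr1 <- simulate_photobleach_trace(cfg, 1, trace_seed = 1)
  # single fluorophore: one down-step to background, never back up
  expect_equal(tr1$n_steps_true, 1L)
  lvl <- unique(tr1$trace)
  expect_equal(sort(lvl)[1], 50)
  expect_true(all(diff(tr1$trace) <= 0))
  # dimer at full maturation: two bleaching fluorophores per trace
  for (s in 1:20) {
    tr2 <- simulate_photobleach_trace(cfg, 2, trace_seed = s)
    expect_equal(tr2$n_fluorophores, 2L)
    expect_true(tr2$n_steps_true %in% 1:2)   # 2 unless both bleach together
  }
  # geometric waiting time: mean time to first bleach ~ frame_interval / p
  waits <- vapply(1:10000, function(s)
    simulate_photobleach_trace(cfg, 1, trace_seed = s)$bleach_frames[1],
    numeric(1)) * cfg$frame_interval
  expect_lt(abs(mean(waits) / (cfg$frame_interval / 0.02) - 1), 0.05)
})

test_that("rendered kymographs carry position, direction and velocity", {
  cfg <- sim_config(seed = 28L, mode = "processive", frame_interval = 1,
                    n_frames = 40L, n_particles = 0L, velocity_mean = 9,
                    mt_lengths = 10)
  px_um <- cfg$pixel_size / 1000
  still <- as_traj_list(line_trajectory(1, rep(5, 40)))
  ky <- render_kymograph(still, 1, cfg)
  cols <- apply(ky$green, 1, which.max)
  expect_true(all(cols == cols[1]))                     # vertical line
  moving <- as_traj_list(line_trajectory(2, seq(9, 9 - 39 * 0.15, by = -0.15)))
  ky2 <- render_kymograph(moving, 1, cfg)
  pk <- apply(ky2$green, 1, which.max)
  slope <- unname(coef(lm(pk ~ seq_len(40)))[2]) * px_um
  expect_lt(abs(slope - (-0.15)), px_um / 2)            # half px per frame
  expect_lt(slope, 0)                                   # toward the minus end
  expect_error(render_kymograph(moving, 2, cfg), "microtubule")
})

test_that("rendered movies place mass where the truth says", {
  cfg <- optics_config(seed = 32L, background_mean = 100)
  I_true <- 2 * pi * 400 * (cfg$psf_sigma / cfg$pixel_size)^2
  stk <- render_spot_field(I_true, cfg, field_px = c(41L, 41L),
                           spots_per_frame = 1L)
  truth <- attr(stk, "truth")
  fr <- stk$channels$green[, , 1]
  am <- which(fr == max(fr), arr.ind = TRUE)
  expect_lt(abs(am[1, 2] - 1 - truth$x_px), 1)
  expect_lt(abs(am[1, 1] - 1 - truth$y_px), 1)
  # integrated signal above background equals 2 pi A sigma^2
  expect_lt(abs(sum(fr - 100) / I_true - 1), 0.01)
})

test_that("organization fields conserve mass while contrast develops", {
  cfg <- fixture_config("org_aster")
  cfg$noise_model <- "none"
  stk <- simulate_organization_field(cfg, "aster")
  sums <- apply(stk$channels$tubulin, 3, sum)
  expect_lt(max(abs(sums / sums[1] - 1)), 0.01)
  ctr <- compute_contrast(stk)
  expect_equal(ctr$contrast[1], 0)
  expect_gt(ctr$contrast[nrow(ctr)], 0)
  uni <- simulate_organization_field(cfg, "uniform")
  expect_true(all(compute_contrast(uni)$contrast == 0))
  expect_error(simulate_organization_field(cfg, "spiral"))
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(sim_config(mode = "diffusive", D_true = -1), "D_true")
  expect_error(sim_config(mode = "diffusive", D_true = 1, frame_interval = 0),
               "frame_interval")
  expect_error(sim_config(mode = "processive", velocity_mean = -3),
               "velocity_mean")
  expect_error(sim_config(mode = "diffusive", D_true = 1,
                          photobleach_prob_per_frame = 1.5), "photobleach")
  expect_error(sim_config(mode = "diffusive", D_true = 1, mt_lengths = c(-2)),
               "mt_lengths")
})
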