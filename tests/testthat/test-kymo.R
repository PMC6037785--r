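test_that("kymograph extraction from a rendered movie recovers the slope", {
  cfg <- sim_config(seed = 61L, mode = "processive", frame_interval = 1,
                    n_frames = 48L, n_particles = 0L, velocity_mean = 9,
                    mt_lengths = 8)
  px_um <- cfg$pixel_size / 1000
  tj <- line_trajectory(1, seq(7.4, 7.4 - 47 * 0.15, by = -0.15))
  stk <- render_movie(as_traj_list(tj), cfg, field_px = c(64L, 96L))
  geom <- mt_field_geometry(cfg, c(64L, 96L))
  line <- rbind(c(geom$x0_um, geom$y0_um) / px_um,
                c(geom$x0_um + 8, geom$y0_um) / px_um)
  ky <- build_kymograph(stk, line, "green", width = 3)
  pk <- apply(ky, 1, which.max)
  slope <- unname(coef(lm(pk ~ seq_along(pk)))[2]) * px_um
  expect_lt(abs(slope / (-0.15) - 1), 0.05)
  # stationary particle gives a vertical stripe
  stk2 <- render_movie(as_traj_list(line_trajectory(2, rep(4, 48))), cfg,
                       field_px = c(64L, 96L))
  ky2 <- build_kymograph(stk2, line, "green")
  expect_equal(length(unique(apply(ky2, 1, which.max))), 1)
  expect_error(build_kymograph(stk, rbind(c(1, 1), c(1.5, 1))), "polyline")
})

test_that("the 3-pixel band recovers more frames of a laterally jittered track", {
  cfg <- sim_config(seed = 62L, mode = "processive", frame_interval = 1,
                    n_frames = 60L, n_particles = 0L, velocity_mean = 9,
                    mt_lengths = 12)
  px_um <- cfg$pixel_size / 1000
  set.seed(63)
  tj <- new_trajectory(1, 1, times = 0:59,
                       positions = seq(10, 10 - 59 * 0.12, by = -0.12),
                       lateral = rnorm(60, 0, 1.2 * px_um),
                       intensities = rep(4000, 60))
  stk <- render_movie(as_traj_list(tj), cfg, field_px = c(64L, 128L))
  geom <- mt_field_geometry(cfg, c(64L, 128L))
  line <- rbind(c(geom$x0_um, geom$y0_um) / px_um,
                c(geom$x0_um + 12, geom$y0_um) / px_um)
  thr <- 100 + 0.7 * 4000 / (2 * pi * (cfg$psf_sigma / cfg$pixel_size)^2)
  frames_above <- function(width) {
    ky <- build_kymograph(stk, line, "green", width = width)
    sum(apply(ky, 1, max) > thr)
  }
  expect_gte(frames_above(3), 1.2 * frames_above(1))
})

test_that("a composite run with an embedded pause yields hand-computed metrics", {
  # 5 um of minus-end motion over 50 s with a 20 s stall: run length 5 um,
  # moving time 30 s, velocity 1/6 um/s
  pos <- c(6 - (5 / 30) * (0:15),                       # moving, t = 0..15
           rep(6 - (5 / 30) * 15, 19),                  # stalled, t = 16..34
           6 - (5 / 30) * 15 - (5 / 30) * (1:15))       # moving, t = 35..50
  cfg <- sim_config(seed = 64L, mode = "processive", frame_interval = 1,
                    n_frames = 200L, n_particles = 0L, velocity_mean = 9,
                    mt_lengths = 20)
  ev <- extract_events(as_traj_list(line_trajectory(1, pos, t0 = 10)), cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$run_length_um, 5, tolerance = 1e-9)
  expect_equal(ev$moving_time_s, 30, tolerance = 1e-9)
  expect_equal(ev$velocity_um_s, 5 / 30, tolerance = 1e-9)
  expect_equal(ev$n_pauses, 1L)
  expect_false(ev$reached_end)
  # the defining identity: run length equals velocity times moving time
  expect_equal(ev$run_length_um, ev$velocity_um_s * ev$moving_time_s)
})

test_that("minimum length, censoring and stationarity rules are enforced", {
  cfg <- sim_config(seed = 65L, mode = "processive", frame_interval = 1,
                    n_frames = 100L, n_particles = 0L, velocity_mean = 9,
                    mt_lengths = 20)
  four <- line_trajectory(1, seq(10, 9.4, length.out = 4))
  at_end <- line_trajectory(2, seq(12, 12 - 0.15 * 19, length.out = 20),
                            t0 = 80)             # still bound at last frame
  still <- line_trajectory(3, rep(5, 30))
  ev <- extract_events(as_traj_list(four, at_end, still), cfg)
  expect_equal(nrow(ev), 3)
  expect_true(ev$censored_end[ev$particle_id == 2])
  expect_true(ev$stationary[ev$particle_id == 3])
  # the 4-frame association never reaches any statistic
  for (m in c("run_length", "velocity", "end_dwell", "frequency"))
    expect_false(1 %in% filter_for_metric(ev, m)$particle_id)
  # censored and stationary events are excluded from run length / velocity
  expect_false(2 %in% filter_for_metric(ev, "run_length")$particle_id)
  expect_false(2 %in% filter_for_metric(ev, "velocity")$particle_id)
  expect_false(3 %in% filter_for_metric(ev, "frequency")$particle_id)
  expect_error(filter_for_metric(ev, "speed"))
})

test_that("end-reaching events are treated separately and coincident dwells drop", {
  cfg <- sim_config(seed = 66L, mode = "processive", frame_interval = 1,
                    n_frames = 300L, n_particles = 0L, velocity_mean = 9,
                    mt_lengths = c(20, 20))
  # two particles arriving at the same MT end with overlapping dwells
  arrive <- function(id, mt, t0, dwell_frames) {
    appr <- seq(3, 0, by = -0.15)
    new_trajectory(id, mt, times = t0 + seq_len(21 + dwell_frames) - 1,
                   positions = c(appr, rep(0, dwell_frames)),
                   intensities = rep(1000, 21 + dwell_frames))
  }
  trs <- as_traj_list(arrive(1, 1, 10, 30), arrive(2, 1, 25, 30),
                      arrive(3, 2, 10, 30),
                      line_trajectory(4, seq(15, 15 - 0.15 * 29,
                                             length.out = 30), t0 = 5,
                                      mt_id = 2))
  ev <- extract_events(trs, cfg)
  expect_equal(sum(ev$reached_end), 3)
  dw <- filter_for_metric(ev, "end_dwell")
  expect_setequal(dw$particle_id, 3)          # overlapping pair removed
  rl <- filter_for_metric(ev, "run_length")
  expect_false(any(rl$reached_end))
  expect_equal(sort(attr(rl, "end_reaching")$particle_id), c(1, 2, 3))
  # interior mover is retained everywhere
  expect_true(4 %in% rl$particle_id)
  expect_true(4 %in% filter_for_metric(ev, "velocity")$particle_id)
  # dwell read at the corner: 30 at-end frames + half-frame detach gap
  expect_equal(dw$end_dwell_s, 30.5, tolerance = 0.101)
})

test_that("event frequency is events per minute per micrometre", {
  ev <- data.frame(event_id = 1:12)
  f <- event_frequency(ev, mt_lengths_um = c(20, 40), observation_time_min = 10)
  expect_equal(f$frequency, 0.02)
  expect_equal(event_frequency(ev[0, , drop = FALSE], 60, 10)$frequency, 0)
  expect_error(event_frequency(ev, c(60), 0), "observation")
  expect_error(event_frequency(ev, numeric(0), 10), "lengths")
})

test_that("event frequency is stationary under a longer observation window", {
  freq_for <- function(n_frames, seed) {
    cfg <- tiny_processive_config(seed = seed, n = 200L)
    cfg$n_frames <- n_frames
    # constant binding rate: events per unit time fixed
    cfg$n_particles <- as.integer(200 * n_frames / 600)
    ev <- filter_for_metric(extract_events(simulate_processive(cfg), cfg),
                            "frequency")
    event_frequency(ev, cfg$mt_lengths, n_frames / 60)$frequency
  }
  ratios <- vapply(1:8, function(s)
    freq_for(1200L, 500 + s) / freq_for(600L, 500 + s), numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.15)
})

test_that("per-microtubule event counts sum to the total and censoring matches truth", {
  cfg <- fixture_config("tubulin_transport")
  cfg$n_particles <- 400L
  trajs <- simulate_processive(cfg)
  ev <- extract_events(trajs, cfg)
  expect_equal(sum(table(ev$mt_id)), nrow(ev))
  # censoring flags agree with generator ground truth
  truth_cens <- vapply(trajs, function(t) t$true_params$censored_end,
                       logical(1))
  expect_equal(ev$censored_end, truth_cens)
  truth_end <- vapply(trajs, function(t) t$true_params$reached_end,
                      logical(1))
  truth_dwell <- vapply(trajs, function(t) t$true_params$dwell_target,
                        numeric(1))
  # every true end-reacher with a resolvable (>= 3 frame) uncensored dwell
  # that starts visibly away from the end is scored as end-reaching
  # (binding directly at the end shows no motion and reads as stationary)
  first_pos <- vapply(trajs, function(t) t$positions[1], numeric(1))
  resolvable <- truth_end & truth_dwell >= 3 & !truth_cens &
    first_pos > 3 * cfg$pixel_size / 1000
  expect_true(all(ev$reached_end[resolvable]))
  # every event scored end-reaching terminates within the end tolerance
  # (a detachment just short of the end is indistinguishable from a brief
  # dwell at the frame rate, so truth may disagree only inside that band)
  tol <- 2 * cfg$pixel_size / 1000
  expect_true(all(ev$end_pos[ev$reached_end] <= tol))
})
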