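# Small configurations used across tests; built in code, no stored fixtures.

tiny_diffusive_config <- function(seed = 11L, D = 6.3e4, n = 30L) {
  sim_config(seed = seed, mode = "diffusive", D_true = D,
             frame_interval = 0.1, n_frames = 200L, n_particles = n,
             assoc_time_mean = 10, mt_lengths = c(15, 20))
}

tiny_processive_config <- function(seed = 21L, n = 200L, ...) {
  sim_config(seed = seed, mode = "processive", frame_interval = 1,
             n_frames = 600L, n_particles = n,
             velocity_mean = 9, velocity_sd = 1.5,
             run_length_mean = 4, end_dwell_mean = 20,
             pause_rate = 0, mt_lengths = rep(c(15, 20, 25), 8), ...)
}

optics_config <- function(seed = 31L, noise = "none", ...) {
  sim_config(seed = seed, mode = "diffusive", D_true = 0,
             frame_interval = 0.1, n_frames = 10L, n_particles = 0L,
             noise_model = noise, ...)
}

# one synthetic spot on a constant background, sub-pixel position
spot_frame <- function(x, y, intensity, background = 100, size = c(31L, 31L),
                       sigma_px = 1.3, noise_sd = 0) {
  img <- matrix(background, size[1], size[2])
  img <- kinetracer:::add_spot(img, x, y, intensity, sigma_px)
  if (noise_sd > 0) img <- img + matrix(rnorm(length(img), 0, noise_sd),
                                        nrow(img))
  img
}

# straight-line trajectory helper (positions um, 1 s frames by default)
line_trajectory <- function(id, positions, dt = 1, t0 = 0, mt_id = 1,
                            intensity = 5000) {
  new_trajectory(id, mt_id,
                 times = t0 + (seq_along(positions) - 1) * dt,
                 positions = positions,
                 intensities = rep(intensity, length(positions)))
}

as_traj_list <- function(...) structure(list(...), class = "trajectory_list")
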