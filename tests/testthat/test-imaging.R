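test_that("maxima detection finds isolated spots and nothing else", {
  expect_equal(nrow(detect_maxima(matrix(5, 20, 20), 1)), 0)
  expect_equal(nrow(detect_maxima(matrix(numeric(0), 0, 0), 1)), 0)
  img <- spot_frame(12.2, 8.7, 6000)
  got <- detect_maxima(img, 150)
  expect_equal(nrow(got), 1)
  expect_lt(abs(got$x_px - 12.2), 1)
  expect_lt(abs(got$y_px - 8.7), 1)
})

test_that("two spots ten pixels apart are both detected at SNR 10", {
  found <- 0L
  for (s in 1:30) {
    set.seed(s)
    noise_sd <- 10
    A <- 10 * noise_sd                      # SNR 10 amplitude
    I <- 2 * pi * A * 1.3^2
    img <- spot_frame(10.3, 15.1, I, noise_sd = noise_sd)
    img <- kinetracer:::add_spot(img, 20.3, 15.1, I, 1.3)
    got <- detect_maxima(img, 100 + 5 * noise_sd)
    ok <- nrow(got) == 2 &&
      min(abs(got$x_px - 10.3)) < 2 && min(abs(got$x_px - 20.3)) < 2
    found <- found + ok
  }
  expect_gte(found, 29)
})

test_that("2D Gaussian fit recovers amplitude, background and volume", {
  img <- spot_frame(15, 15, 2 * pi * 500 * 1.3^2)
  sf <- fit_gaussian_2d(img, list(x_px = 15, y_px = 15))
  expect_true(sf$fit_success)
  expect_lt(abs(sf$amplitude / 500 - 1), 1e-3)
  expect_lt(abs(sf$local_background / 100 - 1), 1e-3)
  expect_lt(abs(sf$integrated_intensity / (2 * pi * 500 * 1.3^2) - 1), 1e-3)
  # invariant: integrated intensity equals 2 pi A sigma^2
  expect_equal(sf$integrated_intensity, 2 * pi * sf$amplitude * sf$sigma^2)
})

test_that("pure background yields a failed or null fit, never an error", {
  img <- matrix(100, 31, 31)
  sf <- fit_gaussian_2d(img, list(x_px = 15, y_px = 15))
  expect_true(!sf$fit_success ||
                sf$integrated_intensity < 0.01 * 2 * pi * 500 * 1.3^2)
  # edge candidate flags clipping and does not throw
  img2 <- spot_frame(1, 1, 5000)
  sf2 <- fit_gaussian_2d(img2, list(x_px = 1, y_px = 1))
  expect_true(sf2$edge_clipped)
})

test_that("sub-pixel centroids are recovered within 0.1 px RMS at SNR 20", {
  errs <- numeric(40)
  for (s in 1:40) {
    set.seed(100 + s)
    noise_sd <- 10
    A <- 20 * noise_sd
    img <- spot_frame(15.3, 14.7, 2 * pi * A * 1.3^2, noise_sd = noise_sd)
    sf <- fit_gaussian_2d(img, list(x_px = 15, y_px = 15))
    errs[s] <- sqrt((sf$centroid_x - 15.3)^2 + (sf$centroid_y - 14.7)^2)
  }
  expect_lt(sqrt(mean(errs^2)), 0.1)
})

test_that("integrated intensity is background-invariant and flux-linear", {
  set.seed(7)
  base <- sapply(1:25, function(i) {
    img <- spot_frame(15.2, 15.4, 5000, background = 100)
    fit_gaussian_2d(img, list(x_px = 15, y_px = 15))
  }, simplify = FALSE)
  for (i in seq_along(base)) {
    img0 <- spot_frame(15.2, 15.4, 5000, background = 100)
    imgc <- img0 + 250
    f0 <- fit_gaussian_2d(img0, list(x_px = 15, y_px = 15))
    fc <- fit_gaussian_2d(imgc, list(x_px = 15, y_px = 15))
    expect_lt(abs(fc$local_background - f0$local_background - 250), 1)
    expect_lt(abs(fc$integrated_intensity / f0$integrated_intensity - 1), 0.01)
  }
  f1 <- fit_gaussian_2d(spot_frame(15, 15, 4000), list(x_px = 15, y_px = 15))
  f2 <- fit_gaussian_2d(spot_frame(15, 15, 8000), list(x_px = 15, y_px = 15))
  expect_lt(abs(f2$integrated_intensity / f1$integrated_intensity - 2), 0.02)
})

test_that("first-frame summaries use one intensity per particle", {
  spots <- data.frame(particle_id = rep(1:3, each = 4),
                      frame = rep(1:4, 3),
                      intensity = c(10, 1, 1, 1, 20, 2, 2, 2, 30, 3, 3, 3))
  s <- first_frame_intensities(spots, "moving_first_frame")
  expect_equal(s$n, 3)
  expect_equal(s$mean, 20)
  expect_equal(sum(s$normalized_counts), 1)
  expect_error(first_frame_intensities(data.frame(intensity = numeric())),
               "usable")
})

test_that("photobleach step counting matches staircases and separates
           dimers from aggregates", {
  # noiseless two-step staircase
  stair <- c(rep(2100, 40), rep(1080, 40), rep(60, 60))
  st <- count_photobleach_steps(stair, single_intensity = 1000)
  expect_equal(st$n_steps, 2L)
  expect_equal(count_photobleach_steps(rep(0, 50))$n_steps, 0L)

  cfg <- sim_config(seed = 41L, mode = "diffusive", D_true = 0,
                    n_frames = 300L, n_particles = 0L,
                    photobleach_prob_per_frame = 0.02,
                    maturation_fraction = 1, intensity_mean = 1000,
                    intensity_sd = 100, background_mean = 100,
                    noise_model = "gaussian", noise_sd = 100)  # SNR 10
  dimer_ok <- 0L
  for (s in 1:100) {
    tr <- simulate_photobleach_trace(cfg, 2, trace_seed = s)
    n <- count_photobleach_steps(tr$trace, single_intensity = 1000)$n_steps
    dimer_ok <- dimer_ok + (n %in% 1:2)
  }
  expect_gte(dimer_ok, 90)                  # dimer criterion
  agg_gt2 <- 0L
  for (s in 1:60) {
    tr <- simulate_photobleach_trace(cfg, 5, trace_seed = 500 + s)
    n <- count_photobleach_steps(tr$trace, single_intensity = 1000)$n_steps
    agg_gt2 <- agg_gt2 + (n > 2)
  }
  expect_gt(agg_gt2, 30)                    # aggregates are distinguishable
})

test_that("expected step count rises with true fluorophore number", {
  cfg <- sim_config(seed = 42L, mode = "diffusive", D_true = 0,
                    n_frames = 250L, n_particles = 0L,
                    photobleach_prob_per_frame = 0.025,
                    maturation_fraction = 1, intensity_mean = 1000,
                    intensity_sd = 100, background_mean = 100,
                    noise_model = "gaussian", noise_sd = 80)
  mean_steps <- sapply(1:6, function(k) {
    mean(vapply(1:60, function(s)
      count_photobleach_steps(
        simulate_photobleach_trace(cfg, k, trace_seed = 1000 * k + s)$trace,
        single_intensity = 1000)$n_steps, numeric(1)))
  })
  expect_true(all(diff(mean_steps) > -0.15))   # nondecreasing in expectation
  expect_gt(mean_steps[6], mean_steps[1])
})
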