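#' Simulate diffusive single-motor trajectories on microtubule tracks
#'
#' Each particle performs 1D Brownian motion along its microtubule with
#' per-frame displacements drawn from a zero-mean Gaussian of variance
#' `2 * D_true * frame_interval`, reflected at the microtubule ends.
#' Association lifetimes are exponential with mean `assoc_time_mean`;
#' binding times are uniform over the acquisition. Ground-truth labels and
#' generating values are attached to every trajectory.
#'
#' @param config a `sim_config` with `mode = "diffusive"`.
#' @return a list of `trajectory` objects (class `trajectory_list`).
#' @export
simulate_diffusive <- function(config) {
  validate_config(config)
  if (config$mode != "diffusive")
    stop("config mode must be 'diffusive'", call. = FALSE)
  dt <- config$frame_interval
  step_sd_um <- sqrt(2 * config$D_true * dt) / 1000
  out <- vector("list", config$n_particles)
  for (i in seq_len(config$n_particles)) {
    set.seed(child_seed(config$seed, i))
    mt_id <- ((i - 1L) %% length(config$mt_lengths)) + 1L
    L <- config$mt_lengths[mt_id]
    start_frame <- sample.int(config$n_frames, 1L)
    lifetime_frames <- max(1L, 1L + floor(stats::rexp(1, 1 / config$assoc_time_mean) / dt))
    n_i <- min(config$n_frames - start_frame + 1L, lifetime_frames)
    pos <- numeric(n_i)
    pos[1] <- stats::runif(1, 0, L)
    if (n_i > 1) {
      steps <- stats::rnorm(n_i - 1, 0, step_sd_um)
      for (k in 2:n_i) pos[k] <- reflect_interval(pos[k - 1] + steps[k - 1], 0, L)
    }
    n_fluor <- max(1L, stats::rbinom(1, config$fluorophores_per_motor,
                                     config$maturation_fraction))
    inten <- pmax(1, stats::rnorm(n_i, n_fluor * config$intensity_mean,
                                  sqrt(n_fluor) * config$intensity_sd))
    out[[i]] <- new_trajectory(
      particle_id = i, mt_id = mt_id,
      times = (start_frame - 1L + seq_len(n_i) - 1L) * dt,
      positions = pos,
      lateral = stats::rnorm(n_i, 0, 0.03),
      intensities = inten, channel = "green",
      true_mode = "diffusive",
      true_params = list(D_true = config$D_true, mt_length = L,
                         start_frame = start_frame)
    )
  }
  structure(out, class = "trajectory_list")
}

#' Simulate processive minus-end-directed transport events
#'
#' Each event binds at a uniform random lattice position and time, moves
#' toward the minus end (position 0) at a per-event velocity drawn once from
#' `Normal(velocity_mean, velocity_sd)`, optionally pauses (Poisson onset at
#' `pause_rate`, exponential durations), and detaches after an exponential
#' run length -- unless it reaches the minus end first, in which case it
#' dwells there for an exponential `end_dwell_mean` before detaching. Events
#' truncated by the acquisition window are flagged censored; the flags are
#' recorded, never dropped.
#'
#' @param config a `sim_config` with `mode = "processive"`.
#' @return a `trajectory_list`; each trajectory's `true_params` carries the
#'   generating velocity, run-length and dwell draws, the continuous
#'   binding/detachment times and the end-arrival/censoring truth.
#' @export
simulate_processive <- function(config) {
  validate_config(config)
  if (config$mode != "processive")
    stop("config mode must be 'processive'", call. = FALSE)
  dt <- config$frame_interval
  T_total <- config$n_frames * dt
  out <- vector("list", config$n_particles)
  kept <- 0L
  for (i in seq_len(config$n_particles)) {
    set.seed(child_seed(config$seed, i))
    mt_id <- ((i - 1L) %% length(config$mt_lengths)) + 1L
    L <- config$mt_lengths[mt_id]
    bind_time <- stats::runif(1, 0, T_total)
    bind_pos <- stats::runif(1, 0, L)
    v <- stats::rnorm(1, config$velocity_mean, config$velocity_sd)
    v <- max(v, 0.05 * config$velocity_mean)      # guard a nonphysical draw
    v_ums <- v / 60
    run_target <- stats::rexp(1, 1 / config$run_length_mean)
    dwell_target <- if (config$end_dwell_mean > 0)
      stats::rexp(1, 1 / config$end_dwell_mean) else 0
    seg <- build_event_segments(bind_time, bind_pos, v_ums, run_target,
                                dwell_target, config$pause_rate,
                                config$pause_duration_mean)
    detach_time <- seg$end_time
    censored_end <- detach_time > T_total
    end_time <- min(detach_time, T_total)
    # camera frames during which the particle is bound
    j0 <- ceiling(bind_time / dt)
    j1 <- min(floor(end_time / dt), config$n_frames - 1L)
    if (j1 < j0) next
    tt <- (j0:j1) * dt
    pos <- eval_segments(seg$segments, tt)
    stoich <- sample_integer_range(config$tubulins_per_cluster_range, 1)
    inten <- pmax(1, stats::rnorm(length(tt), stoich * config$intensity_mean,
                                  sqrt(stoich) * config$intensity_sd))
    kept <- kept + 1L
    out[[kept]] <- new_trajectory(
      particle_id = i, mt_id = mt_id,
      times = tt, positions = pos,
      lateral = stats::rnorm(length(tt), 0, 0.03),
      intensities = inten, channel = "farred",
      true_mode = "processive",
      true_params = list(
        velocity = v, run_target = run_target, dwell_target = dwell_target,
        bind_time = bind_time, bind_pos = bind_pos,
        detach_time = detach_time, mt_length = L,
        reached_end = seg$reached_end, censored_end = censored_end,
        stoichiometry = stoich,
        n_pauses = seg$n_pauses, paused_time = seg$paused_time)
    )
  }
  structure(out[seq_len(kept)], class = "trajectory_list")
}

# Piecewise-linear event timeline: moving / paused / end-dwell segments.
# Returns segments (start_time, end_time, start_pos, slope um/s), the
# continuous detachment time, and the end-arrival truth.
build_event_segments <- function(bind_time, bind_pos, v_ums, run_target,
                                 dwell_target, pause_rate,
                                 pause_duration_mean) {
  segs <- list()
  t <- bind_time; p <- bind_pos; travelled <- 0
  reached_end <- FALSE
  n_pauses <- 0L; paused_time <- 0
  repeat {
    t_pause <- if (pause_rate > 0) stats::rexp(1, pause_rate) else Inf
    t_detach <- (run_target - travelled) / v_ums
    t_end <- p / v_ums
    t_next <- min(t_pause, t_detach, t_end)
    segs[[length(segs) + 1L]] <- c(t, t + t_next, p, -v_ums)
    travelled <- travelled + v_ums * t_next
    p <- p - v_ums * t_next
    t <- t + t_next
    if (t_end <= t_pause && t_end <= t_detach) {        # arrived at minus end
      reached_end <- TRUE
      p <- 0
      segs[[length(segs) + 1L]] <- c(t, t + dwell_target, 0, 0)
      t <- t + dwell_target
      break
    } else if (t_detach <= t_pause) {                    # ran its run length
      break
    } else {                                             # pause (stall)
      dur <- stats::rexp(1, 1 / pause_duration_mean)
      segs[[length(segs) + 1L]] <- c(t, t + dur, p, 0)
      t <- t + dur
      n_pauses <- n_pauses + 1L
      paused_time <- paused_time + dur
    }
  }
  list(segments = do.call(rbind, segs), end_time = t,
       reached_end = reached_end, n_pauses = n_pauses,
       paused_time = paused_time)
}

eval_segments <- function(segments, times) {
  pos <- numeric(length(times))
  for (k in seq_along(times)) {
    t <- times[k]
    row <- which(segments[, 1] <= t & t <= segments[, 2])
    if (!length(row)) row <- if (t < segments[1, 1]) 1L else nrow(segments)
    row <- row[1]
    pos[k] <- max(0, segments[row, 3] + segments[row, 4] * (t - segments[row, 1]))
  }
  pos
}

reflect_interval <- function(x, lo, hi) {
  span <- hi - lo
  while (x < lo || x > hi) {
    if (x < lo) x <- 2 * lo - x
    if (x > hi) x <- 2 * hi - x
  }
  x
}

sample_integer_range <- function(range, n) {
  vals <- range[1]:range[2]
  if (length(vals) == 1L) rep(vals, n) else sample(vals, n, replace = TRUE)
}

#' Sample fluorescence intensities of single fluorophores or clusters
#'
#' Singles get one fluorophore intensity draw each (only matured, hence
#' visible, fluorophores are ever sampled on a coverslip). Clusters draw a
#' stoichiometry uniformly on the configured integer range and sum
#' per-fluorophore draws; for fluorescent-protein tags each subunit carries
#' `fluorophores_per_motor` tags of which a `maturation_fraction` are bright.
#'
#' @param config a `sim_config`.
#' @param n number of particles to draw.
#' @param kind `"single"` or `"cluster"`.
#' @param unit for clusters, `"tubulin"` (one dye each, no maturation) or
#'   `"motor"` (`fluorophores_per_motor` tags each, maturation applied).
#' @return numeric vector of `n` positive intensities (a.u.).
#' @export
sample_cluster_intensities <- function(config, n,
                                       kind = c("single", "cluster"),
                                       unit = c("tubulin", "motor")) {
  validate_config(config)
  kind <- match.arg(kind); unit <- match.arg(unit)
  stopifnot(n >= 1)
  set.seed(child_seed(config$seed, 0L, stream = 11L))
  if (kind == "single")
    return(pmax(1, stats::rnorm(n, config$intensity_mean, config$intensity_sd)))
  rng <- if (unit == "tubulin") config$tubulins_per_cluster_range
         else config$motors_per_cluster_range
  if (rng[1] > rng[2]) stop("empty stoichiometry range", call. = FALSE)
  stoich <- sample_integer_range(rng, n)
  n_fluor <- if (unit == "tubulin") stoich
             else stats::rbinom(n, stoich * config$fluorophores_per_motor,
                                config$maturation_fraction)
  n_fluor <- pmax(1L, n_fluor)
  pmax(1, stats::rnorm(n, n_fluor * config$intensity_mean,
                       sqrt(n_fluor) * config$intensity_sd))
}

#' Simulate a stepwise photobleaching intensity trace
#'
#' Each fluorophore bleaches independently per frame with probability
#' `photobleach_prob_per_frame`; the trace is the background plus the summed
#' intensity of surviving fluorophores plus configured noise.
#'
#' @param config a `sim_config`.
#' @param n_fluorophores number of initially bright fluorophores.
#' @param trace_seed optional seed offset for drawing many traces from one
#'   config.
#' @return a list: `trace` (a.u. per frame), `times` (s),
#'   `n_fluorophores`, `n_steps_true` (distinct bleaching frames, i.e.
#'   observable down-steps), `bleach_frames`.
#' @export
simulate_photobleach_trace <- function(config, n_fluorophores,
                                       trace_seed = 1L) {
  validate_config(config)
  stopifnot(n_fluorophores >= 1)
  p <- config$photobleach_prob_per_frame
  set.seed(child_seed(config$seed, trace_seed, stream = 13L))
  bleach_frame <- 1L + stats::rgeom(n_fluorophores, p)   # frame of the step
  levels <- pmax(1, stats::rnorm(n_fluorophores, config$intensity_mean,
                                 config$intensity_sd))
  nf <- config$n_frames
  trace <- numeric(nf)
  for (k in seq_len(n_fluorophores)) {
    alive <- seq_len(nf) < bleach_frame[k]
    trace <- trace + levels[k] * alive
  }
  trace <- trace + config$background_mean
  trace <- add_noise(trace, config)
  bf <- sort(unique(bleach_frame[bleach_frame <= nf]))
  list(trace = trace, times = (seq_len(nf) - 1) * config$frame_interval,
       n_fluorophores = n_fluorophores,
       n_steps_true = length(bf), bleach_frames = bf)
}

add_noise <- function(x, config) {
  switch(config$noise_model,
         none = x,
         gaussian = pmax(0, x + stats::rnorm(length(x), 0, config$noise_sd)),
         poisson = stats::rpois(length(x), pmax(x, 0)))
}

#' Render a two-channel kymograph directly from trajectories
#'
#' The red channel is the static microtubule line profile; the green/far-red
#' channel is a per-frame line scan along the microtubule axis in which every
#' trajectory appears as a 1D Gaussian of the PSF width, attenuated by the
#' fraction of its lateral PSF mass falling inside a 3-pixel-wide band around
#' the axis. Rows are time, columns are distance from the minus end.
#'
#' @param trajectories a `trajectory_list`, all on the same microtubule.
#' @param mt_id id of that microtubule.
#' @param config the generating `sim_config`.
#' @param band_width_px lateral integration band, pixels.
#' @return list of matrices `green` and `red` (rows = frames, cols = pixels
#'   along the axis) with attributes `pixel_size`, `frame_interval`.
#' @export
render_kymograph <- function(trajectories, mt_id, config, band_width_px = 3) {
  ids <- vapply(trajectories, function(tr) tr$mt_id, numeric(1))
  if (length(ids) && any(ids != mt_id))
    stop("trajectory not on the requested microtubule", call. = FALSE)
  L_um <- config$mt_lengths[mt_id]
  px_um <- config$pixel_size / 1000
  n_col <- max(2L, ceiling(L_um / px_um))
  n_row <- config$n_frames
  sig_px <- config$psf_sigma / config$pixel_size
  green <- matrix(0, n_row, n_col)
  xs <- (seq_len(n_col) - 1) * px_um
  dt <- config$frame_interval
  half_band_um <- band_width_px / 2 * px_um
  sig_um <- config$psf_sigma / 1000
  for (tr in trajectories) {
    frames <- round(tr$times / dt) + 1L
    keep <- frames >= 1 & frames <= n_row
    for (k in which(keep)) {
      lat <- tr$lateral[k]
      w_lat <- stats::pnorm(half_band_um, lat, sig_um) -
        stats::pnorm(-half_band_um, lat, sig_um)
      amp <- tr$intensities[k] * w_lat / (sqrt(2 * pi) * sig_px)
      green[frames[k], ] <- green[frames[k], ] +
        amp * exp(-(xs - tr$positions[k])^2 / (2 * sig_um^2))
    }
  }
  red_profile <- rep(1, n_col)
  red_profile[xs > L_um] <- 0
  red <- matrix(rep(red_profile, each = n_row), n_row, n_col)
  green <- add_noise(green + config$background_mean / 10, config)
  structure(list(green = green, red = red),
            pixel_size = config$pixel_size, frame_interval = dt,
            class = "kymograph")
}

#' Render a TIRF-like movie of point emitters
#'
#' Particles are drawn as symmetric 2D Gaussian PSFs at their true sub-pixel
#' field positions over a constant background with configured noise. A
#' ground-truth table of per-frame positions and integrated intensities is
#' attached.
#'
#' @param trajectories a `trajectory_list`.
#' @param config the generating `sim_config`.
#' @param geometry microtubule field geometry from [mt_field_geometry()];
#'   built automatically when `NULL`.
#' @param field_px `c(ny, nx)` field size in pixels.
#' @return a `field_stack` (see [field_stack()]) with channels `green` and
#'   `red` and attribute `truth` (data.frame).
#' @export
render_movie <- function(trajectories, config, geometry = NULL,
                         field_px = c(128L, 128L)) {
  if (is.null(geometry)) geometry <- mt_field_geometry(config, field_px)
  px_um <- config$pixel_size / 1000
  sig_px <- config$psf_sigma / config$pixel_size
  ny <- field_px[1]; nx <- field_px[2]
  dt <- config$frame_interval
  green <- array(0, c(ny, nx, config$n_frames))
  truth <- list()
  for (tr in trajectories) {
    g <- geometry[geometry$mt_id == tr$mt_id, ]
    if (!nrow(g)) stop("trajectory on microtubule absent from geometry")
    th <- g$angle_deg * pi / 180
    frames <- round(tr$times / dt) + 1L
    keep <- which(frames >= 1 & frames <= config$n_frames)
    x_um <- g$x0_um + cos(th) * tr$positions - sin(th) * tr$lateral
    y_um <- g$y0_um + sin(th) * tr$positions + cos(th) * tr$lateral
    for (k in keep) {
      f <- frames[k]
      green[, , f] <- add_spot(green[, , f], x_um[k] / px_um,
                               y_um[k] / px_um, tr$intensities[k], sig_px)
      truth[[length(truth) + 1L]] <- data.frame(
        particle_id = tr$particle_id, frame = f,
        x_px = x_um[k] / px_um, y_px = y_um[k] / px_um,
        intensity = tr$intensities[k])
    }
  }
  red <- array(0, c(ny, nx, config$n_frames))
  mt_img <- render_mt_lines(geometry, config, field_px)
  for (f in seq_len(config$n_frames)) red[, , f] <- mt_img
  set.seed(child_seed(config$seed, 0L, stream = 17L))
  green <- green + config$background_mean
  green[] <- add_noise(as.vector(green), config)
  stk <- field_stack(list(green = green, red = red),
                     pixel_size = config$pixel_size, frame_interval = dt)
  attr(stk, "truth") <- if (length(truth)) do.call(rbind, truth) else
    data.frame(particle_id = integer(), frame = integer(),
               x_px = numeric(), y_px = numeric(), intensity = numeric())
  stk
}

# Accumulate one symmetric Gaussian spot (total integrated mass = intensity)
# onto an image; positions in pixel units, 0-based pixel centers at integers.
add_spot <- function(img, x_px, y_px, intensity, sig_px) {
  ny <- nrow(img); nx <- ncol(img)
  r <- ceiling(5 * sig_px)
  cx <- round(x_px); cy <- round(y_px)
  x_lo <- max(0, cx - r); x_hi <- min(nx - 1, cx + r)
  y_lo <- max(0, cy - r); y_hi <- min(ny - 1, cy + r)
  if (x_hi < x_lo || y_hi < y_lo) return(img)   # spot entirely off-field
  xs <- x_lo:x_hi
  ys <- y_lo:y_hi
  A <- intensity / (2 * pi * sig_px^2)
  gx <- exp(-(xs - x_px)^2 / (2 * sig_px^2))
  gy <- exp(-(ys - y_px)^2 / (2 * sig_px^2))
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + A * outer(gy, gx)
  img
}

#' Default microtubule field geometry: horizontal tracks on distinct rows
#'
#' @param config a `sim_config`.
#' @param field_px `c(ny, nx)` field size in pixels.
#' @return data.frame with `mt_id`, `x0_um`, `y0_um` (minus-end position),
#'   `angle_deg` (axis direction), `length_um`.
#' @export
mt_field_geometry <- function(config, field_px = c(128L, 128L)) {
  px_um <- config$pixel_size / 1000
  n <- length(config$mt_lengths)
  rows_px <- seq(0.15, 0.85, length.out = n) * field_px[1]
  data.frame(mt_id = seq_len(n),
             x0_um = 2 * px_um,
             y0_um = rows_px * px_um,
             angle_deg = 0,
             length_um = config$mt_lengths)
}

render_mt_lines <- function(geometry, config, field_px) {
  px_um <- config$pixel_size / 1000
  sig_px <- config$psf_sigma / config$pixel_size
  img <- matrix(0, field_px[1], field_px[2])
  for (i in seq_len(nrow(geometry))) {
    g <- geometry[i, ]
    th <- g$angle_deg * pi / 180
    s_um <- seq(0, g$length_um, by = px_um / 2)
    for (s in s_um)
      img <- add_spot(img, (g$x0_um + cos(th) * s) / px_um,
                      (g$y0_um + sin(th) * s) / px_um, 100, sig_px)
  }
  img
}

#' Render a field of static spots with known intensities
#'
#' Convenience renderer for intensity-calibration experiments: spots are
#' placed at uniform sub-pixel positions with a minimum mutual separation and
#' drawn as PSF-width Gaussians over background plus noise.
#'
#' @param intensities integrated intensities, one spot each (a.u.).
#' @param config a `sim_config` (optics, background, noise, seed).
#' @param field_px field size `c(ny, nx)`; spots are distributed over as many
#'   frames as needed at `spots_per_frame`.
#' @param spots_per_frame maximum spots rendered per frame.
#' @param min_sep_px minimum spot separation in pixels.
#' @return a `field_stack` (single `green` channel) with attribute `truth`.
#' @export
render_spot_field <- function(intensities, config, field_px = c(128L, 128L),
                              spots_per_frame = 25L, min_sep_px = 12) {
  sig_px <- config$psf_sigma / config$pixel_size
  n <- length(intensities)
  n_frames <- ceiling(n / spots_per_frame)
  set.seed(child_seed(config$seed, 0L, stream = 19L))
  green <- array(0, c(field_px[1], field_px[2], n_frames))
  truth <- vector("list", n)
  idx <- 1L
  for (f in seq_len(n_frames)) {
    k <- min(spots_per_frame, n - (f - 1L) * spots_per_frame)
    pts <- matrix(NA_real_, 0, 2)
    while (nrow(pts) < k) {
      cand <- c(stats::runif(1, 8, field_px[2] - 9),
                stats::runif(1, 8, field_px[1] - 9))
      if (!nrow(pts) ||
          min(sqrt(rowSums(sweep(pts, 2, cand)^2))) >= min_sep_px)
        pts <- rbind(pts, cand)
    }
    img <- matrix(0, field_px[1], field_px[2])
    for (j in seq_len(k)) {
      img <- add_spot(img, pts[j, 1], pts[j, 2], intensities[idx], sig_px)
      truth[[idx]] <- data.frame(spot_id = idx, frame = f,
                                 x_px = pts[j, 1], y_px = pts[j, 2],
                                 intensity = intensities[idx])
      idx <- idx + 1L
    }
    green[, , f] <- add_noise(img + config$background_mean, config)
  }
  stk <- field_stack(list(green = green),
                     pixel_size = config$pixel_size,
                     frame_interval = config$frame_interval)
  attr(stk, "truth") <- do.call(rbind, truth)
  stk
}

#' Simulate a self-organization time-lapse field
#'
#' Phenomenological renderer for the tubulin channel of an organization
#' assay: total fluorescence mass is conserved while intensity progressively
#' concentrates from a homogeneous field into radially symmetric foci
#' (`"aster"`) or elongated line-like foci (`"bundling"`), so the field
#' standard deviation (contrast) rises monotonically to a plateau. The
#' `"uniform"` scenario stays homogeneous.
#'
#' @param config a `sim_config`; `n_frames` and `frame_interval` set the
#'   time-lapse (15 s intervals by convention for these assays).
#' @param scenario `"uniform"`, `"bundling"` or `"aster"`.
#' @param field_px field size in pixels.
#' @param plateau_frame frame at which organization saturates (defaults:
#'   ~10 min aster-like, ~20 min bundle-like at the configured interval).
#' @return a single-channel (`tubulin`) `field_stack`.
#' @export
simulate_organization_field <- function(config,
                                        scenario = c("uniform", "bundling", "aster"),
                                        field_px = c(64L, 64L),
                                        plateau_frame = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(plateau_frame)) {
    plateau_min <- if (scenario == "aster") 10 else 20
    plateau_frame <- max(1L, round(plateau_min * 60 / config$frame_interval))
  }
  ny <- field_px[1]; nx <- field_px[2]
  set.seed(child_seed(config$seed, 0L, stream = 23L))
  u0 <- config$background_mean + 10 * config$intensity_mean / 1000
  total <- u0 * ny * nx
  template <- matrix(0, ny, nx)
  if (scenario != "uniform") {
    n_foci <- 3L
    cx <- stats::runif(n_foci, 0.2, 0.8) * nx
    cy <- stats::runif(n_foci, 0.2, 0.8) * ny
    th <- stats::runif(n_foci, 0, pi)
    for (i in seq_len(n_foci)) {
      if (scenario == "aster") { sx <- 3; sy <- 3 } else { sx <- 9; sy <- 1.5 }
      xr <- (col(template) - 1 - cx[i]); yr <- (row(template) - 1 - cy[i])
      xu <- cos(th[i]) * xr + sin(th[i]) * yr
      yu <- -sin(th[i]) * xr + cos(th[i]) * yr
      template <- template + exp(-xu^2 / (2 * sx^2) - yu^2 / (2 * sy^2))
    }
    template <- template / sum(template)
  }
  frames <- array(0, c(ny, nx, config$n_frames))
  for (f in seq_len(config$n_frames)) {
    w <- if (scenario == "uniform") 0 else min(1, (f - 1) / (plateau_frame - 1))
    img <- (1 - w) * (total / (ny * nx)) + w * total * template
    frames[, , f] <- add_noise(img, config)
  }
  field_stack(list(tubulin = frames), pixel_size = config$pixel_size,
              frame_interval = config$frame_interval)
}
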