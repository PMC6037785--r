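#' Construct a trajectory object
#'
#' Time-ordered sub-pixel positions of one particle on one microtubule.
#' Positions are distances from the minus end in micrometres; times are
#' seconds on a uniform frame grid.
#'
#' @param particle_id,mt_id integer identifiers.
#' @param times numeric, strictly increasing, uniformly spaced (s).
#' @param positions numeric, in `[0, mt_length]` (um).
#' @param lateral lateral offsets from the axis (um).
#' @param intensities integrated intensities (a.u.).
#' @param channel `"green"`, `"red"` or `"farred"`.
#' @param true_mode ground-truth label, `"diffusive"` or `"processive"`.
#' @param true_params list of generating values (ground truth).
#' @return object of class `trajectory`.
#' @export
new_trajectory <- function(particle_id, mt_id, times, positions,
                           lateral = rep(0, length(times)),
                           intensities = rep(1, length(times)),
                           channel = "green",
                           true_mode = NA_character_, true_params = list()) {
  stopifnot(length(times) >= 1,
            length(positions) == length(times),
            length(lateral) == length(times),
            length(intensities) == length(times))
  if (length(times) > 1) {
    dts <- diff(times)
    stopifnot(all(dts > 0), max(abs(dts - dts[1])) < 1e-9 * max(dts[1], 1))
  }
  structure(list(particle_id = particle_id, mt_id = mt_id,
                 times = times, positions = positions, lateral = lateral,
                 intensities = intensities, channel = channel,
                 true_mode = true_mode, true_params = true_params),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> particle", x$particle_id, "on MT", x$mt_id, "-",
      length(x$times), "frames,", x$true_mode, "\n")
  invisible(x)
}

#' Flatten trajectories to a long data.frame
#'
#' One row per particle per frame, suitable for CSV export.
#' @param trajectories a `trajectory_list`.
#' @return data.frame with `particle_id`, `mt_id`, `frame`, `time_s`,
#'   `x_um`, `lateral_um`, `intensity`, `channel`, `true_mode`.
#' @export
trajectories_to_df <- function(trajectories) {
  if (!length(trajectories))
    return(data.frame(particle_id = integer(), mt_id = integer(),
                      frame = integer(), time_s = numeric(), x_um = numeric(),
                      lateral_um = numeric(), intensity = numeric(),
                      channel = character(), true_mode = character()))
  do.call(rbind, lapply(trajectories, function(tr) {
    dt <- if (length(tr$times) > 1) diff(tr$times)[1] else NA_real_
    data.frame(particle_id = tr$particle_id, mt_id = tr$mt_id,
               frame = if (is.na(dt)) 1L else as.integer(round(tr$times / dt)) + 1L,
               time_s = tr$times, x_um = tr$positions,
               lateral_um = tr$lateral, intensity = tr$intensities,
               channel = tr$channel, true_mode = tr$true_mode)
  }))
}

#' Rebuild a trajectory list from a long table
#'
#' Inverse of [trajectories_to_df()] (ground-truth parameter lists are not
#' round-tripped).
#' @param df a data.frame with at least `particle_id`, `mt_id`, `time_s`,
#'   `x_um`.
#' @return a `trajectory_list`.
#' @export
df_to_trajectories <- function(df) {
  out <- lapply(split(df, df$particle_id), function(d) {
    d <- d[order(d$time_s), ]
    new_trajectory(particle_id = d$particle_id[1], mt_id = d$mt_id[1],
                   times = d$time_s, positions = d$x_um,
                   lateral = if ("lateral_um" %in% names(d)) d$lateral_um else
                     rep(0, nrow(d)),
                   intensities = if ("intensity" %in% names(d)) d$intensity else
                     rep(1, nrow(d)),
                   channel = if ("channel" %in% names(d)) d$channel[1] else "green",
                   true_mode = if ("true_mode" %in% names(d)) d$true_mode[1] else
                     NA_character_)
  })
  structure(unname(out), class = "trajectory_list")
}

#' Construct a multi-channel image stack
#'
#' Container for rendered TIRF / organization movies: named channels, each a
#' `ny x nx x n_frames` array of nonnegative pixel values.
#'
#' @param channels named list of 3D arrays, all the same dimensions.
#' @param pixel_size nm/pixel.
#' @param frame_interval s.
#' @return object of class `field_stack`.
#' @export
field_stack <- function(channels, pixel_size, frame_interval) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)))
  dims <- lapply(channels, dim)
  stopifnot(all(vapply(dims, length, 1L) == 3L))
  for (d in dims) stopifnot(identical(d, dims[[1]]))
  for (ch in channels) stopifnot(all(ch >= 0))
  structure(list(channels = channels, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 dim = dims[[1]]),
            class = "field_stack")
}

#' @export
print.field_stack <- function(x, ...) {
  cat("<field_stack>", paste(names(x$channels), collapse = "/"),
      paste(x$dim, collapse = "x"),
      sprintf("(%.1f nm/px, %.3g s/frame)\n", x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a `field_stack`.
#' @return integer frame count.
#' @export
n_frames <- function(stack) stack$dim[3]
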