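#' Build a kymograph from an image stack along a microtubule line
#'
#' For each frame, the image is sampled at 1-pixel arclength steps along the
#' polyline and the maximum over a `width`-pixel band perpendicular to the
#' line is taken (the convention of standard multiple-kymograph tools,
#' width = 3). Rows are time, columns are distance along the line.
#'
#' @param stack a `field_stack`.
#' @param mt_line two-column matrix of polyline vertices (0-based pixel
#'   coordinates, x = column, y = row).
#' @param channel channel to read.
#' @param width band width in pixels (odd).
#' @return matrix (frames x arclength samples) with attributes `pixel_size`,
#'   `frame_interval`.
#' @export
build_kymograph <- function(stack, mt_line, channel = "green", width = 3) {
  ch <- stack$channels[[channel]]
  if (is.null(ch)) stop("channel not present: ", channel, call. = FALSE)
  mt_line <- as.matrix(mt_line)
  seg_len <- sqrt(diff(mt_line[, 1])^2 + diff(mt_line[, 2])^2)
  if (sum(seg_len) < 2) stop("polyline shorter than 2 px", call. = FALSE)
  # arclength-parameterized sample points and local normals
  s_grid <- seq(0, sum(seg_len), by = 1)
  cum <- c(0, cumsum(seg_len))
  pts <- matrix(NA_real_, length(s_grid), 2)
  nrm <- matrix(NA_real_, length(s_grid), 2)
  for (k in seq_along(s_grid)) {
    i <- findInterval(s_grid[k], cum, rightmost.closed = TRUE)
    i <- min(i, nrow(mt_line) - 1L)
    f <- (s_grid[k] - cum[i]) / seg_len[i]
    p <- mt_line[i, ] + f * (mt_line[i + 1, ] - mt_line[i, ])
    d <- (mt_line[i + 1, ] - mt_line[i, ]) / seg_len[i]
    pts[k, ] <- p
    nrm[k, ] <- c(-d[2], d[1])
  }
  offs <- seq(-(width - 1) / 2, (width - 1) / 2)
  kymo <- matrix(0, dim(ch)[3], length(s_grid))
  for (f in seq_len(dim(ch)[3])) {
    img <- ch[, , f]
    for (k in seq_along(s_grid)) {
      vals <- vapply(offs, function(o)
        bilinear_at(img, pts[k, 1] + o * nrm[k, 1],
                    pts[k, 2] + o * nrm[k, 2]), numeric(1))
      kymo[f, k] <- max(vals, na.rm = TRUE)
    }
  }
  structure(kymo, pixel_size = stack$pixel_size,
            frame_interval = stack$frame_interval)
}

# bilinear interpolation at 0-based (x, y); NA outside the frame
bilinear_at <- function(img, x, y) {
  ny <- nrow(img); nx <- ncol(img)
  if (x < 0 || y < 0 || x > nx - 1 || y > ny - 1) return(NA_real_)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- min(x0 + 1, nx - 1); y1 <- min(y0 + 1, ny - 1)
  fx <- x - x0; fy <- y - y0
  (1 - fx) * (1 - fy) * img[y0 + 1, x0 + 1] +
    fx * (1 - fy) * img[y0 + 1, x1 + 1] +
    (1 - fx) * fy * img[y1 + 1, x0 + 1] +
    fx * fy * img[y1 + 1, x1 + 1]
}

#' Locate the microtubule end (minus end) from the red channel
#'
#' Maximum projection over frames, then the extent of the line profile above
#' half its peak.
#' @param kymo_red red-channel kymograph matrix.
#' @return list `end_col` (column index of the minus end, assumed at the low
#'   -distance side) and `length_cols`.
#' @export
locate_mt_extent <- function(kymo_red) {
  prof <- apply(kymo_red, 2, max)
  on <- which(prof > max(prof) / 2)
  list(end_col = min(on), length_cols = max(on) - min(on) + 1L)
}

#' Extract motility events from trajectories
#'
#' Segments each trajectory (one binding-to-unbinding association) into a
#' motility event, applying the kymograph reading conventions: pauses are
#' runs of at least `pause_min_frames` consecutive frames whose net
#' displacement stays below `movement_threshold_um`; they are excluded from
#' the moving time but included in the run length. Run length is the
#' horizontal (distance) component from the first frame to the last
#' pre-dwell frame; velocity is run length over moving time. A particle is
#' scored as having reached the minus end when it arrives within
#' `end_tol_um` of position zero and remains stationary there; its dwell is
#' read at the kymograph corner: arrival is interpolated from the last
#' approach frame at the measured approach speed and detachment is taken
#' mid-way through the first particle-free frame gap, so frame
#' discretization does not bias the dwell.
#' Censoring at the acquisition boundaries is flagged, never dropped;
#' stationary-only particles yield no event.
#'
#' @param trajectories a `trajectory_list` (uniform frame interval).
#' @param config the `sim_config` describing the acquisition (frame grid,
#'   pixel size).
#' @param movement_threshold_um pause / stationarity floor; default one
#'   camera pixel.
#' @param end_tol_um tolerance for "at the microtubule end"; default two
#'   pixels.
#' @param pause_min_frames minimum pause length in frames (default 5).
#' @param min_frames minimum association length for an event to be recorded
#'   at all (shorter associations are dropped before statistics anyway).
#' @return a data.frame of class `motility_events`.
#' @export
extract_events <- function(trajectories, config,
                           movement_threshold_um = config$pixel_size / 1000,
                           end_tol_um = 2 * config$pixel_size / 1000,
                           pause_min_frames = 5L,
                           min_frames = 1L) {
  dt <- config$frame_interval
  movie_end <- (config$n_frames - 1) * dt
  rows <- list()
  for (tr in trajectories) {
    n <- length(tr$times)
    if (n < min_frames) next
    pos <- tr$positions
    net_disp <- abs(pos[n] - pos[1])
    stationary <- net_disp < movement_threshold_um
    censored_start <- tr$times[1] <= 0
    censored_end <- tr$times[n] >= movie_end - 1e-9
    # terminal at-end stationary run = the dwell
    p_end <- pos[n]
    dwell_idx <- integer(0)
    if (p_end <= end_tol_um) {
      k <- n
      while (k >= 1 && pos[k] <= end_tol_um &&
             abs(pos[k] - p_end) <= movement_threshold_um / 2) k <- k - 1
      dwell_idx <- (k + 1):n
    }
    reached_end <- length(dwell_idx) >= 1 && !stationary
    run_end <- if (reached_end) min(dwell_idx) - 1L else n
    if (run_end < 1L) { run_end <- 1L }
    run_length <- abs(pos[run_end] - pos[1])
    pauses <- find_pauses(pos[seq_len(run_end)], movement_threshold_um,
                          pause_min_frames)
    # vertical (time) component in frame intervals; a k-frame pause spans
    # k - 1 intervals of the kymograph
    n_pause_frames <- sum(pauses$len)
    moving_intervals <- max(0L, (run_end - 1L) -
                              sum(pmax(0L, pauses$len - 1L)))
    moving_time <- moving_intervals * dt
    velocity <- if (moving_time > 0) run_length / moving_time else NA_real_
    # dwell read at the kymograph corner: arrival interpolated from the
    # last approach frame at the measured approach speed; detachment taken
    # mid-way through the first particle-free frame gap
    dwell_s <- NA_real_; dwell_start <- NA_real_
    if (reached_end) {
      f1 <- min(dwell_idx)
      if (f1 > 1 && is.finite(velocity) && velocity > 0) {
        arrival <- tr$times[f1 - 1] + (pos[f1 - 1] - p_end) / velocity
        arrival <- min(max(arrival, tr$times[f1 - 1]), tr$times[n])
      } else arrival <- tr$times[f1]
      dwell_s <- (tr$times[n] + dt / 2) - arrival
      dwell_start <- arrival
    }
    rows[[length(rows) + 1L]] <- data.frame(
      event_id = length(rows) + 1L,
      particle_id = tr$particle_id, mt_id = tr$mt_id,
      start_time = tr$times[1], end_time = tr$times[n],
      start_pos = pos[1], end_pos = p_end,
      run_length_um = run_length,
      moving_time_s = moving_time,
      velocity_um_s = velocity,
      n_frames = n, n_pauses = nrow(pauses),
      n_pause_frames = n_pause_frames,
      reached_end = reached_end,
      end_dwell_s = dwell_s,
      dwell_frames = if (reached_end) length(dwell_idx) else 0L,
      dwell_start_time = dwell_start,
      frame_s = dt,
      censored_start = censored_start,
      censored_end = censored_end,
      stationary = stationary)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = integer(), particle_id = integer(),
               mt_id = integer(), start_time = numeric(),
               end_time = numeric(), start_pos = numeric(),
               end_pos = numeric(), run_length_um = numeric(),
               moving_time_s = numeric(), velocity_um_s = numeric(),
               n_frames = integer(), n_pauses = integer(),
               n_pause_frames = integer(), reached_end = logical(),
               end_dwell_s = numeric(), dwell_frames = integer(),
               dwell_start_time = numeric(), frame_s = numeric(),
               censored_start = logical(), censored_end = logical(),
               stationary = logical())
  class(out) <- c("motility_events", "data.frame")
  out
}

# Maximal non-overlapping runs of >= min_frames frames whose net
# displacement from the run start stays below thr. Returns start/len table.
find_pauses <- function(pos, thr, min_frames) {
  n <- length(pos)
  starts <- integer(0); lens <- integer(0)
  i <- 1L
  while (i <= n - min_frames + 1L) {
    j <- i
    while (j + 1L <= n && abs(pos[j + 1L] - pos[i]) < thr) j <- j + 1L
    if (j - i + 1L >= min_frames) {
      starts <- c(starts, i); lens <- c(lens, j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(start = starts, len = lens)
}

#' Apply the metric-specific inclusion criteria to events
#'
#' Every metric requires at least 5 frames. Run length and velocity
#' additionally require the event to begin during acquisition and to have
#' detached before the end of acquisition. Run-length samples exclude
#' end-reaching events (they are counted but treated separately; the
#' excluded set is attached as attribute `end_reaching`). End-dwell samples
#' keep only events that arrive at and detach from the minus end during
#' acquisition and whose dwell does not coincide in time with another
#' particle dwelling at the same microtubule end; immediate (sub-frame)
#' dissociations remain in the sample. Frequency keeps all moving
#' (nonstationary) events of at least 5 frames.
#'
#' @param events a `motility_events` data.frame.
#' @param metric `"run_length"`, `"velocity"`, `"end_dwell"` or
#'   `"frequency"`.
#' @param min_frames minimum event length (frames).
#' @return the eligible subset (same class); for `"run_length"`, attribute
#'   `end_reaching` holds the separately-treated end-reaching events.
#' @export
filter_for_metric <- function(events,
                              metric = c("run_length", "velocity",
                                         "end_dwell", "frequency"),
                              min_frames = 5L) {
  metric <- match.arg(metric)
  e <- events[events$n_frames >= min_frames & !events$stationary, ]
  if (metric == "frequency") return(e)
  if (metric %in% c("run_length", "velocity")) {
    e <- e[!e$censored_start & !e$censored_end, ]
    if (metric == "velocity") return(e[is.finite(e$velocity_um_s), ])
    keep <- e[!e$reached_end, ]
    attr(keep, "end_reaching") <- e[e$reached_end, ]
    return(keep)
  }
  # end dwell: arrive and detach during acquisition (immediate, sub-frame
  # dissociations stay in the sample; display layers may flag them)
  e <- e[e$reached_end & !e$censored_end & !e$censored_start &
           is.finite(e$end_dwell_s), ]
  if (nrow(e) <= 1) return(e)
  # coincidence: overlapping dwell intervals at the same microtubule end
  drop <- rep(FALSE, nrow(e))
  for (i in seq_len(nrow(e) - 1)) for (j in (i + 1):nrow(e)) {
    if (e$mt_id[i] != e$mt_id[j]) next
    a1 <- e$dwell_start_time[i]; b1 <- e$end_time[i]
    a2 <- e$dwell_start_time[j]; b2 <- e$end_time[j]
    if (a1 <= b2 && a2 <= b1) drop[i] <- drop[j] <- TRUE
  }
  e[!drop, ]
}

#' Processive event frequency
#'
#' Number of events divided by the total observed microtubule length times
#' the observation time.
#'
#' @param events a `motility_events` data.frame (already filtered, e.g. by
#'   [filter_for_metric()] with `metric = "frequency"`).
#' @param mt_lengths_um observed microtubule lengths, um.
#' @param observation_time_min observation time, minutes.
#' @return list `n_events`, `total_mt_length_um`, `observation_time_min`,
#'   `frequency` (events / (min * um)).
#' @export
event_frequency <- function(events, mt_lengths_um, observation_time_min) {
  if (observation_time_min <= 0) stop("observation time must be > 0")
  if (!length(mt_lengths_um) || any(mt_lengths_um <= 0))
    stop("microtubule lengths must be positive and nonempty")
  total <- sum(mt_lengths_um)
  list(n_events = nrow(events), total_mt_length_um = total,
       observation_time_min = observation_time_min,
       frequency = nrow(events) / (observation_time_min * total))
}
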