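#' Detect local intensity maxima in a frame
#'
#' Strict 8-neighbourhood local maxima above a brightness threshold;
#' candidates closer than one PSF radius are merged, keeping the brighter.
#'
#' @param frame numeric matrix (a single image frame).
#' @param threshold minimum pixel value (a.u.), must be > 0.
#' @param psf_radius_px merge radius in pixels.
#' @return data.frame with 0-based `x_px` (column), `y_px` (row) and `value`;
#'   empty for an empty or featureless frame.
#' @export
detect_maxima <- function(frame, threshold, psf_radius_px = 3) {
  stopifnot(threshold > 0)
  empty <- data.frame(x_px = numeric(), y_px = numeric(), value = numeric())
  ny <- nrow(frame); nx <- ncol(frame)
  if (is.null(ny) || ny < 3 || nx < 3) return(empty)
  core <- frame[2:(ny - 1), 2:(nx - 1)]
  is_max <- core > threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & (core > frame[2:(ny - 1) + dy, 2:(nx - 1) + dx])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  cand <- data.frame(x_px = idx[, 2], y_px = idx[, 1],   # 0-based: +1-1
                     value = core[idx])
  cand <- cand[order(-cand$value), ]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1) { keep[1] <- TRUE; next }
    prev <- cand[keep, , drop = FALSE]
    d2 <- (prev$x_px - cand$x_px[i])^2 + (prev$y_px - cand$y_px[i])^2
    keep[i] <- min(d2) > psf_radius_px^2
  }
  out <- cand[keep, ]
  rownames(out) <- NULL
  out
}

#' Fit a symmetric 2D Gaussian plus local background to one spot
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `b + A * exp(-((x-x0)^2 + (y-y0)^2) / (2 sigma^2))` on a square window
#' around the candidate. The reported `integrated_intensity` is the
#' background-corrected volume under the fit, `2 * pi * A * sigma^2`.
#' Fitting never raises on bad data; non-convergence or out-of-bounds
#' parameters are reported as `fit_success = FALSE`.
#'
#' @param frame numeric matrix.
#' @param candidate list or vector with `x_px`, `y_px` (0-based pixel
#'   coordinates; pixel centers at integers, x = column).
#' @param window_px odd window side length (default 9).
#' @param sigma_start initial sigma guess, pixels.
#' @return a `spot_fit`: `centroid_x`, `centroid_y`, `amplitude`, `sigma`,
#'   `local_background`, `integrated_intensity`, `fit_success`,
#'   `residual_norm`, `edge_clipped`.
#' @export
fit_gaussian_2d <- function(frame, candidate, window_px = 9,
                            sigma_start = 1.3) {
  x0 <- as.numeric(candidate[["x_px"]]); y0 <- as.numeric(candidate[["y_px"]])
  ny <- nrow(frame); nx <- ncol(frame)
  half <- (window_px - 1) / 2
  cx <- round(x0); cy <- round(y0)
  xs <- max(0, cx - half):min(nx - 1, cx + half)
  ys <- max(0, cy - half):min(ny - 1, cy + half)
  edge_clipped <- length(xs) < window_px || length(ys) < window_px
  fail <- function() structure(
    list(centroid_x = x0, centroid_y = y0, amplitude = NA_real_,
         sigma = NA_real_, local_background = NA_real_,
         integrated_intensity = NA_real_, fit_success = FALSE,
         residual_norm = NA_real_, edge_clipped = edge_clipped),
    class = "spot_fit")
  if (length(xs) < 4 || length(ys) < 4) return(fail())
  sub <- frame[ys + 1, xs + 1]
  d <- data.frame(z = as.vector(sub),
                  x = rep(xs, each = length(ys)),
                  y = rep(ys, times = length(xs)))
  b0 <- stats::median(d$z)
  A0 <- max(d$z) - b0
  if (!is.finite(A0) || A0 <= 0) return(fail())
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ b + A * exp(-((x - mx)^2 + (y - my)^2) / (2 * s^2)),
      data = d,
      start = list(b = b0, A = A0, mx = x0, my = y0, s = sigma_start),
      lower = c(b = 0, A = 0, mx = min(xs) - 1, my = min(ys) - 1, s = 0.3),
      upper = c(b = Inf, A = Inf, mx = max(xs) + 1, my = max(ys) + 1,
                s = window_px),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail())
  p <- stats::coef(fit)
  ok <- is.finite(p["s"]) && p["s"] > 0.3 && p["s"] < window_px / 1.5 &&
    p["A"] > 0
  structure(list(
    centroid_x = unname(p["mx"]), centroid_y = unname(p["my"]),
    amplitude = unname(p["A"]), sigma = unname(p["s"]),
    local_background = unname(p["b"]),
    integrated_intensity = unname(2 * pi * p["A"] * p["s"]^2),
    fit_success = isTRUE(ok),
    residual_norm = sqrt(sum(stats::resid(fit)^2)),
    edge_clipped = edge_clipped), class = "spot_fit")
}

#' @export
print.spot_fit <- function(x, ...) {
  cat(sprintf("<spot_fit> (%.2f, %.2f) A=%.1f s=%.2f b=%.1f I=%.1f %s\n",
              x$centroid_x, x$centroid_y, x$amplitude, x$sigma,
              x$local_background, x$integrated_intensity,
              if (x$fit_success) "ok" else "FAILED"))
  invisible(x)
}

#' Detect and fit every spot in a stack
#'
#' Runs [detect_maxima()] and [fit_gaussian_2d()] on each frame of one
#' channel.
#'
#' @param stack a `field_stack`.
#' @param channel channel name.
#' @param threshold detection threshold; default background + 5 SD of the
#'   first frame's pixel values.
#' @param window_px fitting window.
#' @return data.frame of successful fits with a `frame` column.
#' @export
fit_spots_in_stack <- function(stack, channel = "green", threshold = NULL,
                               window_px = 9) {
  ch <- stack$channels[[channel]]
  if (is.null(ch)) stop("channel not present: ", channel, call. = FALSE)
  if (is.null(threshold))
    threshold <- stats::median(ch[, , 1]) + 5 * stats::mad(ch[, , 1])
  rows <- list()
  for (f in seq_len(dim(ch)[3])) {
    cands <- detect_maxima(ch[, , f], threshold)
    for (j in seq_len(nrow(cands))) {
      sf <- fit_gaussian_2d(ch[, , f], cands[j, ], window_px = window_px)
      if (sf$fit_success)
        rows[[length(rows) + 1L]] <- data.frame(
          frame = f, x_px = sf$centroid_x, y_px = sf$centroid_y,
          amplitude = sf$amplitude, sigma = sf$sigma,
          local_background = sf$local_background,
          intensity = sf$integrated_intensity)
    }
  }
  if (!length(rows))
    return(data.frame(frame = integer(), x_px = numeric(), y_px = numeric(),
                      amplitude = numeric(), sigma = numeric(),
                      local_background = numeric(), intensity = numeric()))
  do.call(rbind, rows)
}

#' Summarize first-frame spot intensities
#'
#' For surface-adhered singles every fitted spot contributes one intensity;
#' for moving particles only the first frame of each particle's track
#' contributes, mirroring first-frame cluster intensity analysis.
#'
#' @param spots data.frame of fitted spots; for
#'   `which = "moving_first_frame"` it must carry a `particle_id` and
#'   `frame` column.
#' @param which `"surface_singles"` or `"moving_first_frame"`.
#' @param n_bins histogram bin count (fixed-width bins over
#'   `[0, 99.5th percentile]`).
#' @return an `intensity_summary`: `n`, `mean`, `sd`, `breaks`,
#'   `normalized_counts` (counts / n, summing to the fraction of particles
#'   inside the range).
#' @export
first_frame_intensities <- function(spots,
                                    which = c("surface_singles",
                                              "moving_first_frame"),
                                    n_bins = 20) {
  which <- match.arg(which)
  if (which == "moving_first_frame") {
    stopifnot(all(c("particle_id", "frame") %in% names(spots)))
    spots <- do.call(rbind, lapply(split(spots, spots$particle_id),
                                   function(d) d[which.min(d$frame), ]))
  }
  vals <- spots$intensity
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("no usable particles", call. = FALSE)
  hi <- stats::quantile(vals, 0.995, names = FALSE)
  breaks <- seq(0, max(hi, max(vals) * 1e-6 + hi), length.out = n_bins + 1)
  counts <- graphics::hist(pmin(vals, hi), breaks = breaks, plot = FALSE)$counts
  structure(list(n = length(vals), mean = mean(vals), sd = stats::sd(vals),
                 breaks = breaks, normalized_counts = counts / length(vals)),
            class = "intensity_summary")
}

#' @export
print.intensity_summary <- function(x, ...) {
  cat(sprintf("<intensity_summary> n=%d mean=%.1f sd=%.1f\n",
              x$n, x$mean, x$sd))
  invisible(x)
}

#' Count photobleaching steps in an intensity trace
#'
#' Piecewise-constant changepoint fit by binary segmentation with a BIC
#' penalty, followed by rejection of steps smaller than half the
#' single-fluorophore intensity (guards against noise splits). The returned
#' count is the number of accepted downward steps.
#'
#' @param trace numeric intensity time series (>= 10 frames).
#' @param min_step minimum accepted step amplitude (a.u.); default half of
#'   `single_intensity`.
#' @param single_intensity single-fluorophore intensity scale (a.u.).
#' @param max_steps maximum changepoints searched.
#' @return list: `n_steps` (accepted down-steps), `step_frames`,
#'   `step_sizes` (signed, down-steps negative), `levels` (piecewise fit).
#' @export
count_photobleach_steps <- function(trace, min_step = NULL,
                                    single_intensity = 1000,
                                    max_steps = 12) {
  if (all(trace == 0))
    return(list(n_steps = 0L, step_frames = integer(),
                step_sizes = numeric(), levels = trace))
  stopifnot(length(trace) >= 10)
  if (is.null(min_step)) min_step <- 0.5 * single_intensity
  n <- length(trace)
  cps <- integer(0)                       # changepoints: last index of a segment
  repeat {
    segs <- segment_bounds(cps, n)
    best <- NULL
    for (s in seq_len(nrow(segs))) {
      a <- segs[s, 1]; b <- segs[s, 2]
      if (b - a < 3) next
      sp <- best_split(trace, a, b)
      if (!is.null(sp) && (is.null(best) || sp$gain > best$gain)) best <- sp
    }
    if (is.null(best)) break
    cand <- sort(c(cps, best$cp))
    # BIC: accept the split only if it lowers sigma^2-profiled BIC
    if (bic_pcwise(trace, cand) < bic_pcwise(trace, cps) &&
        length(cps) < max_steps) cps <- cand else break
  }
  segs <- segment_bounds(cps, n)
  means <- apply(segs, 1, function(ab) mean(trace[ab[1]:ab[2]]))
  sizes <- diff(means)
  keep <- abs(sizes) >= min_step
  # merge segments across rejected steps, then recompute
  while (any(!keep) && length(cps)) {
    drop <- which(!keep)[1]
    cps <- cps[-drop]
    segs <- segment_bounds(cps, n)
    means <- apply(segs, 1, function(ab) mean(trace[ab[1]:ab[2]]))
    sizes <- diff(means)
    keep <- if (length(sizes)) abs(sizes) >= min_step else logical(0)
  }
  levels <- numeric(n)
  for (s in seq_len(nrow(segs)))
    levels[segs[s, 1]:segs[s, 2]] <- means[s]
  down <- which(sizes < 0)
  list(n_steps = length(down), step_frames = cps[down] + 1L,
       step_sizes = sizes, levels = levels)
}

segment_bounds <- function(cps, n) {
  starts <- c(1L, cps + 1L)
  ends <- c(cps, n)
  cbind(starts, ends)
}

best_split <- function(x, a, b) {
  seg <- x[a:b]
  m <- length(seg)
  cs <- cumsum(seg); cs2 <- cumsum(seg^2)
  tot_ss <- cs2[m] - cs[m]^2 / m
  ks <- 2:(m - 2)
  if (!length(ks)) return(NULL)
  left_ss <- cs2[ks] - cs[ks]^2 / ks
  right_ss <- (cs2[m] - cs2[ks]) - (cs[m] - cs[ks])^2 / (m - ks)
  gain <- tot_ss - (left_ss + right_ss)
  k <- ks[which.max(gain)]
  list(cp = a + k - 1L, gain = max(gain))
}

bic_pcwise <- function(x, cps) {
  n <- length(x)
  segs <- segment_bounds(cps, n)
  rss <- sum(apply(segs, 1, function(ab) {
    s <- x[ab[1]:ab[2]]; sum((s - mean(s))^2)
  }))
  k <- length(cps)
  n * log(max(rss, 1e-12) / n) + (2 * k + 1) * log(n)
}
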