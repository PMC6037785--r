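#' Link per-frame spot fits into trajectories
#'
#' Greedy nearest-neighbour linking: each active track claims its nearest
#' spot in the next frame within `max_disp`. A track ends when no candidate
#' exists, when two tracks would claim the same spot, or when one track faces
#' two (near-)equidistant spots -- the intersection rule: tracking ends when
#' particles intersect a neighbouring particle. Tracks shorter than
#' `min_len` frames are discarded.
#'
#' @param spots data.frame with `frame`, `x_px`, `y_px` and optionally
#'   `intensity`; frames need not be contiguous but must be ordered.
#' @param max_disp maximum per-frame displacement, pixels.
#' @param min_len minimum track length in frames (default 5).
#' @param tie_tol relative distance tolerance within which two candidates are
#'   considered equidistant.
#' @return data.frame with `track_id`, `frame`, `x_px`, `y_px`, `intensity`.
#' @export
link_spots <- function(spots, max_disp, min_len = 5L, tie_tol = 0.05) {
  empty <- data.frame(track_id = integer(), frame = integer(),
                      x_px = numeric(), y_px = numeric(),
                      intensity = numeric())
  if (!nrow(spots)) return(empty)
  if (!"intensity" %in% names(spots)) spots$intensity <- NA_real_
  frames <- sort(unique(spots$frame))
  by_frame <- split(spots, spots$frame)
  next_id <- 0L
  active <- list()    # each: list(id, rows = list of row dfs, last)
  done <- list()
  start_tracks <- function(d, taken) {
    for (j in seq_len(nrow(d))) {
      if (taken[j]) next
      next_id <<- next_id + 1L
      active[[length(active) + 1L]] <<-
        list(id = next_id, rows = list(d[j, ]), last = d[j, ])
    }
  }
  d0 <- by_frame[[as.character(frames[1])]]
  start_tracks(d0, rep(FALSE, nrow(d0)))
  for (fi in seq_along(frames)[-1]) {
    d <- by_frame[[as.character(frames[fi])]]
    n_act <- length(active)
    claim <- rep(NA_integer_, n_act)
    ambiguous <- rep(FALSE, n_act)
    for (a in seq_len(n_act)) {
      dx <- d$x_px - active[[a]]$last$x_px
      dy <- d$y_px - active[[a]]$last$y_px
      dist <- sqrt(dx^2 + dy^2)
      ok <- which(dist <= max_disp)
      if (!length(ok)) next
      o <- ok[order(dist[ok])]
      claim[a] <- o[1]
      if (length(o) > 1 &&
          dist[o[2]] - dist[o[1]] <= tie_tol * max(dist[o[1]], 1e-9))
        ambiguous[a] <- TRUE
    }
    tab <- table(claim[!is.na(claim)])
    contested <- as.integer(names(tab)[tab > 1])
    taken <- rep(FALSE, nrow(d))
    keep_active <- list()
    for (a in seq_len(n_act)) {
      tr <- active[[a]]
      c_a <- claim[a]
      if (is.na(c_a) || ambiguous[a] || c_a %in% contested) {
        done[[length(done) + 1L]] <- tr       # track terminates here
      } else {
        tr$rows[[length(tr$rows) + 1L]] <- d[c_a, ]
        tr$last <- d[c_a, ]
        taken[c_a] <- TRUE
        keep_active[[length(keep_active) + 1L]] <- tr
      }
    }
    active <- keep_active
    start_tracks(d, taken)
  }
  done <- c(done, active)
  rows <- lapply(done, function(tr) {
    if (length(tr$rows) < min_len) return(NULL)
    out <- do.call(rbind, tr$rows)
    out$track_id <- tr$id
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[, c("track_id", "frame", "x_px", "y_px", "intensity")]
}

#' Default linking search radius
#'
#' Three standard deviations of the largest expected 1D Brownian step.
#' @param dt frame interval, s.
#' @param D_max largest plausible diffusion constant, nm^2/s.
#' @return radius in nm.
#' @export
default_max_disp <- function(dt, D_max = 2e5) 3 * sqrt(2 * D_max * dt)

#' Ensemble mean-squared displacement
#'
#' Per-trajectory time-averaged MSD over all overlapping position pairs at
#' each lag, then the ensemble mean and SEM across trajectories. Positions
#' are the 1D coordinates along the microtubule (um); MSD is reported in
#' nm^2.
#'
#' @param trajectories a `trajectory_list` with uniform frame interval.
#' @param max_lag largest lag, s.
#' @return an `msd_curve`: `lag_s`, `mean_msd_nm2`, `sem_nm2`, `n_traj`,
#'   `n_pairs`, and attribute `frame_interval`.
#' @export
compute_msd <- function(trajectories, max_lag = 5) {
  stopifnot(length(trajectories) >= 1)
  dts <- vapply(trajectories, function(tr)
    if (length(tr$times) > 1) diff(tr$times)[1] else NA_real_, numeric(1))
  dts <- dts[!is.na(dts)]
  if (!length(dts)) stop("no trajectory has more than one frame", call. = FALSE)
  if (max(dts) - min(dts) > 1e-9 * max(dts))
    stop("mixed frame intervals", call. = FALSE)
  dt <- dts[1]
  n_lags <- floor(max_lag / dt)
  acc <- matrix(NA_real_, length(trajectories), n_lags)
  pair_counts <- integer(n_lags)
  for (i in seq_along(trajectories)) {
    x_nm <- trajectories[[i]]$positions * 1000
    n <- length(x_nm)
    for (k in seq_len(min(n_lags, n - 1))) {
      d <- x_nm[(1 + k):n] - x_nm[1:(n - k)]
      acc[i, k] <- mean(d^2)
      pair_counts[k] <- pair_counts[k] + length(d)
    }
  }
  mean_msd <- c(0, colMeans(acc, na.rm = TRUE))
  n_traj <- c(length(trajectories), colSums(!is.na(acc)))
  sem <- c(0, apply(acc, 2, function(col)
    stats::sd(col, na.rm = TRUE) / sqrt(max(1, sum(!is.na(col))))))
  structure(list(lag_s = (0:n_lags) * dt,
                 mean_msd_nm2 = mean_msd,
                 sem_nm2 = sem,
                 n_traj = n_traj,
                 n_pairs = c(NA_integer_, pair_counts)),
            frame_interval = dt, class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat("<msd_curve>", length(x$lag_s) - 1, "lags up to",
      max(x$lag_s), "s;", x$n_traj[1], "trajectories\n")
  invisible(x)
}

#' Estimate a diffusion constant from an MSD curve
#'
#' Ordinary least squares of the ensemble mean MSD on lag over `(0, window]`
#' with a free intercept (which absorbs the localization-noise offset).
#' For 1D motion along the microtubule axis `D = slope / 2`; set `dim = 2`
#' for unconstrained in-plane motion (`slope / 4`).
#'
#' @param msd an `msd_curve`.
#' @param window upper lag bound, s (default 5).
#' @param dim dimensionality of the motion (1 or 2).
#' @return a `diffusion_fit`: `D_nm2_s`, `intercept_nm2`, `r_squared`,
#'   `fit_window_s`, `dim`, `negative_slope` flag.
#' @export
fit_diffusion <- function(msd, window = 5, dim = 1) {
  sel <- msd$lag_s > 0 & msd$lag_s <= window
  if (sum(sel) < 3) stop("need >= 3 lag points inside the window", call. = FALSE)
  fit <- stats::lm(y ~ x, data = data.frame(x = msd$lag_s[sel],
                                            y = msd$mean_msd_nm2[sel]))
  slope <- unname(stats::coef(fit)[2])
  y <- msd$mean_msd_nm2[sel]
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
  structure(list(D_nm2_s = slope / (2 * dim),
                 intercept_nm2 = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 fit_window_s = window, dim = dim,
                 negative_slope = slope < 0),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.3g nm^2/s (R^2 = %.3f, window %g s)%s\n",
              x$D_nm2_s, x$r_squared, x$fit_window_s,
              if (x$negative_slope) " [negative slope]" else ""))
  invisible(x)
}
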