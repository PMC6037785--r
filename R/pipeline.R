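#' Field contrast of an organization movie
#'
#' Contrast is the population standard deviation of all pixel values of each
#' frame in the tubulin channel.
#'
#' @param stack a `field_stack`.
#' @param channel channel name (default `"tubulin"`).
#' @return a `contrast_series`: data.frame `time_s`, `contrast`.
#' @export
compute_contrast <- function(stack, channel = "tubulin") {
  ch <- stack$channels[[channel]]
  if (is.null(ch)) stop("channel not present: ", channel, call. = FALSE)
  nf <- dim(ch)[3]
  contrast <- vapply(seq_len(nf), function(f) {
    v <- as.vector(ch[, , f])
    sqrt(mean((v - mean(v))^2))        # population SD of the whole field
  }, numeric(1))
  structure(data.frame(time_s = (seq_len(nf) - 1) * stack$frame_interval,
                       contrast = contrast),
            channel = channel, class = c("contrast_series", "data.frame"))
}

#' Run a full scenario from a fixture name or config
#'
#' Executes the analysis chain appropriate to the scenario class:
#' diffusive fixtures run trajectory simulation, ensemble MSD and the
#' diffusion-constant fit; processive fixtures run simulation, event
#' extraction, the per-metric inclusion filters and the CDF fits (velocity,
#' run length, end dwell) with bootstrap CIs; the intensity fixture runs the
#' render / detect / 2D-Gaussian-fit chain and reports the cluster-to-single
#' fold; organization fixtures render the time-lapse and compute the
#' contrast series. Returns a manifest with the config snapshot, seed,
#' per-stage counts (events in and out of every inclusion filter) and the
#' results; optionally writes results under `out_dir`.
#'
#' @param scenario fixture name (see [fixture_names()]) or a `sim_config`.
#' @param seed optional root-seed override.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param n_keep for processive scenarios, optional named list/vector with
#'   `velocity`, `run_length`, `end_dwell`: keep only the first n eligible
#'   values of each metric (fixed sample sizes).
#' @param n_boot bootstrap resamples for CDF fits.
#' @param organization_scenario for `org_*` fixtures, which pattern to
#'   render.
#' @return a list of class `run_manifest`.
#' @export
run_scenario <- function(scenario, seed = NULL, out_dir = NULL,
                         n_keep = NULL, n_boot = 200) {
  if (is.character(scenario)) {
    name <- scenario
    config <- fixture_config(name, seed = seed)
  } else {
    name <- "custom"
    config <- scenario
    if (!is.null(seed)) config$seed <- as.integer(seed)
    validate_config(config)
  }
  t_start <- Sys.time()
  log <- list()
  note <- function(...) log[[length(log) + 1L]] <<- sprintf(...)
  results <- list()
  if (name %in% c("org_aster", "org_bundle")) {
    sc <- if (name == "org_aster") "aster" else "bundling"
    stk <- simulate_organization_field(config, scenario = sc)
    results$contrast <- compute_contrast(stk)
    note("organization scenario %s: %d frames", sc, n_frames(stk))
  } else if (name == "cluster_intensity") {
    results$intensity <- intensity_pipeline(config, n_boot = n_boot)
    note("intensity fold = %.2f", results$intensity$fold)
  } else if (config$mode == "diffusive") {
    trajs <- simulate_diffusive(config)
    note("simulated %d diffusive trajectories", length(trajs))
    msd <- compute_msd(trajs, max_lag = 5)
    results$msd <- msd
    results$diffusion <- fit_diffusion(msd, window = 5, dim = 1)
    note("D = %.3g nm^2/s (R^2 = %.3f)",
         results$diffusion$D_nm2_s, results$diffusion$r_squared)
  } else {
    trajs <- simulate_processive(config)
    note("simulated %d processive associations", length(trajs))
    events <- extract_events(trajs, config)
    note("extracted %d events", nrow(events))
    results$events <- events
    results$fits <- list()
    for (metric in c("velocity", "run_length", "end_dwell")) {
      elig <- filter_for_metric(events, metric)
      note("%s: %d/%d events eligible", metric, nrow(elig), nrow(events))
      vals <- switch(metric,
                     velocity = elig$velocity_um_s * 60,   # um/min
                     run_length = elig$run_length_um,
                     end_dwell = elig$end_dwell_s)
      if (!is.null(n_keep) && !is.null(n_keep[[metric]])) {
        n_want <- n_keep[[metric]]
        if (metric == "run_length") vals <- vals[vals >= 0.3]
        if (length(vals) < n_want)
          warning(sprintf("%s: only %d eligible values (wanted %d)",
                          metric, length(vals), n_want))
        vals <- utils::head(vals, n_want)
      }
      results$fits[[metric]] <- switch(
        metric,
        velocity = fit_cdf_with_ci(vals, "normal",
                                   n_bootstrap = n_boot, seed = config$seed),
        run_length = fit_cdf_with_ci(vals, "exponential", x0 = 0.3,
                                     n_bootstrap = n_boot, seed = config$seed),
        end_dwell = fit_cdf_with_ci(vals, "exponential", x0 = 0,
                                    n_bootstrap = n_boot, seed = config$seed))
      note("%s mean = %.3g +/- %.2g (n = %d)", metric,
           results$fits[[metric]]$derived_mean,
           results$fits[[metric]]$ci95, results$fits[[metric]]$n)
    }
    freq_events <- filter_for_metric(events, "frequency")
    results$frequency <- event_frequency(
      freq_events, config$mt_lengths,
      config$n_frames * config$frame_interval / 60)
  }
  manifest <- list(scenario = name, seed = config$seed, config = config,
                   log = unlist(log), results = results,
                   elapsed_s = as.numeric(difftime(Sys.time(), t_start,
                                                   units = "secs")))
  class(manifest) <- "run_manifest"
  if (!is.null(out_dir)) write_manifest(manifest, out_dir)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>", x$scenario, "seed", x$seed,
      sprintf("(%.1f s)\n", x$elapsed_s))
  for (line in x$log) cat(" -", line, "\n")
  invisible(x)
}

# Full image-layer intensity chain: render singles and first-frame cluster
# spots, detect, fit, and report the fold difference of mean integrated
# intensities.
intensity_pipeline <- function(config, n_single = 500, n_cluster = 500,
                               n_boot = 200) {
  singles <- sample_cluster_intensities(config, n_single, "single")
  clusters <- sample_cluster_intensities(config, n_cluster, "cluster",
                                         unit = "tubulin")
  cfg_s <- config; cfg_s$seed <- child_seed(config$seed, 1L, 29L)
  cfg_c <- config; cfg_c$seed <- child_seed(config$seed, 2L, 29L)
  stk_s <- render_spot_field(singles, cfg_s)
  stk_c <- render_spot_field(clusters, cfg_c)
  thr <- config$background_mean + 5 * config$noise_sd
  fits_s <- fit_spots_in_stack(stk_s, threshold = thr)
  fits_c <- fit_spots_in_stack(stk_c, threshold = thr)
  sum_s <- first_frame_intensities(fits_s, "surface_singles")
  fits_c$particle_id <- seq_len(nrow(fits_c))   # one frame per cluster spot
  sum_c <- first_frame_intensities(fits_c, "moving_first_frame")
  list(singles = sum_s, clusters = sum_c,
       fold = sum_c$mean / sum_s$mean,
       n_single_fit = sum_s$n, n_cluster_fit = sum_c$n)
}

#' Reference motility values and comparison tolerances
#'
#' The published values the recovery analyses are compared against, with the
#' tolerance rule `max(15% relative, the printed 95% CI)`.
#'
#' @return data.frame `metric`, `value`, `ci95`, `units`, `tolerance`.
#' @export
reference_table <- function() {
  d <- data.frame(
    metric = c("tubulin_transport.velocity", "tubulin_transport.run_length",
               "tubulin_transport.end_dwell",
               "qdot_hset.run_length", "qdot_dtail.run_length",
               "qdot_hset.end_dwell", "qdot_dtail.end_dwell",
               "cluster_intensity.fold",
               "hset_diffusion.D", "dmotor_diffusion.D", "dtail_diffusion.D"),
    value = c(8.9, 4.2, 25, 3.7, 4.0, 37, 7, 11.8, 6.3e4, 9.4e4, 0.1e4),
    ci95 = c(0.2, 0.6, 8, 0.6, 0.6, 16, 2, NA, NA, NA, NA),
    units = c("um/min", "um", "s", "um", "um", "s", "s", "fold",
              "nm2/s", "nm2/s", "nm2/s"))
  d$tolerance <- pmax(0.15 * d$value, ifelse(is.na(d$ci95), 0, d$ci95))
  d
}

#' Compare recovered fits against the reference table
#'
#' A metric passes when the recovered mean lies within the configured
#' tolerance of the reference, or within the fit's own bootstrap 95% CI of
#' it. Metrics absent from `fits` are reported as skipped.
#'
#' @param fits named list mapping reference-metric names to recovered values
#'   (numbers or `cdf_fit` objects).
#' @param reference a reference table (default [reference_table()]).
#' @return data.frame with `metric`, `recovered`, `reference`, `deviation`,
#'   `status` (`"pass"`, `"fail"`, `"skipped"`).
#' @export
compare_to_reference <- function(fits, reference = reference_table()) {
  out <- reference
  out$recovered <- NA_real_
  out$deviation <- NA_real_
  out$status <- "skipped"
  for (i in seq_len(nrow(out))) {
    f <- fits[[out$metric[i]]]
    if (is.null(f)) next
    val <- if (inherits(f, "cdf_fit")) f$derived_mean else
      if (inherits(f, "diffusion_fit")) f$D_nm2_s else as.numeric(f)
    ci <- if (inherits(f, "cdf_fit") && !is.null(f$ci95)) f$ci95 else 0
    out$recovered[i] <- val
    out$deviation[i] <- val - out$value[i]
    ok <- abs(val - out$value[i]) <= max(out$tolerance[i], ci)
    out$status[i] <- if (ok) "pass" else "fail"
  }
  out[, c("metric", "units", "value", "recovered", "deviation",
          "tolerance", "status")]
}
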