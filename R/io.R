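#' Write trajectories to CSV
#' @param trajectories a `trajectory_list`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(trajectories, path) {
  utils::write.csv(trajectories_to_df(trajectories), path, row.names = FALSE)
  invisible(path)
}

#' Read trajectories from CSV
#' @param path CSV written by [write_trajectories_csv()].
#' @return a `trajectory_list`.
#' @export
read_trajectories_csv <- function(path) {
  df_to_trajectories(utils::read.csv(path))
}

#' Write a field stack as multi-page TIFF (one page per frame per channel)
#'
#' Pixel values are stored as 32-bit floats; channels are interleaved
#' frame-major (frame 1 channel 1, frame 1 channel 2, ...). Channel names,
#' pixel size and frame interval go to a JSON sidecar.
#'
#' @param stack a `field_stack`.
#' @param path output `.tif` path; the sidecar is `path` + `.json`.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  scale <- max(1, vapply(stack$channels, max, numeric(1)))
  pages <- list()
  for (f in seq_len(n_frames(stack)))
    for (ch in names(stack$channels))
      pages[[length(pages) + 1L]] <- stack$channels[[ch]][, , f] / scale
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  reduce = FALSE, compression = "none")
  jsonlite::write_json(list(channels = names(stack$channels),
                            pixel_size = stack$pixel_size,
                            frame_interval = stack$frame_interval,
                            dim = stack$dim, intensity_scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a field stack written by [write_stack_tiff()]
#' @param path `.tif` path with its JSON sidecar.
#' @return a `field_stack`.
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nch <- length(meta$channels)
  nf <- length(pages) / nch
  channels <- stats::setNames(vector("list", nch), meta$channels)
  for (c_i in seq_len(nch)) {
    arr <- array(0, c(dim(pages[[1]]), nf))
    for (f in seq_len(nf)) arr[, , f] <- pages[[(f - 1) * nch + c_i]]
    channels[[c_i]] <- arr * meta$intensity_scale
  }
  field_stack(channels, pixel_size = meta$pixel_size,
              frame_interval = meta$frame_interval)
}

#' Write a CDF fit (or any simple result list) as JSON
#' @param fit a `cdf_fit`, `diffusion_fit` or plain list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Write / read a simulation config as YAML
#' @param config a `sim_config`.
#' @param path YAML path.
#' @return `path` (write) or a `sim_config` (read).
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  cfg <- structure(lst, class = "sim_config")
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_frames <- as.integer(cfg$n_frames)
  cfg$n_particles <- as.integer(cfg$n_particles)
  validate_config(cfg)
  cfg
}

# Write the statistics of a run_manifest under out_dir (CSV + JSON).
write_manifest <- function(manifest, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- manifest$results
  if (!is.null(res$events))
    utils::write.csv(res$events,
                     file.path(out_dir, "events.csv"), row.names = FALSE)
  if (!is.null(res$fits))
    for (m in names(res$fits))
      write_fit_json(res$fits[[m]],
                     file.path(out_dir, paste0("fit_", m, ".json")))
  if (!is.null(res$diffusion))
    write_fit_json(res$diffusion, file.path(out_dir, "diffusion.json"))
  if (!is.null(res$msd))
    utils::write.csv(as.data.frame(unclass(res$msd)[c("lag_s", "mean_msd_nm2",
                                                      "sem_nm2")]),
                     file.path(out_dir, "msd.csv"), row.names = FALSE)
  if (!is.null(res$contrast))
    utils::write.csv(res$contrast,
                     file.path(out_dir, "contrast.csv"), row.names = FALSE)
  if (!is.null(res$frequency))
    write_fit_json(res$frequency, file.path(out_dir, "frequency.json"))
  jsonlite::write_json(
    list(scenario = manifest$scenario, seed = manifest$seed,
         log = manifest$log, elapsed_s = manifest$elapsed_s),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
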