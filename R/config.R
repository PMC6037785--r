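#' Build a simulation configuration
#'
#' A `sim_config` holds every generative parameter for one scenario:
#' geometry (microtubule lengths and field placement), kinetics (diffusion
#' constant or velocity / run-length / dwell distributions), optics (pixel
#' size, PSF width, fluorophore brightness, background, noise) and the root
#' random seed. The same config + seed always reproduces the same data.
#'
#' Units follow single-molecule TIRF conventions: lengths along the
#' microtubule in micrometres (minus end at position 0), diffusion constants
#' in nm^2/s, velocities in um/min, times in seconds, optics in nanometres
#' and camera pixels, intensities in arbitrary camera units.
#'
#' @param seed integer root seed; per-particle child streams are derived from
#'   it so adding particles does not perturb existing ones.
#' @param mode `"diffusive"` (Brownian motion on the lattice) or
#'   `"processive"` (unidirectional minus-end-directed transport).
#' @param frame_interval camera frame interval in seconds.
#' @param n_frames number of frames in the acquisition.
#' @param pixel_size camera pixel size in nm/pixel.
#' @param psf_sigma Gaussian PSF standard deviation in nm.
#' @param mt_lengths numeric vector of microtubule lengths in um.
#' @param n_particles number of particles (diffusive) or binding events
#'   (processive) to draw.
#' @param D_true diffusion constant in nm^2/s (diffusive mode).
#' @param assoc_time_mean mean microtubule association lifetime in s
#'   (diffusive mode; lifetimes are exponential).
#' @param velocity_mean,velocity_sd per-event velocity distribution in um/min
#'   (processive mode; one Normal draw per event).
#' @param run_length_mean exponential run-length scale in um.
#' @param end_dwell_mean exponential minus-end dwell scale in s.
#' @param pause_rate Poisson pause-onset rate while moving, 1/s.
#' @param pause_duration_mean exponential pause duration, s.
#' @param motors_per_cluster_range,tubulins_per_cluster_range integer
#'   length-2 vectors; cluster stoichiometries are uniform on the closed
#'   integer interval.
#' @param fluorophores_per_motor fluorophores carried per motor (2 for a
#'   dimer with one tag per chain).
#' @param maturation_fraction probability that a fluorescent-protein tag is
#'   matured (fluorescent); 1 for chemical dyes.
#' @param photobleach_prob_per_frame per-fluorophore bleaching probability
#'   per frame.
#' @param intensity_mean,intensity_sd single-fluorophore integrated
#'   intensity distribution, a.u.
#' @param background_mean camera background offset, a.u.
#' @param noise_model `"none"`, `"gaussian"` or `"poisson"`.
#' @param noise_sd Gaussian read-noise SD, a.u. (used when
#'   `noise_model = "gaussian"`).
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       mode = c("diffusive", "processive"),
                       frame_interval = if (match.arg(mode) == "diffusive") 0.1 else 1,
                       n_frames = if (match.arg(mode) == "diffusive") 600L else 900L,
                       pixel_size = 106.7,
                       psf_sigma = 130,
                       mt_lengths = c(15, 20, 25, 30),
                       n_particles = 100L,
                       D_true = NULL,
                       assoc_time_mean = 6,
                       velocity_mean = NULL,
                       velocity_sd = 0,
                       run_length_mean = 4,
                       end_dwell_mean = 25,
                       pause_rate = 0,
                       pause_duration_mean = 8,
                       motors_per_cluster_range = c(2L, 6L),
                       tubulins_per_cluster_range = c(3L, 20L),
                       fluorophores_per_motor = 2L,
                       maturation_fraction = 0.8,
                       photobleach_prob_per_frame = 0.02,
                       intensity_mean = 1000,
                       intensity_sd = 150,
                       background_mean = 200,
                       noise_model = c("none", "gaussian", "poisson"),
                       noise_sd = 10) {
  mode <- match.arg(mode)
  noise_model <- match.arg(noise_model)
  cfg <- list(
    seed = as.integer(seed), mode = mode,
    frame_interval = frame_interval, n_frames = as.integer(n_frames),
    pixel_size = pixel_size, psf_sigma = psf_sigma,
    mt_lengths = mt_lengths, n_particles = as.integer(n_particles),
    D_true = D_true, assoc_time_mean = assoc_time_mean,
    velocity_mean = velocity_mean, velocity_sd = velocity_sd,
    run_length_mean = run_length_mean, end_dwell_mean = end_dwell_mean,
    pause_rate = pause_rate, pause_duration_mean = pause_duration_mean,
    motors_per_cluster_range = as.integer(motors_per_cluster_range),
    tubulins_per_cluster_range = as.integer(tubulins_per_cluster_range),
    fluorophores_per_motor = as.integer(fluorophores_per_motor),
    maturation_fraction = maturation_fraction,
    photobleach_prob_per_frame = photobleach_prob_per_frame,
    intensity_mean = intensity_mean, intensity_sd = intensity_sd,
    background_mean = background_mean,
    noise_model = noise_model, noise_sd = noise_sd
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Stops with an informative error listing every violated constraint.
#' @param cfg a `sim_config`.
#' @return `cfg`, invisibly.
#' @export
validate_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  chk(is.numeric(cfg$frame_interval) && cfg$frame_interval > 0,
      "frame_interval must be > 0")
  chk(cfg$n_frames >= 1L, "n_frames must be >= 1")
  chk(cfg$pixel_size > 0, "pixel_size must be > 0")
  chk(cfg$psf_sigma > 0, "psf_sigma must be > 0")
  chk(length(cfg$mt_lengths) >= 1 && all(cfg$mt_lengths > 0),
      "mt_lengths must all be > 0")
  chk(cfg$n_particles >= 0L, "n_particles must be >= 0")
  if (cfg$mode == "diffusive") {
    chk(!is.null(cfg$D_true) && is.numeric(cfg$D_true) && cfg$D_true >= 0,
        "diffusive mode requires D_true >= 0")
    chk(cfg$assoc_time_mean > 0, "assoc_time_mean must be > 0")
  }
  if (cfg$mode == "processive") {
    chk(!is.null(cfg$velocity_mean) && is.numeric(cfg$velocity_mean) &&
          cfg$velocity_mean > 0,
        "processive mode requires velocity_mean > 0")
    chk(cfg$velocity_sd >= 0, "velocity_sd must be >= 0")
    chk(cfg$run_length_mean > 0, "run_length_mean must be > 0")
    chk(cfg$end_dwell_mean >= 0, "end_dwell_mean must be >= 0")
    chk(cfg$pause_rate >= 0, "pause_rate must be >= 0")
    chk(cfg$pause_duration_mean > 0, "pause_duration_mean must be > 0")
  }
  rng_ok <- function(r) length(r) == 2L && r[1] <= r[2] && r[1] >= 1L
  chk(rng_ok(cfg$motors_per_cluster_range),
      "motors_per_cluster_range must be a nonempty integer interval >= 1")
  chk(rng_ok(cfg$tubulins_per_cluster_range),
      "tubulins_per_cluster_range must be a nonempty integer interval >= 1")
  chk(cfg$fluorophores_per_motor >= 1L, "fluorophores_per_motor must be >= 1")
  chk(cfg$maturation_fraction >= 0 && cfg$maturation_fraction <= 1,
      "maturation_fraction must be in [0, 1]")
  chk(cfg$photobleach_prob_per_frame >= 0 && cfg$photobleach_prob_per_frame <= 1,
      "photobleach_prob_per_frame must be in [0, 1]")
  chk(cfg$intensity_mean > 0, "intensity_mean must be > 0")
  chk(cfg$intensity_sd >= 0, "intensity_sd must be >= 0")
  chk(cfg$background_mean >= 0, "background_mean must be >= 0")
  chk(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  if (length(bad))
    stop("invalid sim_config: ", paste(bad, collapse = "; "), call. = FALSE)
  invisible(cfg)
}

# Deterministic child seed for particle/stream i under a root seed.
# Keeps streams independent of how many particles are drawn before i.
child_seed <- function(seed, i, stream = 0L) {
  as.integer((as.double(seed) * 48271 + i * 7919 + stream * 104729) %%
               2147483647)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> mode:", x$mode,
      " seed:", x$seed,
      " frames:", x$n_frames, "x", x$frame_interval, "s\n")
  if (x$mode == "diffusive")
    cat("  D_true:", x$D_true, "nm^2/s\n")
  else
    cat("  velocity:", x$velocity_mean, "+/-", x$velocity_sd, "um/min",
        " run:", x$run_length_mean, "um",
        " dwell:", x$end_dwell_mean, "s\n")
  invisible(x)
}
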