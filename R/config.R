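# Configuration objects: acquisition, optics, comet shape, spindle geometry
# and motion models, plus mitotic-phase presets bundling them.

#' Acquisition specification
#'
#' Describes the spatio-temporal sampling of a volumetric time-lapse
#' acquisition: number of volumes, volume interval, voxel pitch and field of
#' view. The voxel grid dimension per axis is `ceiling(fov / pitch)` and is
#' recorded in the object.
#'
#' @param n_frames positive integer, number of volumes in the series.
#' @param interval_s positive number, seconds between consecutive volumes.
#' @param voxel_pitch_um length-3 positive numeric, voxel pitch (x, y, z) in
#'   micrometres; z is the optical axis.
#' @param fov_extent_um length-3 positive numeric, physical field of view
#'   (x, y, z) in micrometres.
#' @return An object of class `acquisition_spec` with fields `n_frames`,
#'   `interval_s`, `voxel_pitch_um`, `fov_extent_um`, `grid_dim`,
#'   `duration_s`.
#' @examples
#' acq <- acquisition_spec(75, 0.755, c(0.104, 0.104, 0.25), c(20, 16, 10))
#' acq$duration_s  # 56.625
#' @export
acquisition_spec <- function(n_frames = 75L, interval_s = 0.755,
                             voxel_pitch_um = c(0.104, 0.104, 0.25),
                             fov_extent_um = c(20, 16, 10)) {
  n_frames <- as.integer(n_frames)
  stopifnot(length(n_frames) == 1, n_frames >= 1,
            length(interval_s) == 1, interval_s > 0,
            length(voxel_pitch_um) == 3, all(voxel_pitch_um > 0),
            length(fov_extent_um) == 3, all(fov_extent_um > 0))
  if (any(voxel_pitch_um > fov_extent_um))
    stop("voxel pitch exceeds the field of view on at least one axis")
  structure(list(
    n_frames = n_frames,
    interval_s = interval_s,
    voxel_pitch_um = as.numeric(voxel_pitch_um),
    fov_extent_um = as.numeric(fov_extent_um),
    grid_dim = as.integer(ceiling(fov_extent_um / voxel_pitch_um)),
    duration_s = n_frames * interval_s
  ), class = "acquisition_spec")
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat(sprintf("Acquisition: %d frames x %.3f s = %.3f s\n",
              x$n_frames, x$interval_s, x$duration_s))
  cat(sprintf("  voxel pitch (um): %s; FOV (um): %s; grid: %s\n",
              paste(x$voxel_pitch_um, collapse = " x "),
              paste(x$fov_extent_um, collapse = " x "),
              paste(x$grid_dim, collapse = " x ")))
  invisible(x)
}

#' Optics and photon-budget model
#'
#' Point-spread function widths of dithered-mode lattice light-sheet imaging
#' (defaults ~230 nm lateral, ~370 nm axial FWHM) together with photon-count
#' and noise parameters for the volume renderer.
#'
#' @param fwhm_lateral_nm lateral PSF full width at half maximum, nm.
#' @param fwhm_axial_nm axial (z) PSF full width at half maximum, nm.
#' @param background_level mean background, photons per voxel.
#' @param peak_signal photons collected from one comet tip per frame.
#' @param read_noise_sd standard deviation of additive Gaussian read noise.
#' @param bleach_rate_per_s first-order photobleaching rate, 1/s; signal
#'   (not background) decays as `exp(-rate * t)`.
#' @return object of class `optics_model`.
#' @export
optics_model <- function(fwhm_lateral_nm = 230, fwhm_axial_nm = 370,
                         background_level = 10, peak_signal = 1000,
                         read_noise_sd = 2, bleach_rate_per_s = 0.004) {
  stopifnot(fwhm_lateral_nm > 0, fwhm_axial_nm > 0,
            background_level >= 0, peak_signal > 0,
            read_noise_sd >= 0, bleach_rate_per_s >= 0)
  if (fwhm_axial_nm < fwhm_lateral_nm)
    warning("axial FWHM below lateral FWHM is unusual for light-sheet optics")
  structure(list(fwhm_lateral_nm = fwhm_lateral_nm,
                 fwhm_axial_nm = fwhm_axial_nm,
                 background_level = background_level,
                 peak_signal = peak_signal,
                 read_noise_sd = read_noise_sd,
                 bleach_rate_per_s = bleach_rate_per_s),
            class = "optics_model")
}

#' EB1 comet shape model
#'
#' A growing microtubule plus end decorated with EB1-GFP appears as a comet:
#' a narrow tip (~25 nm short-axis diameter, far below the optical
#' resolution) trailed by an intensity tail of up to ~500 nm opposite the
#' growth direction. The tail intensity falls off exponentially and is
#' truncated at `tail_length_nm`; `tail_decay` is the number of e-foldings
#' over the full tail length.
#'
#' @param short_axis_diameter_nm comet short-axis diameter, nm.
#' @param tail_length_nm maximal tail extent behind the tip, nm.
#' @param tail_decay positive shape parameter: intensity at distance s behind
#'   the tip is proportional to `exp(-tail_decay * s / tail_length_nm)`.
#' @return object of class `comet_model`.
#' @export
comet_model <- function(short_axis_diameter_nm = 25, tail_length_nm = 500,
                        tail_decay = 3) {
  stopifnot(short_axis_diameter_nm > 0, tail_length_nm > 0, tail_decay > 0)
  if (tail_length_nm < short_axis_diameter_nm)
    stop("tail_length_nm must be at least the short-axis diameter")
  structure(list(short_axis_diameter_nm = short_axis_diameter_nm,
                 tail_length_nm = tail_length_nm,
                 tail_decay = tail_decay),
            class = "comet_model")
}

#' Comet motion model
#'
#' Governs where trajectories are born and how they move. Births follow a
#' Poisson process in time; start positions are drawn in one of the 10
#' spherical zones around a randomly chosen pole with the given weights;
#' each trajectory keeps a constant speed drawn from its zone's normal
#' distribution (clipped to `[0, max_speed]`) and a constant direction drawn
#' with a von Mises-Fisher bias toward the pole-to-opposite-pole axis.
#'
#' @param speed_mean_by_zone length-10 non-negative numeric, mean speed per
#'   zone, um/s.
#' @param speed_sd speed standard deviation, um/s.
#' @param axis_angle_concentration von Mises-Fisher concentration of the
#'   growth direction about the spindle axis; 0 means isotropic.
#' @param lifetime_mean_s mean trajectory lifetime, seconds (exponential).
#' @param birth_rate_per_s expected trajectory births per second.
#' @param birth_density_by_zone length-10 non-negative weights for the birth
#'   zone; normalized to sum to 1.
#' @param max_speed_um_s upper clip for drawn speeds, um/s.
#' @return object of class `motion_model`.
#' @export
motion_model <- function(speed_mean_by_zone = rep(0.45, 10),
                         speed_sd = 0.12,
                         axis_angle_concentration = 2,
                         lifetime_mean_s = 5,
                         birth_rate_per_s = 5.3,
                         birth_density_by_zone = c(0.18, 0.16, 0.14, 0.12,
                                                   0.10, 0.08, 0.07, 0.06,
                                                   0.05, 0.04),
                         max_speed_um_s = 1) {
  stopifnot(length(speed_mean_by_zone) == 10, all(speed_mean_by_zone >= 0),
            speed_sd >= 0, axis_angle_concentration >= 0,
            lifetime_mean_s > 0, birth_rate_per_s >= 0,
            length(birth_density_by_zone) == 10,
            all(birth_density_by_zone >= 0),
            max_speed_um_s > 0)
  if (any(speed_mean_by_zone > max_speed_um_s))
    warning("some zone mean speeds exceed max_speed_um_s; draws will be clipped")
  if (sum(birth_density_by_zone) <= 0)
    stop("birth_density_by_zone weights are all zero")
  structure(list(speed_mean_by_zone = as.numeric(speed_mean_by_zone),
                 speed_sd = speed_sd,
                 axis_angle_concentration = axis_angle_concentration,
                 lifetime_mean_s = lifetime_mean_s,
                 birth_rate_per_s = birth_rate_per_s,
                 birth_density_by_zone =
                   as.numeric(birth_density_by_zone) / sum(birth_density_by_zone),
                 max_speed_um_s = max_speed_um_s),
            class = "motion_model")
}

.PHASES <- c("prometaphase", "metaphase", "anaphase", "telophase")

#' Full simulation preset for a mitotic phase
#'
#' Bundles acquisition, optics, comet, spindle-geometry and motion defaults
#' for one of the four supported mitotic phases. Acquisition timing (75
#' frames at 0.755 s) and optics (230/370 nm FWHM) follow dithered-mode
#' lattice light-sheet imaging of mitotic cells; the phase-specific spindle
#' lengths and birth-zone densities are package defaults chosen to look like
#' typical cultured-cell spindles, not measured values.
#'
#' @param phase one of `"prometaphase"`, `"metaphase"`, `"anaphase"`,
#'   `"telophase"`.
#' @param scale `"desk"` (default, ~300 trajectories per cell for fast runs)
#'   or `"paper"` (birth rate raised so a cell yields >10,000 comet
#'   detections and >2,000 trajectories over 75 frames).
#' @return object of class `spindle_config`: a list with elements
#'   `phase`, `scale`, `acquisition`, `optics`, `comet`, `geometry`,
#'   `motion`.
#' @examples
#' cfg <- make_phase_preset("metaphase")
#' cfg$acquisition$n_frames    # 75
#' cfg$optics$fwhm_lateral_nm  # 230
#' @export
make_phase_preset <- function(phase = "metaphase", scale = c("desk", "paper")) {
  if (length(phase) != 1 || !phase %in% .PHASES)
    stop("unknown phase ", deparse(phase), "; supported phases: ",
         paste(.PHASES, collapse = ", "))
  scale <- match.arg(scale)

  d_um <- switch(phase,
                 prometaphase = 7, metaphase = 10,
                 anaphase = 12, telophase = 14)
  separation_rate <- if (phase == "anaphase") 0.03 else 0
  birth_density <- switch(phase,
    prometaphase = c(0.16, 0.15, 0.13, 0.12, 0.11, 0.09, 0.08, 0.06, 0.05, 0.05),
    metaphase    = c(0.18, 0.16, 0.14, 0.12, 0.10, 0.08, 0.07, 0.06, 0.05, 0.04),
    anaphase     = c(0.20, 0.17, 0.15, 0.12, 0.10, 0.08, 0.06, 0.05, 0.04, 0.03),
    telophase    = c(0.22, 0.18, 0.15, 0.12, 0.09, 0.07, 0.06, 0.05, 0.03, 0.03))
  speed_means <- switch(phase,
    prometaphase = seq(0.52, 0.40, length.out = 10),
    metaphase    = seq(0.50, 0.40, length.out = 10),
    anaphase     = seq(0.48, 0.38, length.out = 10),
    telophase    = seq(0.45, 0.35, length.out = 10))

  if (scale == "paper") {
    acq <- acquisition_spec(voxel_pitch_um = c(0.15, 0.15, 0.3),
                            fov_extent_um = c(20, 16, 10))
    birth_rate <- 100
  } else {
    acq <- acquisition_spec()
    birth_rate <- 5.3
  }

  structure(list(
    phase = phase,
    scale = scale,
    acquisition = acq,
    optics = optics_model(),
    comet = comet_model(),
    geometry = list(d_um = d_um,
                    separation_rate_um_s = separation_rate,
                    drift_um_per_s = 0.05,
                    rotation_deg_per_s = 0.5),
    motion = motion_model(speed_mean_by_zone = speed_means,
                          birth_rate_per_s = birth_rate,
                          birth_density_by_zone = birth_density)
  ), class = "spindle_config")
}

#' @export
print.spindle_config <- function(x, ...) {
  cat(sprintf("Spindle simulation preset: %s (%s scale)\n", x$phase, x$scale))
  print(x$acquisition)
  cat(sprintf("  spindle length d = %g um; birth rate %g /s; PSF %g/%g nm\n",
              x$geometry$d_um, x$motion$birth_rate_per_s,
              x$optics$fwhm_lateral_nm, x$optics$fwhm_axial_nm))
  invisible(x)
}
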