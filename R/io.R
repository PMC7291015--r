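# File formats and the end-to-end pipeline driver.
#
# Volumes: 16-bit multi-page TIFF, one file per time point, with voxel pitch
# (um), volume interval (s) and the intensity scale factor in a JSON sidecar
# so physical metadata round-trips exactly. Tables: CSV, all distances in
# um, times in s, angles in degrees.

VOLUME_SCHEMA <- "digispindle-volume-1"
CONFIG_SCHEMA <- "digispindle-run-1"

#' Write a volume series to disk
#'
#' One multi-page 16-bit TIFF per time point (pages = z planes) named
#' `<prefix>_t###.tif`, plus `<prefix>_metadata.json` holding the physical
#' voxel sizes (PhysicalSizeX/Y/Z, um), the volume interval (TimeIncrement,
#' s) and the photon scale factor used for 16-bit quantization.
#'
#' @param series a `volume_series`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the metadata list.
#' @export
write_volume_series <- function(series, dir, prefix = "volume") {
  stopifnot(inherits(series, "volume_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  acq <- series$acquisition
  scale <- max(1e-12, max(vapply(series$volumes, max, numeric(1))))
  for (i in seq_along(series$volumes)) {
    vol <- series$volumes[[i]] / scale
    pages <- lapply(seq_len(dim(vol)[3]), function(k) vol[, , k])
    tiff::writeTIFF(pages,
                    file.path(dir, sprintf("%s_t%03d.tif", prefix,
                                           series$frames[i])),
                    bits.per.sample = 16L)
  }
  meta <- list(schema = VOLUME_SCHEMA,
               frames = series$frames,
               grid_dim = acq$grid_dim,
               PhysicalSizeX_um = acq$voxel_pitch_um[1],
               PhysicalSizeY_um = acq$voxel_pitch_um[2],
               PhysicalSizeZ_um = acq$voxel_pitch_um[3],
               TimeIncrement_s = acq$interval_s,
               fov_extent_um = acq$fov_extent_um,
               n_frames = acq$n_frames,
               intensity_scale = scale)
  jsonlite::write_json(meta, file.path(dir, paste0(prefix, "_metadata.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(meta)
}

#' Read a volume series written by [write_volume_series()]
#'
#' @param dir directory containing the TIFFs and metadata sidecar.
#' @param prefix file-name prefix used at write time.
#' @return a `volume_series` (photon scale restored up to 16-bit
#'   quantization).
#' @export
read_volume_series <- function(dir, prefix = "volume") {
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, "_metadata.json")),
                              simplifyVector = TRUE)
  if (!identical(meta$schema, VOLUME_SCHEMA))
    stop("unrecognized volume metadata schema: ", meta$schema)
  pitch <- c(meta$PhysicalSizeX_um, meta$PhysicalSizeY_um, meta$PhysicalSizeZ_um)
  acq <- acquisition_spec(meta$n_frames, meta$TimeIncrement_s, pitch,
                          meta$fov_extent_um)
  vols <- lapply(meta$frames, function(f) {
    pages <- tiff::readTIFF(file.path(dir, sprintf("%s_t%03d.tif", prefix, f)),
                            all = TRUE)
    vol <- array(0, dim = meta$grid_dim)
    for (k in seq_along(pages)) vol[, , k] <- pages[[k]]
    vol * meta$intensity_scale
  })
  structure(list(volumes = vols, frames = meta$frames, acquisition = acq,
                 truth = NULL),
            class = "volume_series")
}

#' Write/read pipeline tables
#'
#' Plain CSV with stable column order; distances in um, times in s, angles
#' in degrees. `read_table_csv` is a thin `read.csv` wrapper kept so write
#' -> read -> write round-trips byte-identically.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `write_table_csv`: invisibly `path`; `read_table_csv`: a
#'   data.frame.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

## geometry <-> centrosome table (frame, pole, x_um, y_um, z_um)
geometry_to_table <- function(geometry) {
  n <- geometry$n_frames
  data.frame(frame = rep(seq_len(n), 2),
             pole = rep(c(1L, 2L), each = n),
             x_um = c(geometry$c1[, 1], geometry$c2[, 1]),
             y_um = c(geometry$c1[, 2], geometry$c2[, 2]),
             z_um = c(geometry$c1[, 3], geometry$c2[, 3]))
}

## ground-truth trajectory table (spec'd CSV schema)
truth_to_table <- function(trajectories) {
  info <- trajectories$info
  pts <- trajectories$points
  m <- match(pts$id, info$id)
  data.frame(id = pts$id, frame = pts$frame, x_um = pts$x_um,
             y_um = pts$y_um, z_um = pts$z_um,
             speed_um_per_s = info$true_mean_speed[m],
             zone_true = info$zone_true[m],
             phase = trajectories$phase)
}

.CONFIG_KEYS <- list(
  top = c("schema_version", "phase", "scale", "seed", "simulate", "render",
          "detect", "track", "register", "classify"),
  simulate = c("drift_um_per_s", "rotation_deg_per_s", "d_um",
               "separation_rate_um_s", "birth_rate_per_s", "lifetime_mean_s",
               "speed_sd", "axis_angle_concentration", "speed_mean_by_zone",
               "birth_density_by_zone"),
  render = c("noise", "peak_signal", "background_level", "read_noise_sd",
             "bleach_rate_per_s", "write_volumes"),
  detect = c("threshold_k", "min_sep_um", "use_ground_truth",
             "exclude_centrosomes_um"),
  track = c("gate_um", "min_length"),
  register = character(0),
  classify = c("n_zones", "subsample_fraction"))

#' Default run configuration
#'
#' A fully-resolved configuration for [run_pipeline()]: phase preset plus
#' per-stage parameter blocks. All fields can be overridden before running
#' or via a YAML file ([read_run_config()]).
#'
#' @param phase mitotic phase preset name.
#' @param scale `"desk"` or `"paper"`.
#' @param seed global integer seed; per-stage substreams are derived from it.
#' @return named list with `schema_version` and stage blocks.
#' @export
default_run_config <- function(phase = "metaphase", scale = "desk", seed = 1L) {
  list(schema_version = CONFIG_SCHEMA, phase = phase, scale = scale,
       seed = as.integer(seed),
       simulate = list(),
       render = list(noise = TRUE, write_volumes = FALSE),
       detect = list(threshold_k = 8, min_sep_um = 0.4,
                     use_ground_truth = FALSE,
                     exclude_centrosomes_um = 0.5),
       track = list(gate_um = NULL, min_length = 4L),
       register = list(),
       classify = list(n_zones = 10L, subsample_fraction = NULL))
}

validate_run_config <- function(config) {
  unknown <- setdiff(names(config), .CONFIG_KEYS$top)
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  for (blk in setdiff(.CONFIG_KEYS$top,
                      c("schema_version", "phase", "scale", "seed"))) {
    if (is.null(config[[blk]])) next
    unknown <- setdiff(names(config[[blk]]), .CONFIG_KEYS[[blk]])
    if (length(unknown) > 0)
      stop("unknown keys in '", blk, "' block: ",
           paste(unknown, collapse = ", "))
  }
  if (!is.null(config$schema_version) &&
      !identical(config$schema_version, CONFIG_SCHEMA))
    stop("unsupported config schema_version: ", config$schema_version)
  invisible(config)
}

#' Read / write a run configuration as YAML
#'
#' Unknown keys are rejected; missing stage blocks fall back to defaults.
#'
#' @param path YAML file path.
#' @return `read_run_config`: validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
  base <- default_run_config(cfg$phase %||% "metaphase",
                             cfg$scale %||% "desk",
                             cfg$seed %||% 1L)
  for (blk in c("simulate", "render", "detect", "track", "register",
                "classify"))
    for (k in names(cfg[[blk]])) base[[blk]][[k]] <- cfg[[blk]][[k]]
  base
}

#' @rdname read_run_config
#' @param config configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## apply config overrides onto a phase preset
apply_overrides <- function(preset, config) {
  sim <- config$simulate
  for (k in c("d_um", "separation_rate_um_s", "drift_um_per_s",
              "rotation_deg_per_s"))
    if (!is.null(sim[[k]])) preset$geometry[[k]] <- sim[[k]]
  for (k in c("birth_rate_per_s", "lifetime_mean_s", "speed_sd",
              "axis_angle_concentration", "speed_mean_by_zone",
              "birth_density_by_zone"))
    if (!is.null(sim[[k]])) preset$motion[[k]] <- sim[[k]]
  rnd <- config$render
  for (k in c("peak_signal", "background_level", "read_noise_sd",
              "bleach_rate_per_s"))
    if (!is.null(rnd[[k]])) preset$optics[[k]] <- rnd[[k]]
  preset
}

#' Run the full digital-spindle pipeline
#'
#' simulate -> render -> detect -> track -> register -> classify for one
#' cell. Volumes are rendered and detected frame by frame (the full series
#' is never held in memory); with `config$detect$use_ground_truth = TRUE`
#' the ground-truth comet positions are injected directly as detections,
#' bypassing the imaging stages. Deterministic given the seed (bit-identical
#' outputs in noise-free mode; the noise streams are seed-derived too).
#'
#' @param config configuration list from [default_run_config()] or
#'   [read_run_config()], or a path to a YAML file.
#' @param out_dir output directory for CSV tables and the resolved config;
#'   NULL skips writing.
#' @param seed overrides `config$seed` when non-NULL.
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with `geometry`, `trajectories`, `detections`,
#'   `tracks`, `registered`, `classification`, `speed_counts`,
#'   `zone_angles`, `config`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL,
                         seed = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  seed <- config$seed %||% 1L
  say <- function(...) if (!quiet) message(sprintf(...))

  preset <- apply_overrides(make_phase_preset(config$phase %||% "metaphase",
                                              config$scale %||% "desk"),
                            config)
  acq <- preset$acquisition
  say("[simulate] phase %s (%s scale), %d frames", preset$phase, preset$scale,
      acq$n_frames)
  geometry <- simulate_geometry(preset, derive_seed(seed, "geometry"))
  trajectories <- simulate_trajectories(preset, geometry,
                                        derive_seed(seed, "trajectories"))
  say("[simulate] %d ground-truth trajectories, %d comet-frame observations",
      nrow(trajectories$info), nrow(trajectories$points))

  if (isTRUE(config$detect$use_ground_truth)) {
    pts <- trajectories$points[order(trajectories$points$frame), ]
    detections <- data.frame(frame = pts$frame, x_um = pts$x_um,
                             y_um = pts$y_um, z_um = pts$z_um,
                             intensity = NA_real_, response = NA_real_)
    say("[detect] using %d ground-truth positions as detections",
        nrow(detections))
  } else {
    noise <- isTRUE(config$render$noise %||% TRUE)
    render_seed <- derive_seed(seed, "render")
    fwhm <- c(rep(preset$optics$fwhm_lateral_nm, 2),
              preset$optics$fwhm_axial_nm) * 1e-3
    ann <- list(points = trajectories$points,
                annotated = annotate_directions(trajectories$points))
    det_list <- vector("list", acq$n_frames)
    vols_out <- if (isTRUE(config$render$write_volumes))
      vector("list", acq$n_frames) else NULL
    for (f in seq_len(acq$n_frames)) {
      vol <- render_noise_free_frame(ann, geometry, preset$optics,
                                     preset$comet, acq, f)
      if (noise)
        vol <- with_seed(derive_seed(render_seed, paste0("frame", f)),
                         apply_noise(vol, preset$optics))
      if (!is.null(vols_out)) vols_out[[f]] <- vol
      det <- detect_comets(vol, acq$voxel_pitch_um,
                           target_fwhm_um = fwhm,
                           threshold_k = config$detect$threshold_k %||% 8,
                           min_sep_um = config$detect$min_sep_um %||% 0.4,
                           frame = f)
      # the centrosome foci are known inputs, not comets: mask them out
      excl <- config$detect$exclude_centrosomes_um %||% 0.5
      if (excl > 0 && nrow(det) > 0) {
        xyz <- as.matrix(det[, c("x_um", "y_um", "z_um")])
        near <- sqrt(colSums((t(xyz) - geometry$c1[f, ])^2)) < excl |
                sqrt(colSums((t(xyz) - geometry$c2[f, ])^2)) < excl
        det <- det[!near, , drop = FALSE]
      }
      det_list[[f]] <- det
    }
    detections <- do.call(rbind, det_list)
    say("[detect] %d comet detections over %d frames", nrow(detections),
        acq$n_frames)
    if (!is.null(vols_out) && !is.null(out_dir)) {
      series <- structure(list(volumes = vols_out,
                               frames = seq_len(acq$n_frames),
                               acquisition = acq,
                               truth = trajectories$points),
                          class = "volume_series")
      write_volume_series(series, file.path(out_dir, "volumes"))
    }
  }

  tracks <- build_tracks(detections, acq$interval_s,
                         gate_um = config$track$gate_um,
                         min_length = config$track$min_length %||% 4L,
                         lateral_pitch_um = acq$voxel_pitch_um[1])
  say("[track] %d trajectories survive the length filter", nrow(tracks$summary))

  registered <- register_series(tracks, geometry)
  say("[register] canonical frame, mean intercentrosomal distance %.2f um",
      attr(registered, "mean_d"))

  sub <- config$classify$subsample_fraction
  class_input <- if (!is.null(sub))
    subsample_tracks(registered, sub, derive_seed(seed, "subsample"))
  else registered
  classification <- classify_tracks(class_input,
                                    n_zones = config$classify$n_zones %||% 10L)
  speed_counts <- bin_tracks_by_speed(class_input)$counts
  zone_angles <- zone_angle_summary(
    compute_travel_angle(class_input,
                         assign_zones(class_input,
                                      zone_partition(
                                        config$classify$n_zones %||% 10L,
                                        attr(registered, "mean_d")))))
  say("[classify] %d tracks classified (%d zones occupied)",
      nrow(classification), length(unique(stats::na.omit(classification$zone))))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table_csv(geometry_to_table(geometry),
                    file.path(out_dir, "centrosomes.csv"))
    write_table_csv(truth_to_table(trajectories),
                    file.path(out_dir, "ground_truth.csv"))
    write_table_csv(detections, file.path(out_dir, "detections.csv"))
    write_table_csv(tracks$points, file.path(out_dir, "tracks.csv"))
    write_table_csv(tracks$summary, file.path(out_dir, "track_summary.csv"))
    write_table_csv(registered$points,
                    file.path(out_dir, "registered_tracks.csv"))
    write_table_csv(classification, file.path(out_dir, "classification.csv"))
    write_table_csv(speed_counts, file.path(out_dir, "speed_bins.csv"))
    write_table_csv(zone_angles$summary,
                    file.path(out_dir, "zone_angle_summary.csv"))
    write_table_csv(zone_angles$histogram,
                    file.path(out_dir, "zone_angle_histogram.csv"))
    write_run_config(config, file.path(out_dir, "run_config.yaml"))
  }
  invisible(list(geometry = geometry, trajectories = trajectories,
                 detections = detections, tracks = tracks,
                 registered = registered, classification = classification,
                 speed_counts = speed_counts, zone_angles = zone_angles,
                 config = config))
}
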