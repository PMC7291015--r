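# Ground-truth simulation: spindle geometry (centrosome pair with drift and
# rotation) and EB1 comet trajectories born in spherical zones around the
# poles.

#' Simulate a spindle geometry track
#'
#' Places the centrosome pair at the centre of the field of view, axis along
#' +x, then applies a smooth random rigid drift: a Gaussian random walk of
#' the spindle midpoint plus small random rotations of the axis about the
#' midpoint. The intercentrosomal distance changes linearly at the
#' configured separation rate (anaphase-like pole separation). With all
#' rates zero the geometry is static. Identical seeds give identical output.
#'
#' @param config a `spindle_config`, see [make_phase_preset()].
#' @param seed integer seed.
#' @return object of class `spindle_geometry`: list with `phase`,
#'   `n_frames`, `c1`, `c2` (n_frames x 3 matrices of centrosome positions,
#'   um, lab frame) and `d` (per-frame intercentrosomal distance, um).
#' @export
simulate_geometry <- function(config, seed = 1L) {
  stopifnot(inherits(config, "spindle_config"))
  acq <- config$acquisition
  geo <- config$geometry
  n <- acq$n_frames
  fov <- acq$fov_extent_um

  with_seed(seed, {
    mid <- matrix(NA_real_, n, 3)
    u <- matrix(NA_real_, n, 3)
    mid[1, ] <- fov / 2
    u[1, ] <- c(1, 0, 0)
    step_sd <- geo$drift_um_per_s * acq$interval_s / sqrt(3)
    rot_sd <- geo$rotation_deg_per_s * acq$interval_s * pi / 180
    for (t in seq_len(n)[-1]) {
      mid[t, ] <- mid[t - 1, ] +
        (if (step_sd > 0) stats::rnorm(3, 0, step_sd) else 0)
      if (rot_sd > 0) {
        # random rotation about an axis perpendicular to the current axis
        perp <- stats::rnorm(3)
        perp <- perp - sum(perp * u[t - 1, ]) * u[t - 1, ]
        nrm <- vec_norm(perp)
        ang <- stats::rnorm(1, 0, rot_sd)
        u[t, ] <- if (nrm > 1e-12)
          as.numeric(rotation_about_axis(perp / nrm, ang) %*% u[t - 1, ])
        else u[t - 1, ]
        u[t, ] <- u[t, ] / vec_norm(u[t, ])
      } else u[t, ] <- u[t - 1, ]
    }
    d <- geo$d_um + geo$separation_rate_um_s * acq$interval_s * (seq_len(n) - 1)
    if (any(d <= 0)) stop("intercentrosomal distance must stay positive")
    c1 <- mid - u * (d / 2)
    c2 <- mid + u * (d / 2)
    for (t in seq_len(n)) {
      for (cc in list(c1[t, ], c2[t, ])) {
        if (any(cc < 0) || any(cc > fov))
          stop(sprintf(
            "drift pushes a centrosome out of the field of view at frame %d", t))
      }
    }
    structure(list(phase = config$phase, n_frames = n, c1 = c1, c2 = c2, d = d),
              class = "spindle_geometry")
  })
}

#' @export
print.spindle_geometry <- function(x, ...) {
  cat(sprintf("Spindle geometry (%s): %d frames, d = %.2f-%.2f um\n",
              x$phase, x$n_frames, min(x$d), max(x$d)))
  invisible(x)
}

## sample one unit direction with von Mises-Fisher concentration kappa
## about mu; kappa = 0 is uniform on the sphere
rvmf_dir <- function(mu, kappa) {
  if (kappa < 1e-12) {
    w <- stats::runif(1, -1, 1)
  } else {
    uu <- stats::runif(1)
    w <- 1 + log(uu + (1 - uu) * exp(-2 * kappa)) / kappa
  }
  # random unit vector perpendicular to mu
  v <- stats::rnorm(3)
  v <- v - sum(v * mu) * mu
  nv <- vec_norm(v)
  if (nv < 1e-12) { v <- c(0, 0, 1) - mu[3] * mu; nv <- vec_norm(v) }
  v <- v / nv
  w * mu + sqrt(max(0, 1 - w^2)) * v
}

## uniform point in the spherical shell with radii (r1, r2], volume-uniform
rshell <- function(r1, r2) {
  r <- (stats::runif(1) * (r2^3 - r1^3) + r1^3)^(1 / 3)
  d <- stats::rnorm(3)
  r * d / vec_norm(d)
}

#' Simulate EB1 comet growth trajectories
#'
#' Births follow a Poisson process over the acquisition duration. Each
#' trajectory starts in a spherical zone (radius = intercentrosomal
#' distance, 10 equal shells) around one of the poles, with zone chosen from
#' the configured birth densities and the position volume-uniform within the
#' shell (rejection-sampled to lie inside the field of view). It then moves
#' in a straight line at a constant speed drawn from its zone's normal
#' distribution (clipped to `[0, max_speed]`), in a direction drawn with von
#' Mises-Fisher bias toward the pole-to-opposite-pole axis, for an
#' exponentially distributed lifetime, truncated at the final frame and at
#' the field-of-view boundary. Trajectories with fewer than two in-bounds
#' positions are discarded.
#'
#' @param config a `spindle_config`.
#' @param geometry a `spindle_geometry` spanning `config$acquisition$n_frames`.
#' @param seed integer seed.
#' @return object of class `comet_trajectories`: list with
#'   `points` (data.frame: id, frame, x_um, y_um, z_um),
#'   `info` (data.frame: id, start_frame, n_points, true_mean_speed,
#'   zone_true, pole_true), `interval_s`, `phase`.
#' @export
simulate_trajectories <- function(config, geometry, seed = 1L) {
  stopifnot(inherits(config, "spindle_config"),
            inherits(geometry, "spindle_geometry"))
  acq <- config$acquisition
  mot <- config$motion
  if (geometry$n_frames < acq$n_frames)
    stop("geometry does not span the configured number of frames")
  if (sum(mot$birth_density_by_zone) <= 0)
    stop("birth_density_by_zone weights are all zero")
  fov <- acq$fov_extent_um
  margin <- 0.3  # um kept clear of the boundary so PSF mass stays inside
  n_zones <- 10L

  with_seed(seed, {
    duration <- acq$duration_s
    n_births <- stats::rpois(1, mot$birth_rate_per_s * duration)
    pts_list <- vector("list", n_births)
    info_list <- vector("list", n_births)
    kept <- 0L
    for (b in seq_len(n_births)) {
      t_birth <- stats::runif(1, 0, duration)
      f0 <- min(acq$n_frames, floor(t_birth / acq$interval_s) + 1L)
      zone <- sample.int(n_zones, 1, prob = mot$birth_density_by_zone)
      pole <- sample.int(2L, 1)
      pole_pos <- if (pole == 1L) geometry$c1[f0, ] else geometry$c2[f0, ]
      opp_pos  <- if (pole == 1L) geometry$c2[f0, ] else geometry$c1[f0, ]
      d <- geometry$d[f0]
      r1 <- (zone - 1) * d / n_zones
      r2 <- zone * d / n_zones
      start <- NULL
      for (try in 1:2000) {
        cand <- pole_pos + rshell(r1, r2)
        if (all(cand >= margin) && all(cand <= fov - margin)) { start <- cand; break }
      }
      if (is.null(start)) next  # shell effectively outside the FOV
      speed <- clamp(stats::rnorm(1, mot$speed_mean_by_zone[zone], mot$speed_sd),
                     0, mot$max_speed_um_s)
      dir <- rvmf_dir(unit_vec(opp_pos - pole_pos), mot$axis_angle_concentration)
      lifetime <- stats::rexp(1, 1 / mot$lifetime_mean_s)
      n_pts <- floor(lifetime / acq$interval_s) + 1L
      n_pts <- min(n_pts, acq$n_frames - f0 + 1L)
      if (n_pts < 2L) next
      k <- seq_len(n_pts) - 1
      pos <- cbind(start[1] + k * speed * acq$interval_s * dir[1],
                   start[2] + k * speed * acq$interval_s * dir[2],
                   start[3] + k * speed * acq$interval_s * dir[3])
      inside <- pos[, 1] >= margin & pos[, 1] <= fov[1] - margin &
                pos[, 2] >= margin & pos[, 2] <= fov[2] - margin &
                pos[, 3] >= margin & pos[, 3] <= fov[3] - margin
      n_in <- if (all(inside)) n_pts else (which(!inside)[1] - 1L)
      if (n_in < 2L) next
      pos <- pos[seq_len(n_in), , drop = FALSE]
      kept <- kept + 1L
      steps <- sqrt(rowSums((pos[-1, , drop = FALSE] -
                             pos[-n_in, , drop = FALSE])^2))
      pts_list[[kept]] <- data.frame(
        id = kept, frame = f0 + seq_len(n_in) - 1L,
        x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3])
      info_list[[kept]] <- data.frame(
        id = kept, start_frame = f0, n_points = n_in,
        true_mean_speed = sum(steps) / ((n_in - 1) * acq$interval_s),
        zone_true = zone, pole_true = pole)
    }
    points <- if (kept > 0) do.call(rbind, pts_list[seq_len(kept)])
      else data.frame(id = integer(0), frame = integer(0), x_um = numeric(0),
                      y_um = numeric(0), z_um = numeric(0))
    info <- if (kept > 0) do.call(rbind, info_list[seq_len(kept)])
      else data.frame(id = integer(0), start_frame = integer(0),
                      n_points = integer(0), true_mean_speed = numeric(0),
                      zone_true = integer(0), pole_true = integer(0))
    structure(list(points = points, info = info,
                   interval_s = acq$interval_s, phase = config$phase),
              class = "comet_trajectories")
  })
}

#' @export
print.comet_trajectories <- function(x, ...) {
  cat(sprintf(
    "%d ground-truth comet trajectories (%s), %d comet-frame observations\n",
    nrow(x$info), x$phase, nrow(x$points)))
  if (nrow(x$info) > 0)
    cat(sprintf("  mean travel speed %.3f um/s (range %.3f-%.3f)\n",
                mean(x$info$true_mean_speed), min(x$info$true_mean_speed),
                max(x$info$true_mean_speed)))
  invisible(x)
}
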