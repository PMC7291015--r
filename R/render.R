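# Volume renderer: turns ground-truth comet trajectories and a spindle
# geometry into LLSM-like 3D+t photon-count volumes.
#
# Convention: volume arrays have dim = (nx, ny, nz) (column-major, z = optical
# axis); the centre of voxel [1,1,1] sits at physical position (0,0,0) um and
# voxel [i,j,k] at ((i-1)*px, (j-1)*py, (k-1)*pz).

## Gaussian line-sample weights along the comet tail. The tail is an
## exponential intensity falloff behind the tip, truncated at tail_length.
tail_samples <- function(comet, step_nm = 50) {
  L <- comet$tail_length_nm
  n <- max(2L, as.integer(ceiling(L / step_nm)) + 1L)
  s <- seq(0, L, length.out = n)          # nm behind the tip
  w <- exp(-comet$tail_decay * s / L)
  list(offset_um = s * 1e-3, w = w / sum(w))
}

## One Gaussian spot (photons = total integrated counts) as a local window:
## list(ix, iy, iz, block), or NULL when fully outside the grid. The caller
## accumulates the block so the full volume is never copied per emitter.
gaussian_spot_window <- function(centre, photons, sigma_um, pitch, dims) {
  half <- ceiling(4 * sigma_um / pitch)
  ctr_vox <- centre / pitch  # zero-based voxel coordinate of the centre
  out <- vector("list", 3)
  for (a in 1:3) {
    i0 <- floor(ctr_vox[a]) + 1L
    lo <- max(1L, i0 - half[a]); hi <- min(dims[a], i0 + half[a])
    if (lo > hi) return(NULL)
    idx <- lo:hi
    g <- stats::dnorm((idx - 1) * pitch[a], centre[a], sigma_um[a]) * pitch[a]
    out[[a]] <- list(idx = idx, g = g)
  }
  list(ix = out[[1]]$idx, iy = out[[2]]$idx, iz = out[[3]]$idx,
       block = outer(outer(out[[1]]$g, out[[2]]$g), out[[3]]$g) * photons)
}

## Render one frame: emitters given as tip positions (n x 3), unit direction
## of motion (n x 3, NA rows = point-like), photon budgets (n).
render_frame_core <- function(tips, dirs, photons, acq, optics, comet) {
  dims <- acq$grid_dim
  pitch <- acq$voxel_pitch_um
  sig <- c(rep(fwhm_to_sigma(optics$fwhm_lateral_nm) * 1e-3, 2),
           fwhm_to_sigma(optics$fwhm_axial_nm) * 1e-3)
  vol <- array(0, dim = dims)
  if (length(photons) == 0) return(vol)
  ts <- tail_samples(comet)
  add <- function(w) {
    if (!is.null(w))
      vol[w$ix, w$iy, w$iz] <<- vol[w$ix, w$iy, w$iz] + w$block
  }
  for (e in seq_len(nrow(tips))) {
    p <- tips[e, ]
    v <- dirs[e, ]
    if (any(is.na(v)) || sum(v^2) < 1e-20) {
      # stationary emitter: rendered as a point source at the tip
      add(gaussian_spot_window(p, photons[e], sig, pitch, dims))
    } else {
      v <- v / sqrt(sum(v^2))
      for (j in seq_along(ts$w)) {
        c_j <- p - v * ts$offset_um[j]
        add(gaussian_spot_window(c_j, photons[e] * ts$w[j], sig, pitch, dims))
      }
    }
  }
  vol
}

apply_noise <- function(vol, optics) {
  noisy <- stats::rpois(length(vol), as.vector(vol))
  if (optics$read_noise_sd > 0)
    noisy <- noisy + stats::rnorm(length(vol), 0, optics$read_noise_sd)
  array(pmax(noisy, 0), dim = dim(vol))
}

## annotate each trajectory point with its instantaneous direction of motion:
## the forward step, or the previous step for a trajectory's last point
annotate_directions <- function(points) {
  pts <- points[order(points$id, points$frame), , drop = FALSE]
  n <- nrow(pts)
  dir <- matrix(NA_real_, n, 3)
  if (n > 1) {
    xyz <- as.matrix(pts[, c("x_um", "y_um", "z_um")])
    step <- xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE]
    fwd <- pts$id[-1] == pts$id[-n] & pts$frame[-1] == pts$frame[-n] + 1L
    dir[which(fwd), ] <- step[fwd, , drop = FALSE]          # forward step
    last_pt <- which(fwd) + 1L                              # candidate tails
    need <- last_pt[is.na(dir[last_pt, 1])]
    dir[need, ] <- step[need - 1L, , drop = FALSE]          # backward step
  }
  pts$dir_x <- dir[, 1]; pts$dir_y <- dir[, 2]; pts$dir_z <- dir[, 3]
  pts
}

## per-frame emitter table (tips, directions) from annotated points
frame_emitters <- function(annotated, frame) {
  rows <- which(annotated$frame == frame)
  list(tips = as.matrix(annotated[rows, c("x_um", "y_um", "z_um"),
                                  drop = FALSE]),
       dirs = as.matrix(annotated[rows, c("dir_x", "dir_y", "dir_z"),
                                  drop = FALSE]))
}

#' Render a 3D+t volume series of comet trajectories
#'
#' Each comet is rendered as a tip-anchored intensity line profile elongated
#' opposite its instantaneous velocity (exponential falloff truncated at the
#' comet tail length), convolved with a separable Gaussian PSF whose lateral
#' and axial FWHMs follow the optics model, photobleached as
#' `exp(-bleach_rate * t)`, sampled onto the voxel grid, with the two
#' centrosomes added as bright point-like foci. In noisy mode, Poisson shot
#' noise is applied to signal plus background and zero-mean Gaussian read
#' noise added (clamped at zero). The comet's 25 nm short-axis width is far
#' below both the voxel pitch and the PSF width, so the rendered cross
#' section is PSF-limited: a stationary emitter measures exactly the PSF.
#'
#' @param trajectories `comet_trajectories` (all positions inside the FOV).
#' @param geometry `spindle_geometry` or NULL to omit centrosome foci.
#' @param optics an `optics_model`.
#' @param comet a `comet_model`.
#' @param acquisition an `acquisition_spec`.
#' @param seed integer seed for the noise streams.
#' @param noise logical; FALSE returns expected photon counts
#'   (deterministic).
#' @param frames integer vector of frames to render (default all).
#' @param centrosome_intensity_factor centrosome focus brightness as a
#'   multiple of `optics$peak_signal`.
#' @return object of class `volume_series`: list with `volumes` (list of 3D
#'   arrays, photons), `frames`, `acquisition`, `truth` (ground-truth table:
#'   id, frame, x_um, y_um, z_um).
#' @export
render_volume_series <- function(trajectories, geometry, optics, comet,
                                 acquisition, seed = 1L, noise = TRUE,
                                 frames = NULL,
                                 centrosome_intensity_factor = 5) {
  stopifnot(inherits(acquisition, "acquisition_spec"),
            inherits(optics, "optics_model"),
            inherits(comet, "comet_model"))
  if (is.null(frames)) frames <- seq_len(acquisition$n_frames)
  pts <- trajectories$points
  fov <- acquisition$fov_extent_um
  if (nrow(pts) > 0) {
    xyz <- as.matrix(pts[, c("x_um", "y_um", "z_um")])
    if (any(xyz < 0) || any(sweep(xyz, 2, fov) > 0))
      stop("trajectory positions outside the field of view")
  }
  vols <- vector("list", length(frames))
  traj_ann <- list(points = pts, annotated = annotate_directions(pts))
  with_seed(if (noise) seed else NULL, {
    for (fi in seq_along(frames)) {
      f <- frames[fi]
      vol <- render_noise_free_frame(traj_ann, geometry, optics, comet,
                                     acquisition, f,
                                     centrosome_intensity_factor)
      vols[[fi]] <- if (noise) apply_noise(vol, optics) else vol
    }
  })
  structure(list(volumes = vols, frames = frames, acquisition = acquisition,
                 truth = pts),
            class = "volume_series")
}

## expected-photon frame (no noise); exported via render_volume_series(noise=FALSE)
render_noise_free_frame <- function(trajectories, geometry, optics, comet,
                                    acquisition, frame,
                                    centrosome_intensity_factor = 5) {
  ann <- if (!is.null(trajectories$annotated)) trajectories$annotated
         else annotate_directions(trajectories$points)
  em <- frame_emitters(ann, frame)
  bleach <- exp(-optics$bleach_rate_per_s * (frame - 1) * acquisition$interval_s)
  photons <- rep(optics$peak_signal * bleach, nrow(em$tips))
  vol <- render_frame_core(em$tips, em$dirs, photons, acquisition, optics, comet)
  if (!is.null(geometry)) {
    sig <- c(rep(fwhm_to_sigma(optics$fwhm_lateral_nm) * 1e-3, 2),
             fwhm_to_sigma(optics$fwhm_axial_nm) * 1e-3)
    for (cc in list(geometry$c1[frame, ], geometry$c2[frame, ])) {
      w <- gaussian_spot_window(cc,
                                centrosome_intensity_factor *
                                  optics$peak_signal * bleach,
                                sig, acquisition$voxel_pitch_um,
                                acquisition$grid_dim)
      if (!is.null(w))
        vol[w$ix, w$iy, w$iz] <- vol[w$ix, w$iy, w$iz] + w$block
    }
  }
  vol + optics$background_level
}

#' @export
print.volume_series <- function(x, ...) {
  cat(sprintf("Volume series: %d frames of %s voxels (%s um pitch)\n",
              length(x$volumes),
              paste(x$acquisition$grid_dim, collapse = " x "),
              paste(x$acquisition$voxel_pitch_um, collapse = " x ")))
  invisible(x)
}

#' Measure the FWHM of a 1D intensity profile
#'
#' Finds the profile maximum and locates the two half-maximum crossings by
#' linear interpolation between samples.
#'
#' @param profile numeric vector of intensities (background-subtracted).
#' @param pitch sample spacing in physical units.
#' @return full width at half maximum in the units of `pitch`.
#' @export
measure_fwhm <- function(profile, pitch) {
  i0 <- which.max(profile)
  half <- profile[i0] / 2
  below_l <- which(profile[seq_len(i0)] < half)
  below_r <- which(profile[i0:length(profile)] < half) + i0 - 1L
  if (length(below_l) == 0 || length(below_r) == 0)
    stop("profile does not fall below half maximum on both sides")
  il <- max(below_l)                       # crossing between il and il+1
  xl <- il + (half - profile[il]) / (profile[il + 1] - profile[il])
  ir <- min(below_r)                       # crossing between ir-1 and ir
  xr <- ir - (half - profile[ir]) / (profile[ir - 1] - profile[ir])
  (xr - xl) * pitch
}

#' Rendered-PSF calibration: FWHM of a noise-free point emitter
#'
#' Renders a single stationary emitter on an isotropic grid with zero
#' background and measures the lateral (x) and axial (z) FWHM of the
#' through-peak intensity profiles by linear interpolation at half maximum.
#'
#' @param optics an `optics_model`.
#' @param pitch_um isotropic voxel pitch, um (default 0.05).
#' @param fov_um cubic field of view, um.
#' @return named numeric: `fwhm_lateral_nm`, `fwhm_axial_nm` (measured).
#' @export
psf_calibration <- function(optics, pitch_um = 0.05, fov_um = 4) {
  acq <- acquisition_spec(n_frames = 1, interval_s = 1,
                          voxel_pitch_um = rep(pitch_um, 3),
                          fov_extent_um = rep(fov_um, 3))
  opt0 <- optics
  opt0$background_level <- 0
  # emitter exactly on a voxel centre nearest the volume centre
  ctr_idx <- floor(acq$grid_dim / 2)
  ctr <- ctr_idx * pitch_um
  traj <- list(points = data.frame(id = 1L, frame = 1L, x_um = ctr[1],
                                   y_um = ctr[2], z_um = ctr[3]))
  vol <- render_noise_free_frame(traj, NULL, opt0, comet_model(), acq, 1L)
  i <- ctr_idx + 1L
  c(fwhm_lateral_nm = measure_fwhm(vol[, i[2], i[3]], pitch_um) * 1e3,
    fwhm_axial_nm = measure_fwhm(vol[i[1], i[2], ], pitch_um) * 1e3)
}
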