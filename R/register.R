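# Spindle-frame registration (drift correction): per-frame rigid transforms
# taking lab coordinates into a canonical frame where the centrosomes sit on
# the x axis, symmetric about the origin; plus merging of registered cells.

#' Rigid transform
#'
#' A proper rotation plus translation, applied as `p -> R p + t`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric, um.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param transform a `rigid_transform`.
#' @param points n x 3 matrix (or length-3 vector), um.
#' @return transformed points, same shape.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1, 3) else as.matrix(points)
  out <- p %*% t(transform$rotation)
  out <- sweep(out, 2, transform$translation, "+")
  if (vec) as.numeric(out) else out
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Compose two rigid transforms (`a` after `b`)
#' @param a,b `rigid_transform` objects.
#' @return the composite transform `p -> a(b(p))`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Canonical spindle-frame transform from a centrosome pair
#'
#' Maps the centrosome midpoint to the origin and the unit vector from
#' centrosome 1 to centrosome 2 onto +x by the minimal rotation (axis = the
#' cross product of the two directions), so c1 lands at (-d/2, 0, 0) and c2
#' at (+d/2, 0, 0). When the spindle axis is exactly antiparallel to +x the
#' rotation is a deterministic 180 degrees about +z.
#'
#' @param c1_um,c2_um length-3 centrosome positions, um (must differ).
#' @return a `rigid_transform`.
#' @export
canonical_transform <- function(c1_um, c2_um) {
  if (vec_norm(c2_um - c1_um) < 1e-12)
    stop("coincident centrosomes: spindle axis undefined")
  mid <- (c1_um + c2_um) / 2
  R <- minimal_rotation(unit_vec(c2_um - c1_um), c(1, 0, 0))
  rigid_transform(R, -as.numeric(R %*% mid))
}

#' Register tracks into the canonical spindle frame (drift correction)
#'
#' Transforms every detection at frame t by the rigid transform that puts
#' that frame's centrosomes at (+-d(t)/2, 0, 0). The roll angle about the
#' spindle axis, which two centrosomes leave undetermined, is fixed for
#' temporal smoothness: the first frame uses the minimal rotation from the
#' lab frame, and each subsequent frame applies the minimal rotation
#' relative to the previous registered frame. Pole identity is fixed at the
#' first frame and propagated by proximity so the axis never flips.
#'
#' @param tracks a `comet_tracks` object (lab frame).
#' @param geometry a `spindle_geometry`, or a data.frame with columns
#'   frame, pole (1 or 2), x_um, y_um, z_um covering every frame present in
#'   `tracks`.
#' @param cell_id identifier stored with the registered cell.
#' @return a `comet_tracks` object in the canonical frame, with attributes
#'   `d_per_frame`, `mean_d`, `transforms` (list of `rigid_transform` per
#'   frame, names = frame), `phase` and `cell_id`.
#' @export
register_series <- function(tracks, geometry, cell_id = 1L) {
  stopifnot(inherits(tracks, "comet_tracks"))
  geo <- as_geometry_frames(geometry)
  frames_needed <- sort(unique(tracks$points$frame))
  missing <- setdiff(frames_needed, geo$frames)
  if (length(missing) > 0)
    stop("centrosome data missing for frames: ",
         paste(utils::head(missing, 10), collapse = ", "))

  n <- length(geo$frames)
  c1 <- geo$c1; c2 <- geo$c2
  # pole identity: propagate frame-0 labels by proximity
  for (t in seq_len(n)[-1]) {
    if (sum((c1[t, ] - c1[t - 1, ])^2) > sum((c2[t, ] - c1[t - 1, ])^2)) {
      tmp <- c1[t, ]; c1[t, ] <- c2[t, ]; c2[t, ] <- tmp
    }
  }
  transforms <- vector("list", n)
  R_prev <- NULL
  for (t in seq_len(n)) {
    mid <- (c1[t, ] + c2[t, ]) / 2
    u <- unit_vec(c2[t, ] - c1[t, ])
    if (is.null(R_prev)) {
      R <- minimal_rotation(u, c(1, 0, 0))
    } else {
      R <- minimal_rotation(as.numeric(R_prev %*% u), c(1, 0, 0)) %*% R_prev
    }
    transforms[[t]] <- rigid_transform(R, -as.numeric(R %*% mid))
    R_prev <- R
  }
  names(transforms) <- geo$frames

  pts <- tracks$points
  if (nrow(pts) > 0) {
    xyz <- as.matrix(pts[, c("x_um", "y_um", "z_um")])
    for (t in seq_len(n)) {
      rows <- which(pts$frame == geo$frames[t])
      if (length(rows) > 0)
        xyz[rows, ] <- apply_transform(transforms[[t]],
                                       xyz[rows, , drop = FALSE])
    }
    pts$x_um <- xyz[, 1]; pts$y_um <- xyz[, 2]; pts$z_um <- xyz[, 3]
  }
  out <- new_comet_tracks(pts, tracks$interval_s)
  d <- sqrt(rowSums((c2 - c1)^2))
  attr(out, "d_per_frame") <- stats::setNames(d, geo$frames)
  attr(out, "mean_d") <- mean(d)
  attr(out, "transforms") <- transforms
  attr(out, "phase") <- geo$phase
  attr(out, "cell_id") <- cell_id
  out
}

## normalize geometry input to list(frames, c1, c2, phase)
as_geometry_frames <- function(geometry) {
  if (inherits(geometry, "spindle_geometry"))
    return(list(frames = seq_len(geometry$n_frames), c1 = geometry$c1,
                c2 = geometry$c2, phase = geometry$phase))
  stopifnot(is.data.frame(geometry),
            all(c("frame", "pole", "x_um", "y_um", "z_um") %in% names(geometry)))
  g1 <- geometry[geometry$pole == 1, ]
  g2 <- geometry[geometry$pole == 2, ]
  frames <- sort(intersect(g1$frame, g2$frame))
  list(frames = frames,
       c1 = as.matrix(g1[match(frames, g1$frame), c("x_um", "y_um", "z_um")]),
       c2 = as.matrix(g2[match(frames, g2$frame), c("x_um", "y_um", "z_um")]),
       phase = attr(geometry, "phase"))
}

#' Merge registered cells into one trajectory set
#'
#' Pools the tracks of several cells registered in the common canonical
#' spindle frame, retaining per-track provenance (`cell_id`). Optionally
#' normalizes coordinates by each cell's mean intercentrosomal distance
#' (off by default), putting all spindles at unit half-length.
#'
#' @param cells list of registered `comet_tracks` (from
#'   [register_series()]), all of the same mitotic phase.
#' @param normalize_d logical; divide each cell's coordinates by its mean
#'   intercentrosomal distance.
#' @param allow_mixed_phases logical; permit pooling across phases.
#' @return a `comet_tracks` object with `cell_id` columns in `points` and
#'   `summary`, and attributes `mean_d` (mean over cells, or 1 when
#'   normalized) and `phase`.
#' @export
merge_cells <- function(cells, normalize_d = FALSE,
                        allow_mixed_phases = FALSE) {
  stopifnot(is.list(cells), length(cells) >= 1,
            all(vapply(cells, inherits, TRUE, "comet_tracks")))
  phases <- unique(unlist(lapply(cells, attr, "phase")))
  if (length(phases) > 1 && !allow_mixed_phases)
    stop("cells are from different phases (", paste(phases, collapse = ", "),
         "); set allow_mixed_phases = TRUE to pool anyway")
  interval <- unique(vapply(cells, `[[`, numeric(1), "interval_s"))
  stopifnot(length(interval) == 1)

  pts_list <- list(); next_id <- 0L
  map_list <- list()
  for (k in seq_along(cells)) {
    cl <- cells[[k]]
    cid <- attr(cl, "cell_id"); if (is.null(cid)) cid <- k
    p <- cl$points
    if (nrow(p) == 0) next
    scale <- if (normalize_d) attr(cl, "mean_d") else 1
    if (is.null(scale)) scale <- 1
    old <- sort(unique(p$track_id))
    p$track_id <- next_id + match(p$track_id, old)
    p[, c("x_um", "y_um", "z_um")] <- p[, c("x_um", "y_um", "z_um")] / scale
    p$cell_id <- cid
    map_list[[k]] <- data.frame(track_id = next_id + seq_along(old),
                                cell_id = cid, cell_track_id = old)
    next_id <- next_id + length(old)
    pts_list[[k]] <- p
  }
  pts <- if (length(pts_list) > 0) do.call(rbind, pts_list) else
    data.frame(track_id = integer(0), frame = integer(0), x_um = numeric(0),
               y_um = numeric(0), z_um = numeric(0), intensity = numeric(0),
               cell_id = integer(0))
  out <- new_comet_tracks(pts[, c("track_id", "frame", "x_um", "y_um",
                                  "z_um", "intensity")], interval)
  if (nrow(out$summary) > 0) {
    map <- do.call(rbind, map_list)
    out$summary <- merge(out$summary, map, by = "track_id", sort = TRUE)
  }
  out$points <- pts
  ds <- vapply(cells, function(cl) {
    d <- attr(cl, "mean_d"); if (is.null(d)) NA_real_ else d
  }, numeric(1))
  attr(out, "mean_d") <- if (normalize_d) 1 else mean(ds)
  attr(out, "phase") <- if (length(phases) == 1) phases else "mixed"
  out
}
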