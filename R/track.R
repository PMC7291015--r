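# Frame-to-frame linking of comet detections into trajectories, and
# per-trajectory kinematics.

## connected components of the gated bipartite graph (rows of t vs rows of
## t+1); returns component label per node, nodes = c(rows, cols)
bipartite_components <- function(allowed) {
  n <- nrow(allowed); m <- ncol(allowed)
  lab <- integer(n + m)
  comp <- 0L
  for (s in seq_len(n + m)) {
    if (lab[s] != 0L) next
    comp <- comp + 1L
    queue <- s
    lab[s] <- comp
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- if (v <= n) which(allowed[v, ]) + n else which(allowed[, v - n])
      new <- nb[lab[nb] == 0L]
      lab[new] <- comp
      queue <- c(queue, new)
    }
  }
  lab
}

#' Link detections between two consecutive frames
#'
#' Globally optimal one-to-one assignment minimizing the summed squared
#' displacement over candidate pairs closer than the gate radius; detections
#' left unmatched start or terminate tracks. Solved as a linear assignment
#' problem with birth/death alternatives at cost `gate^2`, decomposed over
#' connected components of the gated candidate graph. Ties are broken
#' deterministically by detection order.
#'
#' @param detections_t,detections_t1 data.frames with columns x_um, y_um,
#'   z_um (detections at frames t and t+1).
#' @param gate_um maximum linking distance, um.
#' @return integer vector of length `nrow(detections_t)`: for each detection
#'   at t, the row index of its match at t+1, or NA.
#' @export
link_frame_pair <- function(detections_t, detections_t1, gate_um) {
  stopifnot(gate_um > 0)
  n <- nrow(detections_t); m <- nrow(detections_t1)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  a <- as.matrix(detections_t[, c("x_um", "y_um", "z_um")])
  b <- as.matrix(detections_t1[, c("x_um", "y_um", "z_um")])
  d2 <- outer(rowSums(a^2), rep(1, m)) + outer(rep(1, n), rowSums(b^2)) -
    2 * a %*% t(b)
  d2[d2 < 0] <- 0
  allowed <- d2 <= gate_um^2
  match <- rep(NA_integer_, n)
  if (!any(allowed)) return(match)
  lab <- bipartite_components(allowed)
  BIG <- 1e9
  alt <- gate_um^2  # cost of leaving a detection unmatched
  for (comp in unique(lab)) {
    rows <- which(lab[seq_len(n)] == comp)
    cols <- which(lab[n + seq_len(m)] == comp)
    a_n <- length(rows); b_n <- length(cols)
    if (a_n == 0 || b_n == 0) next
    if (a_n == 1 && b_n == 1) {
      if (allowed[rows, cols]) match[rows] <- cols
      next
    }
    sz <- a_n + b_n
    cost <- matrix(BIG, sz, sz)
    blk <- d2[rows, cols, drop = FALSE]
    blk[!allowed[rows, cols, drop = FALSE]] <- BIG
    cost[seq_len(a_n), seq_len(b_n)] <- blk
    for (i in seq_len(a_n)) cost[i, b_n + i] <- alt          # track death
    for (j in seq_len(b_n)) cost[a_n + j, j] <- alt          # track birth
    cost[a_n + seq_len(b_n), b_n + seq_len(a_n)] <- 0        # dummy-dummy
    sol <- lap_solve(cost)
    for (i in seq_len(a_n)) {
      j <- sol[i]
      if (j <= b_n && blk[i, j] < BIG / 2) match[rows[i]] <- cols[j]
    }
  }
  match
}

#' Default linking gate
#'
#' `max_speed * interval + 2 * lateral_pitch`: the farthest a comet at the
#' top of the speed scale (1 um/s) can travel in one volume interval, plus a
#' two-pixel localization allowance.
#'
#' @param interval_s volume interval, s.
#' @param lateral_pitch_um lateral voxel pitch, um.
#' @param max_speed_um_s top of the expected speed range, um/s.
#' @return gate radius in um.
#' @export
default_gate_um <- function(interval_s, lateral_pitch_um = 0.104,
                            max_speed_um_s = 1) {
  max_speed_um_s * interval_s + 2 * lateral_pitch_um
}

#' Mean travel speed of a trajectory
#'
#' Path length over elapsed time: the sum of consecutive-point Euclidean
#' step lengths divided by `(n_points - 1) * interval_s`. This per-step
#' definition matches the growth-rate semantics of EB1 comet analysis; the
#' net-displacement alternative is reported alongside it in track summaries.
#'
#' @param positions n x 3 numeric matrix of ordered positions, um.
#' @param interval_s time between consecutive positions, s.
#' @return speed in um/s.
#' @export
compute_mean_travel_speed <- function(positions, interval_s) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2) stop("a trajectory needs at least 2 points to have a speed")
  steps <- sqrt(rowSums((positions[-1, , drop = FALSE] -
                         positions[-n, , drop = FALSE])^2))
  sum(steps) / ((n - 1) * interval_s)
}

#' Build trajectories from per-frame detections
#'
#' Sequentially links consecutive frames with [link_frame_pair()] (no gap
#' closing: a missed frame terminates the track), discards tracks shorter
#' than `min_length` points, and assigns ids in order of start frame then
#' start position.
#'
#' @param detections data.frame with columns frame, x_um, y_um, z_um and
#'   optionally intensity; frames must be in non-decreasing order.
#' @param interval_s volume interval, s.
#' @param gate_um linking gate radius, um; default [default_gate_um()].
#' @param min_length minimum number of points per track (default 4).
#' @param lateral_pitch_um used only for the default gate.
#' @return object of class `comet_tracks`: list with `points` (track_id,
#'   frame, x_um, y_um, z_um, intensity), `summary` (track_id, start_frame,
#'   end_frame, n_points, mean_speed_um_s, displacement_speed_um_s,
#'   start/end coordinates) and `interval_s`.
#' @export
build_tracks <- function(detections, interval_s, gate_um = NULL,
                         min_length = 4L, lateral_pitch_um = 0.104) {
  stopifnot(is.data.frame(detections), interval_s > 0, min_length >= 2)
  if (is.null(gate_um)) gate_um <- default_gate_um(interval_s, lateral_pitch_um)
  if (nrow(detections) > 1 && is.unsorted(detections$frame))
    stop("detections must be ordered by frame")
  if (!"intensity" %in% names(detections))
    detections[["intensity"]] <- rep(NA_real_, nrow(detections))
  if (nrow(detections) == 0)
    return(new_comet_tracks(detections[0, ], interval_s))

  frames <- sort(unique(detections$frame))
  rows_by_frame <- split(seq_len(nrow(detections)), detections$frame)
  # open[[k]] = integer vector of detection rows of the growing track whose
  # head is detection k of the current frame
  track_rows <- list()      # closed tracks
  cur_rows <- rows_by_frame[[as.character(frames[1])]]
  open <- as.list(cur_rows)
  for (fi in seq_along(frames)[-1]) {
    f_prev <- frames[fi - 1]; f <- frames[fi]
    nxt_rows <- rows_by_frame[[as.character(f)]]
    if (f != f_prev + 1L) {
      track_rows <- c(track_rows, open)       # gap: terminate all
      open <- as.list(nxt_rows)
      cur_rows <- nxt_rows
      next
    }
    match <- link_frame_pair(detections[cur_rows, , drop = FALSE],
                             detections[nxt_rows, , drop = FALSE], gate_um)
    new_open <- vector("list", length(nxt_rows))
    extended <- rep(FALSE, length(nxt_rows))
    for (i in seq_along(cur_rows)) {
      j <- match[i]
      if (!is.na(j)) {
        new_open[[j]] <- c(open[[i]], nxt_rows[j])
        extended[j] <- TRUE
      } else {
        track_rows <- c(track_rows, open[i])
      }
    }
    for (j in which(!extended)) new_open[[j]] <- nxt_rows[j]
    open <- new_open
    cur_rows <- nxt_rows
  }
  track_rows <- c(track_rows, open)
  track_rows <- track_rows[vapply(track_rows, length, 1L) >= min_length]
  if (length(track_rows) == 0)
    return(new_comet_tracks(detections[0, ], interval_s))
  # deterministic ids: start frame, then start position
  starts <- t(vapply(track_rows, function(r)
    c(detections$frame[r[1]], detections$x_um[r[1]], detections$y_um[r[1]],
      detections$z_um[r[1]]), numeric(4)))
  ord <- order(starts[, 1], starts[, 2], starts[, 3], starts[, 4])
  track_rows <- track_rows[ord]
  pts <- do.call(rbind, lapply(seq_along(track_rows), function(k) {
    r <- track_rows[[k]]
    data.frame(track_id = k, frame = detections$frame[r],
               x_um = detections$x_um[r], y_um = detections$y_um[r],
               z_um = detections$z_um[r], intensity = detections$intensity[r])
  }))
  new_comet_tracks(pts, interval_s)
}

## construct a comet_tracks object (points -> summary)
new_comet_tracks <- function(points, interval_s) {
  if (nrow(points) == 0) {
    points <- data.frame(track_id = integer(0), frame = integer(0),
                         x_um = numeric(0), y_um = numeric(0),
                         z_um = numeric(0), intensity = numeric(0))
    summary <- data.frame(track_id = integer(0), start_frame = integer(0),
                          end_frame = integer(0), n_points = integer(0),
                          mean_speed_um_s = numeric(0),
                          displacement_speed_um_s = numeric(0),
                          start_x_um = numeric(0), start_y_um = numeric(0),
                          start_z_um = numeric(0), end_x_um = numeric(0),
                          end_y_um = numeric(0), end_z_um = numeric(0))
  } else {
    summary <- do.call(rbind, lapply(split(points, points$track_id), function(p) {
      p <- p[order(p$frame), ]
      xyz <- as.matrix(p[, c("x_um", "y_um", "z_um")])
      n <- nrow(p)
      el <- (n - 1) * interval_s
      data.frame(track_id = p$track_id[1], start_frame = p$frame[1],
                 end_frame = p$frame[n], n_points = n,
                 mean_speed_um_s = compute_mean_travel_speed(xyz, interval_s),
                 displacement_speed_um_s =
                   sqrt(sum((xyz[n, ] - xyz[1, ])^2)) / el,
                 start_x_um = xyz[1, 1], start_y_um = xyz[1, 2],
                 start_z_um = xyz[1, 3], end_x_um = xyz[n, 1],
                 end_y_um = xyz[n, 2], end_z_um = xyz[n, 3])
    }))
    summary <- summary[order(summary$track_id), ]
    rownames(summary) <- NULL
  }
  structure(list(points = points, summary = summary, interval_s = interval_s),
            class = "comet_tracks")
}

#' @export
print.comet_tracks <- function(x, ...) {
  cat(sprintf("%d comet tracks, %d detections", nrow(x$summary),
              nrow(x$points)))
  if (nrow(x$summary) > 0)
    cat(sprintf("; mean travel speed %.3f um/s (median %.3f)",
                mean(x$summary$mean_speed_um_s),
                stats::median(x$summary$mean_speed_um_s)))
  cat("\n")
  invisible(x)
}

#' Convert ground-truth trajectories to comet tracks
#'
#' Bypasses detection and linking: each ground-truth trajectory becomes one
#' track. Useful as an oracle input for the registration and classification
#' stages, and for validating the tracker.
#'
#' @param trajectories a `comet_trajectories` object.
#' @param min_length minimum points per track (default 2 keeps everything
#'   the simulator emitted).
#' @return a `comet_tracks` object.
#' @export
as_comet_tracks <- function(trajectories, min_length = 2L) {
  stopifnot(inherits(trajectories, "comet_trajectories"))
  pts <- trajectories$points
  keep <- trajectories$info$id[trajectories$info$n_points >= min_length]
  pts <- pts[pts$id %in% keep, , drop = FALSE]
  names(pts)[names(pts) == "id"] <- "track_id"
  pts$intensity <- NA_real_
  new_comet_tracks(pts, trajectories$interval_s)
}
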