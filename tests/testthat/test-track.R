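make_det <- function(frame, xyz) {
  data.frame(frame = frame, x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3])
}

test_that("two parallel moving detections link without identity switches", {
  frames <- 1:10
  a <- cbind(1 + 0.3 * (frames - 1), 2, 3)
  b <- cbind(1 + 0.3 * (frames - 1), 7, 3)  # 5 um away
  det <- make_det(rep(frames, 2), rbind(a, b))
  det <- det[order(det$frame, det$y_um), ]
  tk <- build_tracks(det, interval_s = 0.755, min_length = 4)
  expect_equal(nrow(tk$summary), 2)
  expect_equal(sort(tk$summary$n_points), c(10, 10))
  # each track keeps a constant y: no switches between the two lines
  ys <- tapply(tk$points$y_um, tk$points$track_id, function(v) diff(range(v)))
  expect_true(all(ys < 1e-9))
})

test_that("a detection with no successor terminates its track", {
  det <- make_det(c(1L, 1L, 2L), rbind(c(1, 1, 1), c(5, 5, 2), c(1.2, 1, 1)))
  tk <- build_tracks(det, interval_s = 0.755, min_length = 2)
  expect_equal(nrow(tk$summary), 1)  # the isolated detection is dropped
  expect_equal(tk$summary$n_points, 2)
})

test_that("displacements beyond the gate leave only length-1 fragments", {
  frames <- 1:6
  xyz <- cbind(2 * (frames - 1) + 1, 2, 2)  # 2 um steps, gate ~0.96 um
  det <- make_det(frames, xyz)
  tk <- build_tracks(det, interval_s = 0.755, min_length = 2)
  expect_equal(nrow(tk$summary), 0)
})

test_that("empty detections give an empty track set", {
  det <- make_det(integer(0), matrix(0, 0, 3))
  tk <- build_tracks(det, interval_s = 0.755)
  expect_equal(nrow(tk$summary), 0)
  expect_equal(nrow(tk$points), 0)
})

test_that("unordered frames are rejected", {
  det <- make_det(c(3L, 1L, 2L), matrix(1, 3, 3))
  expect_error(build_tracks(det, 0.755), "ordered")
})

test_that("mean travel speed follows the step-length arithmetic", {
  # steps of 0.3775 um every 0.755 s -> 0.5 um/s
  pos <- cbind(0.3775 * (0:4), 0, 0)
  expect_equal(compute_mean_travel_speed(pos, 0.755), 0.5, tolerance = 1e-12)
  expect_equal(compute_mean_travel_speed(matrix(1, 3, 3), 0.755), 0)
  expect_error(compute_mean_travel_speed(matrix(1, 1, 3), 0.755), "2 points")
})

test_that("speeds are invariant under global rotation and translation", {
  set.seed(3)
  pos <- cbind(cumsum(runif(6, 0, 0.4)), cumsum(runif(6, 0, 0.2)),
               cumsum(runif(6, 0, 0.1)))
  R <- digispindle:::rotation_about_axis(c(1, 2, 3), 0.7)
  pos2 <- pos %*% t(R) + matrix(c(5, -2, 1), 6, 3, byrow = TRUE)
  expect_equal(compute_mean_travel_speed(pos, 0.755),
               compute_mean_travel_speed(pos2, 0.755), tolerance = 1e-9)
})

test_that("path-length speed is at least the displacement speed", {
  cfg <- small_config(birth_rate = 5)
  g <- simulate_geometry(cfg, 1)
  tr <- simulate_trajectories(cfg, g, 11)
  tk <- as_comet_tracks(tr)
  expect_true(all(tk$summary$mean_speed_um_s >=
                    tk$summary$displacement_speed_um_s - 1e-9))
})

test_that("every detection belongs to at most one track", {
  cfg <- small_config(birth_rate = 6)
  g <- simulate_geometry(cfg, 1)
  tr <- simulate_trajectories(cfg, g, 13)
  det <- tr$points[order(tr$points$frame), ]
  det <- data.frame(frame = det$frame, x_um = det$x_um, y_um = det$y_um,
                    z_um = det$z_um)
  tk <- build_tracks(det, 0.755, min_length = 2)
  key <- paste(tk$points$frame, tk$points$x_um, tk$points$y_um, tk$points$z_um)
  expect_false(any(duplicated(key)))
  expect_equal(sum(tk$summary$n_points), nrow(tk$points))
})

test_that("tracking ground-truth positions recovers the simulated cohort", {
  cfg <- make_phase_preset("metaphase")  # default desk density
  cfg$geometry$drift_um_per_s <- 0
  cfg$geometry$rotation_deg_per_s <- 0
  g <- simulate_geometry(cfg, 1)
  tr <- simulate_trajectories(cfg, g, 17)
  det <- tr$points[order(tr$points$frame), ]
  truth_key <- paste(det$frame, det$x_um, det$y_um, det$z_um)
  det_df <- data.frame(frame = det$frame, x_um = det$x_um, y_um = det$y_um,
                       z_um = det$z_um)
  tk <- build_tracks(det_df, 0.755, min_length = 2)
  # a truth trajectory counts as recovered when >= 80% of its points land
  # in a single recovered track
  tk_key <- paste(tk$points$frame, tk$points$x_um, tk$points$y_um,
                  tk$points$z_um)
  truth_id <- det$id[match(tk_key, truth_key)]
  n_recovered <- 0
  for (t_id in tr$info$id) {
    in_tracks <- tk$points$track_id[truth_id == t_id]
    if (length(in_tracks) == 0) next
    best <- max(table(in_tracks))
    if (best / tr$info$n_points[tr$info$id == t_id] >= 0.8)
      n_recovered <- n_recovered + 1
  }
  expect_gte(n_recovered / nrow(tr$info), 0.95)
})

test_that("frame-pair linking is the optimal gated assignment", {
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    a <- make_det(rep(1L, n), matrix(runif(3 * n, 0, 3), n, 3))
    b <- make_det(rep(2L, m), matrix(runif(3 * m, 0, 3), m, 3))
    gate <- 1.5
    match <- link_frame_pair(a, b, gate)
    # oracle: enumerate all gated one-to-one matchings, minimize
    # sum(d^2) + gate^2 per unmatched detection on either side
    D2 <- as.matrix(dist(rbind(as.matrix(a[, 2:4]), as.matrix(b[, 2:4]))))^2
    D2 <- D2[seq_len(n), n + seq_len(m), drop = FALSE]
    best <- Inf
    enum <- function(i, used, cost) {
      if (i > n) { best <<- min(best, cost + gate^2 * sum(!used)); return() }
      enum(i + 1, used, cost + gate^2)   # leave row i unmatched
      for (j in which(!used)) if (D2[i, j] <= gate^2) {
        u <- used; u[j] <- TRUE
        enum(i + 1, u, cost + D2[i, j])
      }
    }
    enum(1, rep(FALSE, m), 0)
    got <- sum(ifelse(is.na(match), gate^2, D2[cbind(seq_len(n), match)])) +
      gate^2 * sum(!seq_len(m) %in% match)
    expect_equal(got, best, tolerance = 1e-9)
  }
})
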