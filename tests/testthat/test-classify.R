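## minimal registered-track stand-in: tracks with prescribed start/end points
tracks_from_segments <- function(starts, ends, interval_s = 0.755) {
  n <- nrow(starts)
  pts <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(track_id = i, frame = 1:2,
               x_um = c(starts[i, 1], ends[i, 1]),
               y_um = c(starts[i, 2], ends[i, 2]),
               z_um = c(starts[i, 3], ends[i, 3]),
               intensity = NA_real_)))
  digispindle:::new_comet_tracks(pts, interval_s)
}

test_that("default speed binning yields exactly 10 half-open classes", {
  b <- speed_binning()
  expect_equal(b$n_bins, 10L)
  expect_equal(b$breaks, seq(0, 1, by = 0.1))
  expect_error(speed_binning(width = 0), "positive")
  expect_error(speed_binning(0, 1, 0.3), "integer")
})

test_that("speed bin assignment is exhaustive with half-open edges", {
  speeds <- seq(0.05, 0.95, by = 0.1)
  res <- bin_tracks_by_speed(speeds)
  expect_equal(res$assignments$speed_bin, 1:10)
  expect_equal(res$counts$n, rep(1L, 10))
  # half-open convention: 0.3 belongs to [0.3, 0.4)
  expect_equal(bin_tracks_by_speed(0.3)$assignments$speed_bin, 4L)
  # the top edge is closed
  expect_equal(bin_tracks_by_speed(1.0)$assignments$speed_bin, 10L)
  # out-of-range speeds are reported, not dropped
  res2 <- bin_tracks_by_speed(c(0.5, 1.2))
  expect_equal(attr(res2$counts, "n_out_of_range"), 1L)
  expect_equal(sum(res2$counts$n) + attr(res2$counts, "n_out_of_range"), 2L)
})

test_that("zone partition geometry follows the ceil-based shell rule", {
  # d = 10, start 2.5 um from the nearer pole -> zone 3
  tk <- tracks_from_segments(matrix(c(-5 + 2.5, 0, 0), 1), matrix(c(-2, 1, 0), 1))
  z <- assign_zones(tk, d_um = 10)
  expect_equal(z$zone, 3L)
  expect_equal(z$pole, 1L)
  # a start exactly at a centrosome is zone 1
  tk0 <- tracks_from_segments(matrix(c(5, 0, 0), 1), matrix(c(4, 0, 0), 1))
  expect_equal(assign_zones(tk0, d_um = 10)$zone, 1L)
  # starts beyond d are flagged outside
  tko <- tracks_from_segments(matrix(c(0, 11, 0), 1), matrix(c(0, 10, 0), 1))
  zo <- assign_zones(tko, d_um = 10)
  expect_true(is.na(zo$zone))
  expect_equal(zo$zone_label, "outside")
  expect_error(assign_zones(tk, d_um = -1), "positive")
})

test_that("zone assignment matches a brute-force oracle on random points", {
  set.seed(77)
  d <- 10; n <- 10000
  starts <- cbind(runif(n, -d, d), runif(n, -d, d), runif(n, -d, d))
  tk <- tracks_from_segments(starts, starts + 0.1)
  z <- assign_zones(tk, d_um = d)
  # oracle: explicit distance tests against every shell of both poles
  p1 <- c(-d / 2, 0, 0); p2 <- c(d / 2, 0, 0)
  breaks <- seq(0, d, length.out = 11)
  r1 <- sqrt(colSums((t(starts) - p1)^2))
  r2 <- sqrt(colSums((t(starts) - p2)^2))
  pole <- ifelse(r2 < r1, 2L, 1L)
  r <- pmin(r1, r2)
  zone <- rep(NA_integer_, n)
  for (k in 10:1)
    zone[(r > breaks[k] & r <= breaks[k + 1]) | (k == 1 & r == 0)] <- k
  zone[r > d] <- NA_integer_
  expect_identical(z$zone, zone)
  expect_identical(z$pole, pole)
})

test_that("travel angles hit the parallel/perpendicular/antiparallel anchors", {
  d <- 10
  # pole 1 (-5,0,0): outward axis +x
  starts <- matrix(rep(c(-4, 0, 0), 3), 3, byrow = TRUE)
  ends <- rbind(c(-3, 0, 0),   # toward the opposite pole: 0 deg
                c(-4, 1, 0),   # perpendicular: 90 deg
                c(-5, 0, 0))   # poleward: 180 deg
  tk <- tracks_from_segments(starts, ends)
  ang <- compute_travel_angle(tk, assign_zones(tk, d_um = d))
  expect_equal(ang$angle_deg, c(0, 90, 180), tolerance = 1e-9)
  expect_equal(ang$angle_folded_deg, c(0, 90, 0), tolerance = 1e-9)
})

test_that("zero net displacement gives an undefined angle excluded from summaries", {
  starts <- rbind(c(-4, 0, 0), c(-4, 2, 0))
  ends <- rbind(starts[1, ], c(-4, 3, 0))
  tk <- tracks_from_segments(starts, ends)
  ang <- compute_travel_angle(tk, assign_zones(tk, d_um = 10))
  expect_true(is.na(ang$angle_deg[1]))
  expect_false(ang$defined[1])
  s <- zone_angle_summary(ang)
  expect_equal(sum(s$summary$n), 1)
})

test_that("angle is invariant to rotation about the axis and to scaling", {
  set.seed(12)
  start <- c(-3, 0.5, 0.4)
  disp <- c(0.4, 0.3, -0.2)
  base <- tracks_from_segments(matrix(start, 1), matrix(start + disp, 1))
  a0 <- compute_travel_angle(base, assign_zones(base, d_um = 10))$angle_deg
  for (th in c(0.4, 1.5, 3.0)) {
    R <- digispindle:::rotation_about_axis(c(1, 0, 0), th)
    s2 <- as.numeric(R %*% start); d2 <- as.numeric(R %*% disp)
    tk2 <- tracks_from_segments(matrix(s2, 1), matrix(s2 + d2, 1))
    expect_equal(compute_travel_angle(tk2,
                                      assign_zones(tk2, d_um = 10))$angle_deg,
                 a0, tolerance = 1e-9)
  }
  tk3 <- tracks_from_segments(matrix(start, 1), matrix(start + 5 * disp, 1))
  expect_equal(compute_travel_angle(tk3,
                                    assign_zones(tk3, d_um = 10))$angle_deg,
               a0, tolerance = 1e-9)
})

test_that("zone angle summaries conserve counts and handle pure cohorts", {
  # all angles 0 in one zone
  starts <- matrix(rep(c(-4, 0, 0), 5), 5, byrow = TRUE)
  ends <- starts; ends[, 1] <- ends[, 1] + 0.5
  tk <- tracks_from_segments(starts, ends)
  ang <- compute_travel_angle(tk, assign_zones(tk, d_um = 10))
  s <- zone_angle_summary(ang)
  expect_equal(nrow(s$summary), 1)
  expect_equal(s$summary$mean_deg, 0)
  expect_equal(s$summary$circ_sd_deg, 0)
  expect_equal(sum(s$histogram$n), 5)
  # empty input -> empty tables, no error
  empty <- zone_angle_summary(ang[0, ])
  expect_equal(nrow(empty$summary), 0)
})

test_that("isotropic growth directions give a ~90 degree pooled mean angle", {
  cfg <- small_config(n_frames = 50, birth_rate = 10, kappa = 0)
  g <- simulate_geometry(cfg, 1)
  tk <- as_comet_tracks(simulate_trajectories(cfg, g, 19))
  reg <- register_series(tk, g)
  ang <- compute_travel_angle(reg, assign_zones(reg))
  a <- ang$angle_deg[!is.na(ang$angle_deg)]
  # Monte-Carlo oracle: angle between a uniform random direction and a
  # fixed axis
  set.seed(101)
  u <- matrix(rnorm(3 * 20000), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  oracle <- mean(acos(pmax(pmin(u[, 1], 1), -1)) * 180 / pi)
  se <- sd(a) / sqrt(length(a))
  expect_lt(abs(mean(a) - oracle), 3 * se)
})

test_that("subsampling follows the rounding rule and is seed-stable", {
  cfg <- small_config(birth_rate = 8)
  g <- simulate_geometry(cfg, 1)
  tk <- as_comet_tracks(simulate_trajectories(cfg, g, 23))
  n <- nrow(tk$summary)
  sub <- subsample_tracks(tk, 0.2, seed = 3)
  expect_equal(nrow(sub$summary), round(0.2 * n))
  expect_identical(subsample_tracks(tk, 0.2, seed = 3)$summary$track_id,
                   sub$summary$track_id)
  expect_identical(subsample_tracks(tk, 1)$summary$track_id,
                   tk$summary$track_id)
  expect_error(subsample_tracks(tk, 0), "fraction")
  expect_error(subsample_tracks(tk, 1.2), "fraction")
})

test_that("classify_tracks is consistent with its component classifiers", {
  cfg <- small_config(birth_rate = 6)
  g <- simulate_geometry(cfg, 1)
  reg <- register_series(as_comet_tracks(simulate_trajectories(cfg, g, 29)), g)
  cl <- classify_tracks(reg)
  expect_equal(nrow(cl), nrow(reg$summary))
  zo <- assign_zones(reg)
  expect_identical(cl$zone, zo$zone)
  expect_identical(cl$pole, zo$pole)
  sp <- bin_tracks_by_speed(reg)
  expect_identical(cl$speed_bin, sp$assignments$speed_bin)
})
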