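test_that("canonical transform puts the poles at (+/- d/2, 0, 0)", {
  tf <- canonical_transform(c(1, 1, 1), c(3, 1, 1))
  expect_equal(apply_transform(tf, c(1, 1, 1)), c(-1, 0, 0), tolerance = 1e-9)
  expect_equal(apply_transform(tf, c(3, 1, 1)), c(1, 0, 0), tolerance = 1e-9)

  set.seed(2)
  for (rep in 1:15) {
    c1 <- runif(3, -5, 5); c2 <- runif(3, -5, 5)
    if (sqrt(sum((c1 - c2)^2)) < 1e-3) next
    tf <- canonical_transform(c1, c2)
    d <- sqrt(sum((c2 - c1)^2))
    expect_equal(apply_transform(tf, c1), c(-d / 2, 0, 0), tolerance = 1e-9)
    expect_equal(apply_transform(tf, c2), c(d / 2, 0, 0), tolerance = 1e-9)
    # rigidity
    p <- matrix(runif(9, -5, 5), 3, 3)
    q <- apply_transform(tf, p)
    expect_equal(as.numeric(dist(p)), as.numeric(dist(q)), tolerance = 1e-9)
  }
  expect_error(canonical_transform(c(1, 1, 1), c(1, 1, 1)), "coincident")
})

test_that("antiparallel axis uses the documented 180-degree convention", {
  tf <- canonical_transform(c(2, 0, 0), c(-2, 0, 0))
  expect_equal(apply_transform(tf, c(2, 0, 0)), c(-2, 0, 0), tolerance = 1e-9)
  # rotation about +z: z is unchanged
  expect_equal(as.numeric(tf$rotation %*% c(0, 0, 1)), c(0, 0, 1),
               tolerance = 1e-9)
})

test_that("transforms compose and invert to identity", {
  set.seed(4)
  R <- digispindle:::rotation_about_axis(rnorm(3), 0.9)
  tf <- rigid_transform(R, c(1, -2, 3))
  inv <- invert_transform(tf)
  p <- matrix(rnorm(15), 5, 3)
  expect_equal(apply_transform(inv, apply_transform(tf, p)), p,
               tolerance = 1e-9)
  comp <- compose_transforms(inv, tf)
  expect_equal(comp$rotation, diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(comp$translation, c(0, 0, 0), tolerance = 1e-9)
})

## a registered static, axis-aligned cell for reuse below
static_cell <- function(seed = 21) {
  cfg <- small_config(n_frames = 25, birth_rate = 4)
  g <- simulate_geometry(cfg, 1)
  tr <- simulate_trajectories(cfg, g, seed)
  list(cfg = cfg, g = g, tracks = as_comet_tracks(tr))
}

test_that("a static axis-aligned spindle registers with identity rotation", {
  sc <- static_cell()
  reg <- register_series(sc$tracks, sc$g)
  tfs <- attr(reg, "transforms")
  mid <- (sc$g$c1[1, ] + sc$g$c2[1, ]) / 2
  for (t in c(1, 10, 25)) {
    expect_equal(tfs[[t]]$rotation, diag(3), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(tfs[[t]]$translation, -mid, tolerance = 1e-9)
  }
})

test_that("injected whole-spindle rotation is removed by registration", {
  sc <- static_cell()
  reg0 <- register_series(sc$tracks, sc$g)
  # rotate the whole scene (geometry + detections) about the midpoint by a
  # time-varying angle about z and re-register
  mid <- (sc$g$c1[1, ] + sc$g$c2[1, ]) / 2
  g2 <- sc$g
  tk2 <- sc$tracks
  for (t in seq_len(sc$g$n_frames)) {
    R <- digispindle:::rotation_about_axis(c(0, 0, 1), (30 + t) * pi / 180)
    rot <- function(p) sweep(sweep(p, 2, mid) %*% t(R), 2, mid, "+")
    g2$c1[t, ] <- rot(matrix(sc$g$c1[t, ], 1)); g2$c2[t, ] <- rot(matrix(sc$g$c2[t, ], 1))
    rows <- tk2$points$frame == t
    if (any(rows))
      tk2$points[rows, c("x_um", "y_um", "z_um")] <-
        rot(as.matrix(sc$tracks$points[rows, c("x_um", "y_um", "z_um")]))
  }
  tk2 <- digispindle:::new_comet_tracks(tk2$points, tk2$interval_s)
  reg2 <- register_series(tk2, g2)
  expect_equal(reg2$points[, c("x_um", "y_um", "z_um")],
               reg0$points[, c("x_um", "y_um", "z_um")], tolerance = 1e-6)
})

test_that("registration is an isometry: distances and speeds are preserved", {
  cfg <- small_config(n_frames = 20, birth_rate = 5, drift_um_per_s = 0.08,
                      rotation_deg_per_s = 2)
  g <- simulate_geometry(cfg, 3)
  tk <- as_comet_tracks(simulate_trajectories(cfg, g, 5))
  reg <- register_series(tk, g)
  # same-frame pairwise distances
  for (f in c(2, 9)) {
    a <- as.matrix(tk$points[tk$points$frame == f, c("x_um", "y_um", "z_um")])
    b <- as.matrix(reg$points[reg$points$frame == f,
                              c("x_um", "y_um", "z_um")])
    if (nrow(a) > 1) expect_equal(as.numeric(dist(a)), as.numeric(dist(b)), tolerance = 1e-9)
  }
  # per-track speeds: exactly preserved when the spindle pose is static
  # (a single rigid transform); under drift the whole point of the
  # correction is that the drift component is removed from the motion
  sc <- static_cell()
  reg_s <- register_series(sc$tracks, sc$g)
  expect_equal(reg_s$summary$mean_speed_um_s,
               sc$tracks$summary$mean_speed_um_s, tolerance = 1e-9)
  # registered centrosomes lie on the x axis at +/- d/2
  tfs <- attr(reg, "transforms")
  d <- attr(reg, "d_per_frame")
  for (t in c(1, 10, 20)) {
    expect_equal(apply_transform(tfs[[t]], g$c1[t, ]), c(-as.numeric(d[t]) / 2, 0, 0),
                 tolerance = 1e-9)
    expect_equal(apply_transform(tfs[[t]], g$c2[t, ]), c(as.numeric(d[t]) / 2, 0, 0),
                 tolerance = 1e-9)
  }
})

test_that("registering an already-canonical cell is idempotent", {
  sc <- static_cell()
  reg <- register_series(sc$tracks, sc$g)
  # canonical geometry: poles on the x axis symmetric about the origin
  n <- sc$g$n_frames
  d <- attr(reg, "d_per_frame")
  gc <- sc$g
  gc$c1 <- cbind(-d / 2, 0, 0); gc$c2 <- cbind(d / 2, 0, 0)
  reg2 <- register_series(reg, gc)
  tfs <- attr(reg2, "transforms")
  for (t in c(1, n)) {
    expect_equal(tfs[[t]]$rotation, diag(3), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(tfs[[t]]$translation, c(0, 0, 0), tolerance = 1e-9)
  }
  expect_equal(reg2$points$x_um, reg$points$x_um, tolerance = 1e-9)
})

test_that("round-trip through the inverse transforms restores lab coordinates", {
  cfg <- small_config(n_frames = 15, birth_rate = 4, drift_um_per_s = 0.05,
                      rotation_deg_per_s = 1)
  g <- simulate_geometry(cfg, 8)
  tk <- as_comet_tracks(simulate_trajectories(cfg, g, 9))
  reg <- register_series(tk, g)
  tfs <- attr(reg, "transforms")
  back <- reg$points
  for (t in unique(back$frame)) {
    rows <- back$frame == t
    back[rows, c("x_um", "y_um", "z_um")] <-
      apply_transform(invert_transform(tfs[[as.character(t)]]),
                      as.matrix(back[rows, c("x_um", "y_um", "z_um")]))
  }
  expect_equal(back$x_um, tk$points$x_um, tolerance = 1e-9)
  expect_equal(back$y_um, tk$points$y_um, tolerance = 1e-9)
  expect_equal(back$z_um, tk$points$z_um, tolerance = 1e-9)
})

test_that("merging cells conserves counts and keeps provenance", {
  cells <- lapply(c(31, 32, 33), function(s) {
    sc <- static_cell(s)
    register_series(sc$tracks, sc$g, cell_id = s)
  })
  n_each <- vapply(cells, function(cl) nrow(cl$summary), numeric(1))
  merged <- merge_cells(cells)
  expect_equal(nrow(merged$summary), sum(n_each))
  expect_equal(sort(unique(merged$summary$cell_id)), c(31, 32, 33))
  # merging a single cell is the identity on coordinates
  one <- merge_cells(cells[1])
  expect_equal(one$summary$mean_speed_um_s, cells[[1]]$summary$mean_speed_um_s,
               tolerance = 1e-12)
  expect_equal(nrow(one$points), nrow(cells[[1]]$points))
})

test_that("mixing phases without an override is refused", {
  sc <- static_cell()
  a <- register_series(sc$tracks, sc$g)
  b <- a
  attr(b, "phase") <- "telophase"
  expect_error(merge_cells(list(a, b)), "phase")
  expect_silent(m <- merge_cells(list(a, b), allow_mixed_phases = TRUE))
  expect_equal(attr(m, "phase"), "mixed")
})

test_that("merged same-preset cells reproduce the configured speed mixture", {
  means <- seq(0.55, 0.35, length.out = 10)
  w <- c(0.18, 0.16, 0.14, 0.12, 0.10, 0.08, 0.07, 0.06, 0.05, 0.04)
  cells <- lapply(c(41, 42, 43), function(s) {
    cfg <- small_config(n_frames = 40, birth_rate = 6,
                        speed_mean_by_zone = means, speed_sd = 0.06,
                        birth_density = w)
    g <- simulate_geometry(cfg, 1)
    register_series(as_comet_tracks(simulate_trajectories(cfg, g, s)),
                    g, cell_id = s)
  })
  merged <- merge_cells(cells)
  mixture_mean <- sum(w * means)
  sp <- merged$summary$mean_speed_um_s
  se <- sd(sp) / sqrt(length(sp))
  expect_lt(abs(mean(sp) - mixture_mean), 3 * se + 0.01)
})
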