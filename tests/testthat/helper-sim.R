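# Shared fixtures: small, fast simulation configurations built in code.

## compact spindle configuration for unit tests: short movie, small FOV,
## coarse grid, static spindle unless asked otherwise
small_config <- function(n_frames = 20, d_um = 4,
                         fov = c(10, 8, 6), pitch = c(0.2, 0.2, 0.3),
                         drift_um_per_s = 0, rotation_deg_per_s = 0,
                         separation_rate = 0,
                         birth_rate = 3, lifetime_mean_s = 6,
                         speed_mean_by_zone = rep(0.45, 10),
                         speed_sd = 0.1, kappa = 2,
                         birth_density = c(0.18, 0.16, 0.14, 0.12, 0.10,
                                           0.08, 0.07, 0.06, 0.05, 0.04)) {
  cfg <- make_phase_preset("metaphase")
  cfg$acquisition <- acquisition_spec(n_frames, 0.755, pitch, fov)
  cfg$geometry$d_um <- d_um
  cfg$geometry$drift_um_per_s <- drift_um_per_s
  cfg$geometry$rotation_deg_per_s <- rotation_deg_per_s
  cfg$geometry$separation_rate_um_s <- separation_rate
  cfg$motion <- motion_model(speed_mean_by_zone = speed_mean_by_zone,
                             speed_sd = speed_sd,
                             axis_angle_concentration = kappa,
                             lifetime_mean_s = lifetime_mean_s,
                             birth_rate_per_s = birth_rate,
                             birth_density_by_zone = birth_density)
  cfg
}

## greedy nearest-neighbour matching of detections to ground truth within a
## radius; returns list(recall, precision, n_matched, errors)
match_detections <- function(truth_xyz, det_xyz, radius_um = 0.3) {
  truth_xyz <- as.matrix(truth_xyz); det_xyz <- as.matrix(det_xyz)
  nt <- nrow(truth_xyz); nd <- nrow(det_xyz)
  if (nt == 0 || nd == 0)
    return(list(recall = NA, precision = NA, n_matched = 0, errors = numeric(0)))
  D <- outer(rowSums(truth_xyz^2), rep(1, nd)) +
    outer(rep(1, nt), rowSums(det_xyz^2)) - 2 * truth_xyz %*% t(det_xyz)
  D <- sqrt(pmax(D, 0))
  matched <- 0L; errs <- numeric(0)
  while (min(D) <= radius_um) {
    ij <- which(D == min(D), arr.ind = TRUE)[1, ]
    matched <- matched + 1L
    errs <- c(errs, D[ij[1], ij[2]])
    D[ij[1], ] <- Inf; D[, ij[2]] <- Inf
    if (all(!is.finite(D))) break
  }
  list(recall = matched / nt, precision = matched / nd,
       n_matched = matched, errors = errs)
}

## brute-force minimal-cost assignment by permutation enumeration (oracle
## for the LAP solver), n <= 7
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < best_cost) { best_cost <- cc; best <- p }
  }
  list(assignment = best, cost = best_cost)
}
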