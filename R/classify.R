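# Trajectory classification: mean-travel-speed bins, spherical zones of
# origin around the nearer pole, and travel angles against the spindle axis.

#' Speed binning scheme
#'
#' Half-open bins `[lo, lo + width)` covering `[lower, upper]`; the last bin
#' also includes its upper edge. Defaults give the 10 classes spanning
#' 0-1 um/s in 0.1 um/s steps.
#'
#' @param lower,upper range of the binning, um/s.
#' @param width bin width, um/s; `(upper - lower) / width` must be a
#'   positive integer.
#' @return object of class `speed_binning` with fields `lower`, `upper`,
#'   `width`, `n_bins`, `breaks`.
#' @export
speed_binning <- function(lower = 0, upper = 1, width = 0.1) {
  if (width <= 0) stop("bin width must be positive")
  nb <- (upper - lower) / width
  if (nb <= 0 || abs(nb - round(nb)) > 1e-9)
    stop("(upper - lower) / width must be a positive integer")
  nb <- as.integer(round(nb))
  structure(list(lower = lower, upper = upper, width = width, n_bins = nb,
                 breaks = lower + width * (0:nb)),
            class = "speed_binning")
}

#' Bin tracks by mean travel speed
#'
#' Every in-range track falls in exactly one half-open bin (the last bin is
#' closed above); out-of-range tracks are reported separately, never
#' silently dropped.
#'
#' @param tracks a `comet_tracks` object (with mean speeds in its summary)
#'   or a numeric vector of speeds.
#' @param binning a [speed_binning()].
#' @return list with `assignments` (data.frame: track_id, speed_um_s,
#'   speed_bin integer or NA when out of range, bin_label) and `counts`
#'   (data.frame: bin, lower, upper, n; plus attribute `n_out_of_range`).
#' @export
bin_tracks_by_speed <- function(tracks, binning = speed_binning()) {
  stopifnot(inherits(binning, "speed_binning"))
  if (inherits(tracks, "comet_tracks")) {
    speeds <- tracks$summary$mean_speed_um_s
    ids <- tracks$summary$track_id
  } else {
    speeds <- as.numeric(tracks)
    ids <- seq_along(speeds)
  }
  # small epsilon so edge values (e.g. 0.3 / 0.1) are not pushed one bin
  # down by floating-point division
  bin <- floor((speeds - binning$lower) / binning$width + 1e-9) + 1L
  bin[speeds == binning$upper] <- binning$n_bins   # closed top edge
  bin[speeds < binning$lower | speeds > binning$upper] <- NA_integer_
  labs <- sprintf("[%.3g,%.3g%s", binning$breaks[-length(binning$breaks)],
                  binning$breaks[-1],
                  c(rep(")", binning$n_bins - 1), "]"))
  assignments <- data.frame(track_id = ids, speed_um_s = speeds,
                            speed_bin = bin,
                            bin_label = ifelse(is.na(bin), "out_of_range",
                                               labs[bin]))
  counts <- data.frame(bin = seq_len(binning$n_bins),
                       lower = binning$breaks[-length(binning$breaks)],
                       upper = binning$breaks[-1],
                       n = tabulate(bin, binning$n_bins))
  attr(counts, "n_out_of_range") <- sum(is.na(bin))
  list(assignments = assignments, counts = counts)
}

#' Spherical zone partition
#'
#' Spheres centred on each centrosome with radius equal to the
#' intercentrosomal distance d, divided into `n_zones` concentric shells of
#' equal radial thickness. Zone k covers radial distances
#' `((k-1) d/n, k d/n]`, with r = 0 assigned to zone 1 and r > d labelled
#' "outside".
#'
#' @param n_zones number of shells (default 10).
#' @param radius_um sphere radius = intercentrosomal distance d, um.
#' @return object of class `zone_partition` with fields `n_zones`,
#'   `radius_um`, `breaks`.
#' @export
zone_partition <- function(n_zones = 10L, radius_um) {
  n_zones <- as.integer(n_zones)
  stopifnot(n_zones >= 1)
  if (radius_um <= 0) stop("zone radius (intercentrosomal distance) must be positive")
  structure(list(n_zones = n_zones, radius_um = radius_um,
                 breaks = seq(0, radius_um, length.out = n_zones + 1)),
            class = "zone_partition")
}

## zone index for radial distances r: ceil(n r / d); r = 0 -> 1; r > d -> NA
zone_of_radius <- function(r, partition) {
  z <- ceiling(partition$n_zones * r / partition$radius_um)
  z[r == 0] <- 1L
  z[r > partition$radius_um] <- NA_integer_
  as.integer(z)
}

#' Assign registered tracks to spherical zones
#'
#' Each track is assigned to the nearer centrosome (tie: pole 1) based on
#' its start point, and to the shell containing its start-point distance
#' from that pole. In the canonical frame the poles sit at (-d/2, 0, 0) and
#' (+d/2, 0, 0); `d` defaults to the registered cell's mean intercentrosomal
#' distance.
#'
#' @param tracks registered `comet_tracks`.
#' @param partition a [zone_partition()]; built from `d` when NULL.
#' @param d_um intercentrosomal distance, um; default `attr(tracks, "mean_d")`.
#' @return data.frame: track_id, pole (1 or 2), r_um (distance from the
#'   assigned pole), zone (integer, NA = outside), zone_label.
#' @export
assign_zones <- function(tracks, partition = NULL, d_um = NULL) {
  stopifnot(inherits(tracks, "comet_tracks"))
  if (is.null(d_um)) d_um <- attr(tracks, "mean_d")
  if (is.null(d_um) && !is.null(partition)) d_um <- partition$radius_um
  if (is.null(d_um) || !is.finite(d_um) || d_um <= 0)
    stop("intercentrosomal distance d must be positive (register the cell ",
         "or pass d_um)")
  if (is.null(partition)) partition <- zone_partition(10L, d_um)
  s <- tracks$summary
  p1 <- c(-d_um / 2, 0, 0); p2 <- c(d_um / 2, 0, 0)
  start <- as.matrix(s[, c("start_x_um", "start_y_um", "start_z_um")])
  r1 <- sqrt(colSums((t(start) - p1)^2))
  r2 <- sqrt(colSums((t(start) - p2)^2))
  pole <- ifelse(r2 < r1, 2L, 1L)          # tie -> pole 1
  r <- pmin(r1, r2)
  zone <- zone_of_radius(r, partition)
  data.frame(track_id = s$track_id, pole = pole, r_um = r, zone = zone,
             zone_label = ifelse(is.na(zone), "outside",
                                 as.character(zone)))
}

#' Travel angle of tracks against the spindle axis
#'
#' The angle between a track's net displacement (end - start) and the unit
#' vector pointing from its assigned pole toward the opposite pole, in
#' degrees (0 = growth straight toward the opposite pole, 180 = straight
#' poleward). The folded 0-90 degree version against the undirected axis is
#' returned alongside. Tracks with zero net displacement get NA and are
#' excluded from summaries.
#'
#' @param tracks registered `comet_tracks`.
#' @param zones zone assignments from [assign_zones()] (provides the pole;
#'   computed with defaults when NULL).
#' @return data.frame: track_id, pole, zone, angle_deg, angle_folded_deg,
#'   defined (logical).
#' @export
compute_travel_angle <- function(tracks, zones = NULL) {
  stopifnot(inherits(tracks, "comet_tracks"))
  if (is.null(zones)) zones <- assign_zones(tracks)
  s <- tracks$summary
  stopifnot(identical(s$track_id, zones$track_id))
  disp <- cbind(s$end_x_um - s$start_x_um,
                s$end_y_um - s$start_y_um,
                s$end_z_um - s$start_z_um)
  nrm <- sqrt(rowSums(disp^2))
  # pole 1 sits at -d/2 so its outward axis is +x; pole 2 -> -x
  axis_x <- ifelse(zones$pole == 1L, 1, -1)
  cosang <- clamp(disp[, 1] * axis_x / nrm, -1, 1)
  ang <- acos(cosang) * 180 / pi
  ang[nrm == 0] <- NA_real_
  data.frame(track_id = s$track_id, pole = zones$pole, zone = zones$zone,
             angle_deg = ang, angle_folded_deg = pmin(ang, 180 - ang),
             defined = nrm > 0)
}

#' Per-zone summary of travel angles
#'
#' One row per zone present among the defined angles: count, mean angle,
#' circular standard deviation, plus a long-format histogram at 10 degree
#' bins.
#'
#' @param angles data.frame from [compute_travel_angle()].
#' @param bin_deg histogram bin width in degrees (default 10).
#' @return list with `summary` (zone, n, mean_deg, circ_sd_deg) and
#'   `histogram` (zone, bin_lo_deg, bin_hi_deg, n). Empty input gives empty
#'   tables.
#' @export
zone_angle_summary <- function(angles, bin_deg = 10) {
  ok <- angles[!is.na(angles$angle_deg) & !is.na(angles$zone), , drop = FALSE]
  if (nrow(ok) == 0)
    return(list(summary = data.frame(zone = integer(0), n = integer(0),
                                     mean_deg = numeric(0),
                                     circ_sd_deg = numeric(0)),
                histogram = data.frame(zone = integer(0),
                                       bin_lo_deg = numeric(0),
                                       bin_hi_deg = numeric(0),
                                       n = integer(0))))
  brk <- seq(0, 180, by = bin_deg)
  per_zone <- lapply(split(ok, ok$zone), function(z) {
    th <- z$angle_deg * pi / 180
    Rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
    csd <- if (Rbar >= 1) 0 else sqrt(-2 * log(Rbar)) * 180 / pi
    h <- hist(z$angle_deg, breaks = brk, plot = FALSE,
              include.lowest = TRUE, right = TRUE)
    list(summary = data.frame(zone = z$zone[1], n = nrow(z),
                              mean_deg = mean(z$angle_deg),
                              circ_sd_deg = csd),
         histogram = data.frame(zone = z$zone[1], bin_lo_deg = brk[-length(brk)],
                                bin_hi_deg = brk[-1], n = h$counts))
  })
  out <- list(summary = do.call(rbind, lapply(per_zone, `[[`, "summary")),
              histogram = do.call(rbind, lapply(per_zone, `[[`, "histogram")))
  rownames(out$summary) <- rownames(out$histogram) <- NULL
  out
}

#' Random subsample of tracks
#'
#' Uniform sample without replacement of `round(fraction * n)` tracks;
#' reproducible for a fixed seed. Mirrors the random extraction used to
#' thin trajectory displays (e.g. ~13% or ~20% per cell).
#'
#' @param tracks a `comet_tracks` object.
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed.
#' @return a `comet_tracks` object containing the sampled tracks (track ids
#'   and attributes preserved).
#' @export
subsample_tracks <- function(tracks, fraction, seed = 1L) {
  stopifnot(inherits(tracks, "comet_tracks"))
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  ids <- tracks$summary$track_id
  k <- round(fraction * length(ids))
  keep <- with_seed(seed, sort(sample(ids, k)))
  out <- tracks
  out$points <- tracks$points[tracks$points$track_id %in% keep, , drop = FALSE]
  out$summary <- tracks$summary[tracks$summary$track_id %in% keep, , drop = FALSE]
  rownames(out$points) <- rownames(out$summary) <- NULL
  out
}

#' One-stop classification of registered tracks
#'
#' Runs speed binning, zone assignment and travel-angle computation and
#' returns one row per track, the format written by the pipeline's
#' classification CSV.
#'
#' @param tracks registered (or merged) `comet_tracks`.
#' @param binning a [speed_binning()].
#' @param n_zones number of spherical zones.
#' @param d_um intercentrosomal distance; default the registered mean.
#' @return data.frame: track_id, cell_id (if present), speed_um_s,
#'   speed_bin, pole, zone, r_um, angle_deg, angle_folded_deg.
#' @export
classify_tracks <- function(tracks, binning = speed_binning(),
                            n_zones = 10L, d_um = NULL) {
  if (is.null(d_um)) d_um <- attr(tracks, "mean_d")
  zones <- assign_zones(tracks, zone_partition(n_zones, d_um), d_um)
  speeds <- bin_tracks_by_speed(tracks, binning)$assignments
  angles <- compute_travel_angle(tracks, zones)
  out <- data.frame(track_id = tracks$summary$track_id,
                    speed_um_s = speeds$speed_um_s,
                    speed_bin = speeds$speed_bin,
                    pole = zones$pole, zone = zones$zone, r_um = zones$r_um,
                    angle_deg = angles$angle_deg,
                    angle_folded_deg = angles$angle_folded_deg)
  if ("cell_id" %in% names(tracks$summary))
    out <- cbind(out[1], cell_id = tracks$summary$cell_id, out[-1])
  out
}
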