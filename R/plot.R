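# Static summary figures from the classification tables (base graphics).

#' Bar plot of trajectory counts per speed class
#'
#' @param counts data.frame from [bin_tracks_by_speed()]`$counts`.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plot_speed_bins <- function(counts, ...) {
  mids <- graphics::barplot(counts$n,
                            names.arg = sprintf("%.1f-%.1f", counts$lower,
                                                counts$upper),
                            xlab = "mean travel speed (um/s)",
                            ylab = "trajectories", las = 2, ...)
  invisible(mids)
}

#' Travel-angle distribution per spherical zone
#'
#' One boxplot of travel angles (degrees, against the pole-to-opposite-pole
#' direction) per zone of origin.
#'
#' @param angles data.frame from [compute_travel_angle()].
#' @param ... passed to [graphics::boxplot()].
#' @export
plot_zone_angles <- function(angles, ...) {
  ok <- angles[!is.na(angles$angle_deg) & !is.na(angles$zone), ]
  graphics::boxplot(angle_deg ~ zone, data = ok,
                    xlab = "spherical zone (1 = at the pole)",
                    ylab = "travel angle vs spindle axis (deg)", ...)
  invisible(NULL)
}
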