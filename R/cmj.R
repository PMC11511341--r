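#' Analyse one countermovement-jump trial
#'
#' Runs the full per-trial pipeline: whole-body CoM from the Dempster
#' segment model, optional zero-phase smoothing of the CoM and toe traces
#' (centred moving average, then the same window on the differentiated
#' velocity), detection of the nine jump events, joint-angle series, and
#' extraction of the 21 per-trial variables.
#'
#' @param tset A [landmark_set()] (gap-filled; see [gap_fill_set()]).
#' @param side `"left"` or `"right"`.
#' @param config A [cmj_config()].
#' @param smooth_window_s Moving-average window in seconds applied to the
#'   CoM and toe traces and to the velocity (default 0.05 s; 0 disables
#'   smoothing).
#' @param model A [segment_model()].
#' @return An object of class `cmj`: fields `com` ([com_trajectory]),
#'   `toe_z`, `events` ([detect_events()]), `angles`, `variables`
#'   ([compute_variables()]), `side`, `source_label`, `sampling_rate_hz`.
#' @export
#' @examples
#' sim <- simulate_cmj(cmj_sim_spec())
#' fit <- cmj_analyze(sim$trajectories, side = "left", smooth_window_s = 0)
#' coef(fit)["jump_height_m"]
cmj_analyze <- function(tset, side = c("left", "right"),
                        config = cmj_config(), smooth_window_s = 0.05,
                        model = segment_model()) {
  stopifnot(inherits(tset, "landmark_set"))
  side <- match.arg(side)
  fs <- tset$sampling_rate_hz

  com_raw <- body_com(tset, side, model)
  z <- moving_average_s(com_raw$com_z_m, smooth_window_s, fs)
  vz <- vertical_velocity(z, fs)
  vz <- moving_average_s(vz, smooth_window_s, fs)
  com <- com_trajectory(com_x_m = com_raw$com_x_m, com_z_m = z,
                        sampling_rate_hz = fs,
                        segment_com = com_raw$segment_com, vz_mps = vz)
  # the toe trace is left unsmoothed: its flight excursion is two orders of
  # magnitude above measurement noise, and smoothing correlates the noise,
  # which biases the threshold backtracking at lift-off/touchdown
  toe_z <- landmark_series(tset, paste0(side, "_big_toe"), "z")

  events <- detect_events(com, toe_z, config)
  angles <- list(ankle = joint_angle(tset, "ankle", side),
                 knee = joint_angle(tset, "knee", side),
                 hip = joint_angle(tset, "hip", side))
  vars <- compute_variables(events, com, toe_z, angles)

  structure(list(com = com, toe_z = toe_z, events = events, angles = angles,
                 variables = vars, side = side,
                 source_label = tset$source_label,
                 sampling_rate_hz = fs),
            class = "cmj")
}

#' @export
print.cmj <- function(x, ...) {
  cat(sprintf("<cmj> %s side, source '%s', %d samples @ %g Hz\n",
              x$side, x$source_label, length(x$com$com_z_m),
              x$sampling_rate_hz))
  cat(sprintf("  jump height %.3f m, depth %.3f m, flight %.3f s, take-off Vz %.2f m/s\n",
              x$variables$jump_height_m, x$variables$countermovement_depth_m,
              x$variables$flight_time_s, x$variables$takeoff_com_vz_mps))
  invisible(x)
}

#' @export
summary.cmj <- function(object, ...) {
  cat("Countermovement-jump analysis (", object$side, "side )\n\n")
  print(object$events)
  cat("\n")
  print(object$variables)
  invisible(object)
}

#' @export
coef.cmj <- function(object, ...) {
  unlist(object$variables)
}

#' Plot a countermovement-jump analysis
#'
#' Base-graphics view of the CoM height, toe height (both relative to their
#' quiet-stance baselines) and CoM vertical velocity, with the detected
#' events a, c, d, e, f, g, h, i marked.
#'
#' @param x A `cmj` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cmj <- function(x, ...) {
  fs <- x$sampling_rate_hz
  t <- (seq_along(x$com$com_z_m) - 1) / fs
  zc <- x$com$com_z_m - x$events$baseline_z_m
  zt <- x$toe_z - x$events$toe_baseline_z_m
  vz <- x$com$vz_mps
  ylim <- range(zc, zt, vz / 5)
  graphics::plot(t, zc, type = "l", col = "blue", lwd = 2,
                 xlab = "time (s)", ylab = "displacement (m) / Vz / 5 (m/s)",
                 ylim = ylim, ...)
  graphics::lines(t, zt, col = "darkgreen", lwd = 2)
  graphics::lines(t, vz / 5, col = "red")
  graphics::abline(h = 0, col = "grey70", lty = 3)
  for (k in c("a", "c", "d", "e", "f", "g", "h", "i")) {
    idx <- x$events[[k]]
    graphics::abline(v = (idx - 1) / fs, col = "grey50", lty = 2)
    graphics::mtext(k, at = (idx - 1) / fs, side = 3, line = 0, cex = 0.8)
  }
  graphics::legend("topleft", legend = c("CoM z", "Toe z", "Vz / 5"),
                   col = c("blue", "darkgreen", "red"), lwd = c(2, 2, 1),
                   bty = "n", cex = 0.8)
  invisible(x)
}
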