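#' Standard gravitational acceleration used by the ballistic formulas
#' @export
CMJ_GRAVITY <- 9.81

#' Jump height from flight time
#'
#' Ballistic closed form `h = g * t^2 / 8` for a flight of duration `t`
#' (take-off and touchdown at equal height).
#'
#' @param t_flight Flight time in seconds (> 0).
#' @param g Gravitational acceleration (default 9.81 m/s^2).
#' @return Height in meters.
#' @export
#' @examples
#' jump_height_from_flight_time(0.547)
jump_height_from_flight_time <- function(t_flight, g = CMJ_GRAVITY) {
  if (any(!is.finite(t_flight)) || any(t_flight <= 0))
    stop("flight time must be positive", call. = FALSE)
  g * t_flight^2 / 8
}

#' Jump height from take-off velocity
#'
#' Ballistic closed form `h = v^2 / (2 g)`.
#'
#' @param v Vertical CoM velocity at take-off (m/s, > 0).
#' @param g Gravitational acceleration (default 9.81 m/s^2).
#' @return Height in meters.
#' @export
#' @examples
#' jump_height_from_velocity(2.33)
jump_height_from_velocity <- function(v, g = CMJ_GRAVITY) {
  if (any(!is.finite(v)) || any(v <= 0))
    stop("take-off velocity must be positive", call. = FALSE)
  v^2 / (2 * g)
}

# sub-sample crossing of `series` through `level` between k and k+1
.cross_time <- function(series, level, k, fs) {
  z0 <- series[k]; z1 <- series[k + 1]
  if (z1 == z0) return((k - 1) / fs)
  frac <- (level - z0) / (z1 - z0)
  frac <- min(1, max(0, frac))
  (k - 1 + frac) / fs
}

# Flight time from the toe arc: interpolate the crossings of the lift-off
# threshold (where the crossing is transversal), then apply the exact
# ballistic chord relation t_flight^2 = dt_chord^2 + 8 L / g, with L the
# threshold height above the toe baseline. Also returns the refined
# take-off and touchdown instants (s, 0-based).
.flight_time_ballistic <- function(toe_z, f, h, tau, toe_baseline, fs, g) {
  k_up <- max(1, f - 1)                 # last contact sample before flight
  while (k_up < h && toe_z[k_up + 1] <= tau) k_up <- k_up + 1
  k_dn <- min(length(toe_z), h + 1)     # first contact sample after flight
  while (k_dn > f && toe_z[k_dn - 1] <= tau) k_dn <- k_dn - 1
  t_up <- .cross_time(toe_z, tau, k_up, fs)
  t_dn <- .cross_time(toe_z, tau, k_dn - 1, fs)
  chord <- t_dn - t_up
  L <- max(0, tau - toe_baseline)
  t_flight <- sqrt(chord^2 + 8 * L / g)
  t_mid <- (t_up + t_dn) / 2
  list(t_flight = t_flight,
       t_off = t_mid - t_flight / 2,
       t_on = t_mid + t_flight / 2)
}

#' Extract the 21 per-trial countermovement-jump variables
#'
#' Phase durations are event-index differences divided by the sampling rate
#' (unweighting a-c, braking c-d, eccentric a-d, propulsive d-f, take-off
#' a-f, landing eccentric h-i); the flight time is refined by sub-sample
#' interpolation of the toe crossings of the lift-off threshold followed by
#' the exact ballistic chord correction
#' `t_flight = sqrt(dt_chord^2 + 8 L / g)`, so the flight-time jump-height
#' estimator is free of the 1-sample discretisation of the integer event
#' indices. The take-off velocity is likewise the velocity series linearly
#' interpolated at the refined take-off instant (Vz is linear in time
#' through lift-off under free flight), not the sample value at index `f`,
#' which would overestimate by up to `g / sampling_rate`. Displacements are
#' relative to the quiet-stance CoM baseline; max/min vertical velocity are
#' taken over the ground-contact push-off interval `[a, f]`; push-off joint
#' angles are sampled at `d` and landing angles at `i`.
#'
#' @param events A [detect_events()] result.
#' @param com The [com_trajectory()] the events were detected on.
#' @param toe_z Toe vertical series (m).
#' @param angles Named list with elements `ankle`, `knee`, `hip`, each a
#'   [joint_angle()] result.
#' @param g Gravitational acceleration (default 9.81 m/s^2).
#' @return An object of class `cmj_variables`: a named list of the 21
#'   variables.
#' @export
compute_variables <- function(events, com, toe_z, angles, g = CMJ_GRAVITY) {
  stopifnot(inherits(events, "jump_events"), inherits(com, "com_trajectory"))
  need <- c("ankle", "knee", "hip")
  miss <- setdiff(need, names(angles))
  if (length(miss))
    stop("missing joint angle series: ", paste(miss, collapse = ", "),
         call. = FALSE)
  fs <- com$sampling_rate_hz
  z <- com$com_z_m
  vz <- com$vz_mps
  ev <- events

  dur <- function(from, to) (ev[[to]] - ev[[from]]) / fs
  v <- list(
    unweighting_phase_s = dur("a", "c"),
    braking_phase_s     = dur("c", "d"),
    eccentric_phase_s   = dur("a", "d"),
    propulsive_phase_s  = dur("d", "f"),
    takeoff_phase_s     = dur("a", "f"),
    ld_eccentric_phase_s = dur("h", "i")
  )

  fl <- .flight_time_ballistic(
    toe_z, ev$f, ev$h, ev$liftoff_threshold_m, ev$toe_baseline_z_m, fs, g)
  v$flight_time_s <- fl$t_flight

  bl <- ev$baseline_z_m
  v$jump_height_m <- z[ev$g] - bl
  v$countermovement_depth_m <- bl - z[ev$d]
  v$ld_depth_m <- bl - z[ev$i]

  push <- ev$a:ev$f
  v$max_com_vz_mps <- max(vz[push])
  # Vz at the refined take-off instant (linear interpolation of the velocity
  # series, which is linear in time through lift-off under free flight)
  tgrid <- (seq_along(vz) - 1) / fs
  v$takeoff_com_vz_mps <- stats::approx(tgrid, vz, xout = fl$t_off,
                                        rule = 2)$y
  v$min_com_vz_mps <- min(vz[push])

  v$ankle_angle_deg <- angles$ankle$angle_deg[ev$d]
  v$knee_angle_deg <- angles$knee$angle_deg[ev$d]
  v$hip_angle_deg <- angles$hip$angle_deg[ev$d]
  v$ld_ankle_angle_deg <- angles$ankle$angle_deg[ev$i]
  v$ld_knee_angle_deg <- angles$knee$angle_deg[ev$i]
  v$ld_hip_angle_deg <- angles$hip$angle_deg[ev$i]

  v$jump_height_flight_m <- jump_height_from_flight_time(v$flight_time_s, g)
  v$jump_height_takeoff_v_m <- jump_height_from_velocity(v$takeoff_com_vz_mps, g)
  v$jump_height_max_v_m <- jump_height_from_velocity(v$max_com_vz_mps, g)

  durs <- unlist(v[grep("_phase_s$|flight_time_s", names(v))])
  if (any(durs <= 0))
    stop("invariant violation: non-positive duration(s): ",
         paste(names(durs)[durs <= 0], collapse = ", "), call. = FALSE)
  if (v$countermovement_depth_m <= 0)
    stop("invariant violation: non-positive countermovement depth",
         call. = FALSE)
  if (!(v$min_com_vz_mps < 0 && v$max_com_vz_mps > 0))
    stop("invariant violation: push-off velocity range does not straddle 0",
         call. = FALSE)
  structure(v, class = "cmj_variables")
}

#' @export
print.cmj_variables <- function(x, ...) {
  cat("<cmj_variables>\n")
  nm <- names(x)
  for (k in nm)
    cat(sprintf("  %-26s %9.4f\n", k, x[[k]]))
  invisible(x)
}

#' One-row data frame of per-trial variables
#'
#' @param x A `cmj_variables` object.
#' @param trial_id,side,source_label Key columns prepended to the row.
#' @param ... Unused.
#' @return A one-row `data.frame` mirroring a per-trial report row.
#' @export
as.data.frame.cmj_variables <- function(x, trial_id = NA, side = NA,
                                        source_label = NA, ...) {
  cbind(data.frame(trial_id = trial_id, side = side,
                   source_label = source_label,
                   stringsAsFactors = FALSE),
        as.data.frame(unclass(x)))
}
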