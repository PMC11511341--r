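#' Specification of a synthetic countermovement jump
#'
#' Parameters of the generator. Defaults match the magnitudes reported for
#' adult jumpers in marker-based CMJ testing (unweighting ~0.24 s, braking
#' ~0.18 s, countermovement depth ~0.30 m, take-off velocity ~2.3 m/s).
#'
#' @param sampling_rate_hz Sampling rate (default 100 Hz).
#' @param stance_s Initial quiet-stance duration (default 1.0 s).
#' @param unweighting_s Movement start to peak downward velocity (point c;
#'   default 0.24 s).
#' @param braking_s Peak downward velocity to the lowest CoM position
#'   (point d; default 0.18 s).
#' @param propulsive_s Lowest position to take-off (default 0.22 s). Must
#'   exceed `depth_m / takeoff_velocity_mps` (the take-off posture equals
#'   the stance posture, so the propulsive displacement equals the depth).
#' @param depth_m Countermovement depth (default 0.30 m).
#' @param takeoff_velocity_mps Vertical CoM velocity at take-off (default
#'   2.3 m/s); flight time is `2 v / g` and jump height `v^2 / (2 g)`.
#' @param landing_depth_m Depth of the landing squat (default 0.25 m).
#' @param stature_m Body height used to scale the segment geometry
#'   (default 1.79 m).
#' @param noise_sd_m SD of i.i.d. Gaussian measurement noise added to each
#'   landmark's vertical coordinate (default 0).
#' @param bias_m Constant vertical bias added to each landmark (default 0).
#' @param seed Integer RNG seed for the noise (default `NULL`).
#' @param g Gravitational acceleration (default 9.81 m/s^2).
#' @return A list of class `cmj_sim_spec`.
#' @export
cmj_sim_spec <- function(sampling_rate_hz = 100, stance_s = 1.0,
                         unweighting_s = 0.24, braking_s = 0.18,
                         propulsive_s = 0.22, depth_m = 0.30,
                         takeoff_velocity_mps = 2.3, landing_depth_m = 0.25,
                         stature_m = 1.79, noise_sd_m = 0, bias_m = 0,
                         seed = NULL, g = CMJ_GRAVITY) {
  spec <- list(sampling_rate_hz = sampling_rate_hz, stance_s = stance_s,
               unweighting_s = unweighting_s, braking_s = braking_s,
               propulsive_s = propulsive_s, depth_m = depth_m,
               takeoff_velocity_mps = takeoff_velocity_mps,
               landing_depth_m = landing_depth_m, stature_m = stature_m,
               noise_sd_m = noise_sd_m, bias_m = bias_m, seed = seed, g = g)
  pos <- c("sampling_rate_hz", "stance_s", "unweighting_s", "braking_s",
           "propulsive_s", "depth_m", "takeoff_velocity_mps",
           "landing_depth_m", "stature_m", "g")
  for (k in pos)
    if (!is.numeric(spec[[k]]) || spec[[k]] <= 0)
      stop("`", k, "` must be positive", call. = FALSE)
  if (noise_sd_m < 0) stop("`noise_sd_m` must be >= 0", call. = FALSE)
  if (depth_m >= takeoff_velocity_mps * propulsive_s)
    stop("infeasible spec: need propulsive_s > depth_m / takeoff_velocity",
         call. = FALSE)
  class(spec) <- "cmj_sim_spec"
  spec
}

# --- planar body geometry --------------------------------------------------
# Rigid 4-segment stack over a fixed flat foot, articulated by a single
# crouch parameter q (shank forward-lean, rad): knee and shoulder rotate
# forward by q, hip rotates backward by 1.4 q, keeping the squat balanced.
.body_geometry <- function(stature_m) {
  H <- stature_m
  list(
    heel = c(-0.05, 0.030), big_toe = c(0.19, 0.020),
    small_toe = c(0.17, 0.025), ankle0 = c(0.00, 0.039 * H),
    Ls = 0.246 * H, Lt = 0.245 * H, Ltr = 0.288 * H,
    ct = 1.4, cs = 1.0, q0 = 0.10, qmax = 1.35
  )
}

# landmark points (one side) for crouch q; rows x, z
.posture_points <- function(q, geom) {
  ankle <- geom$ankle0
  knee <- ankle + geom$Ls * c(sin(q), cos(q))
  hip <- knee + geom$Lt * c(-sin(geom$ct * q), cos(geom$ct * q))
  shoulder <- hip + geom$Ltr * c(sin(geom$cs * q), cos(geom$cs * q))
  list(shoulder = shoulder, hip = hip, knee = knee, ankle = ankle,
       heel = geom$heel, small_toe = geom$small_toe, big_toe = geom$big_toe)
}

.dempster_z <- function(pts, model = segment_model()) {
  w <- model$weights; f <- model$com_fractions
  segz <- c(
    foot = pts$heel[2] + f[["foot"]] * (pts$big_toe[2] - pts$heel[2]),
    lower_leg = pts$ankle[2] + f[["lower_leg"]] * (pts$knee[2] - pts$ankle[2]),
    upper_leg = pts$knee[2] + f[["upper_leg"]] * (pts$hip[2] - pts$knee[2]),
    upper_body = pts$hip[2] + f[["upper_body"]] *
      (pts$shoulder[2] - pts$hip[2]))
  sum(w * segz) / sum(w)
}

.interior_angle <- function(P, M, D) {
  u <- P - M; v <- D - M
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

.posture_angles <- function(q, geom) {
  p <- .posture_points(q, geom)
  c(ankle = .interior_angle(p$knee, p$ankle, p$big_toe),
    knee = .interior_angle(p$hip, p$knee, p$ankle),
    hip = .interior_angle(p$shoulder, p$hip, p$knee))
}

# invert .dempster_z over q
.solve_q <- function(target_z, geom, model, lower = 0) {
  stats::uniroot(function(q) .dempster_z(.posture_points(q, geom), model) -
                   target_z,
                 interval = c(lower, geom$qmax), tol = 1e-13)$root
}

# time-warp exponent p of the propulsive velocity profile
# v(s) = v_to (1 - cos(pi s^p)) / 2 so that the propulsive displacement
# fraction  integral_0^1 (1 - cos(pi s^p))/2 ds  equals `area`
.propulsion_shape <- function(area) {
  f <- function(p)
    stats::integrate(function(s) (1 - cos(pi * s^p)) / 2, 0, 1,
                     rel.tol = 1e-12)$value - area
  stats::uniroot(f, interval = c(0.02, 50), tol = 1e-12)$root
}

.prop_disp <- function(s, p) {
  # displacement fraction of v_to over [0, s] of the warped profile
  vapply(s, function(si) {
    if (si <= 0) return(0)
    stats::integrate(function(u) (1 - cos(pi * u^p)) / 2, 0, si,
                     rel.tol = 1e-12)$value
  }, numeric(1))
}

#' Simulate a countermovement-jump landmark trajectory
#'
#' Builds a C1 (continuous position and velocity) whole-body CoM profile —
#' quiet stance, cosine-eased unweighting and braking of total displacement
#' `depth_m` with the velocity minimum at the phase boundary (point c) and
#' zero velocity at the bottom (point d), a time-warped cosine propulsion
#' reaching `takeoff_velocity_mps` exactly at lift-off with displacement
#' equal to the depth (take-off posture = stance posture) and ending in a
#' short ballistic taper so the velocity peaks just before lift-off and
#' acceleration is already `-g` at take-off, exact ballistic
#' flight of duration `2 v / g`, a cosine-eased landing to
#' `landing_depth_m`, and a half-sine recovery — then back-generates the
#' 14-landmark set by inverting a hinged-squat posture model so that the
#' Dempster whole-body CoM of the landmarks reproduces the target CoM
#' within ~1e-12 m. Measurement error (per-landmark vertical Gaussian noise
#' plus a constant bias) is added last, seeded.
#'
#' @param spec A [cmj_sim_spec()].
#' @return A list of class `cmj_sim`: `trajectories` (a [landmark_set()],
#'   both sides identical) and `truth` (ground-truth event times in
#'   seconds, `events_s`; the implied variable values, `variables`;
#'   `baseline_z_m`, `toe_baseline_z_m`, `com_z_m`, `vz_mps`).
#' @export
simulate_cmj <- function(spec = cmj_sim_spec()) {
  stopifnot(inherits(spec, "cmj_sim_spec"))
  g <- spec$g
  fs <- spec$sampling_rate_hz
  geom <- .body_geometry(spec$stature_m)
  model <- segment_model()

  Tu <- spec$unweighting_s; Tb <- spec$braking_s; Tp <- spec$propulsive_s
  depth <- spec$depth_m; vto <- spec$takeoff_velocity_mps
  ld <- spec$landing_depth_m
  Tf <- 2 * vto / g
  Tl <- 2 * ld / vto
  Tr <- 0.4
  vr <- pi * (0.9 * ld) / (2 * Tr)  # half-sine recovery peak velocity
  tail_s <- 0.3

  # The squat bottom (point d) is crossed with acceleration a_d (~1 g, as
  # the ground-reaction force peaks there), continuous from the braking to
  # the propulsive side, so the position minimum is locally quadratic and
  # sharply localisable. a_d is capped to keep the braking velocity
  # monotone (no dip below the commanded velocity minimum).
  a_d <- g
  vmin <- 2 * (depth - a_d * Tb^2 / 12) / (Tu + Tb)
  if (vmin <= 0)
    stop("infeasible spec: depth too small for the braking profile",
         call. = FALSE)
  if (a_d > 2.4 * vmin / Tb) {
    a_d <- 2.4 * vmin / Tb
    vmin <- 2 * (depth - a_d * Tb^2 / 12) / (Tu + Tb)
  }

  # Propulsion = warped-cosine rise to the take-off velocity, then a
  # symmetric quadratic velocity peak of half-width B (curvature g / B)
  # whose descending branch reaches slope -g exactly at lift-off, so the
  # velocity maximum (point e) precedes take-off, is symmetric (detectable
  # to a sample), and acceleration is continuous into free flight.
  B <- min(0.03, 0.2 * depth / vto)   # peak half-width (s)
  T1 <- Tp - 2 * B                    # rise duration
  if (T1 <= 0)
    stop("infeasible spec: propulsive_s too short for the velocity peak",
         call. = FALSE)
  K <- g / B
  vpeak <- vto + g * B / 2
  area_peak <- 2 * B * vto + 2 / 3 * g * B^2
  area_frac <- (depth - area_peak - a_d * T1^2 / 12) / (vto * T1)
  if (!is.finite(area_frac) || area_frac <= 0.05 || area_frac >= 0.95)
    stop("infeasible spec: propulsive displacement fraction ",
         signif(area_frac, 3), " outside (0.05, 0.95); adjust ",
         "propulsive_s, depth_m or takeoff_velocity_mps", call. = FALSE)
  p <- .propulsion_shape(area_frac)

  t_a0 <- spec$stance_s            # movement start (motion, not onset event)
  t_c <- t_a0 + Tu
  t_d <- t_c + Tb
  t_e <- t_d + T1 + B              # velocity peak
  t_f <- t_d + Tp
  t_h <- t_f + Tf
  t_i <- t_h + Tl
  t_end <- t_i + Tr + tail_s

  disp <- function(t) {           # CoM z displacement relative to baseline
    vapply(t, function(ti) {
      if (ti <= t_a0) 0
      else if (ti <= t_c) {
        s <- (ti - t_a0) / Tu
        -vmin * Tu * (s - sin(pi * s) / pi) / 2
      } else if (ti <= t_d) {
        s <- (ti - t_c) / Tb
        -vmin * Tu / 2 + Tb * (-vmin * (s^4 / 2 - s^3 + s) +
                                 a_d * Tb * (s^4 / 4 - s^3 / 3))
      } else if (ti <= t_d + T1) {
        s <- (ti - t_d) / T1
        -depth + a_d * T1^2 * (s^4 / 4 - 2 * s^3 / 3 + s^2 / 2) +
          vto * T1 * .prop_disp(s, p)
      } else if (ti <= t_f) {
        u <- ti - t_d - T1
        -area_peak + vpeak * u - (K / 6) * ((u - B)^3 + B^3)
      } else if (ti <= t_h) {
        tau <- ti - t_f
        vto * tau - g * tau^2 / 2
      } else if (ti <= t_i) {
        s <- (ti - t_h) / Tl
        -vto * Tl * (s + sin(pi * s) / pi) / 2
      } else if (ti <= t_i + Tr) {
        s <- (ti - t_i) / Tr
        -ld + vr * Tr * (1 - cos(pi * s)) / pi
      } else -ld + 2 * vr * Tr / pi
    }, numeric(1))
  }
  vel <- function(t) {
    vapply(t, function(ti) {
      if (ti <= t_a0) 0
      else if (ti <= t_c) -vmin * (1 - cos(pi * (ti - t_a0) / Tu)) / 2
      else if (ti <= t_d) {
        s <- (ti - t_c) / Tb
        -vmin * (2 * s^3 - 3 * s^2 + 1) + a_d * Tb * (s^3 - s^2)
      } else if (ti <= t_d + T1) {
        s <- (ti - t_d) / T1
        a_d * T1 * s * (1 - s)^2 + vto * (1 - cos(pi * s^p)) / 2
      }
      else if (ti <= t_f) vpeak - K * (ti - t_e)^2 / 2
      else if (ti <= t_h) vto - g * (ti - t_f)
      else if (ti <= t_i) -vto * (1 + cos(pi * (ti - t_h) / Tl)) / 2
      else if (ti <= t_i + Tr) vr * sin(pi * (ti - t_i) / Tr)
      else 0
    }, numeric(1))
  }

  z0 <- .dempster_z(.posture_points(geom$q0, geom), model)
  reach <- z0 - .dempster_z(.posture_points(geom$qmax, geom), model)
  if (max(depth, ld) >= reach)
    stop("infeasible spec: requested depth exceeds the posture model's ",
         "squat range (", signif(reach, 3), " m)", call. = FALSE)

  n <- floor(t_end * fs + 1e-9) + 1
  tgrid <- (seq_len(n) - 1) / fs
  dz <- disp(tgrid)
  target <- z0 + dz
  in_flight <- tgrid > t_f & tgrid < t_h

  ids7 <- .landmark_names
  series <- matrix(NA_real_, nrow = n, ncol = 14,
                   dimnames = list(NULL, c(paste0(ids7, "_x"),
                                           paste0(ids7, "_z"))))
  stance_pts <- .posture_points(geom$q0, geom)
  for (k in seq_len(n)) {
    if (in_flight[k]) {
      pts <- stance_pts
      pts <- lapply(pts, function(pp) pp + c(0, dz[k]))
    } else if (dz[k] >= -1e-12) {
      pts <- if (abs(dz[k]) < 1e-12) stance_pts else {
        q <- .solve_q(target[k], geom, model, lower = 0)
        .posture_points(q, geom)
      }
    } else {
      q <- .solve_q(target[k], geom, model, lower = 0)
      pts <- .posture_points(q, geom)
    }
    series[k, ] <- c(vapply(pts[ids7], `[`, numeric(1), 1),
                     vapply(pts[ids7], `[`, numeric(1), 2))
  }

  landmarks <- list()
  for (s in .sides) for (nm in ids7)
    landmarks[[paste(s, nm, sep = "_")]] <-
      cbind(x = series[, paste0(nm, "_x")], z = series[, paste0(nm, "_z")])

  if (spec$noise_sd_m > 0 || spec$bias_m != 0) {
    if (!is.null(spec$seed)) {
      runif(1)  # ensure .Random.seed exists
      old <- .Random.seed
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
      set.seed(spec$seed)
    }
    for (nm in names(landmarks))
      landmarks[[nm]][, "z"] <- landmarks[[nm]][, "z"] + spec$bias_m +
        stats::rnorm(n, 0, spec$noise_sd_m)
  }

  tset <- landmark_set(landmarks, sampling_rate_hz = fs,
                       source_label = "synthetic", side = "both")

  # analytic ground truth -----------------------------------------------
  thr <- 0.05 * vpeak                     # onset: 5% of max upward velocity
  if (thr >= vmin)
    stop("infeasible spec: onset threshold exceeds the downward velocity ",
         "peak", call. = FALSE)
  s_a <- acos(1 - 2 * thr / vmin) / pi
  t_a <- t_a0 + s_a * Tu
  t_g <- t_f + Tf / 2

  q_d <- .solve_q(z0 - depth, geom, model)
  q_i <- .solve_q(z0 - ld, geom, model)
  ang_d <- .posture_angles(q_d, geom)
  ang_i <- .posture_angles(q_i, geom)
  h_jump <- vto^2 / (2 * g)

  truth <- list(
    events_s = c(a = t_a, c = t_c, d = t_d, e = t_e, f = t_f,
                 g = t_g, h = t_h, i = t_i),
    variables = list(
      unweighting_phase_s = t_c - t_a,
      braking_phase_s = Tb,
      eccentric_phase_s = t_d - t_a,
      propulsive_phase_s = Tp,
      takeoff_phase_s = t_f - t_a,
      ld_eccentric_phase_s = Tl,
      flight_time_s = Tf,
      jump_height_m = h_jump,
      countermovement_depth_m = depth,
      ld_depth_m = ld,
      max_com_vz_mps = vpeak,
      takeoff_com_vz_mps = vto,
      min_com_vz_mps = -vmin,
      ankle_angle_deg = ang_d[["ankle"]],
      knee_angle_deg = ang_d[["knee"]],
      hip_angle_deg = ang_d[["hip"]],
      ld_ankle_angle_deg = ang_i[["ankle"]],
      ld_knee_angle_deg = ang_i[["knee"]],
      ld_hip_angle_deg = ang_i[["hip"]],
      jump_height_flight_m = h_jump,
      jump_height_takeoff_v_m = h_jump,
      jump_height_max_v_m = vpeak^2 / (2 * g)),
    baseline_z_m = z0,
    toe_baseline_z_m = geom$big_toe[2],
    com_z_m = target,
    vz_mps = vel(tgrid)
  )
  structure(list(trajectories = tset, truth = truth, spec = spec),
            class = "cmj_sim")
}

#' @export
print.cmj_sim <- function(x, ...) {
  cat("<cmj_sim> synthetic countermovement jump\n")
  print(x$trajectories)
  ev <- x$truth$events_s
  cat("  ground-truth events (s): ",
      paste(sprintf("%s=%.3f", names(ev), ev), collapse = ", "), "\n")
  invisible(x)
}

#' Degrade a landmark set with a two-method measurement-error model
#'
#' Returns a copy with a constant vertical bias plus i.i.d. Gaussian noise
#' added to the z coordinate of the selected landmarks (x untouched),
#' emulating the systematic and random discrepancy between a reference and
#' a comparison capture method.
#'
#' @param tset A [landmark_set()].
#' @param bias_m Constant vertical offset (m).
#' @param noise_sd_m Noise SD (m, >= 0).
#' @param seed Integer RNG seed (optional).
#' @param landmarks Character vector of landmark ids to degrade (default:
#'   all).
#' @param source_label New provenance label (default `"degraded"`).
#' @return A [landmark_set()].
#' @export
degrade <- function(tset, bias_m = 0, noise_sd_m = 0, seed = NULL,
                    landmarks = NULL, source_label = "degraded") {
  stopifnot(inherits(tset, "landmark_set"))
  if (noise_sd_m < 0) stop("`noise_sd_m` must be >= 0", call. = FALSE)
  which_lm <- if (is.null(landmarks)) names(tset$landmarks) else landmarks
  miss <- setdiff(which_lm, names(tset$landmarks))
  if (length(miss)) stop("unknown landmark(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!is.null(seed)) {
    runif(1)
    old <- .Random.seed
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  n <- n_samples(tset)
  for (nm in which_lm) {
    eps <- if (noise_sd_m > 0) stats::rnorm(n, 0, noise_sd_m) else 0
    tset$landmarks[[nm]][, "z"] <- tset$landmarks[[nm]][, "z"] + bias_m + eps
  }
  tset$source_label <- source_label
  tset
}
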