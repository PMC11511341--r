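#' Four-segment Dempster body model
#'
#' Mass fractions and along-segment CoM locations for the planar four-segment
#' model: foot 1.5%, lower leg 4.65%, upper leg 10%, upper body 43% of body
#' mass. The fractions sum to 0.5915 and the whole-body CoM renormalises by
#' that sum rather than forcing the weights to 1. Segment CoM locations: foot
#' at the heel--big-toe midpoint; lower leg at 43.3% of the ankle-to-knee
#' length from the ankle; upper leg at 43.3% of the knee-to-hip length from
#' the knee; upper body at the hip--shoulder midpoint.
#'
#' @param weights Named numeric mass fractions per segment.
#' @param com_fractions Named numeric along-segment CoM fractions in `[0, 1]`.
#' @return An object of class `segment_model`.
#' @export
#' @examples
#' m <- segment_model()
#' sum(m$weights)  # 0.5915
segment_model <- function(weights = c(foot = 0.015, lower_leg = 0.0465,
                                      upper_leg = 0.10, upper_body = 0.43),
                          com_fractions = c(foot = 0.5, lower_leg = 0.433,
                                            upper_leg = 0.433,
                                            upper_body = 0.5)) {
  segs <- c("foot", "lower_leg", "upper_leg", "upper_body")
  stopifnot(all(segs %in% names(weights)),
            all(segs %in% names(com_fractions)))
  if (any(weights[segs] <= 0)) stop("all weights must be > 0", call. = FALSE)
  if (any(com_fractions[segs] < 0 | com_fractions[segs] > 1))
    stop("com_fractions must lie in [0, 1]", call. = FALSE)
  structure(list(weights = weights[segs], com_fractions = com_fractions[segs]),
            class = "segment_model")
}

# (proximal-reference A, distal-reference B): segment CoM = A + f * (B - A)
.segment_endpoints <- list(
  foot       = c("heel", "big_toe"),
  lower_leg  = c("ankle", "knee"),
  upper_leg  = c("knee", "hip"),
  upper_body = c("hip", "shoulder")
)

#' Per-sample CoM of one body segment
#'
#' The segment CoM is `A + f * (B - A)` where `f` is the segment's
#' along-segment fraction and `(A, B)` the segment's reference landmark pair
#' (foot: heel to big toe; lower leg: ankle to knee; upper leg: knee to hip;
#' upper body: hip to shoulder).
#'
#' @param tset A [landmark_set()].
#' @param segment One of `"foot"`, `"lower_leg"`, `"upper_leg"`,
#'   `"upper_body"`.
#' @param side `"left"` or `"right"`.
#' @param model A [segment_model()].
#' @return An `n x 2` matrix with columns `x`, `z` (meters).
#' @export
segment_com <- function(tset, segment, side = c("left", "right"),
                        model = segment_model()) {
  stopifnot(inherits(tset, "landmark_set"))
  side <- match.arg(side)
  segment <- match.arg(segment, names(.segment_endpoints))
  ends <- paste(side, .segment_endpoints[[segment]], sep = "_")
  miss <- setdiff(ends, names(tset$landmarks))
  if (length(miss))
    stop("missing landmark(s) for segment ", segment, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  A <- tset$landmarks[[ends[1]]]
  B <- tset$landmarks[[ends[2]]]
  f <- model$com_fractions[[segment]]
  out <- A + f * (B - A)
  colnames(out) <- c("x", "z")
  out
}

#' Whole-body centre of mass (Dempster model)
#'
#' Per sample, the weighted mean of the four segment CoMs with weights
#' divided by their sum (0.5915), applied identically to X and Z. The
#' vertical velocity series is obtained by central differences
#' ([vertical_velocity()]).
#'
#' @inheritParams segment_com
#' @return An object of class `com_trajectory` with fields `com_x_m`,
#'   `com_z_m`, `segment_com` (list of `n x 2` matrices), `vz_mps`,
#'   `sampling_rate_hz`.
#' @export
#' @examples
#' # four segment CoMs at z = 1 give ZCoM = 1 (weighted mean of equal values)
body_com <- function(tset, side = c("left", "right"),
                     model = segment_model()) {
  stopifnot(inherits(tset, "landmark_set"))
  side <- match.arg(side)
  segs <- names(.segment_endpoints)
  scoms <- lapply(segs, function(s) segment_com(tset, s, side, model))
  names(scoms) <- segs
  w <- model$weights[segs]
  wsum <- sum(w)
  acc <- matrix(0, nrow = nrow(scoms[[1]]), ncol = 2)
  for (s in segs) acc <- acc + w[[s]] * scoms[[s]]
  acc <- acc / wsum
  com_trajectory(com_x_m = acc[, 1], com_z_m = acc[, 2],
                 sampling_rate_hz = tset$sampling_rate_hz,
                 segment_com = scoms)
}

#' Construct a CoM trajectory
#'
#' @param com_x_m,com_z_m CoM coordinate series (meters).
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param segment_com Optional list of per-segment `n x 2` CoM matrices.
#' @param vz_mps Optional vertical velocity series; computed by
#'   [vertical_velocity()] when omitted.
#' @return An object of class `com_trajectory`.
#' @export
com_trajectory <- function(com_x_m, com_z_m, sampling_rate_hz,
                           segment_com = NULL, vz_mps = NULL) {
  stopifnot(length(com_x_m) == length(com_z_m))
  if (is.null(vz_mps)) vz_mps <- vertical_velocity(com_z_m, sampling_rate_hz)
  stopifnot(length(vz_mps) == length(com_z_m))
  structure(list(com_x_m = as.numeric(com_x_m),
                 com_z_m = as.numeric(com_z_m),
                 segment_com = segment_com,
                 vz_mps = as.numeric(vz_mps),
                 sampling_rate_hz = as.numeric(sampling_rate_hz)),
            class = "com_trajectory")
}

#' @export
print.com_trajectory <- function(x, ...) {
  cat(sprintf("<com_trajectory> %d samples @ %g Hz, z range [%.3f, %.3f] m\n",
              length(x$com_z_m), x$sampling_rate_hz,
              min(x$com_z_m), max(x$com_z_m)))
  invisible(x)
}

#' Centred moving-average smoother
#'
#' Centred moving mean with the window truncated at the series edges (the
#' mean is taken over the available samples within the half-window). Output
#' length equals input length; a one-sample window is the identity.
#'
#' @param series Numeric vector.
#' @param window Window length in samples (odd lengths are symmetric; even
#'   lengths use half-width `floor(window / 2)`).
#' @return Smoothed series.
#' @export
moving_average <- function(series, window) {
  if (!is.numeric(window) || window < 1)
    stop("window must span >= 1 sample", call. = FALSE)
  x <- as.numeric(series)
  n <- length(x)
  k <- floor(window / 2)
  if (k == 0) return(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - k, 1)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Moving-average smoother with window in seconds
#'
#' @inheritParams moving_average
#' @param window_s Window length in seconds.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @return Smoothed series.
#' @export
moving_average_s <- function(series, window_s, sampling_rate_hz) {
  if (window_s <= 0) return(as.numeric(series))
  moving_average(series, max(1, round(window_s * sampling_rate_hz)))
}

#' Zero-phase exponential moving-average filter
#'
#' A first-order exponential moving average applied forward, then backward,
#' and averaged, so that smoothing introduces no net phase lag. `alpha = 1`
#' is the identity; smaller `alpha` smooths more.
#'
#' @param series Numeric vector (non-empty).
#' @param alpha Smoothing coefficient in `(0, 1]`.
#' @return Filtered series of equal length.
#' @export
ema_filter <- function(series, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]", call. = FALSE)
  x <- as.numeric(series)
  if (!length(x)) stop("empty series", call. = FALSE)
  ema1 <- function(v) {
    out <- v
    for (i in seq_along(v)[-1]) out[i] <- alpha * v[i] + (1 - alpha) * out[i - 1]
    out
  }
  (ema1(x) + rev(ema1(rev(x)))) / 2
}

#' Vertical velocity by finite differences
#'
#' Central differences in the interior, one-sided differences at the two
#' edges; exact for linear signals everywhere and for quadratics in the
#' interior.
#'
#' @param com_z Vertical position series (m), length >= 3.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @return Velocity series (m/s) of equal length.
#' @export
vertical_velocity <- function(com_z, sampling_rate_hz) {
  z <- as.numeric(com_z)
  n <- length(z)
  if (n < 3) stop("series must have length >= 3", call. = FALSE)
  dt <- 1 / sampling_rate_hz
  v <- numeric(n)
  v[1] <- (z[2] - z[1]) / dt
  v[n] <- (z[n] - z[n - 1]) / dt
  v[2:(n - 1)] <- (z[3:n] - z[1:(n - 2)]) / (2 * dt)
  v
}

.joint_landmarks <- list(
  hip   = c("shoulder", "hip", "knee"),
  knee  = c("hip", "knee", "ankle"),
  ankle = c("knee", "ankle", "big_toe")
)

#' Interior joint angle series
#'
#' Per-sample interior angle (degrees) at the middle landmark between the two
#' rays to the flanking landmarks, via the arc-cosine of the normalised dot
#' product (clipped to `[-1, 1]`). 180 degrees is a fully extended joint.
#' Joint definitions: hip = shoulder--hip--knee, knee = hip--knee--ankle,
#' ankle = knee--ankle--big-toe.
#'
#' @param tset A [landmark_set()].
#' @param joint `"ankle"`, `"knee"`, or `"hip"`.
#' @param side `"left"` or `"right"`.
#' @return An object of class `joint_angle_series` with fields `joint`,
#'   `side`, `angle_deg`.
#' @export
joint_angle <- function(tset, joint = c("ankle", "knee", "hip"),
                        side = c("left", "right")) {
  stopifnot(inherits(tset, "landmark_set"))
  joint <- match.arg(joint)
  side <- match.arg(side)
  ids <- paste(side, .joint_landmarks[[joint]], sep = "_")
  miss <- setdiff(ids, names(tset$landmarks))
  if (length(miss))
    stop("missing landmark(s) for ", joint, " angle: ",
         paste(miss, collapse = ", "), call. = FALSE)
  P <- tset$landmarks[[ids[1]]]
  M <- tset$landmarks[[ids[2]]]
  D <- tset$landmarks[[ids[3]]]
  u <- P - M
  v <- D - M
  nu <- sqrt(rowSums(u^2))
  nv <- sqrt(rowSums(v^2))
  bad <- which(nu == 0 | nv == 0)
  if (length(bad))
    stop("zero-length ray at sample(s) ", paste(utils::head(bad, 5),
         collapse = ", "), call. = FALSE)
  cosang <- pmin(1, pmax(-1, rowSums(u * v) / (nu * nv)))
  structure(list(joint = joint, side = side,
                 angle_deg = acos(cosang) * 180 / pi),
            class = "joint_angle_series")
}

#' @export
print.joint_angle_series <- function(x, ...) {
  cat(sprintf("<joint_angle_series> %s %s: %d samples, range [%.1f, %.1f] deg\n",
              x$side, x$joint, length(x$angle_deg),
              min(x$angle_deg), max(x$angle_deg)))
  invisible(x)
}
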