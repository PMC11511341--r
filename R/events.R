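#' Event-detection configuration
#'
#' @param onset_fraction Movement onset threshold as a fraction of the
#'   reference velocity (default 0.05).
#' @param onset_reference Reference for the onset threshold: `"max_up"`
#'   (maximum upward CoM velocity; default) or `"max_down"` (peak downward
#'   speed).
#' @param min_height_m Floor of the toe lift-off threshold above the toe
#'   baseline (default 0.01 m).
#' @param stance_window_s Initial quiet-stance window used for baselines and
#'   the toe noise estimate (default 0.5 s).
#' @return A named list of class `cmj_detection_config`.
#' @export
cmj_config <- function(onset_fraction = 0.05,
                       onset_reference = c("max_up", "max_down"),
                       min_height_m = 0.01,
                       stance_window_s = 0.5) {
  onset_reference <- match.arg(onset_reference)
  stopifnot(onset_fraction > 0, onset_fraction < 1,
            min_height_m >= 0, stance_window_s > 0)
  structure(list(onset_fraction = onset_fraction,
                 onset_reference = onset_reference,
                 min_height_m = min_height_m,
                 stance_window_s = stance_window_s),
            class = "cmj_detection_config")
}

#' Quiet-stance baselines
#'
#' Means of the CoM and toe vertical series over the initial stance window,
#' plus the standard deviation of the toe series over that window (used as a
#' noise estimate by the lift-off detector).
#'
#' @param com_z,toe_z Vertical series (m).
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param stance_window_s Window length in seconds.
#' @return List with `baseline_z`, `toe_baseline_z`, `noise_sd`.
#' @export
quiet_stance_baseline <- function(com_z, toe_z, sampling_rate_hz,
                                  stance_window_s = 0.5) {
  n <- length(com_z)
  stopifnot(length(toe_z) == n)
  w <- round(stance_window_s * sampling_rate_hz)
  if (w < 1 || w > n)
    stop("stance window longer than the series", call. = FALSE)
  idx <- seq_len(w)
  list(baseline_z = mean(com_z[idx]),
       toe_baseline_z = mean(toe_z[idx]),
       noise_sd = stats::sd(toe_z[idx]))
}

#' Toe lift-off and touchdown
#'
#' Thresholds the toe vertical trace at
#' `toe_baseline + max(min_height_m, 5 * noise_sd)`, takes the longest
#' supra-threshold excursion as the flight, then refines by backtracking to
#' the contact level `toe_baseline + noise_sd`: `f` is the first airborne
#' sample (the one after the last pre-excursion index at contact level) and
#' `h` the last airborne sample before ground contact is re-established.
#'
#' @param toe_z Toe vertical series (m).
#' @param toe_baseline_z,noise_sd Quiet-stance baseline and noise estimate.
#' @param min_height_m Threshold floor (default 0.01 m).
#' @return List with integer sample indices `f` and `h` (1-based).
#' @export
detect_takeoff_touchdown <- function(toe_z, toe_baseline_z, noise_sd,
                                     min_height_m = 0.01) {
  n <- length(toe_z)
  tau <- toe_baseline_z + max(min_height_m, 5 * noise_sd)
  above <- toe_z > tau
  if (!any(above)) stop("no flight detected: toe never exceeds ",
                        signif(tau, 4), " m", call. = FALSE)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  k <- runs[which.max(r$lengths[runs])]
  s <- starts[k]; e <- ends[k]
  contact <- toe_baseline_z + noise_sd
  f <- s
  while (f > 1 && toe_z[f] > contact) f <- f - 1
  h <- e
  while (h < n && toe_z[h] > contact) h <- h + 1
  if (toe_z[f] > contact || toe_z[h] > contact)
    stop("no flight detected: toe never returns to baseline", call. = FALSE)
  # f/h now sit on the flanking contact samples; report the airborne span
  list(f = as.integer(f + 1), h = as.integer(h - 1))
}

count_excursions <- function(toe_z, tau, min_len) {
  r <- rle(toe_z > tau)
  sum(r$values & r$lengths >= min_len)
}

#' Detect the nine countermovement-jump events
#'
#' Rule-based detection on the CoM vertical position (`Z-t`), CoM vertical
#' velocity (`Vz-t`) and toe vertical (`Toe Z-t`) traces of a single jump:
#'
#' * `f`, `h` — toe lift-off / touchdown ([detect_takeoff_touchdown()]);
#' * `d` — lowest CoM position before take-off (argmin of Z before `f`);
#' * `c` — peak downward velocity before `d` (argmin of Vz);
#' * `a` — movement onset: searching backward from `c`, the first sample at
#'   which downward speed exceeds `onset_fraction` of the reference velocity
#'   (maximum upward velocity by default);
#' * `e` — maximum upward velocity on `(d, f]`;
#' * `g` — maximum CoM height on `(f, h)`;
#' * `i` — lowest CoM position from `h` onward.
#'
#' Ties break toward the earlier index. The ordering
#' `a < c < d < e <= f < g < h <= i` is enforced; a violation raises a
#' detection-failure error naming the offending pair. More than one flight
#' excursion raises an ambiguous-trial error.
#'
#' @param com A [com_trajectory()].
#' @param toe_z Toe vertical series (m), same length and rate.
#' @param cfg A [cmj_config()].
#' @return An object of class `jump_events`: integer indices `a`, `c`, `d`,
#'   `e`, `f`, `g`, `h`, `i` (1-based), event times `times_s`, and
#'   `baseline_z_m`, `toe_baseline_z_m`, `toe_noise_sd_m`.
#' @export
detect_events <- function(com, toe_z, cfg = cmj_config()) {
  stopifnot(inherits(com, "com_trajectory"))
  z <- com$com_z_m
  vz <- com$vz_mps
  fs <- com$sampling_rate_hz
  n <- length(z)
  stopifnot(length(toe_z) == n)

  bl <- quiet_stance_baseline(z, toe_z, fs, cfg$stance_window_s)
  tau <- bl$toe_baseline_z + max(cfg$min_height_m, 5 * bl$noise_sd)
  n_exc <- count_excursions(toe_z, tau, min_len = max(3, round(0.05 * fs)))
  if (n_exc > 1)
    stop("ambiguous trial: ", n_exc, " flight excursions detected",
         call. = FALSE)
  fh <- detect_takeoff_touchdown(toe_z, bl$toe_baseline_z, bl$noise_sd,
                                 cfg$min_height_m)
  f <- fh$f; h <- fh$h

  if (f <= 2) stop("detection failure: take-off at the series start",
                   call. = FALSE)
  d <- which.min(z[1:(f - 1)])
  c_ <- which.min(vz[1:d])
  vmax <- max(vz)
  vref <- if (cfg$onset_reference == "max_up") vmax else -min(vz)
  if (vref <= 0) stop("detection failure: flat or monotone CoM trace",
                      call. = FALSE)
  thr <- cfg$onset_fraction * vref
  a <- c_
  while (a > 1 && -vz[a - 1] > thr) a <- a - 1
  # a is now the first sample (searching back from c) with downward speed
  # above threshold
  if (-vz[a] <= thr)
    stop("detection failure: no onset found before the velocity minimum",
         call. = FALSE)
  e <- d + which.max(vz[(d + 1):f])
  g <- f + which.max(z[(f + 1):(h - 1)])
  i_ <- h - 1 + which.min(z[h:n])

  ev <- list(a = a, c = c_, d = d, e = e, f = f, g = g, h = h, i = i_)
  ord <- c("a", "c", "d", "e", "f", "g", "h", "i")
  strict <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE) # e<=f and h<=i
  for (k in seq_len(7)) {
    lhs <- ev[[ord[k]]]; rhs <- ev[[ord[k + 1]]]
    bad <- if (strict[k]) lhs >= rhs else lhs > rhs
    if (bad)
      stop(sprintf("detection failure: event ordering violated (%s %s %s)",
                   ord[k], if (strict[k]) ">=" else ">", ord[k + 1]),
           call. = FALSE)
  }
  structure(c(lapply(ev, as.integer),
              list(times_s = (unlist(ev) - 1) / fs,
                   sampling_rate_hz = fs,
                   baseline_z_m = bl$baseline_z,
                   toe_baseline_z_m = bl$toe_baseline_z,
                   toe_noise_sd_m = bl$noise_sd,
                   liftoff_threshold_m = tau)),
            class = "jump_events")
}

#' @export
print.jump_events <- function(x, ...) {
  cat("<jump_events> (index @", x$sampling_rate_hz, "Hz / time s)\n")
  for (k in c("a", "c", "d", "e", "f", "g", "h", "i"))
    cat(sprintf("  %s: %5d  %7.3f s\n", k, x[[k]],
                (x[[k]] - 1) / x$sampling_rate_hz))
  cat(sprintf("  baseline CoM z: %.4f m, toe baseline: %.4f m\n",
              x$baseline_z_m, x$toe_baseline_z_m))
  invisible(x)
}
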