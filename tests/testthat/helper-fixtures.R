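# Small landmark sets built in code for the io/kinematics tests.

# a minimal valid set: all 14 landmarks, constant or linear z
make_flat_set <- function(n = 10, fs = 100) {
  lm <- list()
  zs <- c(shoulder = 1.45, hip = 0.95, knee = 0.50, ankle = 0.07,
          heel = 0.03, small_toe = 0.025, big_toe = 0.02)
  xs <- c(shoulder = 0.02, hip = 0.0, knee = 0.05, ankle = 0.0,
          heel = -0.05, small_toe = 0.17, big_toe = 0.19)
  for (s in c("left", "right")) for (nm in names(zs))
    lm[[paste(s, nm, sep = "_")]] <-
      cbind(x = rep(xs[[nm]], n), z = rep(zs[[nm]], n))
  landmark_set(lm, sampling_rate_hz = fs, source_label = "fixture")
}

# a set where each landmark has prescribed z series (x constant 0)
make_z_set <- function(zmap, fs = 100) {
  lm <- lapply(zmap, function(z) cbind(x = rep(0, length(z)), z = z))
  landmark_set(lm, sampling_rate_hz = fs)
}

expect_events_close <- function(fit, truth, tol_samples, fs = 100) {
  for (k in names(truth$events_s)) {
    err <- abs((fit$events[[k]] - 1) / fs - truth$events_s[[k]]) * fs
    expect_lt(err, tol_samples + 1e-6,
              label = sprintf("event %s error (samples)", k))
  }
}
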