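test_that("quiet-stance baseline recovers mean and noise level", {
  fs <- 100
  com <- rep(0.95, 200); toe <- rep(0.02, 200)
  bl <- quiet_stance_baseline(com, toe, fs, 0.5)
  expect_equal(bl$baseline_z, 0.95)
  expect_equal(bl$noise_sd, 0)

  set.seed(101)
  toe_n <- toe + rnorm(200, 0, 0.001)
  bl2 <- quiet_stance_baseline(com, toe_n, fs, 1.0)  # 100-sample window
  expect_lt(abs(bl2$noise_sd - 0.001) / 0.001, 0.30)

  bl3 <- quiet_stance_baseline(com, toe, fs, 2.0)  # full series
  expect_equal(bl3$baseline_z, mean(com))
  expect_error(quiet_stance_baseline(com, toe, fs, 3), "longer")
})

test_that("take-off/touchdown from a constructed square excursion", {
  toe <- rep(0, 300)
  toe[101:151] <- 0.15  # plateau on 0-based indices 100..150
  fh <- detect_takeoff_touchdown(toe, toe_baseline_z = 0, noise_sd = 0,
                                 min_height_m = 0.01)
  expect_equal(fh$f, 101L)  # first airborne sample (1-based)
  expect_equal(fh$h, 151L)  # last airborne sample
  expect_error(detect_takeoff_touchdown(rep(0, 300), 0, 0, 0.01),
               "no flight")
})

test_that("all nine events recovered within one sample on noise-free jumps", {
  fs <- 100
  for (cfg in list(c(0.30, 2.3), c(0.20, 2.0), c(0.40, 2.6))) {
    sp <- cmj_sim_spec(depth_m = cfg[1], takeoff_velocity_mps = cfg[2],
                       propulsive_s = max(0.22, 1.45 * cfg[1] / cfg[2]))
    sim <- simulate_cmj(sp)
    fit <- cmj_analyze(sim$trajectories, "left", smooth_window_s = 0)
    expect_events_close(fit, sim$truth, tol_samples = 1, fs = fs)
    # toe-based f and h specifically within 1 sample
    expect_lt(abs((fit$events$f - 1) / fs - sim$truth$events_s[["f"]]) * fs, 1 + 1e-6)
    expect_lt(abs((fit$events$h - 1) / fs - sim$truth$events_s[["h"]]) * fs, 1 + 1e-6)
  }
})

test_that("with 2 mm landmark noise events stay within 3 samples in >= 18/20 seeds", {
  fs <- 100
  ok <- 0
  for (s in 1:20) {
    sim <- simulate_cmj(cmj_sim_spec(noise_sd_m = 0.002, seed = s))
    fit <- tryCatch(cmj_analyze(sim$trajectories, "left"),
                    error = function(e) NULL)
    if (is.null(fit)) next
    errs <- vapply(names(sim$truth$events_s), function(k)
      abs((fit$events[[k]] - 1) / fs - sim$truth$events_s[[k]]) * fs,
      numeric(1))
    if (max(errs) <= 3 + 1e-6) ok <- ok + 1
  }
  expect_gte(ok, 18)
})

test_that("event ordering and degenerate traces raise detection errors", {
  fs <- 100
  # an isolated one-sample notch as the "countermovement": no sample before
  # the velocity minimum ever exceeds the onset threshold, so the onset
  # collides with the velocity minimum and the ordering a < c is violated
  n <- 260
  z <- rep(1, n)
  z[140] <- 0.95
  z[151:180] <- 1 + 0.3 * (1:30) / 30
  z[181:210] <- 1.3 - 0.3 * (1:30) / 30
  toe <- rep(0.02, n)
  toe[151:200] <- 0.30
  com <- com_trajectory(com_x_m = z * 0, com_z_m = z, sampling_rate_hz = fs)
  expect_error(detect_events(com, toe, cmj_config()), "ordering violated")

  # monotone CoM trace with no upward velocity: onset reference undefined
  z2 <- 1 - (seq_len(n) - 1) * 0.001
  com2 <- com_trajectory(com_x_m = z2 * 0, com_z_m = z2,
                         sampling_rate_hz = fs)
  expect_error(detect_events(com2, toe, cmj_config()),
               "flat or monotone|ordering violated")

  # flat trace: no flight excursion
  flat <- make_flat_set(n = 300)
  expect_error(cmj_analyze(flat, "left", smooth_window_s = 0), "no flight")
})

test_that("two flight excursions are flagged as an ambiguous trial", {
  sim <- simulate_cmj(cmj_sim_spec())
  com <- body_com(sim$trajectories, "left")
  toe <- landmark_series(sim$trajectories, "left_big_toe", "z")
  toe2 <- toe
  toe2[10:25] <- toe2[10:25] + 0.2  # spurious second excursion in stance
  expect_error(detect_events(com, toe2, cmj_config(stance_window_s = 0.05)),
               "ambiguous")
})

test_that("event indices are invariant under a constant height shift", {
  sim <- simulate_cmj(cmj_sim_spec(noise_sd_m = 0.001, seed = 5))
  tset <- sim$trajectories
  shifted <- tset
  shifted$landmarks <- lapply(tset$landmarks, function(m)
    cbind(x = m[, 1], z = m[, 2] + 0.37))
  f1 <- cmj_analyze(tset, "left")
  f2 <- cmj_analyze(shifted, "left")
  for (k in c("a", "c", "d", "e", "f", "g", "h", "i"))
    expect_equal(f2$events[[k]], f1$events[[k]])
})

test_that("event times agree across sampling rates within one 100 Hz period", {
  s100 <- simulate_cmj(cmj_sim_spec(sampling_rate_hz = 100))
  s300 <- simulate_cmj(cmj_sim_spec(sampling_rate_hz = 300))
  f100 <- cmj_analyze(s100$trajectories, "left", smooth_window_s = 0)
  f300 <- cmj_analyze(s300$trajectories, "left", smooth_window_s = 0)
  for (k in c("a", "c", "d", "e", "f", "g", "h", "i")) {
    t100 <- (f100$events[[k]] - 1) / 100
    t300 <- (f300$events[[k]] - 1) / 300
    expect_lt(abs(t100 - t300), 1 / 100 + 1e-9)
  }
})

test_that("velocity crosses zero at the countermovement bottom", {
  sim <- simulate_cmj(cmj_sim_spec())
  fit <- cmj_analyze(sim$trajectories, "left", smooth_window_s = 0)
  d <- fit$events$d
  vz <- fit$com$vz_mps
  expect_lte(vz[d - 1], 1e-9)
  expect_gte(vz[d + 1], -1e-9)
})
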