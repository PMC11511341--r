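test_that("segment CoM follows the along-segment fractions", {
  n <- 3
  zmap <- list()
  for (id in landmark_ids()) zmap[[id]] <- rep(0, n)
  zmap$left_ankle <- rep(0.1, n)
  zmap$left_knee <- rep(0.5, n)
  zmap$left_hip <- rep(1.0, n)
  zmap$left_shoulder <- rep(1.5, n)
  zmap$left_heel <- rep(0.04, n)
  zmap$left_big_toe <- rep(0.04, n)
  tset <- make_z_set(zmap)
  # lower leg: 43.3% of the way from ankle toward knee
  expect_equal(segment_com(tset, "lower_leg", "left")[, "z"],
               rep(0.1 + 0.433 * 0.4, 3), tolerance = 1e-12)
  # heel = toe: foot CoM equals the shared point
  expect_equal(segment_com(tset, "foot", "left")[, "z"], rep(0.04, 3))
  # upper body: hip-shoulder midpoint
  expect_equal(segment_com(tset, "upper_body", "left")[, "z"], rep(1.25, 3))
  expect_error(segment_com(make_z_set(zmap[-1]), "upper_body", "left"),
               "left_shoulder")
})

test_that("whole-body CoM is the renormalised Dempster weighted mean", {
  n <- 3
  zmap <- list()
  # place landmarks so segment CoMs are foot 0, lower leg 0.2, upper leg
  # 0.6, upper body 1.2 (knee shared: lower-leg CoM 0.2 needs ankle=knee=0.2;
  # upper-leg CoM 0.6 = 0.2 + 0.433 (hip - 0.2))
  hip <- 0.2 + 0.4 / 0.433
  for (id in landmark_ids()) zmap[[id]] <- rep(0, n)
  for (s in c("left", "right")) {
    zmap[[paste0(s, "_heel")]] <- rep(0, n)
    zmap[[paste0(s, "_big_toe")]] <- rep(0, n)
    zmap[[paste0(s, "_ankle")]] <- rep(0.2, n)
    zmap[[paste0(s, "_knee")]] <- rep(0.2, n)
    zmap[[paste0(s, "_hip")]] <- rep(hip, n)
    zmap[[paste0(s, "_shoulder")]] <- rep(2 * 1.2 - hip, n)
  }
  tset <- make_z_set(zmap)
  expected <- (0.015 * 0 + 0.0465 * 0.2 + 0.10 * 0.6 + 0.43 * 1.2) / 0.5915
  com <- body_com(tset, "left")
  expect_equal(com$com_z_m, rep(expected, n), tolerance = 1e-9)

  # equal segment CoMs give that value back; translation equivariance
  tset2 <- tset
  tset2$landmarks <- lapply(tset$landmarks, function(m)
    cbind(x = m[, 1], z = m[, 2] + 0.3))
  expect_equal(body_com(tset2, "left")$com_z_m, com$com_z_m + 0.3,
               tolerance = 1e-12)
})

test_that("ZCoM is a convex combination of the segment CoMs", {
  sim <- simulate_cmj(cmj_sim_spec(noise_sd_m = 0.003, seed = 7))
  com <- body_com(sim$trajectories, "left")
  segz <- sapply(com$segment_com, function(m) m[, "z"])
  expect_true(all(com$com_z_m >= apply(segz, 1, min) - 1e-12))
  expect_true(all(com$com_z_m <= apply(segz, 1, max) + 1e-12))
})

test_that("body_com applies one formula to both axes", {
  sim <- simulate_cmj(cmj_sim_spec())
  tset <- sim$trajectories
  swapped <- tset
  swapped$landmarks <- lapply(tset$landmarks, function(m)
    cbind(x = m[, "z"], z = m[, "x"]))
  a <- body_com(tset, "left")
  b <- body_com(swapped, "left")
  expect_equal(b$com_x_m, a$com_z_m, tolerance = 1e-12)
  expect_equal(b$com_z_m, a$com_x_m, tolerance = 1e-12)
})

test_that("moving average: edge truncation, identity window, constants", {
  expect_equal(moving_average(c(0, 3, 0), 3), c(1.5, 1, 1.5))
  expect_equal(moving_average(rep(2.5, 10), 5), rep(2.5, 10))
  x <- rnorm(20)
  expect_equal(moving_average(x, 1), x)
  expect_error(moving_average(x, 0), "window")
})

test_that("smoothers preserve constants and never extend the range", {
  set.seed(3)
  for (rep_i in 1:5) {
    x <- cumsum(rnorm(50))
    for (sm in list(moving_average(x, 7), ema_filter(x, 0.3))) {
      expect_gte(min(sm), min(x) - 1e-12)
      expect_lte(max(sm), max(x) + 1e-12)
    }
  }
  expect_equal(ema_filter(rep(1.7, 30), 0.2), rep(1.7, 30))
})

test_that("zero-phase EMA matches the direct forward-backward recursion", {
  x <- c(0, 0, 0, 1, 0, 0, 0)
  alpha <- 0.5
  fwd <- function(v) {
    out <- v
    for (i in 2:length(v)) out[i] <- alpha * v[i] + (1 - alpha) * out[i - 1]
    out
  }
  manual <- (fwd(x) + rev(fwd(rev(x)))) / 2
  expect_equal(ema_filter(x, alpha), manual, tolerance = 1e-12)
  expect_equal(ema_filter(x, 1), x)  # alpha = 1 is the identity
  expect_error(ema_filter(x, 0), "alpha")
  expect_error(ema_filter(x, 1.2), "alpha")
  # zero net phase lag: a symmetric pulse stays symmetric
  sm <- ema_filter(x, 0.3)
  expect_equal(sm, rev(sm), tolerance = 1e-12)
})

test_that("finite-difference velocity is exact for linear and quadratic z", {
  fs <- 100
  t <- (0:199) / fs
  expect_equal(vertical_velocity(2 * t, fs), rep(2, 200), tolerance = 1e-9)
  expect_equal(vertical_velocity(rep(1, 200), fs), rep(0, 200))
  v <- vertical_velocity(t^2, fs)
  expect_equal(v[2:199], 2 * t[2:199], tolerance = 1e-9)
  expect_error(vertical_velocity(c(1, 2), fs), "length")
})

test_that("joint angles: collinear, right-angle, and hand-computed cases", {
  n <- 2
  zmap <- list()
  for (id in landmark_ids()) zmap[[id]] <- rep(0, n)
  tset <- make_z_set(zmap)
  pt <- function(x, z) cbind(x = rep(x, n), z = rep(z, n))
  # collinear: hip above knee above ankle
  tset$landmarks$left_hip <- pt(0, 1)
  tset$landmarks$left_knee <- pt(0, 0.5)
  tset$landmarks$left_ankle <- pt(0, 0)
  expect_equal(joint_angle(tset, "knee", "left")$angle_deg, rep(180, n))
  # right angle at the ankle
  tset$landmarks$left_big_toe <- pt(0.3, 0)
  expect_equal(joint_angle(tset, "ankle", "left")$angle_deg, rep(90, n))
  # hand trigonometry: knee at 150 degrees
  tset$landmarks$left_hip <- pt(0, 1)
  tset$landmarks$left_knee <- pt(0, 0)
  tset$landmarks$left_ankle <- pt(0.5, -sqrt(3) / 2)
  expect_equal(joint_angle(tset, "knee", "left")$angle_deg, rep(150, n),
               tolerance = 1e-9)
  # zero-length ray errors with the sample flagged
  tset$landmarks$left_ankle <- tset$landmarks$left_knee
  expect_error(joint_angle(tset, "knee", "left"), "zero-length ray")
})
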