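traj <- function(x, y) data.frame(x = x, y = y)

test_that("step kinematics match hand geometry", {
  k <- step_kinematics(traj(c(0, 1, 2), c(0, 0, 0)))
  expect_equal(k$linear_distance, c(1, 1))
  expect_equal(k$heading, c(0, 0))
  expect_equal(k$angular_speed, 0)

  k2 <- step_kinematics(traj(c(0, 1, 1), c(0, 0, 1)))
  expect_equal(k2$heading, c(0, pi / 2))
  expect_equal(k2$angular_speed, pi / 2)

  # regular octagon: constant turning angle pi/4 at every interior step
  a <- 2 * pi * (0:8) / 8
  k3 <- step_kinematics(traj(cos(a), sin(a)))
  expect_equal(k3$angular_speed, rep(pi / 4, 7))

  expect_error(step_kinematics(traj(0, 0)), "at least 2")
})

test_that("zero-length steps carry the previous heading forward", {
  k <- step_kinematics(traj(c(0, 1, 1, 2), c(0, 0, 0, 0)))
  expect_equal(k$heading, c(0, 0, 0))
  # leading zero-length steps are dropped from the heading series
  k2 <- step_kinematics(traj(c(0, 0, 1), c(0, 0, 0)))
  expect_equal(k2$heading, 0)
  expect_length(k2$angular_speed, 0)
})

test_that("circular variance matches the resultant-length oracle", {
  expect_equal(circular_variance(rep(0.7, 5)), 0)
  expect_equal(circular_variance(c(0, pi)), 1)
  expect_equal(circular_variance(c(0, pi / 2)), 1 - sqrt(2) / 2)
  expect_error(circular_variance(numeric(0)), "empty")
  set.seed(21)
  for (i in 1:25) {
    ang <- runif(sample(1:40, 1), -pi, pi)
    expect_equal(circular_variance(ang), 1 - oracle_resultant(ang),
                 tolerance = 1e-12)
  }
})

test_that("straightness anchors and oracle equivalence hold", {
  expect_equal(straightness(traj(0:10, rep(0, 11))), 1)
  expect_equal(straightness(traj(c(0, 1, 0), c(0, 0, 0))), 0)
  set.seed(5)
  h <- runif(64, -pi, pi)
  walk <- traj(cumsum(c(0, cos(h))), cumsum(c(0, sin(h))))
  expect_equal(straightness(walk), oracle_resultant(h), tolerance = 1e-12)
  # complementarity with circular variance is exact
  k <- step_kinematics(walk)
  expect_identical(straightness(walk) + circular_variance(k$heading), 1)
})

test_that("gyration anchors: polygon 1, line 0, alternating turns 0", {
  a <- 2 * pi * (0:12) / 12
  expect_equal(gyration(traj(cos(a), sin(a))), 1)
  expect_equal(gyration(traj(0:10, rep(0, 11))), 0)
  # alternating +-pi/3 turns: pooled set equals the set itself
  h <- cumsum(c(0, rep(c(pi / 3, -pi / 3), 5)))
  zig <- traj(cumsum(c(0, cos(h))), cumsum(c(0, sin(h))))
  expect_equal(gyration(zig), 0, tolerance = 1e-12)
})

test_that("the eversion feature vector has 14 named axes and exact anchors", {
  line <- traj(seq(0, 20, by = 2), rep(0, 11))
  f <- eversion_features(line)
  expect_length(f, 14)
  expect_equal(f[["mean_linear_speed"]], 2)
  expect_equal(f[["median_linear_speed"]], 2)
  expect_equal(f[["sd_linear_speed"]], 0)
  expect_equal(f[["straightness"]], 1)
  expect_equal(f[["gyration"]], 0)

  a <- 2 * pi * (0:24) / 24
  fc <- eversion_features(traj(50 * cos(a), 50 * sin(a)))
  expect_equal(fc[["sd_angular_speed"]], 0)
  expect_equal(fc[["gyration"]], 1)
})

test_that("displacer features equal a single-pass recomputation oracle", {
  sim <- gen_trajectory("displacer", seed = 7)
  f <- eversion_features(sim$trajectory)
  expect_equal(f, oracle_eversion(sim$trajectory), tolerance = 1e-12)
})

test_that("rotation, translation, scale and reversal behave as they must", {
  sim <- gen_trajectory("displacer", seed = 13)
  t0 <- sim$trajectory
  f0 <- eversion_features(t0)

  phi <- 0.83
  rot <- traj(cos(phi) * t0$x - sin(phi) * t0$y,
              sin(phi) * t0$x + cos(phi) * t0$y)
  fr <- eversion_features(rot)
  unchanged <- setdiff(names(f0), c("mean_heading", "median_heading"))
  expect_equal(fr[unchanged], f0[unchanged], tolerance = 1e-9)
  dmean <- (fr[["mean_heading"]] - f0[["mean_heading"]] - phi) %% (2 * pi)
  expect_true(min(dmean, 2 * pi - dmean) < 1e-9)

  shifted <- traj(t0$x + 100, t0$y - 50)
  expect_equal(eversion_features(shifted), f0, tolerance = 1e-9)

  scaled <- traj(3 * t0$x, 3 * t0$y)
  fs <- eversion_features(scaled)
  expect_equal(fs[["straightness"]], f0[["straightness"]], tolerance = 1e-12)
  expect_equal(fs[["gyration"]], f0[["gyration"]], tolerance = 1e-12)

  rev <- traj(rev(t0$x), rev(t0$y))
  kf <- step_kinematics(t0); kr <- step_kinematics(rev)
  expect_equal(sort(kr$angular_speed), sort(-kf$angular_speed),
               tolerance = 1e-12)
  expect_equal(gyration(rev), gyration(t0), tolerance = 1e-12)
})

test_that("gyration stays in [0,1] on random correlated walks", {
  set.seed(42)
  for (s in 1:20) {
    sim <- gen_trajectory("displacer", n_steps = 30,
                          heading_sd = runif(1, 0.05, 2), seed = 100 + s)
    gy <- gyration(sim$trajectory)
    expect_gte(gy, 0)
    expect_lte(gy, 1)
  }
})
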