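dt30 <- 1 / 30

test_that("central differences match hand-computed stencils", {
  expect_equal(central_difference_velocity(c(0, 1, 2), dt30),
               c(NA, 30, NA))
  # linearity: exact recovery of a linear motion at interior frames
  tt <- 0:99 * dt30
  v <- central_difference_velocity(3 + 12.5 * tt, dt30)
  expect_equal(v[2:99], rep(12.5, 98), tolerance = 1e-12)
  expect_true(all(is.na(v[c(1, 100)])))
  # constant position -> zero velocity wherever defined
  expect_equal(central_difference_velocity(rep(2, 10), dt30)[2:9], rep(0, 8))
  # segments shorter than 3 valid frames are entirely undefined
  expect_true(all(is.na(central_difference_velocity(c(0, 1), dt30))))
  valid <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  v <- central_difference_velocity(c(0, 1, NA, 3, 4, 5), dt30, valid)
  expect_true(all(is.na(v[1:4])))   # 2-frame run and frames touching the gap
  expect_false(is.na(v[5]))
})

test_that("angular speed wraps the heading difference across the branch cut", {
  w <- angular_speed(c(3.0, pi, -3.0), dt30)
  expect_equal(w[2], (2 * pi - 6) * 15)   # +0.2832 rad over 2 frames
  # steady turning: 0.1 rad/frame -> 3 rad/s
  th <- (0.1 * (0:59) + pi) %% (2 * pi) - pi
  expect_equal(angular_speed(th, dt30)[2:59], rep(3, 58), tolerance = 1e-12)
  expect_equal(angular_speed(rep(0.7, 10), dt30)[5], 0)
  # invariant under adding 2 pi to all headings
  th2 <- stats::runif(50, -pi, pi)
  expect_equal(angular_speed(th2, dt30), angular_speed(th2 + 2 * pi, dt30))
})

test_that("circular motion recovers speed and angular rate through the full chain", {
  # v = omega * r: 20.6 cm/s on a 51.5 cm circle -> 0.4 rad/s
  tab <- make_circle_swimmer(d_w = 4, v = 20.6, duration_s = 10)
  kin <- compute_kinematics(tab)
  inner <- kin$valid_kin
  omega0 <- 20.6 / 51.5
  expect_equal(unique(round(kin$omega[inner], 9)), omega0)
  # finite-difference speed has only the O(dt^2) chord error
  err <- abs(kin$speed[inner] - 20.6)
  expect_lt(max(err), 20.6 * (omega0 * dt30)^2 / 6 * 1.01)
  expect_gt(max(err), 0)    # the discretization error is real, not zero
})

test_that("tracking-error filters buffer three frames on each side, per fish", {
  # occlusion at frame 50 -> frames 47..53 invalid for that fish only
  tab0 <- straight_with_occlusion(50)
  tab1 <- make_circle_swimmer(4, 20.6, 5, fish_id = 1L)
  both <- combine_trajectories(tab0, tab1)
  ser <- apply_validity_filters(compute_kinematics(both), run_config())
  f0 <- ser[ser$fish_id == 0L, ]
  f1 <- ser[ser$fish_id == 1L, ]
  expect_false(any(f0$valid_kin[f0$frame %in% 47:53]))
  expect_true(all(f0$valid_kin[f0$frame %in% c(46, 54)]))
  expect_true(all(f1$valid_kin[f1$frame %in% 44:56]))

  # a speed glitch: displacing frame 50 by 10 cm spikes frames 49 and 51
  tab <- make_straight(20, duration_s = 5)
  tab$x[tab$frame == 50] <- tab$x[tab$frame == 50] + 10
  kin <- compute_kinematics(tab)
  expect_true(all(kin$speed[kin$frame %in% c(49, 51)] > 100))
  ser <- apply_validity_filters(kin, run_config())
  expect_false(any(ser$valid_kin[ser$frame %in% 46:54]))
  expect_true(all(ser$valid_kin[ser$frame %in% c(45, 55)]))

  # clean fixture passes through untouched; filtering is idempotent
  clean <- compute_kinematics(make_circle_swimmer(4, 20.6, 5))
  once <- apply_validity_filters(clean, run_config())
  expect_equal(once$valid_kin, clean$valid_kin)
  twice <- apply_validity_filters(once, run_config())
  expect_identical(as.data.frame(twice), as.data.frame(once))
  dirty <- apply_validity_filters(kin, run_config())
  expect_identical(as.data.frame(apply_validity_filters(dirty, run_config())),
                   as.data.frame(dirty))
})

test_that("activity classification reproduces constructed active fractions", {
  cfg <- run_config()
  # stop-go fixture at 73% duty cycle
  tab <- make_stop_go(0.73, duration_s = 60)
  ser <- classify_activity(apply_validity_filters(compute_kinematics(tab),
                                                  cfg), cfg)
  one_bout <- round(0.73 * 300) / (60 * 30)
  expect_lt(abs(active_fraction(ser) - 0.73), one_bout)
  expect_false(as.logical(trial_rejected(ser)))
  # no active-state frame sits within the buffer of an inactive frame
  inact_f <- ser$frame[ser$valid_kin & !ser$active]
  state_f <- ser$frame[ser$active_state]
  expect_gt(length(inact_f), 0)
  gap <- abs(outer(inact_f, state_f, `-`))
  expect_gt(min(gap), cfg$buffer_frames)

  # fully active fixture: fraction 1, no buffering anywhere
  full <- classify_activity(apply_validity_filters(
    compute_kinematics(make_circle_swimmer(4, 20, 20)), cfg), cfg)
  expect_equal(active_fraction(full), 1)
  expect_equal(full$active_state, full$active)

  # 40% duty cycle: more than half the frames inactive -> trial rejected
  lazy <- classify_activity(apply_validity_filters(
    compute_kinematics(make_stop_go(0.4, duration_s = 60)), cfg), cfg)
  expect_true(as.logical(trial_rejected(lazy)))
  expect_match(attr(trial_rejected(lazy), "reason"), "inactive")
})
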