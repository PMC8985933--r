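test_that("pair samples compute distance and heading angle per frame", {
  md <- fixture_md(n = 2, analysis_s = 1)
  tab <- trajectory_table(
    frame = c(0L, 0L), fish_id = c(0L, 1L),
    x = c(0, 3), y = c(0, 4),
    heading = c(pi / 4, -pi / 4), metadata = md)
  s <- pair_samples(tab)
  expect_equal(s$distance, 5)          # 3-4-5 triangle
  expect_equal(s$angle, pi / 2)        # +45 vs -45 degrees
  # antiparallel headings -> 180 degrees; coincident aligned -> (0, 0)
  tab2 <- trajectory_table(c(0L, 0L), c(0L, 1L), c(0, 3), c(0, 4),
                           c(0.3, 0.3 - pi), metadata = md)
  expect_equal(pair_samples(tab2)$angle, pi)
  tab3 <- trajectory_table(c(0L, 0L), c(0L, 1L), c(1, 1), c(2, 2),
                           c(0.5, 0.5), metadata = md)
  expect_equal(pair_samples(tab3)$distance, 0)
  expect_equal(pair_samples(tab3)$angle, 0)
  # relabeling the fish leaves the metrics unchanged
  swapped <- trajectory_table(tab$frame, 1L - tab$fish_id, tab$x, tab$y,
                              tab$heading, metadata = md)
  expect_equal(pair_samples(swapped)[c("distance", "angle")],
               s[c("distance", "angle")])
  # single fish -> empty stream with a warning
  expect_warning(s1 <- pair_samples(make_straight(10)), "fewer than two")
  expect_equal(nrow(s1), 0L)
})

test_that("joint density normalizes and is flat in angle for isotropic headings", {
  set.seed(21)
  n <- 60000
  samples <- data.frame(frame = seq_len(n), fish_i = 0L, fish_j = 1L,
                        distance = 5, angle = stats::runif(n, 0, pi))
  jd <- joint_density(samples)
  w <- (jd$d_hi - jd$d_lo) * (jd$theta_hi - jd$theta_lo)
  expect_equal(sum(jd$density * w), 1, tolerance = 1e-9)
  occupied <- jd[jd$d_lo == 4, ]
  expect_equal(sum(jd$density[jd$d_lo != 4]), 0)
  # all 36 angle bins at d in [4,6) should be equally occupied
  expect_lt(stats::sd(occupied$density) / mean(occupied$density), 0.05)

  # all samples identical -> single occupied bin with density 1 / bin area
  one <- joint_density(data.frame(frame = 1:5, fish_i = 0L, fish_j = 1L,
                                  distance = 5, angle = 0.1))
  expect_equal(max(one$density), 1 / (2 * 5))
  expect_equal(sum(one$density > 0), 1L)
  expect_error(joint_density(one[0, ]), "no pair samples")
  expect_error(joint_density(data.frame(frame = 1, fish_i = 0, fish_j = 1,
                                        distance = 5, angle = 0.1),
                             dist_edges = c(3, 3)), "degenerate")
})

test_that("wall-following arches match the closed form and the circle-pair fixtures", {
  R <- 55.5; d_w <- 4
  arch <- wall_following_arches(R, d_w, theta = c(0, pi / 2, pi))
  expect_equal(arch$d_minus, c(0, 51.5 * sqrt(2), 103))
  expect_equal(arch$d_plus, c(103, 51.5 * sqrt(2), 0))
  expect_error(wall_following_arches(R, R), "d_w")

  # co-rotating pair: a single point on the minus branch at theta = phase
  phase <- pi / 3
  co <- pair_samples(make_circle_pair(d_w, 20.6, phase, TRUE, duration_s = 20))
  expect_equal(co$angle, rep(phase, nrow(co)), tolerance = 1e-9)
  expect_equal(co$distance, rep(51.5 * sqrt(2 - 2 * cos(phase)), nrow(co)),
               tolerance = 1e-9)

  # counter-rotating pair: samples trace the plus branch as theta varies
  ct <- pair_samples(make_circle_pair(d_w, 20.6, phase, FALSE,
                                      duration_s = 20))
  expect_gt(diff(range(ct$angle)), 2)   # theta actually sweeps
  pred <- 51.5 * sqrt(2 + 2 * cos(ct$angle))
  expect_equal(ct$distance, pred, tolerance = 1e-9)
})

test_that("close-range alignment measures the heading order parameter", {
  # rigid parallel pair at 5 cm: all mass at (5 cm, 0), <cos theta> = 1
  par <- pair_samples(make_pair_school(c(5, 0), 0))
  cra <- close_range_alignment(par, cutoff = 10)
  expect_equal(cra$mean_cos, 1)
  expect_equal(sum(cra$density$density > 0), 1L)
  expect_equal(cra$density$theta_lo[cra$density$density > 0], 0)
  # antiparallel pair: <cos theta> = -1
  anti <- pair_samples(make_pair_school(c(5, 0), pi))
  expect_equal(close_range_alignment(anti)$mean_cos, -1)
  # isotropic headings: symmetric density, <cos theta> ~ 0
  set.seed(22)
  iso <- data.frame(frame = 1:50000, fish_i = 0L, fish_j = 1L,
                    distance = stats::runif(50000, 0, 12),
                    angle = acos(stats::runif(50000, -1, 1)))
  expect_equal(close_range_alignment(iso)$mean_cos, 0, tolerance = 0.02)
  # no close pairs -> undefined with a warning
  far <- data.frame(frame = 1, fish_i = 0L, fish_j = 1L, distance = 80,
                    angle = 1)
  expect_warning(out <- close_range_alignment(far), "undefined")
  expect_true(is.na(out$mean_cos))
})

test_that("schooling summary fractions follow their constructions", {
  par <- pair_samples(make_pair_school(c(0.01, 0), 0))
  ss <- schooling_summary(par)
  expect_equal(ss$p_close, 1)
  expect_equal(ss$p_aligned, 1)
  # diametrically opposite circle swimmers never come within 15 cm
  opp <- pair_samples(make_circle_pair(4, 20.6, pi, TRUE, duration_s = 10))
  expect_equal(schooling_summary(opp)$p_close, 0)
  # isotropic headings are aligned within 45 degrees a quarter of the time
  set.seed(23)
  iso <- data.frame(frame = 1:50000, fish_i = 0L, fish_j = 1L, distance = 5,
                    angle = stats::runif(50000, 0, pi))
  expect_equal(schooling_summary(iso)$p_aligned, 0.25, tolerance = 0.01)
})
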