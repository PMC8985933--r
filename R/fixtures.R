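#' Synthetic trajectory fixtures
#'
#' Deterministic and seeded generators producing [trajectory_table()]
#' objects with known kinematic structure, so every analysis stage can be
#' validated against closed-form expectations without experimental data.
#' Fixture headings are velocity directions (fixtures have no body axis).
#'
#' @name fixtures
NULL

fixture_metadata <- function(kind, n, fps, R, duration_s) {
  trial_metadata(kind, n, fps = fps, tank_radius = R, acclimation_s = 0,
                 analysis_s = duration_s)
}

#' Wall-following circular swimmer
#'
#' Uniform circular motion at constant wall distance `d_w`: radius
#' `R - d_w`, heading tangent to the path, speed `v`, angular speed
#' `chirality * v / (R - d_w)`. Its nematic wall alignment is exactly -1
#' and its wall-distance density is a delta at `d_w`.
#'
#' @param d_w Wall distance in cm (0 < d_w < R).
#' @param v Speed in cm/s.
#' @param duration_s Duration in s.
#' @param fps Frames per second (default 30).
#' @param R Tank radius in cm (default 55.5).
#' @param chirality +1 for counterclockwise, -1 for clockwise.
#' @param phase Starting angular position in rad.
#' @param fish_id Fish identifier (default 0).
#' @return A `trajectory_table`.
#' @export
#' @examples
#' tab <- make_circle_swimmer(d_w = 4, v = 20.6, duration_s = 2)
make_circle_swimmer <- function(d_w, v, duration_s, fps = 30, R = 55.5,
                                chirality = 1, phase = 0, fish_id = 0L) {
  if (d_w <= 0 || d_w >= R) stop("`d_w` must lie in (0, R)", call. = FALSE)
  if (v <= 0) stop("`v` must be > 0", call. = FALSE)
  stopifnot(chirality %in% c(-1, 1))
  rr <- R - d_w
  omega <- chirality * v / rr
  t <- (0:(round(duration_s * fps) - 1L)) / fps
  phi <- phase + omega * t
  trajectory_table(
    frame = seq_along(t) - 1L,
    fish_id = rep(as.integer(fish_id), length(t)),
    x = rr * cos(phi), y = rr * sin(phi),
    heading = wrap_angle(phi + chirality * pi / 2),
    metadata = fixture_metadata("circle_swimmer", 1L, fps, R, duration_s))
}

#' Straight-line swimmer
#'
#' Constant velocity along a fixed heading, starting at `start`.
#'
#' @param v Speed in cm/s.
#' @param heading Heading in rad.
#' @param duration_s Duration in s.
#' @param start Starting position `c(x, y)` in cm.
#' @param fps Frames per second.
#' @param R Tank radius in cm; the path must stay inside.
#' @param fish_id Fish identifier.
#' @return A `trajectory_table`.
#' @export
make_straight <- function(v, heading = 0, duration_s = 1,
                          start = c(-v * duration_s / 2, 0), fps = 30,
                          R = 55.5, fish_id = 0L) {
  t <- (0:(round(duration_s * fps) - 1L)) / fps
  trajectory_table(
    frame = seq_along(t) - 1L,
    fish_id = rep(as.integer(fish_id), length(t)),
    x = start[1] + v * t * cos(heading),
    y = start[2] + v * t * sin(heading),
    heading = rep(wrap_angle(heading), length(t)),
    metadata = fixture_metadata("straight", 1L, fps, R, duration_s))
}

#' Stop-go swimmer with a prescribed active fraction
#'
#' Alternates swimming bouts at speed `v` along a wall-following circular
#' path with stationary bouts, so that the realized fraction of active
#' frames is within one bout of `active_fraction`. Stationary bouts emit
#' identical positions (not missing rows), so finite differences yield a
#' true zero speed.
#'
#' @param active_fraction Target fraction of moving frames in [0, 1].
#' @param v Swimming speed during bouts, cm/s.
#' @param duration_s Duration in s.
#' @param cycle_s Length of one go+stop cycle in s (default 10).
#' @param d_w Wall distance of the circular path, cm.
#' @param fps Frames per second.
#' @param R Tank radius in cm.
#' @param fish_id Fish identifier.
#' @return A `trajectory_table`.
#' @export
make_stop_go <- function(active_fraction, v = 20, duration_s = 60,
                         cycle_s = 10, d_w = 4, fps = 30, R = 55.5,
                         fish_id = 0L) {
  if (active_fraction < 0 || active_fraction > 1)
    stop("`active_fraction` must lie in [0, 1]", call. = FALSE)
  n <- round(duration_s * fps)
  cyc <- round(cycle_s * fps)
  go <- round(active_fraction * cyc)
  moving <- ((0:(n - 1L)) %% cyc) < go
  rr <- R - d_w
  # arc position advances only while moving
  step <- v / (fps * rr)
  phi <- cumsum(c(0, step * as.numeric(moving[-n])))
  trajectory_table(
    frame = 0:(n - 1L),
    fish_id = rep(as.integer(fish_id), n),
    x = rr * cos(phi), y = rr * sin(phi),
    heading = wrap_angle(phi + pi / 2),
    metadata = fixture_metadata("stop_go", 1L, fps, R, duration_s))
}

#' Free active-Brownian walker
#'
#' Unconfined active-Brownian path sampled at the frame rate: the heading
#' performs a Gaussian random walk with variance `2 * D_r / fps` per frame
#' and the position advances at speed `v0` along it. The stored tank
#' radius is enlarged to contain the whole path, since the walker is not
#' confined. With `D_r = 0` the path is a straight line.
#'
#' @param D_r Angular diffusion constant, rad^2/s (>= 0).
#' @param v0 Speed, cm/s.
#' @param duration_s Duration in s.
#' @param fps Frames per second.
#' @param seed Integer seed.
#' @param fish_id Fish identifier.
#' @return A `trajectory_table`.
#' @export
make_free_abp <- function(D_r, v0 = 21, duration_s = 200, fps = 30,
                          seed = 1L, fish_id = 0L) {
  if (D_r < 0) stop("`D_r` must be >= 0", call. = FALSE)
  n <- round(duration_s * fps)
  set.seed(seed)
  dth <- if (D_r > 0) stats::rnorm(n - 1L, sd = sqrt(2 * D_r / fps)) else
    rep(0, n - 1L)
  th <- cumsum(c(0, dth))
  x <- cumsum(c(0, v0 / fps * cos(th[-n])))
  y <- cumsum(c(0, v0 / fps * sin(th[-n])))
  R_box <- max(sqrt(x^2 + y^2)) + 1
  trajectory_table(
    frame = 0:(n - 1L),
    fish_id = rep(as.integer(fish_id), n),
    x = x, y = y, heading = wrap_angle(th),
    metadata = fixture_metadata("free_abp", 1L, fps, max(R_box, 55.5),
                                duration_s))
}

#' Rigid pair with fixed offset and relative heading
#'
#' Two fish translating together: fish 1 follows a straight path and
#' fish 2 keeps a fixed offset from it and a fixed relative heading angle.
#' The pair distance-angle map of this fixture is a single point.
#'
#' @param offset Offset vector `c(dx, dy)` in cm.
#' @param rel_angle Heading of fish 2 relative to fish 1, rad.
#' @param v Speed in cm/s.
#' @param duration_s Duration in s.
#' @param fps Frames per second.
#' @param R Tank radius in cm.
#' @return A `trajectory_table` with two fish.
#' @export
make_pair_school <- function(offset = c(5, 0), rel_angle = 0, v = 20,
                             duration_s = 2, fps = 30, R = 55.5) {
  if (sqrt(sum(offset^2)) >= R)
    stop("`offset` must be smaller than the tank radius", call. = FALSE)
  base <- make_straight(v, heading = pi / 2, duration_s = duration_s,
                        start = c(0, -v * duration_s / 2), fps = fps, R = R,
                        fish_id = 0L)
  mate <- trajectory_table(
    frame = base$frame, fish_id = rep(1L, nrow(base)),
    x = base$x + offset[1], y = base$y + offset[2],
    heading = wrap_angle(base$heading + rel_angle),
    metadata = attr(base, "metadata"))
  combine_trajectories(base, mate,
                       metadata = fixture_metadata("pair_school", 2L, fps, R,
                                                   duration_s))
}

#' Pair of wall-following circular swimmers
#'
#' Two circle swimmers at the same wall distance, either co-rotating with a
#' fixed angular separation or counter-rotating. Co-rotating pairs sample a
#' single point of the minus-branch wall-following arch; counter-rotating
#' pairs trace the plus branch as their pair angle varies.
#'
#' @param d_w Wall distance in cm.
#' @param v Speed in cm/s.
#' @param phase_sep Angular separation along the tank in rad.
#' @param co_rotating `TRUE` for same chirality, `FALSE` for opposite.
#' @param duration_s Duration in s.
#' @param fps Frames per second.
#' @param R Tank radius in cm.
#' @return A `trajectory_table` with two fish.
#' @export
make_circle_pair <- function(d_w = 4, v = 20.6, phase_sep = pi / 3,
                             co_rotating = TRUE, duration_s = 10, fps = 30,
                             R = 55.5) {
  a <- make_circle_swimmer(d_w, v, duration_s, fps, R, chirality = 1,
                           phase = 0, fish_id = 0L)
  b <- make_circle_swimmer(d_w, v, duration_s, fps, R,
                           chirality = if (co_rotating) 1 else -1,
                           phase = phase_sep, fish_id = 1L)
  combine_trajectories(a, b,
                       metadata = fixture_metadata("circle_pair", 2L, fps, R,
                                                   duration_s))
}
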