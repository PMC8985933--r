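#' @useDynLib schoolkin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Simulation parameters for the active-Brownian fish model
#'
#' The model propels each fish at constant speed `v0` along its heading,
#' which diffuses rotationally with angular diffusion constant `D_r`. A
#' soft elastic force of strength `k_w` and range `r_w` keeps fish off the
#' wall; a torque of strength `k_wt` and range `r_wt` aligns fish moving
#' towards the wall with it; an avoidance torque of strength `k_a` and
#' range `r_a` turns a fish away from any neighbor closer than `r_a`
#' (evasive maneuvers). Mobilities `mu` (translational) and `mu_r`
#' (angular) are redundant scale factors when the interaction strengths
#' are calibrated directly to behavior, and default to 1.
#'
#' Defaults are the calibrated values for an isolated cavefish-like
#' swimmer: `v0 = 21` cm/s (isolated-fish mean active speed), `D_r = 0.2`
#' rad^2/s (from the short-lag decay of the heading autocorrelation),
#' `k_w = 100`, `r_w = 2.5` cm, `k_wt = 0.83`, `r_wt = 5` cm (tuned so an
#' isolated fish spends about 13% of its time in the inner half of the
#' tank), `k_a = 0` (no avoidance), `r_a = 2.5` cm, `R = 55.5` cm,
#' `dt = 0.005` s.
#'
#' @param v0 Self-propulsion speed, cm/s.
#' @param D_r Angular diffusion constant, rad^2/s.
#' @param mu,mu_r Translational and angular mobility.
#' @param k_w,r_w Wall repulsion strength and range (cm).
#' @param k_wt,r_wt Wall alignment torque strength and range (cm). The
#'   alternate calibration `k_wt = 0.2, r_wt = 10` gives nearly identical
#'   behavior.
#' @param k_a,r_a Avoidance torque strength and range (cm).
#' @param R Tank radius, cm.
#' @param n_fish Number of fish.
#' @param dt Integration time step, s.
#' @param duration Simulated time, s.
#' @param discard Leading time excluded from all statistics, s.
#' @param out_fps Frame rate of the exported trajectory (default 30, so
#'   simulator output is analyzed exactly like tracker output).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(v0 = 21, D_r = 0.2, mu = 1, mu_r = 1,
                       k_w = 100, r_w = 2.5, k_wt = 0.83, r_wt = 5,
                       k_a = 0, r_a = 2.5, R = 55.5, n_fish = 1,
                       dt = 0.005, duration = 20000, discard = 5000,
                       out_fps = 30) {
  p <- list(v0 = v0, D_r = D_r, mu = mu, mu_r = mu_r, k_w = k_w, r_w = r_w,
            k_wt = k_wt, r_wt = r_wt, k_a = k_a, r_a = r_a, R = R,
            n_fish = as.integer(n_fish), dt = dt, duration = duration,
            discard = discard, out_fps = out_fps)
  if (p$dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (p$discard >= p$duration)
    stop("`discard` must be smaller than `duration`", call. = FALSE)
  if (any(c(p$r_w, p$r_wt, p$r_a) >= p$R))
    stop("interaction ranges must be smaller than the tank radius",
         call. = FALSE)
  if (p$n_fish < 1L) stop("`n_fish` must be >= 1", call. = FALSE)
  if (p$D_r < 0) stop("`D_r` must be >= 0", call. = FALSE)
  structure(p, class = "sim_params")
}

#' Wall repulsion force
#'
#' Soft elastic repulsion from the tank wall: zero when the fish is further
#' than `r_w` from the wall, otherwise `k_w * (R - r_w - |r|)` along the
#' outward radial direction (the factor is negative inside the range, so
#' the force points inward).
#'
#' @param x,y Positions in cm (tank-centered); vectorized.
#' @param params A [sim_params()] object.
#' @return A data frame with columns `fx, fy` (force per unit mobility).
#' @export
wall_force <- function(x, y, params = sim_params()) {
  r <- sqrt(x^2 + y^2)
  f <- ifelse(params$R - params$r_w - r < 0,
              params$k_w * (params$R - params$r_w - r), 0)
  rx <- ifelse(r > 0, x / r, 1)
  ry <- ifelse(r > 0, y / r, 0)
  data.frame(fx = f * rx, fy = f * ry)
}

#' Wall alignment torque
#'
#' Acts on a fish within `r_wt` of the wall *and* moving towards it
#' (`e . r_hat > 0`): `k_wt * (e . r_hat) * (e x r_hat) * (R - r_wt - |r|)`.
#' The dot-cross product makes wall-parallel orientations attracting fixed
#' points without favoring either chirality, and the last factor fades the
#' torque linearly to zero at wall distance `r_wt`.
#'
#' @param heading Headings in rad; vectorized.
#' @param x,y Positions in cm.
#' @param params A [sim_params()] object.
#' @return Torques in rad/s (per unit angular mobility).
#' @export
wall_torque <- function(heading, x, y, params = sim_params()) {
  r <- sqrt(x^2 + y^2)
  rx <- x / r
  ry <- y / r
  ex <- cos(heading)
  ey <- sin(heading)
  edotr <- ex * rx + ey * ry
  ecrossr <- ex * ry - ey * rx
  on <- (params$R - params$r_wt - r < 0) & (edotr > 0)
  ifelse(on, params$k_wt * edotr * ecrossr * (params$R - params$r_wt - r), 0)
}

#' Avoidance torque
#'
#' Evasive-maneuver torque exerted on fish i by a neighbor j closer than
#' `r_a`: magnitude `k_a * |sin(angle between heading and the line to j)| *
#' (r_a - d)`, signed so that the heading turns away from the neighbor
#' (facing directly away is the attracting fixed point, facing the
#' neighbor the unstable one).
#'
#' @param heading Heading of fish i, rad; vectorized.
#' @param xi,yi Position of fish i, cm.
#' @param xj,yj Position of fish j, cm.
#' @param params A [sim_params()] object.
#' @return Torques in rad/s (per unit angular mobility).
#' @export
avoidance_torque <- function(heading, xi, yi, xj, yj, params = sim_params()) {
  dx <- xj - xi
  dy <- yj - yi
  d <- sqrt(dx^2 + dy^2)
  if (any(d == 0))
    stop("coincident fish: avoidance direction undefined", call. = FALSE)
  ux <- dx / d
  uy <- dy / d
  ex <- cos(heading)
  ey <- sin(heading)
  ifelse(d < params$r_a,
         params$k_a * (ux * ey - uy * ex) * (params$r_a - d), 0)
}

#' One Euler-Maruyama step of the fish model (reference implementation)
#'
#' Pure-R single step over a state data frame, matching the compiled
#' integrator: positions advance along the heading plus the wall force,
#' headings by the wall and avoidance torques plus rotational noise
#' `sqrt(2 * D_r * dt) * N(0, 1)`. Useful for inspecting the dynamics and
#' as a cross-check of the compiled loop; use [run_simulation()] for
#' production runs.
#'
#' @param state Data frame with columns `x, y, heading` (one row per fish).
#' @param params A [sim_params()] object.
#' @param noise Optional pre-drawn standard normal deviates (one per fish);
#'   drawn from the session RNG when `NULL`, or set to 0 for a
#'   deterministic step.
#' @return The updated state data frame.
#' @export
abp_step <- function(state, params = sim_params(), noise = NULL) {
  n <- nrow(state)
  if (is.null(noise)) noise <- stats::rnorm(n)
  f <- wall_force(state$x, state$y, params)
  tau <- wall_torque(state$heading, state$x, state$y, params)
  if (params$k_a != 0 && n > 1) {
    for (i in seq_len(n)) {
      j <- setdiff(seq_len(n), i)
      tau[i] <- tau[i] + sum(avoidance_torque(
        state$heading[i], state$x[i], state$y[i],
        state$x[j], state$y[j], params))
    }
  }
  ex <- cos(state$heading)
  ey <- sin(state$heading)
  state$x <- state$x + (params$v0 * ex + params$mu * f$fx) * params$dt
  state$y <- state$y + (params$v0 * ey + params$mu * f$fy) * params$dt
  state$heading <- wrap_angle(
    state$heading + params$mu_r * tau * params$dt +
      sqrt(2 * params$D_r * params$dt) * noise)
  state
}

#' Run the active-Brownian fish simulation
#'
#' Integrates the model with the compiled Euler-Maruyama loop. Fish start
#' at a random spot along the wall, at distance `r_w` from it, heading
#' parallel to the wall with random chirality. The first `discard` seconds
#' are excluded from the returned trajectory and from the
#' fraction-in-center statistic. Results at a fixed seed are
#' bit-reproducible.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed for all randomness of the run.
#' @param return_trajectory When `TRUE` (default), the post-discard
#'   trajectory sub-sampled at `params$out_fps` is returned as a
#'   [trajectory_table()], ready for the analysis modules. Set `FALSE` for
#'   sweeps where only the summary is needed.
#' @return A list with elements `fraction_in_center`, `params`, `seed`,
#'   and (when requested) `trajectory`.
#' @export
#' @examples
#' \donttest{
#' sim <- run_simulation(sim_params(duration = 600, discard = 100), seed = 1)
#' sim$fraction_in_center
#' }
run_simulation <- function(params = sim_params(), seed = 1L,
                           return_trajectory = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  out_every <- if (return_trajectory)
    max(1L, as.integer(round(1 / (params$out_fps * params$dt)))) else 0L
  set.seed(seed)
  res <- .abp_run_cpp(params$n_fish, params$v0, params$D_r, params$mu,
                      params$mu_r, params$k_w, params$r_w, params$k_wt,
                      params$r_wt, params$k_a, params$r_a, params$R,
                      params$dt, params$duration, params$discard, out_every)
  out <- list(fraction_in_center = res$fraction_in_center,
              params = params, seed = seed)
  if (return_trajectory) {
    nf <- nrow(res$x)
    n <- params$n_fish
    fps_eff <- 1 / (out_every * params$dt)
    md <- trial_metadata("simulation", n, fps = fps_eff,
                         tank_radius = params$R, acclimation_s = 0,
                         analysis_s = nf / fps_eff)
    out$trajectory <- trajectory_table(
      frame = rep(0:(nf - 1L), times = n),
      fish_id = rep(0:(n - 1L), each = nf),
      x = as.vector(res$x), y = as.vector(res$y),
      heading = as.vector(res$theta),
      metadata = md)
  }
  out
}

#' Fraction-in-center sweep over self-propulsion speeds
#'
#' Runs replicate single-fish simulations at each speed of `v0_grid` and
#' tabulates the fraction of time in the inner half of the tank. The
#' companion summary [sweep_percent_change()] expresses each grid point as
#' a percentage change relative to the baseline speed, the way the
#' speed-only model is compared against observed group-size slowdowns.
#'
#' @param v0_grid Speeds in cm/s.
#' @param replicates Seeded replicates per speed (default 20).
#' @param params Base [sim_params()] (its `v0` and `n_fish` are
#'   overridden; `n_fish` is forced to 1).
#' @param base_seed Offset for the per-run seeds.
#' @return A data frame `v0, replicate, seed, fraction_center`.
#' @export
speed_sweep <- function(v0_grid, replicates = 20, params = sim_params(),
                        base_seed = 1L) {
  grid <- expand.grid(replicate = seq_len(replicates), v0 = v0_grid)
  res <- mapply(function(v0, rep) {
    p <- params
    p$v0 <- v0
    p$n_fish <- 1L
    seed <- base_seed + 1000L * match(v0, v0_grid) + rep
    run_simulation(p, seed = seed,
                   return_trajectory = FALSE)$fraction_in_center
  }, grid$v0, grid$replicate)
  data.frame(v0 = grid$v0, replicate = grid$replicate,
             seed = base_seed + 1000L * match(grid$v0, v0_grid) +
               grid$replicate,
             fraction_center = res)
}

#' Percentage change of center occupancy versus a baseline speed
#'
#' @param sweep Output of [speed_sweep()].
#' @param baseline_v0 Reference speed (default the largest in the sweep).
#' @return A data frame `v0, pct_speed_change, mean_fraction,
#'   pct_center_change` (both changes relative to the baseline point).
#' @export
sweep_percent_change <- function(sweep, baseline_v0 = max(sweep$v0)) {
  agg <- stats::aggregate(fraction_center ~ v0, data = sweep, FUN = mean)
  base <- agg$fraction_center[agg$v0 == baseline_v0]
  if (!length(base)) stop("baseline speed not in sweep", call. = FALSE)
  data.frame(
    v0 = agg$v0,
    pct_speed_change = 100 * (agg$v0 - baseline_v0) / baseline_v0,
    mean_fraction = agg$fraction_center,
    pct_center_change = 100 * (agg$fraction_center - base) / base)
}

#' Fraction-in-center sweep over avoidance strength and group size
#'
#' Runs the full model (wall interactions plus evasive-maneuver torque)
#' for every combination of group size and avoidance strength.
#'
#' @param n_values Group sizes.
#' @param ka_grid Avoidance strengths.
#' @param replicates Seeded replicates per point (default 3).
#' @param params Base [sim_params()] (its `n_fish` and `k_a` are
#'   overridden).
#' @param base_seed Offset for the per-run seeds.
#' @return A data frame `N, k_a, replicate, seed, fraction_center`.
#' @export
avoidance_sweep <- function(n_values, ka_grid, replicates = 3,
                            params = sim_params(), base_seed = 1L) {
  grid <- expand.grid(replicate = seq_len(replicates), k_a = ka_grid,
                      N = n_values)
  res <- mapply(function(N, ka, rep) {
    p <- params
    p$n_fish <- as.integer(N)
    p$k_a <- ka
    seed <- base_seed + 100000L * match(N, n_values) +
      1000L * match(ka, ka_grid) + rep
    run_simulation(p, seed = seed,
                   return_trajectory = FALSE)$fraction_in_center
  }, grid$N, grid$k_a, grid$replicate)
  data.frame(N = grid$N, k_a = grid$k_a, replicate = grid$replicate,
             seed = base_seed + 100000L * match(grid$N, n_values) +
               1000L * match(grid$k_a, ka_grid) + grid$replicate,
             fraction_center = res)
}

#' Estimate the angular diffusion constant from a trajectory
#'
#' Computes the heading autocorrelation `C(tau) = <cos(theta(t + tau) -
#' theta(t))>` for lags up to `max_lag_s` (default 1 s) and returns the
#' initial decay rate `D_r`, the slope of the short-lag decay
#' `C(tau) = 1 - D_r * tau`. The slope is obtained by regressing
#' `-log C(tau)` on `tau` through the origin, which agrees with the linear
#' form to first order but stays unbiased over a finite lag window when the
#' decay is exponential (as it is for rotational diffusion). For tank
#' trajectories, restrict to frames in the central half of the tank
#' (`central_only = TRUE`) so the wall interactions do not contaminate the
#' free-swimming decorrelation.
#'
#' @param tab A `trajectory_table` (or `kinematic_series`); headings must
#'   be present. At least 100 s of trajectory are required.
#' @param max_lag_s Longest lag entering the fit, s.
#' @param central_only Restrict lag pairs to frames where the fish is
#'   within `R / sqrt(2)` of the tank center at both ends of the pair.
#' @return Estimated `D_r` in rad^2/s.
#' @export
estimate_Dr <- function(tab, max_lag_s = 1, central_only = FALSE) {
  md <- attr(tab, "metadata")
  stopifnot(inherits(md, "trial_metadata"))
  fps <- md$fps
  lags <- seq_len(round(max_lag_s * fps))
  num <- rep(0, length(lags))
  den <- rep(0L, length(lags))
  for (d in split(as.data.frame(tab), tab$fish_id)) {
    d <- d[order(d$frame), ]
    ok <- d$valid & !is.na(d$heading)
    if (central_only) {
      r <- sqrt(d$x^2 + d$y^2)
      ok <- ok & !is.na(r) & r < md$tank_radius / sqrt(2)
    }
    th <- d$heading
    n <- length(th)
    for (k in seq_along(lags)) {
      L <- lags[k]
      if (n <= L) next
      i <- 1:(n - L)
      use <- ok[i] & ok[i + L]
      if (!any(use)) next
      num[k] <- num[k] + sum(cos(th[i + L][use] - th[i][use]))
      den[k] <- den[k] + sum(use)
    }
  }
  if (!all(den > 0) || min(den) < (100 - max_lag_s) * fps)
    stop("insufficient data to estimate D_r (need >= 100 s of trajectory",
         if (central_only) " in the central half" else "", ")",
         call. = FALSE)
  C <- num / den
  tau <- lags / fps
  # short-lag decay rate: -log C regressed on tau through the origin
  # (equals the 1 - D_r * tau fit at small lags, without curvature bias)
  use <- C > 0.05
  sum(tau[use] * (-log(C[use]))) / sum(tau[use]^2)
}
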