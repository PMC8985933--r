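#' Central-difference velocity
#'
#' Second-order central finite difference of a position series sampled at a
#' fixed frame interval: `v[i] = (p[i+1] - p[i-1]) / (2 * dt)`. The
#' derivative is undefined at the endpoints of each contiguous run of valid
#' frames and wherever a neighbor is invalid; those entries are `NA`.
#'
#' @param p Numeric vector of positions (cm), one entry per frame.
#' @param dt Frame interval in seconds (1/fps).
#' @param valid Logical vector flagging frames with a defined position.
#' @return Numeric vector of velocities (cm/s) with `NA` where undefined.
#' @export
#' @examples
#' central_difference_velocity(c(0, 1, 2), 1 / 30)  # 30 cm/s at the middle
central_difference_velocity <- function(p, dt, valid = !is.na(p)) {
  stopifnot(dt > 0, length(p) == length(valid))
  n <- length(p)
  v <- rep(NA_real_, n)
  if (n >= 3L) {
    i <- 2:(n - 1L)
    ok <- valid[i - 1L] & valid[i] & valid[i + 1L]
    v[i][ok] <- (p[i + 1L][ok] - p[i - 1L][ok]) / (2 * dt)
  }
  v
}

#' Angular speed from a heading series
#'
#' Central difference of the heading with the angle difference first brought
#' back into (-pi, pi], so that crossings of the +/-pi branch cut do not
#' produce spurious 2 pi jumps:
#' `omega[i] = wrap(theta[i+1] - theta[i-1]) / (2 * dt)`.
#'
#' @param theta Numeric vector of headings in rad, one entry per frame.
#' @param dt Frame interval in seconds.
#' @param valid Logical vector flagging frames with a defined heading.
#' @return Numeric vector of angular speeds (rad/s, signed) with `NA` where
#'   undefined.
#' @export
#' @examples
#' angular_speed(c(3.0, pi, -3.0), 1 / 30)  # crosses the branch cut smoothly
angular_speed <- function(theta, dt, valid = !is.na(theta)) {
  stopifnot(dt > 0, length(theta) == length(valid))
  n <- length(theta)
  w <- rep(NA_real_, n)
  if (n >= 3L) {
    i <- 2:(n - 1L)
    ok <- valid[i - 1L] & valid[i] & valid[i + 1L]
    d <- (theta[i + 1L][ok] - theta[i - 1L][ok] + pi) %% (2 * pi) - pi
    w[i][ok] <- d / (2 * dt)
  }
  w
}

#' Per-frame kinematics of a trajectory table
#'
#' Computes velocity, speed and angular speed for every fish with the
#' central-difference scheme of [central_difference_velocity()] and
#' [angular_speed()]. `valid_kin` is `TRUE` where all three derivative
#' components are defined, i.e. on the interior of contiguous valid runs.
#'
#' @param tab A [trajectory_table()].
#' @return A data frame of class `kinematic_series` with columns
#'   `frame, fish_id, x, y, heading, valid, vx, vy, speed, omega, valid_kin`,
#'   carrying the trial metadata in attribute `"metadata"`.
#' @export
compute_kinematics <- function(tab) {
  validate_trajectory_table(tab)
  md <- attr(tab, "metadata")
  dt <- 1 / md$fps
  tab <- as.data.frame(tab)
  parts <- lapply(split(tab, tab$fish_id), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    ok <- d$valid & !is.na(d$x)
    d$vx <- central_difference_velocity(d$x, dt, ok)
    d$vy <- central_difference_velocity(d$y, dt, ok)
    d$omega <- angular_speed(d$heading, dt, ok)
    d$speed <- sqrt(d$vx^2 + d$vy^2)
    d$valid_kin <- !is.na(d$speed) & !is.na(d$omega)
    d
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$frame, out$fish_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("kinematic_series", "data.frame")
  attr(out, "metadata") <- md
  out
}

# mark FALSE every index within `buffer` frames of a TRUE in `event`
buffer_mask <- function(event, buffer) {
  hit <- which(event)
  if (!length(hit)) return(rep(FALSE, length(event)))
  idx <- unique(as.vector(outer(hit, (-buffer):buffer, `+`)))
  idx <- idx[idx >= 1L & idx <= length(event)]
  out <- rep(FALSE, length(event))
  out[idx] <- TRUE
  out
}

#' Exclude tracking-error and occlusion frames
#'
#' Invalidates, per fish, every frame whose speed exceeds
#' `config$max_speed` (default 100 cm/s) or whose |angular speed| exceeds
#' `config$max_turn` (default 30 rad/s), together with the
#' `config$buffer_frames` (default 3) frames before and after each such
#' event. Frames flagged invalid in the input (occlusions) receive the same
#' buffer. The cut only affects the fish exhibiting the event; the other
#' fish's frames are untouched. Speed and angular-speed values are retained
#' (only the `valid_kin` mask changes), which makes the operation
#' idempotent.
#'
#' @param series A `kinematic_series` from [compute_kinematics()].
#' @param config A [run_config()].
#' @return The series with `valid_kin` updated.
#' @export
apply_validity_filters <- function(series, config = run_config()) {
  stopifnot(inherits(series, "kinematic_series"))
  md <- attr(series, "metadata")
  b <- config$buffer_frames
  parts <- lapply(split(as.data.frame(series), series$fish_id), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    spike <- (!is.na(d$speed) & d$speed > config$max_speed) |
      (!is.na(d$omega) & abs(d$omega) > config$max_turn)
    occluded <- !d$valid
    excl <- buffer_mask(spike | occluded, b)
    d$valid_kin <- d$valid_kin & !excl
    d
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$frame, out$fish_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("kinematic_series", "data.frame")
  attr(out, "metadata") <- md
  out
}

#' Classify active versus inactive frames
#'
#' A frame is *active* when the fish swims faster than
#' `config$activity_threshold` (default 1 cm/s). The per-trial
#' `active_fraction` is the share of active frames among valid frames,
#' computed before any buffering. For downstream swimming-state statistics,
#' frames within `config$buffer_frames` of an inactive interval are
#' additionally excluded; the column `active_state` is `TRUE` on frames that
#' are valid, active and outside those buffers. A trial in which more than
#' `1 - trial_inactivity_limit` of the frames are inactive is marked
#' rejected.
#'
#' @param series A filtered `kinematic_series`.
#' @param config A [run_config()].
#' @return The series with logical columns `active` and `active_state`
#'   added, and attributes `active_fraction` (scalar) and `rejected`
#'   (logical with a `reason` attribute when `TRUE`).
#' @export
classify_activity <- function(series, config = run_config()) {
  stopifnot(inherits(series, "kinematic_series"))
  md <- attr(series, "metadata")
  thr <- config$activity_threshold
  b <- config$buffer_frames
  parts <- lapply(split(as.data.frame(series), series$fish_id), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    d$active <- d$valid_kin & !is.na(d$speed) & d$speed > thr
    inactive <- d$valid_kin & !d$active
    d$active_state <- d$active & !buffer_mask(inactive, b)
    d
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$frame, out$fish_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("kinematic_series", "data.frame")
  attr(out, "metadata") <- md
  n_valid <- sum(out$valid_kin)
  if (n_valid == 0L) {
    attr(out, "active_fraction") <- NA_real_
    rejected <- TRUE
    attr(rejected, "reason") <- "no valid frames"
  } else {
    af <- sum(out$active) / n_valid
    attr(out, "active_fraction") <- af
    rejected <- af < config$trial_inactivity_limit
    if (rejected)
      attr(rejected, "reason") <-
        sprintf("more than half of the frames are inactive (active fraction %.3f)", af)
  }
  attr(out, "rejected") <- rejected
  out
}

#' Per-trial active fraction
#' @param series Output of [classify_activity()].
#' @return Fraction of valid frames that are active (scalar).
#' @export
active_fraction <- function(series) attr(series, "active_fraction")

#' Was the trial rejected by the inactivity rule?
#' @param series Output of [classify_activity()].
#' @return Logical; when `TRUE` it carries a `reason` attribute.
#' @export
trial_rejected <- function(series) attr(series, "rejected")

#' Write a per-trial kinematics CSV
#'
#' Columns `frame,fish_id,vx,vy,speed,omega,valid,active`, with `valid`
#' being the post-filter kinematic validity mask.
#'
#' @param series Output of [classify_activity()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kinematics <- function(series, path) {
  out <- data.frame(
    frame = series$frame, fish_id = series$fish_id,
    vx = round(series$vx, 4), vy = round(series$vy, 4),
    speed = round(series$speed, 4), omega = round(series$omega, 4),
    valid = as.integer(series$valid_kin),
    active = as.integer(series$active)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
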