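#' Pairwise distance and angle samples
#'
#' For every frame in which both fish of an unordered pair are valid, emits
#' the pair distance `d` (cm) and the pair angle `theta` (rad, in [0, pi]),
#' the angle between the two heading vectors. Frames are taken from the
#' post-filter validity mask when the input is a `kinematic_series`
#' (column `valid_kin`), otherwise from the `valid` flag.
#'
#' @param tab A `trajectory_table` or `kinematic_series` with at least two
#'   fish.
#' @return A data frame `frame, fish_i, fish_j, distance, angle`
#'   (`fish_i < fish_j`). When fewer than two fish are present, an empty
#'   data frame is returned with a warning.
#' @export
pair_samples <- function(tab) {
  mask <- if ("valid_kin" %in% names(tab)) tab$valid_kin else tab$valid
  d <- as.data.frame(tab)[mask & !is.na(tab$x), , drop = FALSE]
  ids <- sort(unique(d$fish_id))
  empty <- data.frame(frame = integer(), fish_i = integer(),
                      fish_j = integer(), distance = numeric(),
                      angle = numeric())
  if (length(ids) < 2L) {
    warning("fewer than two fish: no pair samples", call. = FALSE)
    return(empty)
  }
  per_fish <- split(d, d$fish_id)
  out <- list()
  for (a in seq_along(ids)[-length(ids)]) {
    for (b in (a + 1L):length(ids)) {
      di <- per_fish[[as.character(ids[a])]]
      dj <- per_fish[[as.character(ids[b])]]
      common <- intersect(di$frame, dj$frame)
      if (!length(common)) next
      di <- di[match(common, di$frame), ]
      dj <- dj[match(common, dj$frame), ]
      dist <- sqrt((di$x - dj$x)^2 + (di$y - dj$y)^2)
      # angle between unit heading vectors, robust at the +/-1 boundary
      ang <- acos(pmin(1, pmax(-1, cos(di$heading - dj$heading))))
      out[[length(out) + 1L]] <- data.frame(
        frame = common, fish_i = ids[a], fish_j = ids[b],
        distance = dist, angle = ang)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$frame, res$fish_i, res$fish_j), ]
  rownames(res) <- NULL
  res
}

#' Joint density of pair distance and pair angle (single trial)
#'
#' 2D histogram of `(d, theta)` normalized to a joint probability density:
#' the sum of `density * bin area` over all bins is 1. Distances are binned
#' in cm, angles in degrees.
#'
#' @param samples Output of [pair_samples()].
#' @param dist_edges Distance bin edges in cm (default `seq(0, 112, by 2)`,
#'   covering a 55.5 cm tank's maximal pair distance).
#' @param angle_edges Angle bin edges in degrees (default `seq(0, 180, 5)`).
#' @return A data frame `d_lo, d_hi, theta_lo, theta_hi, density` with
#'   density in (cm * degree)^-1.
#' @export
joint_density <- function(samples,
                          dist_edges = seq(0, 112, by = 2),
                          angle_edges = seq(0, 180, by = 5)) {
  if (!nrow(samples)) stop("no pair samples", call. = FALSE)
  if (length(dist_edges) < 2L || any(diff(dist_edges) <= 0) ||
      length(angle_edges) < 2L || any(diff(angle_edges) <= 0))
    stop("degenerate bin edges", call. = FALSE)
  d <- samples$distance
  a <- samples$angle * 180 / pi
  if (any(d > max(dist_edges)))
    stop("pair distances exceed the distance grid", call. = FALSE)
  id <- findInterval(d, dist_edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  ia <- findInterval(a, angle_edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  nd <- length(dist_edges) - 1L
  na <- length(angle_edges) - 1L
  counts <- matrix(0, nd, na)
  tt <- table(factor(id, levels = 1:nd), factor(ia, levels = 1:na))
  counts[] <- as.numeric(tt)
  grid <- expand.grid(i = 1:nd, j = 1:na)
  w <- diff(dist_edges)[grid$i] * diff(angle_edges)[grid$j]
  data.frame(
    d_lo = dist_edges[grid$i], d_hi = dist_edges[grid$i + 1L],
    theta_lo = angle_edges[grid$j], theta_hi = angle_edges[grid$j + 1L],
    density = counts[cbind(grid$i, grid$j)] / (nrow(samples) * w))
}

#' Wall-following reference arches
#'
#' Two fish swimming parallel to the wall at the same constant wall
#' distance `d_w`, at angular positions separated by `phi` along the tank,
#' sit at pair distance `d = (R - d_w) * sqrt(2 - 2 cos(theta))` when they
#' circle in the same direction (`theta = phi`), and on the
#' `sqrt(2 + 2 cos(theta))` branch when they circle in opposite directions.
#' Overlaying both branches on a pair distance-angle map marks the
#' signature of mutual wall-following.
#'
#' @param R Tank radius in cm.
#' @param d_w Wall distance of the swimmers in cm (`0 <= d_w < R`).
#' @param theta Pair angles in rad (default a fine grid over [0, pi]).
#' @return A data frame `theta, theta_deg, d_minus, d_plus` (cm).
#' @export
#' @examples
#' wall_following_arches(55.5, 4, theta = pi)  # d_minus = 103 cm
wall_following_arches <- function(R, d_w, theta = seq(0, pi, length.out = 181)) {
  if (d_w < 0 || d_w >= R) stop("`d_w` must lie in [0, R)", call. = FALSE)
  rr <- R - d_w
  data.frame(
    theta = theta,
    theta_deg = theta * 180 / pi,
    d_minus = rr * sqrt(pmax(0, 2 - 2 * cos(theta))),
    d_plus = rr * sqrt(pmax(0, 2 + 2 * cos(theta)))
  )
}

#' Close-range pair alignment
#'
#' Restricts the pair samples to pairs closer than `cutoff` (default 10 cm)
#' and returns the probability density of the pair angle over those close
#' pairs together with the order parameter `mean(cos(theta))`: positive
#' values signal a preference for alignment, values near zero no
#' preference, negative values anti-alignment.
#'
#' @param samples Output of [pair_samples()].
#' @param cutoff Distance cutoff in cm.
#' @param angle_bin Angle bin width in degrees (default 5).
#' @return A list with elements `density` (data frame
#'   `theta_lo, theta_hi, density` in degree^-1), `mean_cos` and `n_samples`.
#'   When no pair is within the cutoff, `mean_cos` is `NA` and a warning is
#'   raised (the trial should then be excluded from group statistics).
#' @export
close_range_alignment <- function(samples, cutoff = 10, angle_bin = 5) {
  close <- samples[samples$distance < cutoff, , drop = FALSE]
  if (!nrow(close)) {
    warning("no pair samples within ", cutoff,
            " cm: close-range alignment undefined", call. = FALSE)
    return(list(density = NULL, mean_cos = NA_real_, n_samples = 0L))
  }
  edges <- seq(0, 180, by = angle_bin)
  if (edges[length(edges)] < 180) edges <- c(edges, 180)
  counts <- graphics::hist(close$angle * 180 / pi, breaks = edges,
                           plot = FALSE, right = FALSE,
                           include.lowest = TRUE)$counts
  dens <- data.frame(theta_lo = edges[-length(edges)], theta_hi = edges[-1],
                     density = counts / (nrow(close) * diff(edges)))
  list(density = dens, mean_cos = mean(cos(close$angle)),
       n_samples = nrow(close))
}

#' Schooling summary fractions
#'
#' Fractions of pair samples in close proximity (`d < d_cutoff`, default
#' 15 cm, three body lengths) and aligned (`theta < angle_cutoff`, default
#' 45 degrees). Schooling groups score high on both; shoaling groups only
#' on the first.
#'
#' @param samples Output of [pair_samples()].
#' @param d_cutoff Distance cutoff in cm.
#' @param angle_cutoff Angle cutoff in degrees.
#' @return A list `p_close`, `p_aligned`, `n_samples`.
#' @export
schooling_summary <- function(samples, d_cutoff = 15, angle_cutoff = 45) {
  if (!nrow(samples))
    return(list(p_close = NA_real_, p_aligned = NA_real_, n_samples = 0L))
  list(
    p_close = mean(samples$distance < d_cutoff),
    p_aligned = mean(samples$angle < angle_cutoff * pi / 180),
    n_samples = nrow(samples)
  )
}
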