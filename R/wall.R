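#' Distance to the tank wall
#'
#' For a circular tank of radius `R` centered at the origin, the distance
#' from a point to the wall is `R - |r|`, ranging from 0 (against the wall)
#' to `R` (tank center).
#'
#' @param x,y Positions in cm (tank-centered).
#' @param R Tank radius in cm.
#' @param tol Radial tolerance in cm (default 1e-6).
#' @return Wall distances in cm.
#' @export
#' @examples
#' distance_to_wall(33.3, 44.4, R = 55.5)  # exactly at the wall
distance_to_wall <- function(x, y, R, tol = 1e-6) {
  r <- sqrt(x^2 + y^2)
  if (any(r > R + tol, na.rm = TRUE))
    stop("position outside tank (|r| > R)", call. = FALSE)
  pmax(R - r, 0)
}

#' Nematic alignment with the nearest wall
#'
#' `cos(2 * theta)` where `theta` is the angle between the fish's heading
#' and the normal of the nearest wall (the radial direction). The value is
#' -1 for a fish swimming parallel to the wall, +1 for a fish heading
#' straight at (or away from) the wall, and 0 at 45 degrees. It is nematic:
#' reversing the heading leaves it unchanged.
#'
#' @param heading Headings in rad.
#' @param x,y Positions in cm (tank-centered).
#' @return Values in [-1, 1]; `NA` at the exact tank center, where the wall
#'   normal is undefined.
#' @export
nematic_wall_alignment <- function(heading, x, y) {
  r <- sqrt(x^2 + y^2)
  out <- cos(2 * (heading - atan2(y, x)))
  out[r == 0] <- NA_real_
  out
}

#' Wall-distance density per unit area (single trial)
#'
#' Histogram of wall distances converted to a probability per unit tank
#' area: the count in bin `[s1, s2)` is divided by the trial sample count
#' and by the bin's annulus area `pi * ((R - s1)^2 - (R - s2)^2)`. The
#' area-weighted sum over bins is exactly 1.
#'
#' @param wall_distances Wall distances in cm (one trial).
#' @param R Tank radius in cm.
#' @param bin_width Bin width in cm (default 1).
#' @return A data frame `bin_lo, bin_hi, area, density` (density in cm^-2).
#' @export
density_per_unit_area <- function(wall_distances, R, bin_width = 1) {
  if (bin_width <= 0) stop("`bin_width` must be > 0", call. = FALSE)
  s <- wall_distances[!is.na(wall_distances)]
  if (any(s < 0 | s > R)) stop("wall distances outside [0, R]", call. = FALSE)
  edges <- seq(0, R, by = bin_width)
  if (edges[length(edges)] < R) edges <- c(edges, R)
  counts <- graphics::hist(s, breaks = edges, plot = FALSE,
                           right = FALSE, include.lowest = TRUE)$counts
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  area <- pi * ((R - lo)^2 - (R - hi)^2)
  data.frame(bin_lo = lo, bin_hi = hi, area = area,
             density = counts / (length(s) * area))
}

#' Average per-trial profiles with a standard-error halo
#'
#' Aligns a list of per-trial binned profiles (identical bin edges) and
#' returns the across-trial mean and standard error of the mean for each
#' bin, the way figure curves carry one standard error on either side of
#' the mean.
#'
#' @param profiles List of data frames sharing `bin_lo`/`bin_hi` columns.
#' @param value_col Name of the per-trial value column (default
#'   `"density"`).
#' @return A data frame `bin_lo, bin_hi, mean, sem, n_trials`.
#' @export
average_profiles <- function(profiles, value_col = "density") {
  stopifnot(length(profiles) >= 1L)
  ref <- profiles[[1]]
  for (p in profiles)
    if (!isTRUE(all.equal(p$bin_lo, ref$bin_lo)))
      stop("profiles must share bin edges", call. = FALSE)
  m <- vapply(profiles, function(p) p[[value_col]], numeric(nrow(ref)))
  m <- matrix(m, nrow = nrow(ref))
  n <- ncol(m)
  mu <- rowMeans(m)
  sem <- if (n > 1L) apply(m, 1, stats::sd) / sqrt(n) else rep(NA_real_, nrow(m))
  data.frame(bin_lo = ref$bin_lo, bin_hi = ref$bin_hi,
             mean = mu, sem = sem, n_trials = n)
}

#' Median wall distance and its uniform-density reference
#'
#' The reference is the median wall distance under a spatially uniform
#' density: half of a disc's area lies within `R * (1 - 1/sqrt(2))` of its
#' edge.
#'
#' @param wall_distances Wall distances in cm (one trial).
#' @return Median wall distance in cm.
#' @export
median_wall_distance <- function(wall_distances) {
  s <- wall_distances[!is.na(wall_distances)]
  if (!length(s)) stop("no valid frames: median wall distance undefined",
                       call. = FALSE)
  stats::median(s)
}

#' @rdname median_wall_distance
#' @param R Tank radius in cm.
#' @export
uniform_median_reference <- function(R) R * (1 - 1 / sqrt(2))

#' Fraction of time in the inner half of the tank
#'
#' Share of valid frames spent within `R / sqrt(2)` of the tank center,
#' the radius enclosing half of the tank's area (39.2 cm for R = 55.5 cm).
#'
#' @param x,y Positions in cm (tank-centered); `NA` entries are dropped.
#' @param R Tank radius in cm.
#' @return A fraction in [0, 1].
#' @export
fraction_in_center <- function(x, y, R) {
  r <- sqrt(x^2 + y^2)
  r <- r[!is.na(r)]
  if (!length(r)) return(NA_real_)
  mean(r < R / sqrt(2))
}

#' Radial position uncertainty due to swimming depth
#'
#' Fish filmed from above can swim a few cm above or below the assumed
#' half-depth plane, which biases the apparent radial position by up to
#' `r / 14.2` cm at radial position `r` — zero at the center and 3.9 cm at
#' the wall of a 55.5 cm tank.
#'
#' @param r Radial positions in cm (non-negative).
#' @return Upper bounds on the radial position error, in cm.
#' @export
depth_uncertainty <- function(r) {
  if (any(r < 0, na.rm = TRUE))
    stop("radial position must be non-negative", call. = FALSE)
  r / 14.2
}
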