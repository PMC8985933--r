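#' Speed distribution (single trial)
#'
#' Binned probability density of swimming speed, normalized so the density
#' integrates to 1 over the binned range. With `active_only = TRUE` only
#' frames in the active swimming state (active and outside inactivity
#' buffers, column `active_state`) enter; otherwise all valid frames do,
#' so the zero-speed peak's area equals the inactive fraction.
#'
#' @param series A `kinematic_series` (after [classify_activity()] when
#'   `active_only = TRUE`), or a bare numeric vector of speeds in cm/s.
#' @param bin_width Bin width in cm/s (default 1).
#' @param active_only Restrict to the active swimming state.
#' @param max_speed Upper edge of the binned range (default 100 cm/s).
#' @return A data frame `bin_lo, bin_hi, density` (density in s/cm).
#' @export
speed_distribution <- function(series, bin_width = 1, active_only = FALSE,
                               max_speed = 100) {
  if (is.numeric(series)) {
    v <- series[!is.na(series)]
  } else if (active_only) {
    if (!"active_state" %in% names(series))
      stop("run classify_activity() before active-only distributions",
           call. = FALSE)
    v <- series$speed[series$active_state]
  } else {
    v <- series$speed[series$valid_kin]
  }
  v <- v[!is.na(v)]
  if (!length(v)) stop("no frames to bin", call. = FALSE)
  edges <- seq(0, max(max_speed, max(v) + bin_width), by = bin_width)
  counts <- graphics::hist(v, breaks = edges, plot = FALSE, right = FALSE,
                           include.lowest = TRUE)$counts
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             density = counts / (length(v) * bin_width))
}

#' Mean active swimming speed of a trial
#'
#' @param series Output of [classify_activity()].
#' @return Mean speed (cm/s) over frames in the active swimming state.
#' @export
mean_active_speed <- function(series) {
  v <- series$speed[series$active_state]
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' Group-size trend of per-trial mean speeds
#'
#' Ordinary least-squares regression of per-trial mean (active) speed
#' against group size, the statistic used to detect populations that slow
#' down in larger groups.
#'
#' @param mean_speeds Per-trial mean speeds (cm/s).
#' @param group_sizes Per-trial group sizes (same length).
#' @return An object of class `group_trend`: a list with `slope`, `stderr`,
#'   `p_value`, `intercept`, `n_trials` and the fitted `lm` model. With only
#'   two trials the slope is the exact interpolant and `p_value` is `NA`.
#' @export
#' @examples
#' mean_speed_trend(c(21, 19.6, 18.2), c(1, 2, 3))$slope  # -1.4
mean_speed_trend <- function(mean_speeds, group_sizes) {
  stopifnot(length(mean_speeds) == length(group_sizes))
  ok <- !is.na(mean_speeds) & !is.na(group_sizes)
  mean_speeds <- mean_speeds[ok]
  group_sizes <- group_sizes[ok]
  if (length(unique(group_sizes)) < 2L)
    stop("slope undefined: need at least two distinct group sizes",
         call. = FALSE)
  fit <- stats::lm(mean_speeds ~ group_sizes)
  # degenerate exact fits (e.g. two trials) are legitimate inputs here
  co <- suppressWarnings(summary(fit))$coefficients
  structure(list(
    slope = unname(co["group_sizes", "Estimate"]),
    stderr = unname(co["group_sizes", "Std. Error"]),
    p_value = if (length(mean_speeds) > 2L)
      unname(co["group_sizes", "Pr(>|t|)"]) else NA_real_,
    intercept = unname(co["(Intercept)", "Estimate"]),
    n_trials = length(mean_speeds),
    model = fit
  ), class = "group_trend")
}

#' @export
print.group_trend <- function(x, ...) {
  cat(sprintf("<group_trend> slope = %.3f +/- %.3f cm/s per fish (N = %d, p = %s)\n",
              x$slope, x$stderr, x$n_trials,
              ifelse(is.na(x$p_value), "NA", format.pval(x$p_value))))
  invisible(x)
}

#' Turning-speed density and its rotation-weighted companion (single trial)
#'
#' Probability density of the unsigned turning speed `|omega|` over frames
#' in the active swimming state, plus the rotation-weighted curve
#' `|omega| * p(|omega|)`. Integrating the plain density over a band gives
#' the fraction of time spent turning at those speeds; integrating the
#' weighted curve gives the angle turned per second in that band. The
#' weighted value of each bin uses the within-bin mean of `|omega|`, so its
#' integral equals the trial's mean `|omega|` exactly.
#'
#' @param series A `kinematic_series` after [classify_activity()], or a
#'   bare numeric vector of angular speeds in rad/s.
#' @param bin_width Bin width in rad/s (default 0.25).
#' @param max_turn Upper edge of the binned range (default 30 rad/s).
#' @return A data frame `bin_lo, bin_hi, density, weighted`.
#' @export
turning_density <- function(series, bin_width = 0.25, max_turn = 30) {
  if (is.numeric(series)) {
    w <- abs(series)
  } else {
    if (!"active_state" %in% names(series))
      stop("run classify_activity() before turning distributions",
           call. = FALSE)
    w <- abs(series$omega[series$active_state])
  }
  w <- w[!is.na(w)]
  if (!length(w)) stop("no frames to bin", call. = FALSE)
  edges <- seq(0, max(max_turn, max(w) + bin_width), by = bin_width)
  idx <- findInterval(w, edges, rightmost.closed = TRUE, all.inside = TRUE)
  nb <- length(edges) - 1L
  counts <- tabulate(idx, nbins = nb)
  sums <- vapply(1:nb, function(b) sum(w[idx == b]), numeric(1))
  n <- length(w)
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             density = counts / (n * bin_width),
             weighted = sums / (n * bin_width))
}

#' Time and rotation shares of turning-speed bands
#'
#' Splits the turning-speed axis at the landmark speeds in `edges`
#' (default 0.5 and 3.5 rad/s: nearly straight / gradual turning / quick
#' turning) and integrates the plain and rotation-weighted densities over
#' each band. The time shares sum to 1; the rotation shares sum to the
#' mean unsigned turning speed (total angle turned per second).
#'
#' @param density Output of [turning_density()]. Band edges must fall on
#'   bin edges.
#' @param edges Interior band edges in rad/s.
#' @return A data frame `band, time_share, rotation_share` with bands
#'   `[0, e1)`, `[e1, e2)`, `[e2, Inf)`.
#' @export
turning_band_integrals <- function(density, edges = c(0.5, 3.5)) {
  stopifnot(length(edges) == 2L, diff(edges) > 0)
  cuts <- c(0, edges, Inf)
  bw <- density$bin_hi - density$bin_lo
  band <- findInterval(density$bin_lo, cuts)
  miss <- setdiff(edges, density$bin_lo)
  miss <- miss[miss < max(density$bin_hi)]
  if (length(miss))
    stop("band edges must align with bin edges", call. = FALSE)
  ts <- vapply(1:3, function(b) sum(density$density[band == b] * bw[band == b]),
               numeric(1))
  rs <- vapply(1:3, function(b) sum(density$weighted[band == b] * bw[band == b]),
               numeric(1))
  data.frame(
    band = c(sprintf("[0,%g)", edges[1]),
             sprintf("[%g,%g)", edges[1], edges[2]),
             sprintf("[%g,Inf)", edges[2])),
    time_share = ts, rotation_share = rs)
}
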