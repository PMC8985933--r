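#' Trial metadata
#'
#' Describes one behavioral trial: which population the fish belong to, how
#' many fish were in the tank, the frame rate of the recording, the tank
#' geometry, and the acclimation/analysis time windows.
#'
#' @param population Character label for the population (e.g. `"surface"`,
#'   `"pachon"`, `"tinaja"`, `"molino"`, `"surface_dark"`).
#' @param group_size Number of fish in the tank (positive integer).
#' @param fps Frames per second of the recording. Default 30.
#' @param tank_radius Tank radius in cm. Default 55.5.
#' @param body_length Nominal fish body length in cm, used only when
#'   reporting distances in body lengths. Default 5.
#' @param acclimation_s Seconds of leading video discarded as acclimation.
#'   Default 600 (10 minutes).
#' @param analysis_s Seconds retained after acclimation. Default 1200
#'   (20 minutes).
#'
#' @return An object of class `trial_metadata` (a validated list).
#' @export
#' @examples
#' trial_metadata("surface", group_size = 2)
trial_metadata <- function(population,
                           group_size,
                           fps = 30,
                           tank_radius = 55.5,
                           body_length = 5,
                           acclimation_s = 600,
                           analysis_s = 1200) {
  stopifnot(is.character(population), length(population) == 1L)
  group_size <- as.integer(group_size)
  if (is.na(group_size) || group_size < 1L)
    stop("`group_size` must be a positive integer", call. = FALSE)
  if (!is.numeric(fps) || fps <= 0)
    stop("`fps` must be > 0", call. = FALSE)
  if (!is.numeric(tank_radius) || tank_radius <= 0)
    stop("`tank_radius` must be > 0", call. = FALSE)
  if (!is.numeric(acclimation_s) || acclimation_s < 0)
    stop("`acclimation_s` must be >= 0", call. = FALSE)
  if (!is.numeric(analysis_s) || analysis_s <= 0)
    stop("`analysis_s` must be > 0", call. = FALSE)
  structure(
    list(
      population = population,
      group_size = group_size,
      fps = fps,
      tank_radius = tank_radius,
      body_length = body_length,
      acclimation_s = acclimation_s,
      analysis_s = analysis_s
    ),
    class = "trial_metadata"
  )
}

#' @export
print.trial_metadata <- function(x, ...) {
  cat(sprintf(
    "<trial_metadata> population=%s n=%d fps=%g R=%g cm (acclimation %gs, analysis %gs)\n",
    x$population, x$group_size, x$fps, x$tank_radius, x$acclimation_s,
    x$analysis_s
  ))
  invisible(x)
}

#' Analysis run configuration
#'
#' Collects every filtering threshold and binning choice used by the analysis
#' modules. All values have defaults; override individual entries as needed.
#'
#' Thresholds:
#' \describe{
#'   \item{max_speed}{Tracking-error speed cutoff, cm/s (default 100).}
#'   \item{max_turn}{Tracking-error turning-speed cutoff, rad/s (default 30).}
#'   \item{buffer_frames}{Frames invalidated on each side of an excluded
#'     event (default 3).}
#'   \item{activity_threshold}{Speed separating active from inactive frames,
#'     cm/s (default 1).}
#'   \item{trial_inactivity_limit}{A trial whose active fraction falls below
#'     this value is rejected outright (default 0.5).}
#' }
#' Binning and cutoffs:
#' \describe{
#'   \item{wall_bin_width}{Wall-distance profile bin width, cm (default 1).}
#'   \item{speed_bin_width}{Speed distribution bin width, cm/s (default 1).}
#'   \item{turn_bin_width}{Turning-speed bin width, rad/s (default 0.25).}
#'   \item{pair_dist_bin}{Pair-distance bin width, cm (default 2).}
#'   \item{pair_angle_bin}{Pair-angle bin width, degrees (default 5).}
#'   \item{close_range_cutoff}{Pair distance below which the close-range
#'     alignment statistic is computed, cm (default 10).}
#'   \item{school_dist_cutoff}{Pair distance defining "in close proximity",
#'     cm (default 15).}
#'   \item{school_angle_cutoff}{Pair angle defining "aligned", degrees
#'     (default 45).}
#'   \item{turn_band_edges}{Turning-speed landmarks separating straight /
#'     gradual / quick turning, rad/s (default `c(0.5, 3.5)`).}
#' }
#'
#' @param ... Named overrides of the defaults listed above, plus `seed`
#'   (integer, default 1).
#'
#' @return An object of class `run_config` (a validated list).
#' @export
#' @examples
#' cfg <- run_config(wall_bin_width = 2)
#' cfg$max_speed
run_config <- function(...) {
  defaults <- list(
    max_speed = 100,
    max_turn = 30,
    buffer_frames = 3L,
    activity_threshold = 1,
    trial_inactivity_limit = 0.5,
    wall_bin_width = 1,
    speed_bin_width = 1,
    turn_bin_width = 0.25,
    pair_dist_bin = 2,
    pair_angle_bin = 5,
    close_range_cutoff = 10,
    school_dist_cutoff = 15,
    school_angle_cutoff = 45,
    turn_band_edges = c(0.5, 3.5),
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown run_config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, over)
  pos <- c("max_speed", "max_turn", "activity_threshold",
           "trial_inactivity_limit", "wall_bin_width", "speed_bin_width",
           "turn_bin_width", "pair_dist_bin", "pair_angle_bin",
           "close_range_cutoff", "school_dist_cutoff", "school_angle_cutoff")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || any(cfg[[f]] <= 0))
      stop("`", f, "` must be strictly positive", call. = FALSE)
  cfg$buffer_frames <- as.integer(cfg$buffer_frames)
  if (cfg$buffer_frames < 0L)
    stop("`buffer_frames` must be >= 0", call. = FALSE)
  if (length(cfg$turn_band_edges) != 2L ||
      any(cfg$turn_band_edges <= 0) || diff(cfg$turn_band_edges) <= 0)
    stop("`turn_band_edges` must be two increasing positive values",
         call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The file is a flat key-value mapping; every key is optional and fills in
#' over the [run_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(run_config, vals)
}
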