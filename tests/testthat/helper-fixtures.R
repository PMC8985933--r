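# shared fixture shorthands

fixture_md <- function(n = 1L, fps = 30, R = 55.5, acclimation_s = 0,
                       analysis_s = 60, population = "fixture") {
  trial_metadata(population, n, fps = fps, tank_radius = R,
                 acclimation_s = acclimation_s, analysis_s = analysis_s)
}

# straight swimmer with an occlusion (valid = FALSE) at given frames
straight_with_occlusion <- function(occluded_frames, v = 20, duration_s = 5) {
  tab <- make_straight(v, duration_s = duration_s)
  tab$valid[tab$frame %in% occluded_frames] <- FALSE
  tab
}

# uniform random points on a disc of radius R
runif_disc <- function(n, R) {
  r <- R * sqrt(stats::runif(n))
  a <- stats::runif(n, 0, 2 * pi)
  list(x = r * cos(a), y = r * sin(a), r = r)
}
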