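#' Trajectory tables
#'
#' A trajectory table is the universal input of the analysis pipeline: one
#' row per (frame, fish), with tank-centered coordinates in cm, a heading in
#' radians measured counterclockwise from the +x axis and wrapped to
#' (-pi, pi], and a validity flag. Invalid rows (e.g. occlusions reported by
#' the tracker) keep their (frame, fish) key with `NA` pose fields so that
#' downstream buffer-frame logic can see the gaps.
#'
#' @param frame Integer frame indices (0-based; time of frame i is i/fps s).
#' @param fish_id Integer fish identifiers.
#' @param x,y Positions in cm, origin at the tank center.
#' @param heading Heading angles in rad, in (-pi, pi].
#' @param valid Logical validity flags (default all `TRUE`).
#' @param metadata A [trial_metadata()] object.
#'
#' @return A data frame of class `trajectory_table` with columns
#'   `frame, fish_id, x, y, heading, valid` and the metadata stored in
#'   attribute `"metadata"`, sorted by (frame, fish_id).
#' @export
#' @examples
#' md <- trial_metadata("surface", 1, acclimation_s = 0)
#' trajectory_table(0:2, rep(0L, 3), c(0, 1, 2), c(0, 0, 0),
#'                  rep(0, 3), metadata = md)
trajectory_table <- function(frame, fish_id, x, y, heading,
                             valid = rep(TRUE, length(frame)),
                             metadata) {
  stopifnot(inherits(metadata, "trial_metadata"))
  tab <- data.frame(
    frame = as.integer(frame),
    fish_id = as.integer(fish_id),
    x = as.numeric(x),
    y = as.numeric(y),
    heading = as.numeric(heading),
    valid = as.logical(valid)
  )
  tab <- tab[order(tab$frame, tab$fish_id), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("trajectory_table", "data.frame")
  attr(tab, "metadata") <- metadata
  validate_trajectory_table(tab)
  tab
}

#' @rdname trajectory_table
#' @param tab A candidate trajectory table.
#' @param tol Radial tolerance in cm for the in-tank check (default 1e-6).
#' @export
validate_trajectory_table <- function(tab, tol = 1e-6) {
  md <- attr(tab, "metadata")
  stopifnot(inherits(md, "trial_metadata"))
  need <- c("frame", "fish_id", "x", "y", "heading", "valid")
  if (!all(need %in% names(tab)))
    stop("trajectory table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab[c("frame", "fish_id")]))
    stop("duplicate (frame, fish_id) pairs", call. = FALSE)
  v <- which(tab$valid)
  if (length(v)) {
    bad <- v[is.na(tab$x[v]) | is.na(tab$y[v]) | is.na(tab$heading[v])]
    if (length(bad))
      stop("valid rows with missing pose fields (first: row ", bad[1], ")",
           call. = FALSE)
    r <- sqrt(tab$x[v]^2 + tab$y[v]^2)
    out <- which(r > md$tank_radius + tol)
    if (length(out))
      stop(sprintf(
        "position outside tank: |r| = %.3f cm > R = %.3f cm at frame %d, fish %d",
        r[out[1]], md$tank_radius, tab$frame[v[out[1]]],
        tab$fish_id[v[out[1]]]), call. = FALSE)
    h <- tab$heading[v]
    if (any(h <= -pi - 1e-9 | h > pi + 1e-9))
      stop("headings must lie in (-pi, pi]", call. = FALSE)
  }
  frames <- sort(unique(tab$frame))
  if (length(frames) > 2L && length(unique(diff(frames))) != 1L)
    stop("non-uniform frame spacing", call. = FALSE)
  invisible(tab)
}

#' @export
print.trajectory_table <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf(
    "<trajectory_table> %d rows, %d fish, %d frames (%s, %g fps)\n",
    nrow(x), length(unique(x$fish_id)), length(unique(x$frame)),
    md$population, md$fps))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

# wrap an angle (or vector of angles) into (-pi, pi]
wrap_angle <- function(a) {
  w <- a - 2 * pi * floor((a + pi) / (2 * pi))
  w[w <= -pi] <- pi   # map the branch point to +pi, keeping (-pi, pi]
  w
}

#' Read a trajectory CSV
#'
#' Reads tracker output in the package's CSV dialect (comma-separated,
#' mandatory header `frame,fish_id,x_cm,y_cm,heading_rad,valid`; empty pose
#' fields allowed only when `valid` is 0), drops the acclimation window, and
#' retains at most `analysis_s` seconds after it.
#'
#' @param path Path to the CSV file.
#' @param metadata A [trial_metadata()] object; its `acclimation_s`, `fps`
#'   and `analysis_s` fields define the analysis window, and `tank_radius`
#'   is enforced on valid rows.
#' @return A `trajectory_table`.
#' @export
read_trajectories <- function(path, metadata) {
  stopifnot(inherits(metadata, "trial_metadata"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("frame", "fish_id", "x_cm", "y_cm", "heading_rad", "valid")
  if (!identical(names(raw), need))
    stop("bad header in ", path, ": expected ",
         paste(need, collapse = ","), call. = FALSE)
  num <- function(col, name, allow_empty = FALSE) {
    empty <- raw[[col]] == "" | is.na(raw[[col]])
    out <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(out) & !empty)
    if (length(bad))
      stop(sprintf("malformed %s at line %d of %s", name, bad[1] + 1L, path),
           call. = FALSE)
    if (!allow_empty && any(empty))
      stop(sprintf("empty %s at line %d of %s", name,
                   which(empty)[1] + 1L, path), call. = FALSE)
    out
  }
  frame <- num("frame", "frame index")
  fish <- num("fish_id", "fish id")
  valid <- num("valid", "validity flag")
  if (!all(valid %in% c(0, 1)))
    stop("valid column must be 0 or 1 in ", path, call. = FALSE)
  x <- num("x_cm", "x coordinate", allow_empty = TRUE)
  y <- num("y_cm", "y coordinate", allow_empty = TRUE)
  h <- num("heading_rad", "heading", allow_empty = TRUE)
  pose_missing <- is.na(x) | is.na(y) | is.na(h)
  if (any(pose_missing & valid == 1)) {
    i <- which(pose_missing & valid == 1)[1]
    stop(sprintf("empty pose fields on valid row at line %d of %s",
                 i + 1L, path), call. = FALSE)
  }
  first <- ceiling(metadata$acclimation_s * metadata$fps)
  last <- first + metadata$analysis_s * metadata$fps  # exclusive
  keep <- frame >= first & frame < last
  trajectory_table(frame[keep], fish[keep], x[keep], y[keep], h[keep],
                   valid[keep] == 1, metadata = metadata)
}

#' Write a trajectory CSV
#'
#' Inverse of [read_trajectories()] (with `acclimation_s = 0`): positions and
#' headings are stored with 4 decimals (below tracking noise), and invalid
#' rows keep empty pose fields.
#'
#' @param tab A `trajectory_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(tab, path) {
  validate_trajectory_table(tab)
  fmt <- function(z) ifelse(is.na(z), "", sprintf("%.4f", z))
  out <- data.frame(
    frame = tab$frame,
    fish_id = tab$fish_id,
    x_cm = fmt(tab$x),
    y_cm = fmt(tab$y),
    heading_rad = fmt(tab$heading),
    valid = as.integer(tab$valid)
  )
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write trajectory file ", path, ": ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Combine several single- or multi-fish trajectory tables
#'
#' Fish ids must be disjoint; all tables must share frame indices and
#' metadata geometry. Used to assemble multi-fish fixtures from single-fish
#' generators.
#'
#' @param ... `trajectory_table` objects.
#' @param metadata Optional replacement metadata (e.g. to set `group_size`);
#'   defaults to the first table's metadata with `group_size` set to the
#'   total number of fish.
#' @return A `trajectory_table`.
#' @export
combine_trajectories <- function(..., metadata = NULL) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1L)
  ids <- unlist(lapply(tabs, function(t) unique(t$fish_id)))
  if (anyDuplicated(ids))
    stop("fish ids must be disjoint across tables", call. = FALSE)
  if (is.null(metadata)) {
    metadata <- attr(tabs[[1]], "metadata")
    metadata$group_size <- length(ids)
  }
  all <- do.call(rbind, lapply(tabs, as.data.frame))
  trajectory_table(all$frame, all$fish_id, all$x, all$y, all$heading,
                   all$valid, metadata = metadata)
}
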