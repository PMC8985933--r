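#' Compare per-trial values to a reference constant
#'
#' Normality-gated one-sample comparison: a Shapiro-Wilk test at
#' `alpha = 0.05` selects a one-sample t-test against the reference when
#' normality is not rejected, and a Wilcoxon signed-rank test otherwise.
#'
#' @param values Per-trial values (>= 3).
#' @param reference Reference constant.
#' @param alpha Normality-test level (default 0.05).
#' @return A list `test` ("t" or "wilcoxon"), `shapiro_p`, `statistic`,
#'   `p_value`, `n`.
#' @export
compare_to_reference <- function(values, reference, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3L)
    stop("need at least 3 trials for a reference comparison", call. = FALSE)
  if (stats::sd(values) == 0) {
    # degenerate sample: no spread, nothing to test
    return(list(test = "degenerate", shapiro_p = NA_real_,
                statistic = NA_real_,
                p_value = if (values[1] == reference) 1 else 0,
                n = length(values)))
  }
  sh <- stats::shapiro.test(values)$p.value
  if (sh >= alpha) {
    tt <- stats::t.test(values, mu = reference)
    list(test = "t", shapiro_p = sh, statistic = unname(tt$statistic),
         p_value = tt$p.value, n = length(values))
  } else {
    wt <- stats::wilcox.test(values, mu = reference, exact = FALSE)
    list(test = "wilcoxon", shapiro_p = sh, statistic = unname(wt$statistic),
         p_value = wt$p.value, n = length(values))
  }
}

# Games-Howell pairwise comparisons: Welch-type pairwise tests with
# studentized-range adjustment; does not assume equal variances or sizes.
games_howell <- function(values, groups) {
  g <- split(values, groups)
  k <- length(g)
  m <- vapply(g, mean, numeric(1))
  v <- vapply(g, stats::var, numeric(1))
  n <- vapply(g, length, numeric(1))
  combs <- utils::combn(names(g), 2)
  out <- data.frame(group1 = combs[1, ], group2 = combs[2, ],
                    diff = NA_real_, statistic = NA_real_, df = NA_real_,
                    p_adj = NA_real_)
  for (i in seq_len(ncol(combs))) {
    a <- combs[1, i]; b <- combs[2, i]
    se2 <- v[a] / n[a] + v[b] / n[b]
    t <- (m[a] - m[b]) / sqrt(se2)
    df <- se2^2 / ((v[a] / n[a])^2 / (n[a] - 1) + (v[b] / n[b])^2 / (n[b] - 1))
    out$diff[i] <- unname(m[a] - m[b])
    out$statistic[i] <- unname(t)
    out$df[i] <- unname(df)
    out$p_adj[i] <- stats::ptukey(abs(t) * sqrt(2), k, df,
                                  lower.tail = FALSE)
  }
  out
}

#' Compare per-trial values across populations
#'
#' Runs one of the two standard batteries over a grouped set of per-trial
#' scalars: the parametric one (one-way ANOVA omnibus followed by Tukey HSD
#' pairwise comparisons) or the nonparametric one (Kruskal-Wallis omnibus
#' followed by Games-Howell pairwise comparisons). Groups with fewer than 3
#' trials are excluded with a warning.
#'
#' @param values Per-trial values.
#' @param groups Group labels (same length).
#' @param method `"parametric"` or `"nonparametric"`.
#' @return A list `method`, `omnibus` (list `test, statistic, p_value`),
#'   `pairwise` (data frame with adjusted p-values), `n_per_group`.
#' @export
compare_groups <- function(values, groups,
                           method = c("parametric", "nonparametric")) {
  method <- match.arg(method)
  ok <- !is.na(values)
  values <- values[ok]
  groups <- as.character(groups)[ok]
  sizes <- table(groups)
  small <- names(sizes)[sizes < 3L]
  if (length(small)) {
    warning("excluding groups with fewer than 3 trials: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !groups %in% small
    values <- values[keep]
    groups <- groups[keep]
  }
  if (length(unique(groups)) < 2L)
    stop("need at least two groups with >= 3 trials", call. = FALSE)
  gf <- factor(groups)
  if (method == "parametric") {
    fit <- stats::aov(values ~ gf)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$gf
    pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    pairwise <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                           diff = tk[, "diff"], p_adj = tk[, "p adj"],
                           row.names = NULL)
    omnibus <- list(test = "anova", statistic = an[["F value"]][1],
                    p_value = an[["Pr(>F)"]][1])
  } else {
    kw <- stats::kruskal.test(values, gf)
    pairwise <- games_howell(values, groups)
    omnibus <- list(test = "kruskal-wallis",
                    statistic = unname(kw$statistic), p_value = kw$p.value)
  }
  list(method = method, omnibus = omnibus, pairwise = pairwise,
       n_per_group = as.list(table(gf)))
}

#' Analyze one trial end to end
#'
#' Runs the full per-trial chain: kinematics, tracking-error filtering,
#' activity classification, wall metrics, pair metrics (for groups of two
#' or more) and speed/turning summaries.
#'
#' @param tab A [trajectory_table()].
#' @param config A [run_config()].
#' @return A list with elements `metrics` (one-row data frame of scalar
#'   summaries), `series` (the classified `kinematic_series`), `profiles`
#'   (wall-distance density, turning density), `pair` (pair metrics or
#'   `NULL` for single fish), `rejected`, and `filter_log` (frame counts
#'   per filtering rule).
#' @export
analyze_trial <- function(tab, config = run_config()) {
  md <- attr(tab, "metadata")
  kin <- compute_kinematics(tab)
  n_defined <- sum(kin$valid_kin)
  filt <- apply_validity_filters(kin, config)
  n_after <- sum(filt$valid_kin)
  ser <- classify_activity(filt, config)
  rejected <- trial_rejected(ser)
  ok <- ser$valid_kin & !is.na(ser$x)
  wd <- distance_to_wall(ser$x[ok], ser$y[ok], md$tank_radius)
  metrics <- data.frame(
    population = md$population,
    group_size = md$group_size,
    n_frames = length(unique(tab$frame)),
    active_fraction = active_fraction(ser),
    mean_active_speed = mean_active_speed(ser),
    median_wall_distance = if (length(wd)) median_wall_distance(wd) else NA,
    fraction_in_center = fraction_in_center(ser$x[ok], ser$y[ok],
                                            md$tank_radius),
    mean_abs_turning = mean(abs(ser$omega[ser$active_state]), na.rm = TRUE),
    mean_cos_theta = NA_real_,
    p_close = NA_real_,
    p_aligned = NA_real_
  )
  profiles <- list(
    wall_density = density_per_unit_area(wd, md$tank_radius,
                                         config$wall_bin_width),
    speed = speed_distribution(ser, config$speed_bin_width,
                               active_only = FALSE),
    turning = if (any(ser$active_state))
      turning_density(ser, config$turn_bin_width) else NULL
  )
  pair <- NULL
  if (md$group_size >= 2L) {
    samples <- pair_samples(ser)
    if (nrow(samples)) {
      cra <- close_range_alignment(samples, config$close_range_cutoff,
                                   config$pair_angle_bin)
      ss <- schooling_summary(samples, config$school_dist_cutoff,
                              config$school_angle_cutoff)
      metrics$mean_cos_theta <- cra$mean_cos
      metrics$p_close <- ss$p_close
      metrics$p_aligned <- ss$p_aligned
      pair <- list(samples = samples, close_range = cra, schooling = ss)
    }
  }
  list(metrics = metrics, series = ser, profiles = profiles, pair = pair,
       rejected = rejected,
       filter_log = data.frame(
         rows_in = nrow(tab),
         frames_with_kinematics = n_defined,
         removed_by_filters = n_defined - n_after,
         frames_analyzed = n_after))
}

#' Run the analysis pipeline over a set of trials
#'
#' Applies [analyze_trial()] to every input (trajectory tables, file paths
#' read with [read_trajectories()], or simulation outputs from
#' [run_simulation()]) and assembles the per-trial metrics into a report.
#' Trials rejected by the inactivity rule are kept in the table with
#' `rejected = TRUE` but excluded from group statistics. The report is
#' invariant to the ordering of the inputs.
#'
#' @param inputs A list whose elements are `trajectory_table` objects,
#'   file paths (requires `metadata`), or [run_simulation()] results.
#' @param config A [run_config()].
#' @param metadata Optional list of [trial_metadata()] parallel to
#'   `inputs`, required for file-path inputs.
#' @param out_dir Optional directory; when given, the metrics table is
#'   written as `metrics.csv` and a JSON summary as `report.json`.
#' @return A list of class `metrics_report`: `trials` (data frame, one row
#'   per trial, sorted by population, group size and trial id), `details`
#'   (per-trial [analyze_trial()] outputs), `filter_log`.
#' @export
run_pipeline <- function(inputs, config = run_config(), metadata = NULL,
                         out_dir = NULL) {
  if (!length(inputs)) {
    message("no inputs: empty report")
    return(structure(list(trials = data.frame(), details = list(),
                          filter_log = data.frame()),
                     class = "metrics_report"))
  }
  tabs <- lapply(seq_along(inputs), function(i) {
    inp <- inputs[[i]]
    if (inherits(inp, "trajectory_table")) return(inp)
    if (is.list(inp) && !is.null(inp$trajectory)) return(inp$trajectory)
    if (is.character(inp)) {
      if (is.null(metadata) || length(metadata) < i)
        stop("file-path inputs require `metadata`", call. = FALSE)
      return(read_trajectories(inp, metadata[[i]]))
    }
    stop("cannot interpret input ", i, call. = FALSE)
  })
  details <- lapply(seq_along(tabs), function(i) {
    res <- tryCatch(analyze_trial(tabs[[i]], config), error = function(e)
      stop("trial ", i, " failed during analysis: ", conditionMessage(e),
           call. = FALSE))
    res$metrics$trial <- i
    res$metrics$rejected <- isTRUE(as.logical(res$rejected))
    res
  })
  trials <- do.call(rbind, lapply(details, `[[`, "metrics"))
  ord <- order(trials$population, trials$group_size, trials$trial)
  trials <- trials[ord, , drop = FALSE]
  rownames(trials) <- NULL
  logs <- do.call(rbind, lapply(details, `[[`, "filter_log"))[ord, ,
                                                              drop = FALSE]
  rownames(logs) <- NULL
  report <- structure(list(trials = trials, details = details[ord],
                           filter_log = logs),
                      class = "metrics_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(trials, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(n_trials = nrow(trials),
           n_rejected = sum(trials$rejected),
           trials = trials),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
  }
  report
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d trials (%d rejected)\n",
              nrow(x$trials), sum(x$trials$rejected)))
  if (nrow(x$trials)) print(x$trials[, c(
    "trial", "population", "group_size", "active_fraction",
    "mean_active_speed", "median_wall_distance", "fraction_in_center",
    "rejected")], digits = 4)
  invisible(x)
}
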