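#!/usr/bin/env Rscript
# Thin shell entry point over run_simulation(): simulate a group of model
# fish and write the trajectory CSV plus a JSON summary.
#
#   Rscript scripts/simulate.R --n 1 --v0 21 --ka 0 --duration 2000 \
#       --discard 500 --seed 1 --out traj.csv --summary summary.json
#
# Any omitted flag keeps the sim_params() default.

suppressPackageStartupMessages(library(schoolkin))

args <- commandArgs(trailingOnly = TRUE)
val <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1]
}
num <- function(flag, default) as.numeric(val(flag, default))

p <- sim_params(
  v0 = num("--v0", 21), D_r = num("--dr", 0.2),
  k_w = num("--kw", 100), r_w = num("--rw", 2.5),
  k_wt = num("--kwt", 0.83), r_wt = num("--rwt", 5),
  k_a = num("--ka", 0), r_a = num("--ra", 2.5),
  R = num("--R", 55.5), n_fish = num("--n", 1),
  dt = num("--dt", 0.005),
  duration = num("--duration", 20000), discard = num("--discard", 5000),
  out_fps = num("--out-fps", 30))
seed <- as.integer(num("--seed", 1))
out <- val("--out", "trajectory.csv")
summary_path <- val("--summary", NA)

sim <- run_simulation(p, seed = seed)
write_trajectories(sim$trajectory, out)
message("wrote ", out)

if (!is.na(summary_path)) {
  ser <- classify_activity(apply_validity_filters(
    compute_kinematics(sim$trajectory), run_config()), run_config())
  jsonlite::write_json(
    list(seed = seed, n_fish = p$n_fish, v0 = p$v0, k_a = p$k_a,
         fraction_in_center = sim$fraction_in_center,
         mean_active_speed = mean_active_speed(ser),
         active_fraction = active_fraction(ser)),
    summary_path, auto_unbox = TRUE, digits = NA)
  message("wrote ", summary_path)
}
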