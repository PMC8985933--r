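---
title: "Quantifying social swimming in a circular tank: methods and model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying social swimming in a circular tank: methods and model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schoolkin)
```

## Scope

`schoolkin` quantifies how fish swim together — or fail to — in a circular
tank filmed from above. It takes per-frame, per-fish poses (tank-centered
`x`, `y` in cm, heading in rad, validity flag) as produced by a video
tracker, and computes the kinematic, wall-relative, and pairwise statistics
used to characterize schooling, shoaling, wall-following (thigmotaxis) and
activity. Alongside the analysis it provides a data-driven
active-Brownian-particle (ABP) swimmer model that reproduces the
wall-centric exploration statistics of a single fish and lets one ask what
behavioral changes (slower swimming, evasive turns) do to the way fish
explore the tank. Video acquisition and tracking are out of scope; synthetic
generators stand in for tracker output in all tests.

## Kinematics and filtering

Velocities are second-order central finite differences,
$v_{x,i} = (x_{i+1} - x_{i-1}) / (2\Delta t)$, with $\Delta t = 1/\mathrm{fps}$.
Angular speed uses the same stencil after wrapping the heading difference
into $(-\pi, \pi]$, so crossings of the $\pm\pi$ branch cut never produce
spurious $2\pi$ jumps. Derivatives are undefined at the endpoints of each
contiguous run of valid frames.

Tracking glitches show up as impossible kinematics. Frames with speed above
100 cm/s or turning speed above 30 rad/s are excluded, along with the three
frames before and after each event; occlusions flagged by the tracker get
the same buffer. The cut applies per fish — the same frames remain usable
for the other fish. Filtering only alters the validity mask, never the
stored values, which makes it idempotent.

A fish is *active* when moving faster than 1 cm/s, the consistent location
of the base of the zero-speed peak in speed distributions. The per-trial
active fraction is computed on the raw (unbuffered) mask; downstream
swimming-state statistics additionally drop three frames on each side of
every inactive interval. A trial with more than half of its frames inactive
is rejected outright.

## Wall and pair statistics

With the origin at the tank center, the wall distance is simply $R - |r|$
and profiles of density *per unit area* divide bin counts by the annulus
area $\pi[(R-s_1)^2 - (R-s_2)^2]$, so a spatially uniform fish gives a flat
profile at $1/(\pi R^2)$. Orientation relative to the wall is summarized by
the nematic parameter $\cos 2\theta$ ($\theta$ = angle between heading and
the local wall normal): $-1$ is wall-parallel, $+1$ wall-normal, and the
statistic ignores head/tail polarity. Two scalar landmarks come directly
from the area measure of the disc: half of the tank's area lies within
$R(1 - 1/\sqrt 2) \approx 16.3$ cm of the wall (the uniform-density median
wall distance) and within $R/\sqrt 2 \approx 39.2$ cm of the center (the
"inner half" used for the fraction-in-center). Because the fish can swim a
few cm above or below the assumed half-depth plane, apparent radial
positions carry a bound error of $r/14.2$ — up to 3.9 cm at the wall, zero
at the center; we report the bound and do not attempt a correction.

Pairwise structure is summarized by the joint density of pair distance $d$
and pair angle $\theta = \arccos(\hat e_i \cdot \hat e_j) \in [0, \pi]$.
Schooling shows up as a peak at small $d$ and small $\theta$; shoaling as a
band at small $d$ spanning all angles. Two fish that both follow the wall
at distance $d_w$ trace the closed-form arches
$d = (R - d_w)\sqrt{2 \pm 2\cos\theta}$ (minus branch when co-rotating,
plus when counter-rotating), which we overlay as reference curves. The
close-range alignment order parameter $\langle\cos\theta\rangle$ over pairs
within 10 cm separates aligned swimming (positive) from indifference
(near zero); group-level statistics use per-trial means as the unit of
replication.

## Binning choices

The sources describing this assay do not state bin widths, so the package
fixes them once: 1 cm for wall-distance profiles (resolves a 2–5 cm wall
peak from a 7 cm one), 1 cm/s for speed, 0.25 rad/s for turning speed
(aligns with the 0.5 and 3.5 rad/s band landmarks), and 2 cm × 5° for the
pair maps (resolves a schooling peak confined to d < 15 cm, θ < 45°). The
rotation-weighted turning curve stores per-bin means of $|\omega|$ times
the density, so its integral equals the trial's mean $|\omega|$ to machine
precision rather than to binning accuracy. Turning-band integrals therefore
split time shares and rotation shares exactly at 0.5 and 3.5 rad/s.

## The swimmer model

Each model fish obeys

$$\dot{\mathbf r}_i = v_0 \hat e_i + \mu \mathbf F^w_i, \qquad
\dot\theta_i = \eta_i(t) + \mu_r\Big(\tau^w_i + \sum_j \tau^a_{ij}\Big),$$

with white rotational noise of variance $2 D_r \delta(t - t')$. The wall
exerts a soft elastic force $k_w(R - r_w - |r_i|)\hat r_i$ inside range
$r_w$, and a torque $k_{wt}(\hat e_i \cdot \hat r_i)(\hat e_i \times \hat
r_i)(R - r_{wt} - |r_i|)$ that acts only on fish within $r_{wt}$ of the
wall *and* moving towards it; the dot–cross structure makes both
wall-parallel orientations attracting without favoring a chirality.
Evasive maneuvers add $\tau^a_{ij} = k_a (\hat r_{ij} \times \hat e_i)(r_a
- |r_{ij}|)$ for neighbors within $r_a$, which turns fish $i$ away from
fish $j$. The printed dot–cross forms leave the orientation of the 2D cross
product implicit; the package fixes both signs by the stability
requirements (wall-parallel attracting for the wall torque, facing-away
attracting for avoidance) and locks them with deterministic relaxation
tests. Mobilities are set to $\mu = \mu_r = 1$: all interaction strengths
were calibrated directly to behavior, which makes separate mobilities
redundant scale factors.

Defaults are the calibrated values: $v_0 = 21$ cm/s (isolated-fish mean
active speed), $D_r = 0.2$ rad²/s, $k_w = 100$, $r_w = 2.5$ cm, $k_{wt} =
0.83$, $r_{wt} = 5$ cm, $r_a = 2.5$ cm, $R = 55.5$ cm, integrated by
Euler–Maruyama with $dt = 0.005$ s (heading increments
$\sqrt{2 D_r\, dt}\,\mathcal N(0,1)$, the standard consistent
discretization of the stated noise). With these values an isolated model
fish spends about 13% of its time in the inner half of the tank; the
alternate wall-alignment pair $k_{wt} = 0.2, r_{wt} = 10$ changes this by
under three percentage points. Fish start at a random point along the wall,
a distance $r_w$ from it, parallel to the wall with chirality drawn
uniformly — the chirality is unstated in the model's description, and the
uniform draw preserves the nematic symmetry. All randomness of a run flows
from one seed, and runs are bit-reproducible.

A dynamical detail worth knowing: a noiseless fish gliding along the wall
does not align *exactly* wall-parallel. Following the circular wall
requires a sustained angular rate of about $v_0/R \approx 0.4$ rad/s, which
the wall torque can only supply at a small outward tilt; the steady nematic
alignment is therefore near $-0.93$ rather than $-1$. Likewise a simulated
fish occasionally drops below the 1 cm/s activity threshold while turning
at the wall, so simulated active fractions are slightly below 1.

### Estimating $D_r$

The angular diffusion constant is the initial decay rate of the heading
autocorrelation $C(\tau) = \langle\hat e(t) \cdot \hat e(t+\tau)\rangle
\approx 1 - D_r\tau$ at short lags. The estimator regresses
$-\log C(\tau)$ on $\tau$ through the origin over lags up to 1 s: identical
to fitting the linear form at small lags, but unbiased over the whole
window when the decay is exponential, as it is for rotational diffusion.
(Fitting $1 - D_r\tau$ directly over a 1 s window underestimates $D_r$ by
$\approx 3 D_r/8$ in relative terms — 17% at $D_r = 0.5$ — purely from the
curvature of the exponential.) For tank data the estimate is restricted to
frames in the central half so wall torques do not contaminate the
decorrelation; at least 100 s of usable trajectory are required.

### Protocol sizes

The package's own validation runs use 20 replicates of 20,000 time units
(5,000 discarded) for the single-fish calibration and speed sweep, and
25,000 time units per point with 2–3 seeds for the ten-fish avoidance
sweep. Longer runs shrink the seed-to-seed spread of the fraction-in-center
(about 0.005 at these sizes) but do not move the means; the defaults keep a
full validation pass to a few minutes on one core.

## What the synthetic generators do and do not show

The fixture generators emulate the *statistical structure the analysis
assumes*: wall-following circular swimmers (delta wall-distance density,
alignment $-1$, exact arch geometry), stop-go swimmers with a prescribed
duty cycle (activity fractions by construction), straight-line and rigid
pair motion (single-point pair maps), and free active-Brownian walkers with
known $D_r$ (autocorrelation and MSD closed forms). Passing tests on these
fixtures establishes that the estimators compute what they claim on inputs
with known truth. They do not establish anything about real fish — real
trajectories have correlated tracking noise, occlusion patterns that
cluster near fish encounters, body-axis headings that deviate from velocity
directions during turns (fixture headings are velocity directions), and
inter-fish interactions richer than the avoidance torque. Conclusions about
biology must come from applying the pipeline to tracked video, not from
the fixtures.

## Numerical and degenerate-input conventions

Headings live in $(-\pi, \pi]$; wrapped differences map the branch point to
$+\pi$. The nematic alignment is undefined (NA) at the exact tank center,
where the wall normal is undefined. Coincident simulated fish (zero
separation) resolve their avoidance direction by a random unit vector from
the run's seeded generator. Trials with no close pairs return an undefined
close-range alignment and are excluded from group statistics with a
warning. Constant-valued samples short-circuit the normality-gated
reference comparison (nothing to test; p is 1 or 0 by inspection).
Histogram bins are left-closed, and band edges must align with bin edges —
the band integrals are then exact sums, not quadrature.

## Statistical batteries

Two comparison batteries are provided and selected explicitly by the
caller, never auto-chosen: parametric (one-way ANOVA omnibus, Tukey HSD
pairwise) and nonparametric (Kruskal–Wallis omnibus, Games–Howell
pairwise). The nonparametric pairing of a Kruskal–Wallis omnibus with the
Welch-type Games–Howell post hoc mirrors common practice in this assay
literature; the package reproduces the pairing without endorsing it.
One-sample comparisons against a reference constant gate on a Shapiro–Wilk
test at $\alpha = 0.05$ between a t-test and a Wilcoxon signed-rank test.
Games–Howell is computed directly (Welch statistics against the
studentized-range distribution) since no installed package provides it; for
two groups it reduces to Welch's t-test, which the test suite checks.

## Known limitations

The analysis deliberately excludes trajectory smoothing (raw finite
differences only), swimming-depth corrections (only the error bound is
reported), leader–follower or time-lagged correlations, and parametric turn
models. The simulator has no attraction or alignment interaction between
fish — by design, so the speed sweep isolates the effect of swimming speed
and the avoidance sweep isolates evasive turns; it cannot and does not
model schooling itself. Simulated trajectories are exported at 30 frames/s
so the analysis treats them exactly like tracker output, which also means
sub-frame dynamics are invisible to the analysis modules, as they are for
real video.
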