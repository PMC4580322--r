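---
title: "Detecting area-restricted search: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting area-restricted search: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arstrack)
```

This vignette explains the models and procedures the package implements, the
assumptions behind them, the parameters that matter, and the design choices
made where the methodology left the design genuinely open. It is the
package's own account of its science; every number quoted here is computed
by the test suite or the acceptance script, not asserted.

## The inference problem

A migrating marine animal alternates between *transiting* — fast, directed
movement along a corridor — and *area-restricted search* (ARS) — slow,
tortuous movement concentrated where food is. Satellite tags deliver an
irregular sequence of noisy positions (Argos quality classes 3–0, A, B, Z,
or GPS fixes, class G). The pipeline infers, per fix: a migration flag, a
behavioural mode (`NoARS`/`ARS`), and a migration phase (before/within/after
a turbid river plume), plus per-animal quantities such as the foraging onset
date and the spatial scale of searching.

## First passage time

For path point $i$ and radius $r$, $\mathrm{FPT}_i(r)$ is the time between
the last entry into and the first exit out of the circle of radius $r$
centred at $i$: the implementation walks backward and forward along the path
to the first positions at great-circle distance $> r$ and interpolates each
crossing time linearly in distance-to-centre between the bracketing path
points. If either walk reaches a track end still inside the circle the FPT
is *undefined* — a value, not an error, and common near track ends and, for
large $r$, inside a terminal foraging residence.

Three numerical conventions follow from this definition:

* **Interpolation first.** The track is linearly interpolated along great
  circles at 1-km target spacing, raw fixes retained, so FPT is not an
  artefact of fix density. A raw segment of length $L$ km is divided into
  $\lceil L \rceil$ equal sub-arcs with timestamps linear in distance.
* **Monotonicity.** Within a point, FPT is non-decreasing in $r$ wherever
  defined; the tests assert this on simulated tracks.
* **Closed form.** On a straight constant-speed track,
  $\mathrm{FPT}(r) = 2r/v$ exactly and the log-FPT variance is zero — the
  first acceptance check, exact to well below the 0.1 % tolerance.

The ARS spatial scale is the radius maximising the variance of
$\log \mathrm{FPT}$ over path points (sample variance, $n-1$; radii with
fewer than 3 defined values are dropped). Ties break toward the smaller
radius — the analysis targets the smallest foraging scale — and a
numerically zero maximum (below $10^{-12}$) means "no scale": straight
transit produces exactly this.

## Segmentation into behavioural modes

The FPT series at the selected radius, ordered in time and restricted to
defined values, is segmented by penalised-contrast change-point detection:
exact dynamic programming minimises
$J(K) = \sum_k \sum_{i\in k}(y_i - \bar y_k)^2$ over partitions into $K$
contiguous segments of at least $L_{\min} = 5$ points, for
$K = 1,\dots,K_{\max} = 20$. $K^\*$ is chosen adaptively: $J$ is rescaled
affinely so that it decreases from $K_{\max}-1$ at $K=1$ to $0$ at
$K=K_{\max}$, and $K^\*$ is the largest $K$ whose second difference of the
rescaled contrast exceeds $\alpha = 0.75$ ($K^\*=1$ when none does).
$L_{\min}$, $K_{\max}$ and $\alpha$ are exposed parameters; the defaults are
the package's choices, documented here because the method family does not
fix them. The DP is verified exactly against exhaustive enumeration for
series up to length 60 and $K \le 3$.

Segments are then classified into two modes by a threshold on segment means
maximising the between-class variance, with two deliberate refinements:

* classes are weighted by segment length (the split optimises over the point
  distribution, not the bare set of means), and
* the split is computed on $\log$ means when all means are positive.

Both matter in practice: FPT is heavy-tailed, and on raw means the criterion
prefers to cut *inside* the foraging class (between a 6-day and a 14-day
segment) rather than between transit (hours) and foraging (days).
Diagnostics on simulated tracks showed exactly this failure before the log
refinement; with it, pooled mode accuracy across ten default-noise
simulations is above 90 %.

Modes are transferred from interpolated points back to raw fixes by
timestamp; points with undefined FPT inherit the mode of the nearest-in-time
defined point. The foraging onset is the first ARS-labelled fix; a track
with no ARS fix has no onset, which the dive-record labelling treats as
"all transiting".

## Pre-filters

Filters run in a fixed order, each fix charged to the first rule that
rejects it, and a `filter_report` reconciles counts exactly
($n_\text{in} = n_\text{out} + \sum \text{removed}$):

1. **Land** — bathymetry (positive down) at the fix is negative.
2. **Class Z** — invalid Argos fixes.
3. **Speed cap** — instantaneous speed from the previously *retained* fix
   above 10 km/h; a greedy forward pass drops the later fix of an offending
   pair and re-evaluates. The greedy pass is a documented choice; the
   methodology names the filter but not the algorithm.

Migration labelling uses a per-consecutive-pair daily speed (distance over
elapsed time scaled to km/day) with a strict 30 km/day threshold, the first
fix inheriting the second's label; "average daily speed" admits several
windowings and this is the simplest deterministic one.

Dive-histogram records whose deepest occupied maximum-depth bin lies beyond
100 m are dropped (tag pressure sensors and shelf bathymetry diverge below
that); optionally a record is also dropped when its deepest occupied bin's
lower edge exceeds local water depth by more than 10 m — the tolerance is a
parameter because the field convention is not fixed.

## Phases, currents, habitat

**Plume phases.** Among transiting fixes, plume candidates have
$K_d490 \ge 0.15\ \mathrm{m^{-1}}$; candidate runs separated by fewer than 3
clear fixes are merged, and phase 2 is the longest merged run of at least 3
fixes. The threshold sits between typical clear-water foraging
($\sim 0.05$–$0.1\ \mathrm{m^{-1}}$) and in-plume transit
($\sim 0.4\ \mathrm{m^{-1}}$) turbidities and is a required, logged
parameter; the run-merging suppresses single-fix speckle from position noise
at the plume edge. Time-in-plume is non-increasing in the threshold, a
property the tests check.

**Currents.** Ground velocity comes from consecutive fixes (speed along the
initial bearing, decomposed east/north); the swimming vector is
ground − current, sampled at the step's start fix and nearest in time —
cell-nearest rather than bilinear, a documented choice. The reverse triangle
inequality bounds
$|v_g - v_c| \le v_s \le v_g + v_c$ hold to machine precision.

**Fields.** Grids are regular lon/lat with half-open cells
$[e_i, e_{i+1})$ — a point exactly on an edge belongs to the larger-index
cell, making edge assignment deterministic. Monthly fields match by
calendar month, daily fields by nearest time. Missing cells (cloud, failed
atmospheric correction) are filled by inverse distance weighting over the 8
nearest observed cell centres with power 2 (both parameters exposed; the
method convention does not fix them); IDW is exact at observed cells and
bounded by its neighbours' extremes. Slope uses Horn's 3×3 gradients with
the zonal cell size scaled by $\cos(\text{lat})$, one-sided differences at
borders.

## Dive histograms

Tags transmit 4-hour histograms, not dives: per-bin counts of maximum depth
(every 10 m to 100 m, then every 50 m to 250 m) and maximum duration (30 s,
1 min, each minute to 5 min, then each 10 min to 60 min), plus
time-at-depth and time-at-temperature percent vectors that must sum to
100 ± 0.5. The duration layout as transmitted leaves a 5–10 min gap; a
single 5–10 min bin is inserted so the scheme is contiguous — a documented
deviation. Records get the behavioural mode of the track by onset date
(`foraging` iff period start ≥ onset, a closed lower bound) and the phase of
the nearest-in-time transiting fix. Summaries report per-bin shares (summing
to 1) and mean ± SD on bin midpoints — explicitly an approximation, since
within-bin values are never transmitted.

## Statistics

Two-sample mode comparisons gate on Shapiro–Wilk normality per group at
$\alpha = 0.05$: rank-sum if either group departs, else a t-test, with the
branch recorded. The rank-sum test uses mid-ranks, exact enumeration when
$n+m \le 12$ without ties, else the normal approximation with tie and
continuity corrections; a fully tie-saturated comparison returns $p = 1$.
Three-group phase comparisons use Tukey–Kramer with the studentized-range
distribution on $N-k$ degrees of freedom.

Model selection for time-in-plume regressions screens predictor pairs with
$|\rho_{\text{Spearman}}| > 0.8$ (strict), fits every admissible subset
including intercept-only, and selects the lowest
$\mathrm{AIC} = n\ln(\mathrm{RSS}/n) + 2(p+2)$ — constants omitted
consistently, so differences are unaffected. The full fit table is retained
so the minimum is auditable. A perfect fit (numerically zero RSS) is an
error rather than $-\infty$. Note a structural fact the validation makes
visible: with one true and one noise predictor at $n=100$, AIC admits the
spurious predictor with probability $P(F_{1,98} > 1.98) \approx 0.16$, so
exact-true-model selection concentrates near 84 %, not above it.

## The synthetic study system

The generator (`sim_config()`, `simulate_track()`, `simulate_fields()`,
`simulate_dive_histograms()`) emulates a shelf migration against a boundary
current, with ground truth for every inferred label:

* **Movement.** A biased correlated random walk alongshore (through-water
  speed 0.8 m/s, turning SD 0.2 rad) switching permanently to ARS on first
  entry into a 15-km foraging patch (0.2 m/s, turning SD 1.2 rad,
  reflective confinement). Headings are redrawn every 4 h: the turning SDs
  only define a process jointly with this behavioural step, and 4-h redraws
  give transit persistence of tens of km and in-patch mixing that traverses
  the patch over a multi-week residence — both necessary for patch-scale
  FPT to be observable at all. Regime switching is spatial, not Markovian in
  time, so truth labels are unambiguous.
* **Observation.** Fixes at exponential intervals (mean 2 h) with
  class-dependent isotropic Gaussian noise (G 50 m to B 15 km); the default
  class mix is GPS-heavy (60 % G, 1 % Z), reflecting a fleet of GPS-linked
  tags with upstream-filtered Argos positions. Defaults span 600 fixes
  (~7 weeks): long enough that the terminal foraging residence supports
  defined FPT at radii near the patch scale.
* **Seascape.** A meridional coast; an alongshore counter-jet with Gaussian
  cross-shore profile (peak 0.5 m/s at 100 km offshore, SD 50 km); Kd490 as
  a 0.05 m⁻¹ background plus a Gaussian plume blob (amplitude 0.6 m⁻¹,
  SD 80 km); a linear shelf ramp (1 m depth per km offshore; land west of
  the coast).
* **Dives.** Per 4-h period, Poisson(25) dives with regime-dependent
  lognormal maximum depth (median 30 m transiting vs 18 m foraging) and
  duration (20 vs 35 min): foraging dives shallower and longer.

What the generator does *not* emulate — and hence what passing tests do not
show about field data: Argos error ellipses (noise is isotropic), temporal
autocorrelation of fix quality, tidal and mesoscale currents, plume
dynamics, haul-outs and gaps, and multi-patch or revisited foraging.
Recovery rates quoted anywhere in the package are statements about this
synthetic system, not about any real deployment.

## Validation problem sizes

The acceptance studies use: a 60-fix straight track (closed form); a ~210-km
spiral densified to 10-m spacing (brute-force FPT oracle, 20 random cells,
1 % tolerance); 50 noisy series of length ≤ 60 for the DP-vs-enumeration
check; 20 low-noise simulations with radii 1–100 km at 1-km steps for scale
recovery (the 15-km patch and its $[\rho/2, 2\rho]$ recovery band are well
inside 100 km, and FPT beyond ~100 km is mostly undefined on a ~700-km
track); 10 full-noise simulations for phase-boundary recovery (±3 fixes);
200 replicates for selection consistency; $10^4$ random vectors for the
current-correction identity. These sizes are the package's choices and are
stated here so the studies are interpretable and reproducible.

## Known limitations

* A single maximum-variance scale per track: nested or multi-scale ARS is
  out of scope, as is state-space or HMM behavioural inference.
* Spherical geometry ($R = 6371$ km) throughout; geodesic error is far
  below Argos noise at corridor scales.
* The plume boundary is a threshold on Kd490, not an objective mixture or
  salinity-based delineation.
* Phase summaries attribute each step to its start fix; steps straddling a
  phase boundary are not split.
* With no deposited real tracks, the package's quantitative claims are
  validated on the synthetic system above; applying the pipeline to real
  data should start by checking the pre-filter report and the variance
  spectrum (`autoplot`) rather than trusting defaults.
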