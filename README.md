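# arstrack

Movement-ecology tooling for detecting **area-restricted search (ARS)** —
the slow, tortuous movement that marks foraging — in satellite telemetry
tracks of marine migrants, and for relating migration behaviour to the
oceanography the animals cross: boundary currents, a turbid river plume,
shelf bathymetry. It is written for biologging analysts who have Argos/GPS
fix tables, gridded environmental fields and tag-transmitted 4-hour dive
histograms, and want a reproducible pipeline from raw fixes to labelled
behavioural modes, migration phases and habitat statistics.

## What it computes

**First passage time (FPT).** For a point on the track and a radius $r$, the
FPT is the time the animal takes to cross a circle of radius $r$ centred on
that point. Tracks are linearly interpolated at 1-km spacing (raw fixes
retained), FPT is evaluated at every path point for radii $r = 1 \dots 400$
km, and the variance of $\log \mathrm{FPT}$ across points is plotted against
$r$: a peak at radius $r^\*$ identifies the spatial scale of searching
activity. If several peaks appear, the maximum-variance (and on ties the
smallest) radius is used.

**Lavielle segmentation.** The FPT series at $r^\*$, ordered in time, is
partitioned by exact dynamic programming into $K$ segments minimising the
within-segment squared error $J(K)=\sum_k \sum_{i \in k} (y_i-\bar y_k)^2$,
with $K$ chosen by the second-difference rule on the rescaled contrast.
Segment means are split into two classes (between-class variance criterion on
the log scale), giving per-fix modes: `NoARS` (transiting) vs `ARS`
(foraging), and the foraging onset date.

**Around the core** the package provides: pre-filters (30 km/day migration
labelling, land masking by bathymetry, class-Z removal, a 10 km/h speed cap);
plume-phase delineation (before / within / after a turbid plume) from Kd490
along the track; current-corrected swimming velocity (swim = ground − current,
vector subtraction); IDW gap-filling and Horn-slope derivation for
environmental rasters; 4-hour dive-histogram summaries (max depth, max
duration, TAD/TAT); Wilcoxon/t mode comparisons with a Shapiro–Wilk gate,
Tukey–Kramer phase comparisons, and all-subsets AIC linear-model selection
behind a Spearman collinearity screen ($|\rho| > 0.8$ excluded). A
synthetic-data generator simulates the whole study system — two-regime
movement, counter-current jet, plume field, shelf ramp, Argos-class noise,
dive records — with ground truth for every label the pipeline infers.

## Worked example

Simulate a tagged migrant, run the pipeline, and read off the behavioural
and phase structure:

```r
library(arstrack)

cfg    <- sim_config(seed = 42)          # 600 fixes, 15-km foraging patch
sim    <- simulate_track(cfg)
fields <- simulate_fields(cfg)

filt  <- apply_plausibility_filters(sim$track, bathy = fields$bathymetry)
filt$report
#> <filter_report> 600 in -> 543 out
#>   rule      n_removed
#> 1 on_land           2
#> 2 class_Z           4
#> 3 speed_cap        51

fit <- detect_foraging(label_migration(filt$track), radii = 1:100)
fit
#> <ars_fit> sim1: 543 fixes, ARS scale 17 km, 377 ARS fix(es), onset 2014-03-18 08:49
```

The selected ARS scale (17 km) recovers the simulated 15-km patch, and the
onset is the day the simulated animal entered it. Phases and the per-phase
movement table:

```r
phased <- segment_phases(extract_kd_along_track(fit$track, fields$kd))
phased
#> <phase_assignment> phases 1/2/3: 45/51/70 fixes; time in plume 5.31 days

phase_summaries(phased$track, fields$coast, fields$current_u, fields$current_v)
#>    variable             phase   mean      sd     n
#>  9 observed_speed_ms    1      0.687  0.334     45
#> 10 observed_speed_ms    2      0.801  0.393     51
#> 11 observed_speed_ms    3      0.650  0.593     70
#> 13 swimming_speed_ms    1      0.835  0.349     45
#> 14 swimming_speed_ms    2      0.930  0.383     51
#> 15 swimming_speed_ms    3      0.770  0.556     70
#> ...
```

Swimming speed exceeds observed speed throughout — the simulated animal
fights an alongshore counter-current — and both peak inside the plume.
`autoplot(fit)` draws the FPT series with its segmentation;
`autoplot(fit$spectrum)` the variance spectrum; `plot_track()` maps modes or
phases. `tidy()`/`glance()` return the per-fix and per-animal tables.

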