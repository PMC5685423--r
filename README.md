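# perisr

Simulation pipeline for peripheral-acuity psychophysics with masked,
moving Landolt-C targets, built to probe **motion-based
super-resolution**: the idea that the visual system can co-register and
merge successive undersampled glimpses of a moving target into a finer
reconstruction than any single glimpse supports.

The package renders the complete stimulus paradigm — a Landolt C at
10 deg eccentricity behind a 7 x 7 deg occluder mask whose elements are
drawn at the background luminance (invisible occlusion, simulating
clustered retinal loss) under six target/mask dynamic conditions —
and replaces human subjects with parameterized model observers:

* `single_frame` — decides from one glimpse;
* `prob_summation` — independent decisions per frame pooled by a max
  rule (more looks, no integration: the null model);
* `super_resolution` — shift-and-add: registers all frames (oracle,
  estimated, or no motion knowledge) and decides on the merged
  composite.

Around the observers it implements the full measurement chain of this
literature: a 3-down-1-up adaptive staircase (start 17.8 arcmin, step
4.5 arcmin halving on size-increasing reversals, 8 reversals or 50
trials), maximum-likelihood fitting of the 4AFC psychometric function

    p(correct) = 0.25 + 0.75 / (1 + exp((mu - x) / sigma))

with nonparametric bootstrap CIs for the size threshold `mu` (arcmin),
per-density motion-benefit contrasts, and two-way repeated-measures
ANOVA over a simulated subject panel.

## Worked example

Measure one simulated subject's threshold for a moving vs a static
target behind a static mask of density 0.75:

```r
library(perisr)

obs  <- observer_params("super_resolution")   # oracle registration
cond <- condition_spec("smooth_static", 0.75) # moving target, fixed mask

trials <- run_staircase(cond, obs, seed = 7)
fit <- fit_ml(trials)
fit
#> <psychometric_fit> mu = 3.648 arcmin, sigma = 0.708 arcmin (n = 39, logLik = -10.29)

static <- run_staircase(condition_spec("static_static", 0.75), obs, seed = 7)
fit_ml(static)
#> <psychometric_fit> mu = 10.489 arcmin, sigma = 2.877 arcmin (n = 50, logLik = -18.51)
```

The integrating observer resolves a ~3.6 arcmin gap when the target
moves (registration slides the mask across the target, uncovering it),
but needs ~10.5 arcmin when everything is static and three quarters of
the target never becomes visible. A full experiment crosses subjects,
conditions and densities:

```r
subs <- subject_models(n_subjects = 8, seed = 1)
tab  <- run_experiment(1, subjects = subs, n_runs = 10, seed = 1)
motion_benefit(tab)      # per-density threshold difference + bootstrap CI
rm_anova_2way(tab)       # density x motion repeated-measures ANOVA
plot_thresholds(tab)     # threshold-vs-density summary figure
```

Stimulus movies can be exported for inspection with
`write_stimulus_tiff()` (16-bit multi-page TIFF plus a JSON sidecar
with the path coordinates and seeds).

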