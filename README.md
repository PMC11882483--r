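# ulmvasc

Super-resolution ultrasound localization microscopy (ULM) turns long
ultrafast-ultrasound movies of circulating microbubbles into maps of the
microvascular bed far below the diffraction limit: individual bubbles are
separated from tissue clutter, localized to sub-pixel precision, tracked
across frames, and accumulated into density, velocity and flow-direction
images from which vascular architecture and hemodynamics can be measured.

`ulmvasc` is a complete, tested R implementation of that analysis chain,
aimed at quantitative comparisons of microvascular structure between tissue
regions (for example a tumor core, its invasive margin, and normal tissue).
Because suitable in vivo data are rarely shared, the package also ships a
first-class synthetic-data module — vascular phantoms with analytic ground
truth, Poiseuille bubble flow, low-rank tissue clutter — so every stage is
verifiable end to end on one laptop core.

## The measurements

For each region of interest the pipeline reports nine quantities: vascular
density (vessel-area fraction), mean vessel diameter, branches, branch
points, curvature, fractal dimension, orientation variance, mean flow
velocity and total flow volume. The four defined quantities are

- curvature (tortuosity) of a vessel segment: `Lc / L`, path length over
  chord;
- fractal dimension: slope of `log M(r)` vs `log(1/r)` from box counting,
  fitted on the contiguous scale range (>= 4 scales) with the best
  R-squared, which must exceed 0.99;
- orientation variance: `(1/N) * sum(wrap(theta_i - theta_bar)^2)` around
  the circular mean direction;
- flow volume under the Poiseuille assumption: `Q = A * V` with
  `A = pi (d/2)^2`, reported in nL/s.

The statistics stage mirrors the field's workflow: Kolmogorov-Smirnov
normality gate, then ANOVA with Bonferroni-corrected pairwise tests or
Kruskal-Wallis with pairwise Mann-Whitney U (exact by enumeration for
combined n <= 12), plus Pearson/Spearman correlations labeled weak /
moderate (0.400-0.699) / strong (>= 0.700).

## Worked example

```r
library(ulmvasc)

res <- run_pipeline(default_run_config(seed = 5), out_dir = "demo_run")
res$spectrum
#> singular_spectrum: 400 values, cutoff rank 2 (sv1 = 1.95e+05, sv at cutoff+1 = 199)
res$tracks
#> ulm_tracks: 290 tracks (length 15-167 frames, median 31.5)
round(res$dice, 3)
#> [1] 0.715
subset(res$metrics, select = c(region, density, branches, curvature, fractal_dimension))
#>     region    density branches curvature fractal_dimension
#> 1     core 0.04384311       80  1.025463          1.229866
#> 2 invasive 0.17659505      434  1.051392          1.452173
#> 3   normal 0.03437273       49  1.019198          1.187375
head(res$comparison[, c("parameter", "test", "p")], 3)
#>       parameter           test            p
#> 1     curvature kruskal_wallis 4.222725e-03
#> 2   diameter_um kruskal_wallis 1.685324e-02
#> 3 velocity_mm_s          anova 1.015986e-13
```

The movie is filtered at the automatically selected clutter rank (2 — the
constructed clutter rank), ~290 bubble trajectories of 15 frames or more
are recovered, and the recovered regional contrasts reproduce the phantom's
built-in pattern: the invasive-like strip is denser, more branched, more
tortuous and more complex than core and normal strips. `demo_run/` holds
every intermediate artifact (TIFF movies and maps, CSV localizations,
tracks, graph, metrics, comparison tables, PNG masks) plus the exact
configuration for provenance.

A thin command-line front end is installed with the package
(`exec/ulm`): `ulm run --config config.yaml --seed 3 --out rundir/`, with
per-stage subcommands (`simulate`, `filter`, `track`, `reconstruct`,
`segment`).

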