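# abscissr

Directional seed abscission mechanics for the dandelion.

Dandelion seeds detach when the pedicle — the thin, porous vascular stalk
anchoring the achene to the receptacle — breaks. The force this takes is
strongly direction-dependent: the attachment site is a raised,
horseshoe-shaped ridge on the scape side of the pedicle only, so a seed
pulled toward the capitulum apex ("positive") abscises under roughly an
order of magnitude less force than one pulled toward the scape
("negative"), and two orders less than one pulled straight out. Since wind
loads seeds through drag ($F \sim U^2$), this asymmetry biases *which*
winds disperse seeds.

`abscissr` is for plant biomechanics and seed-dispersal researchers who
want to work with this mechanism quantitatively. It provides:

* **Composite-beam mechanics.** The pedicle plus the engaged
  (compression-side) base tissue bend as one transformed section, base
  material weighted by $1/\beta$ with $\beta = E_p/E_b > 1$ the
  pedicle-to-base stiffness ratio. At abscission the outer-fibre stress
  $\sigma_t + \sigma_b = F\cos\Delta\theta/A + F\,p\,y_{max}/I$ reaches
  the pedicle's breaking stress, which cancels against the straight-pull
  force, giving

  $$\frac{F_a}{F_{as}} = \frac{1}{\cos\Delta\theta + A\,y_{max}\,p/I},
    \qquad
    \frac{F_a}{F_{as}} \approx \frac{I}{k\pi c^2\, y_{max}\, L \sin\Delta\theta}$$

  with $\Delta\theta = |\theta_1| - |\theta_2|$, $A = k\pi c^2$ and
  $p = (L+\ell)\sin\Delta\theta$. Because the engaged section differs by
  pull direction, so do $y_{max}$ and $I$ — that is the whole asymmetry.
* **Fitting and sensitivity.** Deterministic fit of $\beta$ to measured
  force ratios (`fit_beta()`, with broom-style `tidy()`/`glance()`), error
  propagation from morphology uncertainty, and sweeps of the geometry
  (`sweep_parameter()`, with `autoplot()`).
* **Robust statistics.** Median/IQR summaries, 1000-resample percentile
  bootstrap CIs for the median (25th/975th order statistics), and Wilcoxon
  rank-sum tests (exact by enumeration for small tie-free groups).
* **Synthetic force data.** A log-normal generator calibrated per
  experiment/angle bin to published medians and quartile ratios, so the
  whole analysis runs without any raw-data download.
* **A pipeline.** `run_pipeline()` chains simulate → summarise → test →
  fit → sweep → report, writes TSV/JSON artifacts, and is byte-identical
  under a fixed seed. A thin CLI wrapper lives in
  `inst/scripts/run_analysis.R`.

## Worked example

The sideways experiment's published bin medians are 45 mN (straight out),
1.3 mN (negative) and 0.26 mN (positive). The directional ratios and the
derived wind asymmetry:

```r
library(abscissr)

er <- experimental_ratios(tibble::tibble(
  experiment = "sideways", angle_bin = c("0", "-90", "+90"),
  median_mN  = c(45, 1.3, 0.26)))
er
#> # A tibble: 1 × 4
#>   fap_fas fan_fas fap_fan method
#>     <dbl>   <dbl>   <dbl> <chr>
#> 1 0.00578  0.0289     0.2 median

1 / er$fap_fan                 # negative-to-positive force factor
#> [1] 5
wind_speed_factor(er$fap_fan)  # implied wind-speed factor, F ~ U^2
#> [1] 2.236068
```

So abscising a seed in the negative direction takes ~5× the force — hence
a ~2.2× faster wind — of the positive direction. The full pipeline on a
synthetic dataset calibrated to the published bins:

```r
report <- run_pipeline(pipeline_config(seed = 1), quiet = TRUE)
report
#> <abscission_report>
#>   293 measurements in 9 bins
#>   beta* = 1; Fap/Fan (experimental) = 0.177
#>   negative/positive force factor = 5.66; wind-speed factor = 2.38

tidy(report$fit)
#> # A tibble: 4 × 3
#>   term      estimate   target
#>   <chr>        <dbl>    <dbl>
#> 1 beta_star  1       NA
#> 2 fap_fas    0.00110  0.00523
#> 3 fan_fas    0.0122   0.0296
#> 4 fap_fan    0.0905   0.177
```

The report also carries per-bin summaries (median, quartiles, bootstrap
CI), the nine pairwise Wilcoxon comparisons (all $p < 0.01$ for the
calibrated generator), propagated prediction intervals, and the $c$ and
$r$ sensitivity sweeps. With this package's compression-side engagement
rule the measured ratios sit just below the model's reachable range, so
the $\beta$ fit lands on the lower search bound (flagged `boundary` in
`glance()`) while still agreeing with the targets within one order of
magnitude; the methods vignette
(`vignettes/directional-abscission.Rmd`) discusses this and every other
open design choice.

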