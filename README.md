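# nbicontrast

Quantifies how much narrow-band imaging (NBI) enhances the contrast of
arterial vessel-wall lesions over conventional white-light imaging (WLI),
and provides a physics-based synthetic generator of co-registered WLI/NBI
endoscopic image pairs so that the whole comparison is testable without any
archived endoscopy images.

NBI restricts illumination to narrow blue (415 nm) and green (540 nm) bands
sitting on haemoglobin absorption maxima. An intact intima is nearly
colourless, but blood accumulates at wall defects — dissection-type tears
and ablation burns — so under NBI those defects darken sharply while the
background barely changes. The package is aimed at researchers developing or
evaluating endoscopic imaging pipelines who need a controlled, reproducible
test bed for that effect.

## The statistic

For a co-registered pair and one rectangular ROI (0-based, half-open)
applied identically to both modalities, each ROI pixel row is a *line
profile* $p_r(c)$. The analysis computes signed first differences
$g_r(c) = p_r(c{+}1) - p_r(c)$, the per-modality **average intensity
change**

$$S = \frac{1}{R\,(C-1)} \sum_{r,c} |g_r(c)|,$$

and the **percent increase** of NBI over the WLI baseline,

$$\Delta = 100\,\frac{S_\mathrm{NBI} - S_\mathrm{WLI}}{S_\mathrm{WLI}}.$$

Simulated pairs are rendered from a two-layer haemoglobin field by
band-integrated Beer–Lambert attenuation,
$T = \sum_k g_k \exp(-\mu(\lambda_k)(c_s d_s + f(\lambda_k) c_d d_d))$,
where the deep-layer fraction $f(\lambda)$ ramps from 0 at 450 nm to 1 at
600 nm (short wavelengths stay superficial). Optional additive sensor noise
and a hexagonal fibre-bundle degradation (~5000 cores, as in small vascular
fibrescopes) complete the forward model. See
`vignettes/nbi-contrast-methods.Rmd` for the model, its assumptions and its
limits.

## Worked example

```r
library(nbicontrast)

pair <- simulate_pair(preset_scenario("tear"))   # co-registered WLI/NBI pair
report <- analyze_pair(pair, preset_roi("tear"))
print(report)
#> Matched-ROI gradient contrast report
#>   ROI: rows [35, 85) x cols [45, 115)   (3450 gradient samples)
#>   mean |gradient|  WLI: 0.01347
#>   mean |gradient|  NBI: 0.01614
#>   NBI percent increase over WLI: +19.9%
```

The mean absolute gradient of the NBI line profiles is ~20% larger than in
WLI for this seeded scalpel-tear scene: the lesion's accumulated haemoglobin
absorbs the narrow bands strongly, steepening its edges in every row profile.
Replicated experiments aggregate the same statistic over seeds:

```r
summ <- run_experiment(run_config(c("tear", "burn"), n_replicates = 10, base_seed = 1))
print(summ)
#> experiment_summary (v0.1.0, config 3c7cc888, base seed 1)
#> NBI percent increase over WLI, per scenario:
#>  scenario n_replicates mean_percent_increase sd_percent_increase
#>      tear           10             18.334785            2.381398
#>      burn           10              8.919535            2.541327
#>  min_percent_increase max_percent_increase
#>             15.120580             22.20187
#>              4.448278             11.87462
```

Other entry points: `recover_uplift()` calibrates the tear scenario's lesion
haemoglobin to a target mean uplift by bisection; `analyze_external()` runs
the identical statistic on user-supplied co-registered PNG/TIFF pairs;
`apply_fibre_bundle()` degrades renders through a low-fibre-count flexible
scope; `inst/scripts/nbi-contrast` wraps the main verbs
(`presets`/`simulate`/`analyze`/`run`/`calibrate`) for shell use. Run
configurations round-trip through YAML/JSON (`write_run_config()` /
`read_run_config()`), and every output is reproducible byte-for-byte from
the config and base seed.

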