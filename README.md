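# optoflow

Quantitative analysis of optically patterned microtubule–kinesin active
fluids, for experimentalists working with light-switchable motor clusters.
When kinesin fragments are clustered by a light-induced dimer, illumination
turns on extensile active stresses in a bundled microtubule network;
patterned light then controls where and how strongly the network flows,
bends and buckles. This package measures those responses from fluorescence
time-lapse images and fits the models that describe them:

* **PIV flow fields** — windowed normalized cross-correlation with
  subpixel Gaussian peak refinement, normalized-median outlier filtering,
  and mean-speed time traces annotated by the illumination schedule.
* **Photoswitching kinetics** — activation
  ⟨|v(t)|⟩ = v_max (1 − e^(−t/τ_on)) and normalized deactivation
  v̂(t) = 2/(1 + e^(t/τ_off)), fitted per light cycle; per-cycle plateau and
  dark-speed summaries; intensity–speed response with a saturation rule.
* **Bend-angle analysis** — structure-tensor orientation fields, the mean
  in-plane deviation angle ⟨θ⟩ from the initial alignment, its activated
  growth rate γ̇, and the post-deactivation relaxation
  ⟨θ⟩(t) = e^(−t/τ) γ̇ t + C e^(−t/r) combining motor-cluster unbinding (τ)
  with elastic network recovery (r).
* **Strain and regimes** — Eulerian displacement accumulation, region-
  averaged normal strains γ_xx/γ_yy, region fluorescence flux, and
  quiescent / sliding / buckling classification with the 0.5% transverse-
  strain threshold rule.
* **Confinement threshold** — the piecewise effective-activity bound
  α_eff(L, W, H) = π²L²(1/L² + 1/W² + 1/H²)² for short regions, saturating
  at 4π²(1/W² + 1/H²), the linear intensity–activity fit I = a·α_eff, and
  the generic 1/L² + C comparison fit.
* **Synthetic microscopy** — seeded generators for advected filamentous
  textures, speed/angle traces and threshold datasets, so the entire
  pipeline is testable without experimental data.

Everything takes and returns tibbles, chains with the pipe, and provides
broom-style `tidy()`/`glance()` methods and ggplot2 `autoplot()` methods.

## Worked example

Fit switching kinetics on a synthetic two-cycle experiment, then recover a
confinement-threshold coefficient:

```r
library(optoflow)

schedule <- illumination_schedule(t_start = c(0, 900),
                                  t_end = c(600, 1500), intensity = 1)
trace <- gen_speed_trace(vmax = 1.2, tau_on = 8, tau_off = 13,
                         dark_speed = 0.01, schedule = schedule,
                         noise_sd = 0.06, seed = 42, dt = 2,
                         span = c(0, 1800))

fit <- trace |> dplyr::filter(time_s < 600) |> fit_activation()
tidy(fit)
#> # A tibble: 2 × 3
#>   term   estimate std.error
#>   <chr>     <dbl>     <dbl>
#> 1 vmax       1.20   0.00349
#> 2 tau_on     7.28   0.382

v0 <- normalize_deactivation(trace, t_off = 600)
trace |>
  dplyr::filter(time_s >= 600, time_s < 900) |>
  fit_deactivation(v0 = v0) |>
  tidy()
#> # A tibble: 1 × 3
#>   term    estimate std.error
#>   <chr>      <dbl>     <dbl>
#> 1 tau_off     13.1     0.368

geo <- tibble::tibble(L_um = c(50, 100, 150, 200, 250, 300, 400, 500),
                      W_um = L_um, H_um = 100)
gen_threshold_dataset(a = 1.17, geometries = geo, rel_noise = 0.05,
                      seed = 1) |>
  fit_activity_coefficient() |>
  tidy()
#> # A tibble: 1 × 3
#>   term  estimate std.error
#>   <chr>    <dbl>     <dbl>
#> 1 a         1.15    0.0127
```

The activation fit recovers the programmed plateau (1.2 µm/s) and rise
time (8 s, here 7.3 ± 0.4 s under 5% speed noise); the deactivation fit
recovers the 13 s switch-off time; and the threshold fit recovers the
programmed intensity–activity coefficient (1.17, here 1.15 ± 0.013 under
5% intensity noise). `autoplot(trace)` draws the trace with illuminated
episodes shaded; `run_pipeline()` executes simulate → PIV → analysis
stages from a YAML config (see `inst/scripts/run_pipeline.R`).

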