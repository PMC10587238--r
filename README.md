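# allometherm

Body-size and acute-temperature effects on fish aerobic metabolism and
cardiac thermal tolerance: an R package for the full analysis chain from raw
intermittent-flow respirometry traces and maximum heart-rate (fHmax) ramps
to allometric scaling models and thermal-performance summaries.

## Who this is for

Comparative and conservation ecophysiologists who measure oxygen uptake
(MO2) in flush/measure respirometry cycles and cardiac thermal limits with
1 °C warming ramps, and who want the downstream statistics — scaling
exponents, temperature effects, mass-normalized group means, Q10s — in one
tested, reproducible pipeline.

## The model at the core

Physiological rates scale with body mass `BM` as a power law; on log axes,

```
ln(rate) = ln(a_T) + b · ln(BM)
```

with a common exponent `b` and temperature-specific intercepts `ln(a_T)`.
For repeated measures across acute temperatures (12, 16, 20, 22 °C) the
package fits `ln(response) ~ 0 + temperature + ln(mass) + (1 | fish)` by
maximum likelihood; independent one-off traits use OLS. Cardiac thermal
tolerance comes from broken-stick regression of `ln(fHmax)` on inverse
temperature `1000/T_K`: the knot is the Arrhenius breakpoint temperature
T_AB, the curve's maximum gives T_PEAK and PEAK_fHmax, and the first
arrhythmic beat gives T_ARR. Derived quantities: mass-normalized rates
`value · (ref/BM)^b / ref` at a 65-g reference size, interval
`Q10 = (R2/R1)^(10/(T2−T1))`, and the Fick-equation slope decomposition
`b_MR = b_Vs + b_fH`.

A seeded synthetic-data generator (`study_config()`, `generate_study()`)
emulates the whole study design — log-uniform 5–700 g cohorts, overnight
flush/measure traces with injected maximum-metabolic-rate episodes and
microbial background, per-degree cardiac series with mass-dependent
breakpoints — and retains every latent truth for parameter-recovery testing.

## Worked example

```r
library(allometherm)

cfg   <- study_config(n_fish = 12, n_cardiac = 6, seed = 42)
study <- generate_study(cfg)

# one trial: trace -> MO2 series -> metabolic summary
tr  <- study$traces[["fish003_20"]]
ser <- extract_mo2_series(tr, tr$background_slope_pre, tr$background_slope_post)
ser
#> MO2 series fish003 @ 20 degC: 62 cycles (62 accepted), V_net 10.397 L
summarize_metabolism(ser)
#> Metabolic summary fish003 @ 20 degC: MMR 1.6797, RMR 0.6138, AAS 1.0659, FAS 2.736 (62 cycles)

# one cardiac ramp: transform -> breakpoint -> summary
analyze_cardiac_series(study$cardiac[["fish003"]], seed = 7)
#> Cardiac summary fish003: T_AB NA, T_PEAK 26.0, PEAK_fHmax 155.5 bpm, T_ARR 28.0 degC

# scaling across the cohort (MMR, all four temperatures)
rows <- lapply(study$traces, function(tr) {
  s <- summarize_metabolism(extract_mo2_series(tr))
  data.frame(fish_id = tr$fish_id, temperature = tr$temperature,
             ln_mass = log(tr$fish_mass), ln_response = log(s$mmr))
})
fit <- fit_scaling_mixed(do.call(rbind, rows))
fit
#> Scaling fit (ln_response, mixed): b = 0.799 (SE 0.026) [0.749, 0.849], BIC -35.7
#>   ln(a) per temperature:
#>     12 degC: 1.048 (SE 0.096)
#>     16 degC: 1.208 (SE 0.096)
#>     20 degC: 1.416 (SE 0.096)
#>     22 degC: 1.477 (SE 0.096)

predict_group_mean(fit, 12)   # mass-normalized 65-g mean, mgO2 min^-1 65 g^-1
#> [1] 4.929938
q10(predict_group_mean(fit, 12), predict_group_mean(fit, 22), 12, 22, "mmr")
#> Q10(12-22 degC) [mmr] = 1.536
fick_decompose(fit$slope, -0.052)
#> Fick decomposition: b_MR 0.799 = b_Vs 0.851 + b_fH -0.052
```

Reading the numbers: the 12-fish cohort recovers a hypoallometric exponent
(`b ≈ 0.80`: doubling body mass raises whole-animal MMR by only ~74%) with
intercepts rising across acute temperatures; the 65-g normalized MMR rises
from ~4.9 to ~7.6 mgO2 min⁻¹ 65 g⁻¹ between 12 and 22 °C, a mild thermal
sensitivity (Q10 ≈ 1.5); and if fHmax scales with exponent −0.05, Fick's
principle attributes the remaining mass dependence (b ≈ 0.85) to cardiac
stroke volume. This fish's T_AB is reported as `NA` because its breakpoint
confidence interval failed the ±1.5 °C inclusion rule — exclusions are part
of the method, not an error state.

## Pipeline and command line

`run_pipeline(run_config(...))` (or a YAML file via `read_run_config()`)
chains `simulate → respiro → cardiac → scaling → report`, writing CSV
products and a JSON manifest under one output directory; a thin wrapper
lives at `inst/cli/allometherm.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","allometherm.R",package="allometherm"))')" \
  run --config inst/extdata/example_config.yaml --verbose
```

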