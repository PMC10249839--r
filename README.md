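# optifib

Continuous estimation of fecal-indicator and human-associated indicator
bacteria in urban streams from in-situ optical fluorescence sensors.

Discrete water samples for *E. coli*, enterococci, fecal coliforms and the
human sewage markers HF183 (human *Bacteroides*, HB) and Lachno3 (human
*Lachnospiraceae*, L3) are sparse and slow to analyze, while optical
fluorometers (FDOM / tryptophan-like channels), turbidity, temperature and
streamflow are measured every ten minutes. `optifib` implements the surrogate
workflow that links the two — for water-quality scientists and monitoring
programs who want concentration, load, sewage-proportion and
criteria-exceedance estimates at the sensor's time resolution:

* **Sensor corrections** — fouling (linear ramp between cleanings), drift
  (multiplicative, linear in time from pre/post-deployment calibrations),
  mV→Raman-unit least-squares conversion, temperature compensation
  `F / (1 + ρ(T − T_ref))`, turbidity compensation `F · exp(k·turb)`.
* **Censored regression** — left-censored Gaussian (Tobit) maximum likelihood
  on log10 concentrations,

  `log10 c = β₀ + Σⱼ Xⱼ(βⱼ + βⱼˢ sin(2πd/365.25) + βⱼᶜ cos(2πd/365.25)) + β_T·turb + β_Q·log10 Q̄₁ₕ + ε`,

  with seasonal sine/cosine interaction terms on each optical variable and
  Duan smearing `ĉ = D·10^{xβ}`, `D = mean(10^e)`, for back-transformation.
* **Model selection** — candidate enumeration over optical subsets ×
  turbidity × flow; 5-fold cross-validation repeated 50 times; median
  log10-space RMSEP; two-step rule (lowest median, then fewest terms among
  candidates within 3%); fit separately on CSO-influenced, non-CSO and
  combined data (8 markers × 3 regimes = 24 scenarios).
* **Estimation** — 10-minute concentration series with CSO/non-CSO model
  switching, calibration-range capping, daily loads (c·Q integration),
  proportion of sewage (estimate / mean wastewater-influent concentration),
  flow-weighted annual proportion and annual sewage volume.
* **Benchmarks** — single-sample and trailing 30-day geometric-mean/STV
  recreational water-quality criteria, including the 4,200 and 7,800
  CN/100 mL human-*Bacteroides* QMRA benchmarks.
* **Synthetic data** — a seeded generator (hydrograph with gamma-kernel
  events and CSO periods, optical/turbidity/temperature series, discrete
  samples with left-censoring, influent composites) so the whole pipeline is
  testable end to end without field data.

## Worked example

Simulate a year-long study, select a model for human *Bacteroides* on the
non-CSO samples, estimate the continuous series with CSO switching, and
summarize loads, sewage proportion and benchmark exceedance:

```r
library(optifib)

sim  <- simulate_study(hydro_config(seed = 1), truth = truth_model(), seed = 1)
covs <- c(sim$sensors, list(flow = sim$flow))
covs$flow1h <- rolling_hour_mean(sim$flow)

cands <- enumerate_candidates("HB", pool = "S2-F", regime = "nonCSO")
cv    <- lapply(seq_along(cands), function(j)
  cross_validate(sim$samples, covs, cands[[j]], reps = 10, seed = 100 + j))
best  <- select_model(cv)
m_non <- fit_surrogate(sim$samples, covs, best$spec)
m_non
#> <fib_model> HB [nonCSO]
#> <fib_tobit> n=110 (3 censored), sigma=0.3339, logLik=-38.06
#>   (Intercept)          S2-F      S2-F:sin      S2-F:cos log10(flow1h)
#>      2.132200      0.543600      0.089681     -0.065558      0.829170
#>   smearing D=1.3585, calibration max=4.254e+05
```

The selected variable set is the generator's true one (S2-F plus flow), the
coefficients sit near the truth (2.0, 0.6, 0.8), `sigma` estimates the true
0.3 log10 noise, and the smearing factor 1.36 is what normal residuals of
that scale imply. Estimation and summaries:

```r
m_cso <- fit_surrogate(sim$samples, covs,
  model_spec("HB", opticals = best$spec$opticals, flow = best$spec$flow,
             regime = "CSO"))
est   <- estimate_continuous(list(CSO = m_cso, nonCSO = m_non), covs,
                             sim$schedule)
est
#> <conc_estimate> HB: 52560 points, 75 capped, 551 CSO-period

loads <- daily_loads(est, sim$flow)
p     <- annual_flow_weighted_proportion(loads, sim$flow,
                                         influent_mean(sim$influent, "HB"))
signif(p, 3)                                  # flow-weighted annual proportion
#> 0.0136
signif(annual_sewage_volume(p, sim$flow), 3)  # m^3 of sewage over the year
#> 1680000

benchmark_report(list(HB = est), default_criteria()[6:7, ])[,
  c("label", "percent_exceedance")]
#>                                      label percent_exceedance
#> 1 Human Bacteroides 4200 CN QMRA benchmark          12.562785
#> 2 Human Bacteroides 7800 CN QMRA benchmark           9.554795
```

So on this synthetic year, an estimated 1.36% of the stream's annual volume
was sewage and the 4,200 CN/100 mL risk benchmark was exceeded 12.6% of the
monitoring period. `run_pipeline()` wraps the same sequence for all markers
and regimes and writes CSV/JSON artifacts; see the vignette
(`vignettes/surrogate-modeling.Rmd`) for the model, its assumptions and the
design decisions.

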