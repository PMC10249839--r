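---
title: "Estimating bacteria concentrations and sewage contamination from in-situ optical sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating bacteria concentrations and sewage contamination from in-situ optical sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optifib)
```

## The problem

Fecal-indicator bacteria (FIB: *E. coli*, enterococci, fecal coliforms) and
human-associated indicator bacteria (HIB: human *Bacteroides* HF183, human
*Lachnospiraceae* Lachno3) are measured from discrete water samples that take
a day or more to analyze, so a monitoring campaign of ~150 samples per year
cannot resolve the hour-scale dynamics of urban streams. In-situ optical
fluorometers measure dissolved organic matter (FDOM, tryptophan-like
fluorescence) every ten minutes, and sewage carries a distinctive DOM
signature. `optifib` implements the surrogate-modeling workflow that turns
those optical signals into continuous bacteria estimates: sensor corrections,
left-censored regression in log10 space, cross-validated variable selection,
continuous estimation with combined-sewer-overflow (CSO) model switching,
load and sewage-proportion integration, and recreational water-quality
benchmark screening.

## The model

For a marker with concentration $c(t)$ the surrogate regression is

$$\log_{10} c = \beta_0 + \sum_{j \in \text{opt}} X_j\left(\beta_j +
\beta_j^{s}\sin\tfrac{2\pi d}{365.25} + \beta_j^{c}\cos\tfrac{2\pi d}{365.25}\right)
+ \beta_T\,\text{turb} + \beta_Q \log_{10} \bar Q_{1h} + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),$$

where $X_j$ are the optical signals (S1-CF, S1-A, S2-F in Raman units), $d$
is the decimal day of year, turbidity enters untransformed (FNU), and
$\bar Q_{1h}$ is the trailing one-hour mean streamflow. The seasonal
sine/cosine terms enter only as interactions with the optical variables: they
let the optics-to-bacteria slope drift with the annual cycle of background
DOM, which is the phenomenon they are meant to absorb. A configuration flag
can add seasonal main effects, but the default follows the interaction-only
design.

Design choices worth noting, since the workflow leaves them open:

* **Decimal day of year.** $d$ is days since January 1 (00:00 UTC = 0)
  including the fractional time of day, so $d/365.25 = 0.25$ lands a quarter
  of the way through the year.
* **Flow transform.** Flow enters as $\log_{10}$ of the one-hour rolling
  mean. The model is multiplicative in linear units, so a log-transformed
  flow term keeps the predictor on the same footing as the response; a switch
  (`model_spec`'s design is assembled by `build_design`) allows untransformed
  flow for sensitivity analysis.
* **Turbidity untransformed**, as a local optical interference/particle
  proxy rather than a second discharge surrogate.

### Censoring

Nondetects are left-censored at a detection limit $L$ that depends on
filtered volume (see `loq_from_volume`). The likelihood is the Tobit form:
uncensored points contribute $\phi\!\left(\tfrac{y - x\beta}{\sigma}\right)/\sigma$,
censored points contribute $\Phi\!\left(\tfrac{\log_{10} L - x\beta}{\sigma}\right)$.
`tobit_fit` maximizes this by BFGS on $(\beta, \log\sigma)$ with analytic
gradients, initialized at ordinary least squares on the uncensored points,
with a $10^{-8}$ relative log-likelihood tolerance. With nothing censored the
OLS solution *is* the MLE and is returned directly; $\sigma$ is the MLE
(no degrees-of-freedom correction) so the likelihood is comparable across
censoring patterns. The fit never returns parameters with lower likelihood
than its OLS start. Right-censoring is not supported.

### Back-transformation

Predictions on the concentration scale use Duan's smearing estimator
$\hat c = D \cdot 10^{x\hat\beta}$ with $D = \frac{1}{n}\sum_i 10^{e_i}$ over
the *uncensored* residuals. Censored observations have no observed residual;
restricting the smearing mean to uncensored points is a documented decision —
it slightly overstates $D$ when censoring is heavy, because the
most-negative residuals are unobservable. For exactly normal residuals
$D \to \exp((\sigma \ln 10)^2 / 2)$, which the tests verify by Monte Carlo.

## Sensor corrections

Field fluorometers drift, foul, and respond to temperature and turbidity.
`correct_sensors` applies, in a fixed order: fouling, drift, unit
conversion, temperature compensation, turbidity compensation.

* **Fouling** ramps linearly from zero at the previous cleaning to the
  (after − before) reagent-water difference at each maintenance visit;
  fouling accrues gradually, so a ramp is the default and a step at the
  visit is available (`mode = "step"`).
* **Drift** is multiplicative and linear in time: the pre/post-deployment
  calibration curves over quinine-sulfate standards give start and end
  sensitivities whose ratio scales the signal; sensitivity loss of an
  optical cell rescales the whole signal, hence a divisor interpolating from
  1 to that ratio. Deployment summaries often report drift as a single
  percentage without defining its base; the multiplicative-linear reading is
  this package's decision.
* **Unit conversion** (mV to Raman units) is an ordinary least-squares
  offset and slope against laboratory values.
* **Temperature** uses the standard linear divisor
  $F_{\mathrm{ref}} = F / (1 + \rho\,(T - T_{\mathrm{ref}}))$ (fluorescence
  quenching, $\rho \approx -0.01\,^{\circ}\mathrm{C}^{-1}$), and
  **turbidity** the exponential attenuation $F\,e^{k\,\mathrm{turb}}$;
  `fit_compensation` estimates $(\rho, k)$ from paired field/laboratory
  values by minimizing squared log-ratios. Inner-filter and absorbance-based
  corrections are out of scope.

Tryptophan-channel sensors with erratic laboratory relationships (the S1-T
and S3-T class) and channels redundant with S2-F are excluded from the
default variable pool.

## Model selection

Candidates are all non-empty subsets of the optical pool, each optical
carrying its seasonal interaction pair, crossed with inclusion of turbidity
and flow (`enumerate_candidates`; 28 candidates for the full three-sensor
pool). Predictive skill is estimated by five-fold cross-validation repeated
50 times: per repetition, a seeded shuffle partitions the samples into five
folds (stratified by regime label for combined-data models, so no training
fold is CSO-free), each fold is predicted out-of-fold, and one error is
computed on the pooled predictions — pooling, rather than averaging per-fold
errors, is the decision here. The score is the median over repetitions of
the log10-space RMSE (`nrmsep`). Censored observations score
$\max(0, \text{prediction} - \log_{10} L)$: predicting at or under the limit
is consistent with a nondetect. The normalization inside "normalized RMSEP"
is configurable (`none`, `range`, `mean`); the default is `none`, because
published medians for data of this kind (0.5–1.2) match raw log10 RMSE
magnitudes.

Selection is two-step (`select_model`): lowest median error; then, among
candidates within three percent of that minimum (relative, because error
scale varies by marker), the fewest explanatory-variable *terms*. A term is
a design column other than the intercept, so an optical variable with its
seasonal pair counts three. Ties on terms break by lower median, then by
canonical candidate order, making selection deterministic.

Eight markers (FC, EN and EC by culture, EN and EC by qPCR, HB, L3, and the
HB+L3 sum sHM) are each fit three ways — CSO-only samples, non-CSO samples,
all samples — giving the 24 scenarios of `fit_all_regimes`.

## Estimation, loads, proportions, benchmarks

`estimate_continuous` predicts every 10-minute step with the non-CSO model
except inside scheduled CSO discharge intervals, where the CSO model
applies. Predictions above the active model's *calibration maximum* (the
largest uncensored concentration in its training data) are set to that
maximum and flagged capped: extrapolation beyond the calibration range is
not trusted, but capped values are retained — conservatively — in loads and
benchmark screening, with the bias direction (understatement) documented.

Daily loads integrate concentration times discharge over calendar days (UTC,
no daylight-saving shifts, matching daily-value conventions):
$\mathrm{load} = \sum_t c_t \cdot 10^4 \cdot Q_t \cdot 600$ organisms/day,
with $c_t$ per 100 mL and $Q_t$ in m³/s. Days under 90% coverage are flagged
but still reported, not gap-filled. The proportion of sewage divides an HIB
estimate by the mean wastewater-influent concentration of the same marker
(for sHM, the sum of the HB and L3 means); the flow-weighted annual mean
proportion is total load over total water volume, divided by the influent
mean; the annual sewage volume multiplies that single annual proportion by
the total water volume — the uniform-annual reading of the procedure, rather
than summing daily proportions.

Benchmark screening (`benchmark_report`) ships seven criteria: the EPA
freshwater culture criteria for enterococci (GM 35 / STV 130 CFU per 100 mL)
and *E. coli* (126 / 410), their single-sample beach action values (70 and
235), the qPCR enterococci value (1000 cce), and two human-*Bacteroides*
QMRA risk benchmarks (4,200 and 7,800 CN per 100 mL) consumed as constants.
The GM/STV rule is evaluated on a *trailing 30-day window anchored at every
10-minute step* — the criterion text says "any 30-day interval", not
calendar months — a window exceeding if its geometric mean passes the GM
magnitude or more than 10% of its values pass the STV. Missing points leave
both numerator and denominator; windows under 50% coverage are unevaluable.
Culture criteria are never applied to qPCR estimates or vice versa.

## The synthetic-data generator

The generator (`simulate_study`) exists so the whole pipeline is testable
without field data. Its defaults emulate the structure of a year-long urban
deployment: a 10-minute grid over 365 days; baseflow 1.5 m³/s with 40
gamma-kernel runoff events (smooth rise and recession in one closed form),
15% of them CSO-influenced — six CSO discharge periods; 153 discrete samples
split 119 event-runoff (43 of those CSO) and 34 low-flow; twelve monthly
influent composites with lognormal month-to-month spread under one order of
magnitude.

Optical channels are a base level plus an annual sinusoid (background DOM
seasonality), a flow-coupled term in log10 relative flow (DOM flushed by
runoff), an independent AR(1) component with a ~5-day decorrelation time
(DOM composition changes that are *not* flow-driven), and measurement noise.
The AR(1) component matters statistically: without it every covariate is a
deterministic function of flow and season, all candidate models become
exchangeable, and variable selection is vacuous. Turbidity couples to flow
with multiplicative AR(1) scatter (sediment hysteresis makes real
turbidity–discharge relations scattered); temperature is an annual sinusoid.
True concentrations follow the same design the regression fits — so a
correctly specified model on noise-free data cross-validates to zero error —
with a +1 log10 intercept shift inside CSO intervals and truth noise
σ = 0.3 log10 units. Default truth intercepts are pitched at realistic
stream medians (human markers in the low thousands CN/100 mL, fecal
coliforms highest) and give concentrations spanning five-plus orders of
magnitude over the year; influent means (~10⁷ CN/100 mL for the human
markers, enterococci ~1.5 orders higher) are order-of-magnitude
placeholders, configurable and never asserted as ground truth. Censoring is
represented as a flag plus the limit — never zero or NA — because the
likelihood needs the limit explicitly.

What the generator does *not* emulate: EEM spectra or DOM chemistry,
rainfall-runoff physics, sediment-bound bacteria persistence, diurnal
cycles, or hysteresis in the optics-bacteria relation. Tests passing on this
generator show the estimators are correct and the workflow is wired
together; they do not show that any particular watershed satisfies the
model's assumptions.

## Test problem sizes and numerical choices

The test suite runs the full study conditions where the check is structural
(counts, regime membership, grid conservation) and scales Monte Carlo sizes
to what the statistic needs: coefficient-recovery uses 100 replicates of
n = 500 at 30% censoring; the end-to-end recovery check runs 50 seeded
year-long studies with a single-optical candidate pool (the optical channels
are mutually collinear by construction, so set recovery is only meaningful
for the turbidity/flow choices — a known limitation of any surrogate
workflow whose sensors share a driver) and requires the true variable set in
at least 70% of seeds and the flow-weighted annual sewage proportion within
25% relative error; cross-validation repetitions are reduced from 50 to 2–5
in tests that assert structure rather than selection power. Optimizer
tolerances are fixed (1e-8 relative log-likelihood; BFGS, max 500
iterations); ties in selection break deterministically; degenerate inputs
(all-censored responses, singular designs, constant predictors, zero
sensitivity, non-positive temperature divisors, negative turbidity) raise
errors or flag points rather than returning silent numbers.

## Known limitations

* Optical channels generated from shared drivers are statistically
  exchangeable; selection among them is not identifiable and real
  deployments should expect the same whenever sensors are highly correlated
  (the workflow's own reason for dropping one of two channels correlated at
  r ≈ 0.9).
* The smearing factor from uncensored residuals only is biased upward under
  heavy censoring.
* Capped estimates understate loads and exceedance above the calibration
  range; the cap is reported per point so users can quantify the exposure.
* No prediction intervals are propagated through loads or proportions;
  σ is reported per model and that is where uncertainty reporting stops.
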