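---
title: "Gaussian cue combination for perceived eye level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian cue combination for perceived eye level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelbayes)
```

## The model

Perceived eye level (PEL) is a subject's self-reported elevation angle judged
to be at eye level, in signed degrees with 0 at true eye level and positive
upward. In darkness the report is driven by a body-referenced belief — the
*body prior* — modelled as a Gaussian $N(\mu_b, \sigma_b^2)$. An illuminated
line on a frontoparallel wall, pitched by $\theta_i$ degrees, supplies a
visual cue: under the geometric interpretation the visual system treats the
line as a vertical seen in perspective, so the cue alone would place eye
level at $\theta_i$. Each line therefore contributes a Gaussian likelihood
$N(\theta_i, \sigma_{vi}^2)$ whose spread shrinks as the line lengthens.

Multiplying Gaussian densities gives another Gaussian: precision adds, and
the mean is the precision-weighted average. Fusing the prior with $n$
per-line likelihoods gives the posterior whose mean is the predicted PEL,

$$
\mu_p
 = \frac{\mu_b/\sigma_b^2 + \sum_i \theta_i/\sigma_{vi}^2}
        {1/\sigma_b^2 + \sum_i 1/\sigma_{vi}^2}.
$$

`combine_gaussians()` is that single primitive; `visual_likelihood()`,
`posterior()` and `predict_pel()` are thin compositions of it. The posterior
mean is always a convex combination of $\mu_b$ and the pitches, and the
posterior variance never exceeds any component's variance — both are tested
as properties against an independent grid-integration oracle.

### Length scaling and the simplified form

Treating each unit of line length as an independent sample motivates
$\sigma_{vi} = \sigma_{vl}/\sqrt{l}$ with a single length-free constant
$\sigma_{vl}$. Substituting into the fusion gives the simplified form

$$
\mu_p = a(l) + \frac{\sum_i \theta_i}{k/l + n}, \qquad
a(l) = \frac{\mu_b}{1 + nl/k}, \qquad
k = \sigma_{vl}^2/\sigma_b^2 ,
$$

implemented as `predict_pel_varying()` and `a_of_l()` and verified as an
algebraic identity against the general fusion to $10^{-9}$.

Two prediction routes coexist deliberately. The default,
`predict_pel()`, resolves each line's noise from a per-length calibrated map
(`sigma_vi`), because the published comparison calibrated the short and long
line separately. The length-scaled route is opt-in for extrapolating to
lengths never tested, since the independence assumption weakens for long
lines. Concretely, back-computing $k = \sigma_{vi}^2\, l / \sigma_b^2$ from
the calibrated values gives about 72.7 from the 12° line but about 134 from
the 64° line: a single $k$ does not describe both lengths, so the package
never silently forces one.

## Calibration

Two experimentally determined quantities pin the model down:

* **Prior**: the sample mean and sd (n−1 denominator, for small-sample
  unbiasedness) of dark-trial settings (`fit_dark_prior()`).
* **Likelihood variances**: a single-line sweep's regression slope of mean
  PEL on pitch equals the relative precision
  $m = \sigma_b^2/(\sigma_b^2 + \sigma_v^2)$, so
  $\sigma_v^2 = |\sigma_b^2/m - \sigma_b^2|$ (`fit_single_line_slope()`,
  `variance_from_slope()`). The absolute value covers slopes above 1, which
  no prior/likelihood decomposition can produce; such fits warn and are
  never clamped.

```{r calibration}
sqrt(variance_from_slope(0.1415, 2.08^2))  # short-line sigma_vi
sqrt(variance_from_slope(0.3234, 2.08^2))  # long-line sigma_vi
```

Regression runs on per-pitch condition means by default (the published
analysis regresses mean PEL on pitch); `regress_on = "trials"` uses raw
settings. A caveat the package reports but does not resolve: the published
regression intercepts (−1.869 short, −4.9429 long) are not equal to the
model-implied intercept $(1-m)\mu_b$ for the calibrated prior mean of
−0.622°; `calibrate_trials()` returns the fitted intercepts alongside the
model parameters so users can see both.

## Additive versus averaging combination

Weak cues add; strong cues average. For two identical cues the shift of the
combined percept away from the prior, divided by the sum of the two
single-cue shifts, is

$$
\frac{\sigma_{vi}^2 + \sigma_b^2}{\sigma_{vi}^2 + 2\sigma_b^2} \in (0.5,\ 1),
$$

approaching 1 (pure summing) as the cue weakens and 0.5 (pure averaging) as
it strengthens. `combination_regime()` measures this empirically by
regressing the two-line shift on the sum of single-line shifts over a pitch
grid; because the model is exactly linear in pitch the regression equals the
closed form to machine precision, which is itself a test. Shifts are taken
relative to the prior mean so a nonzero $\mu_b$ does not bias the slope.
The regressor choice (sum of single-line shifts) follows the summation/
averaging reference lines of the published two-line figure.

```{r regime}
p <- generate_matin_li_preset()$params
combination_regime(p, 12)$slope   # short line: more additive
combination_regime(p, 64)$slope   # long line: closer to averaging
```

The labels "additive-like" (slope ≥ 0.9) and "averaging-like" (≤ 0.6) are
heuristic conveniences only — published analyses report raw slopes without
cutoffs — and the raw slope is always attached to the report.

## The comparison baseline

The earlier behavioural model,
$\mathrm{PEL} = a + k_1 \sum_i \theta_i / (k_2/l + n)$, is implemented
exactly in `predict_pel_matin_li()` with the published constants available
via `matin_li_published_params()` ($k_1 = 0.51$, $k_2 = 19.44$ shared;
$a = -0.29$ short / $-4.61$ long, stored per length as published).
Refitting these constants is out of scope: they are inputs. Structurally the
two models differ only in the gain $k_1$ and in $a$ being a constant rather
than the derived $a(l)$.

## The synthetic observer

`simulate_observer()` generates a full experiment's trial table from an
`experiment_design()` and observer parameters. What it emulates: the classic
design — dark trials, single-line sweeps over pitches −30°…30° in 10° steps
at 12° and 64° lengths, and two-line conditions (both lines at one pitch by
default). What is assumed, because no trial-to-trial variability model was
published: each setting is a draw from the condition's *posterior*
(probability matching, sd $\sigma_p$), with optional additive motor noise
(default 0 — the stated comparisons concern condition means, which motor
noise leaves unchanged). Trial counts per condition are likewise unstated;
200 is the default, chosen so that calibration recovers scale parameters to
a few percent while a full simulate-calibrate round trip stays below a
second. A single subject is simulated per run; batches loop with derived
seeds. Tables are bit-identical under a fixed seed and the global RNG state
is restored afterwards.

A green parameter-recovery test therefore establishes that the pipeline
inverts *this* generative observer at this scale — not that real subjects
are probability matchers, nor anything about sequential effects, lapses, or
adaptation, none of which are modelled.

## Evaluation

`standard_error_of_estimate()` is population RMSE
($\sqrt{\sum (o-p)^2/n}$) by default — the published "standard error in
estimation" is not defined, so the convention is explicit and an $n-2$
regression variant is available. `compare_models()` scores both models per
condition mean (per trial optionally). The published two-line error table
cannot be recomputed here because the underlying two-line settings were
never printed; the package's tests replace it with oracle-equivalence,
regime, and parameter-recovery properties plus a self-consistency check on
synthetic data. Dark conditions carry no line length, so the behavioural
model's per-length intercept is unresolvable there: its prediction is `NA`
and such rows are excluded from its error.

## Numerical choices and limitations

* All internal arithmetic is in variance (deg²); standard deviations appear
  only at interfaces, avoiding repeated squaring slips.
* Uninformative beliefs carry an explicit zero-precision flag rather than a
  huge sentinel variance, so limits are exact.
* Fusion is closed-form; the grid-integration oracle (step 0.01° over
  ±150°) exists only in the test suite and agrees to $10^{-6}$.
* Angles are degrees everywhere; there is no radian surface.
* CSV round-trips write 17 significant digits so doubles survive exactly.
* Out of scope: non-Gaussian priors/likelihoods, head-tilt or vestibular
  manipulations beyond shifting the prior, 2-D (azimuth) generalisation,
  and any implementation-level neural account.
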