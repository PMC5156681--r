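# pelbayes

Bayesian cue combination for **perceived eye level (PEL)** — the elevation
angle a seated observer reports as "straight ahead", in signed degrees.
In darkness the report reflects a body-referenced prior; pitched illuminated
lines on a wall pull it toward the pitch angle, because the visual system
reads a pitched line as a vertical seen in perspective. `pelbayes` is for
visual-psychophysics researchers who want to model, calibrate, simulate and
score this kind of prior–likelihood fusion without external data.

The core model is closed-form Gaussian fusion. With a body prior
$N(\mu_b, \sigma_b^2)$ and $n$ lines of pitch $\theta_i$ contributing
likelihoods $N(\theta_i, \sigma_{vi}^2)$, the predicted PEL is the posterior
mean

$$
\mu_p = \frac{\mu_b/\sigma_b^2 + \sum_i \theta_i/\sigma_{vi}^2}
             {1/\sigma_b^2 + \sum_i 1/\sigma_{vi}^2},
$$

equivalently $\mu_p = a(l) + \sum_i\theta_i/(k/l + n)$ with
$a(l) = \mu_b/(1 + nl/k)$ and $k = \sigma_{vl}^2/\sigma_b^2$ under the
length-scaling assumption $\sigma_{vi} = \sigma_{vl}/\sqrt{l}$. Calibration
uses the dark-condition sample moments for the prior and the single-line
sweep slope $m = \sigma_b^2/(\sigma_b^2+\sigma_v^2)$, inverted as
$\sigma_v^2 = |\sigma_b^2/m - \sigma_b^2|$, for the visual noise. The
Matin–Li behavioural model
$\mathrm{PEL} = a + k_1\sum_i\theta_i/(k_2/l + n)$ is included as the
comparison baseline.

## Worked example

```r
library(pelbayes)

p <- generate_matin_li_preset()$params
p
#> <model_params> prior: mean -0.6220 deg, sd 2.0800 deg
#>   sigma_vi: 5.120 deg @ 12 deg, 3.010 deg @ 64 deg

# Two long lines pitched 20 deg: the posterior mean sits between the prior
# (-0.622 deg) and the pitch, pulled hard toward 20 by two strong cues.
predict_pel(line_stimuli(c(20, 20), 64), p)
#> [1] 9.451903

# How do two identical short-line cues combine? Slope 1 = their effects sum,
# 0.5 = they average. Short lines are weak cues, so they are nearly additive.
combination_regime(p, 12)
#> <regime_report> length 12 deg: combined-vs-sum slope 0.8759 (intermediate)
#>   closed-form shift ratio 0.8759; cutoffs: additive-like >= 0.9,
#>   averaging-like <= 0.6

# Simulate a full experiment (dark + single- and two-line conditions) from a
# seeded Bayesian observer, then recover its parameters from the trials.
preset <- generate_matin_li_preset(seed = 7)
trials <- simulate_observer(preset$design, preset$params)
calibrate_trials(trials)
#> <calibration_fit> prior mean -0.3421 deg, sd 1.9792 deg (n = 200)
#>   length 12 deg: slope 0.1419 -> sigma_vi 4.8679 deg
#>   length 64 deg: slope 0.3209 -> sigma_vi 2.8790 deg

# Score the Bayesian observer against the behavioural baseline on condition
# means; on data the Bayesian observer generated it wins, as it must.
compare_models(trials, preset$params, matin_li_published_params())
#> <pel_model_comparison> 29 rows; SEE: Bayesian 0.114 deg, Matin-Li 3.193 deg
```

The recovered values (prior sd 1.98 vs 2.08, sigma_vi 4.87 vs 5.12 and 2.88
vs 3.01) show the calibration pipeline inverting the generator at 200
trials/condition; the residual gaps are sampling noise.

A command-line wrapper ships at `inst/cli/pel.R`
(`Rscript $(Rscript -e 'cat(system.file("cli", "pel.R", package = "pelbayes"))') simulate --preset matin-li --seed 7 --out trials.csv`),
with subcommands `simulate`, `calibrate`, `predict`, `compare`, `regimes`;
see `?pel_cli`.

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch through the installed
package, the calibrated likelihood standard deviations for the short and
long line (from the published regression slopes and prior sd) and the
model-predicted single-line sweep slopes for both calibrated observers
(by OLS over the experimental pitch grid), writing them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
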