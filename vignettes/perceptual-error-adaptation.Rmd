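---
title: "Perceptual-error models of implicit visuomotor adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perceptual-error models of implicit visuomotor adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peadapt)
```

## The scientific problem

In the error-clamp paradigm a reaching participant sees a cursor whose
direction is fixed at an angle $\theta$ from the target regardless of
where the hand actually goes. Although participants are told to ignore
the cursor, their movements drift trial by trial in the direction
opposite the clamp — implicit adaptation. Two of its features resist
classical error-based learning accounts: *overcompensation* (adaptation
to a 2–16° clamp can exceed the perturbation several-fold) and a
*concave* dependence on clamp size (adaptation grows, plateaus around
8–32°, and declines for very large clamps).

The perceptual-error adaptation (PEA) model implemented here explains
both with two ingredients:

1. **Precision-weighted cue combination.** The hand-direction percept on
   trial $n$ combines three Gaussian cues — visual
   $x_v \sim N(\theta, \sigma_v^2)$, proprioceptive
   $x_p \sim N(x_{\text{hand}}, \sigma_p^2)$ and predictive
   $x_u \sim N(T, \sigma_u^2)$ — as
   $\hat{x}_n = \sum_i W_i x_{i,n}$ with
   $W_i = (1/\sigma_i^2) / \sum_j (1/\sigma_j^2)$.
2. **State-space learning from the perceptual error.** The adapted hand
   direction updates as
   $x_{p,n+1} = A\,x_{p,n} + B\,(T - \hat{x}_n)$, with retention $A$ and
   learning rate $B$. The driving error is the deviation of the
   *percept* from the target, not a visual error.

The third, load-bearing assumption is that visual uncertainty grows
linearly with the cursor's eccentricity from fixation,
$\sigma_v = a + b\,|\theta|$: participants fixate the target, so large
clamps land in the visual periphery, where direction discrimination is
poor. Small clamps are seen precisely and keep pulling the percept off
the target (overcompensation); huge clamps are seen so imprecisely that
they barely move the percept (the declining limb of the concave
profile).

The closed-form asymptote of the adapted state under a constant clamp is

$$x_p^{\text{asym}} \;=\; -\,\frac{B/\sigma_v^2}
{B/\sigma_p^2 + (1-A)\sum_j 1/\sigma_j^2}\;\theta ,$$

and with full retention ($A \equiv 1$) this reduces to the
two-parameter ratio form
$-\big(R_1/(1 + R_2\theta)\big)^2\,\theta$ with $R_1 = \sigma_p/a$,
$R_2 = b/a$ (`asymptote_ratio_form()`).

```{r asymptote}
p <- pea_params()     # defaults: the published operating point
-pea_asymptote(c(2, 8, 32, 95), p)
```

## Sign conventions

Internally the target sits at 0°, the clamp at $+\theta$, and the
adapted state goes negative (away from the cursor). All public outputs
carry `extent_deg = -state_deg` so that adaptation plots positive, the
field's plotting convention. The PReMo equations natively use the
positive-adaptation convention, so its simulator's state *is* the
extent. `|theta|` is used inside the eccentricity law; the sign of the
clamp only sets the direction of the bias (clockwise and
counter-clockwise perturbations are treated symmetrically, and the
synthetic generators counterbalance and sign-fold directions).

## Feedback modes

The published equations cover clamp cycles only; a full session also
has veridical-feedback baseline and no-feedback phases. The package's
choices (flagged as its own):

* `clamp`: visual cue at $\theta$, with $\sigma_v = a + b|\theta|$.
* `veridical`: visual cue at the hand, with the intercept uncertainty
  $\sigma_v = a$ (the cursor is near fixation).
* `none`: the visual cue is removed and the remaining two weights are
  renormalised. How cue combination behaves without vision is not
  constrained by the data the model was built for; renormalisation is
  the minimal choice consistent with the combination rule.

Deterministic simulations (`noise = FALSE`) evaluate every cue at its
mean — this is the fitting mode, matching the practice of fitting
group-mean trajectories. Stochastic mode draws each cue per cycle and
is reserved for synthetic data generation. Simulation granularity is
the cycle (four targets averaged); the canonical session is 15
veridical + 15 no-feedback baseline cycles, 80 clamp cycles, 10
no-feedback washout cycles.

## Tunable parameters

| parameter | units | default | role |
|---|---|---|---|
| `A` | – | 0.974 | retention per cycle |
| `B` | – | 0.208 | fraction of perceptual error corrected |
| `sigma_p` | deg | 11.119 | proprioceptive uncertainty |
| `sigma_u` | deg | 5.048 | prediction uncertainty |
| `a` | deg | 1.853 | visual uncertainty at fixation |
| `b` | deg/deg | 0.309 | uncertainty growth with eccentricity |
| `Rp` | – | 0.2 | probe-bias fraction of the hand estimate |
| `decay_lambda` | – | 0.3 | per-probe decay of that influence |

The defaults for `A`, `B`, `sigma_p`, `sigma_u` are the values
estimated from the seven-group adaptation experiment, and `a`, `b` the
psychophysically measured law; together they are the operating point at
which all qualitative signatures below hold. `Rp = 0.2` reflects the
commonly reported ~20% proprioceptive-recalibration fraction;
`decay_lambda = 0.3` makes the hand-estimate influence on a passive
probe essentially vanish by the third probe trial ($0.3^2 = 0.09$), the
behaviour seen empirically. The exact decay law is not constrained
beyond "fast"; geometric decay is the simplest choice.

## Rival models

**PReMo** (proprioceptive re-alignment): the percept is shifted by a
*saturating* function of the visual–proprioceptive discrepancy,
$\beta_p = -\operatorname{sign}(d)\min(\beta_{sat}, \eta_p|d|)$ with
$d = R_1 x_v - R_2 x_p$; once saturation binds, extent-versus-size is a
ramp and cursor blurring has no effect at large clamps. Whether the
saturation clamps the signed value or the magnitude is ambiguous in the
printed form; the magnitude (with mirrored sign) is used so the two
rotation directions behave symmetrically.

**Causal inference**: learning is scaled by the probability of
attributing the cursor to one's own action,
$p = S\,N(x_v; 0, \sigma^2) / (N(x_v; 0, \sigma^2) + C)$, which
collapses for large clamps (extent peaks mid-range, then declines
steeply) and — distinctively — *rises* under blur at large clamps,
because a wider density assigns far-off cursors more probability.
`S` and `C` are validated jointly at construction so `p` cannot exceed
1, a constraint implicit in its role as a probability.

Neither rival's fitted parameter values are published for this
comparison; the package defaults are its own choices, made once, that
place each model in its characteristic regime: PReMo's
`beta_sat = 6.5`° puts saturation near the 6–7° discrepancy associated
with that account (with `R1 = 0.739`, `R2 = 0.171` derived from the PEA
uncertainties and `sigma_v = 3`°), and the causal-inference defaults
(`sigma = 20`, `S = 0.2`, `C = 0.0073`) give an extent profile that
tracks mid-size clamps and collapses beyond. Both share the PEA's `A`
and `B`. PReMo's blur mapping needs `sigma_u` and `sigma_v` separately,
which `R1` alone does not give; the package fixes `sigma_u` at the PEA
value and inverts `R1` for `sigma_v`.

```{r signatures}
rbind(pea = -pea_single_trial(c(4, 16, 64), pea_params(), blur_ratio = 2) /
            -pea_single_trial(c(4, 16, 64), pea_params()),
      premo = premo_single_trial(c(4, 16, 64), premo_params(), blur_ratio = 2) /
              premo_single_trial(c(4, 16, 64), premo_params()),
      ci = ci_single_trial(c(4, 16, 64), ci_params(), blur_ratio = 2) /
           ci_single_trial(c(4, 16, 64), ci_params()))
```

Each row is the ratio of blurred to clear single-trial learning: PEA
attenuates large clamps most, PReMo spares saturated clamps entirely,
and causal inference reverses at 64°.

## Psychophysical calibration

Visual uncertainty is measured with a 2AFC judgment of the cursor's
direction against a briefly flashed reference point, driven by a PEST
staircase: the reference starts 30° to one side, steps toward the
cursor in 10° steps, and the step halves (and the movement direction
reverses) whenever the judgment changes; a round ends when the step
drops below 1° or after 30 trials, and successive rounds start on
alternating sides. The printed procedure specifies the halving rule but
not the movement-direction rule or the exact termination step; both are
configurable arguments with these defaults.

Responses are fitted with a two-parameter logistic (no lapse rate —
exactly the printed form) by Bernoulli maximum likelihood
(`stats::glm`), and the uncertainty is the 25–75% quartile width
$\sigma_v = 2\ln 3 / k$. Per-observer, per-size uncertainties are then
regressed on $|\theta|$ with a gamma-family GLM and identity link —
gamma because uncertainties are positive and right-skewed across
observers, identity to match the linear functional form of the law.

## Fitting protocol

`multistart_fit()` mirrors the standard protocol: bounded local least
squares (`optim(method = "L-BFGS-B")`) from 100 starting points drawn
uniformly within box bounds (defaults: $A \in [0.5, 1]$,
$B \in [0, 1]$, uncertainties $\in [0.5, 45]$°,
$\beta_{sat} \in [1, 45]$°, $\eta_p \in [0.01, 5]$, $S \in [0, 10]$,
$C \in [10^{-6}, 1]$), seeded and bit-reproducible. The loss is the sum
of squared differences between deterministic model trajectories and
observed cycle-mean hand angles over *all* 120 cycles including
baseline and washout (model curves are conventionally drawn through all
phases; a clamp-only loss is available by subsetting the data). Model
comparison uses the Gaussian-SSE information criterion
$\mathrm{AIC} = n\ln(\mathrm{SSE}/n) + 2k$ with $n$ the number of
cycle-mean points; because the published comparison's AIC convention is
not printed, only *orderings* of AIC are meaningful here, never
absolute values.

One numerical caveat found while validating the machinery: the
free-per-size-uncertainty refit (`fit_free_sigma_v()`, one
$\sigma_v$ per clamp size instead of the linear law) has a practically
flat ridge on noise-free cycle means — an $A = 1$ solution reproduces
the 840 points to about $10^{-5}$° RMS. The recovered uncertainties
remain strongly linear in $|\theta|$ anywhere on the ridge (that is the
scientifically relevant claim), but the raw rates are only weakly
pinned; `fit_free_sigma_v()` therefore accepts a linear-law fit as a
warm start, the standard way to anchor such a refit.

## Synthetic data: what it emulates, and what it does not

The generators produce exactly the data-generating process the model
family assumes: Gaussian cues, linear eccentricity law, state-space
updating, blur-scaled visual uncertainty, probe bias proportional to
the recent hand estimate with geometric decay. Per-trial motor
execution noise defaults to 5.128° (typical baseline movement
variability), entering cycle-level data as the mean of four per-trial
draws. Subject-level parameter heterogeneity is off by default: every
simulated subject shares the truth parameters.

Consequently, passing recovery tests shows that the *pipeline*
(generators → staircase → psychometric fits → GLM; generators →
multi-start least squares) identifies the generating parameters under
the model's own assumptions at realistic noise levels and sample sizes.
It does not show that real reaching data satisfy those assumptions —
no use-dependent biases, no explicit strategy leakage, no attentional
lapses in the 2AFC (the fitted logistic has no lapse rate), no
subject-level parameter spread, no savings or meta-learning.

Default problem sizes mirror the experimental designs: 7 groups × 12
subjects × 120 cycles (adaptation), 18 observers × 3 sizes × both
directions × 3 days × 4 PEST rounds (discrimination), 11 subjects × 32
perturbation blocks (proprioception), 19 subjects × 3 days × 15 blocks
× 12 triplets (single-trial learning). Tests that only need the law of
large numbers use larger groups (e.g. 200 subjects for the
asymptote-convergence check) or smaller ones (property checks), chosen
per test and stated there.

## Degenerate inputs and numerical choices

Non-positive uncertainties, empty schedules, blur ratios below 1,
out-of-range rates and probabilities are rejected with explicit errors
at construction — never clamped silently. The deterministic simulator
evaluates per-cycle affine recursions with precomputed coefficients
(algebraically identical to literal per-cycle iteration; the
asymptote/simulation agreement test pins this to $10^{-6}$). The
asymptote is undefined for $A = 1, B = 0$ and for non-positive
denominators; both are signalled. Psychometric fits fail loudly on
fewer than four distinct offsets, one-sided responses, or complete
separation. The causal-inference attribution cap ($p \le 1$) is
enforced at construction and, during fitting, by a finite penalty so
bounded optimisation remains well-behaved.

## Known limitations

* The no-feedback cue-combination rule and the probe-decay law are
  package choices where the published account is silent; both are
  arguments, not constants.
* Rival-model default parameters are regime choices, not published
  fits; conclusions about the rivals should rest on their fitted
  versions (`run_compare()`), not the defaults.
* Absolute AIC values depend on an unprinted convention and are not
  comparable across software.
* Explicit/strategic learning, savings, relearning, and 2-D kinematics
  are out of scope.
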