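---
title: "Models and methods behind memmixr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind memmixr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(memmixr)
```

This vignette is the package's account of its science: the mixture model and
its block-diagram interpretation, the estimation machinery, the synthetic
data generator, and the numerical and design choices that were genuinely
open, with the reasons we settled them the way we did.

## The error distribution and its two readings

Each trial of a continuous-report experiment yields a signed error angle
ε on (−180°, 180°]. We model its density as an n-Gaussian + uniform mixture

$$\mathrm{PDF}(\varepsilon) \;=\; \sum_{i=1}^{n} \omega_i\,
G(\varepsilon;\mu_i,\sigma_i) \;+\; \Big(1-\sum_i \omega_i\Big)\,U(-180,180),$$

with n between 1 and 5. The uniform component models guessing — reports made
with no stored information — so the total Gaussian weight ω is the *intake*
(quantitative measure) and each 1/σᵢ a *precision* (qualitative measure).
The scalar transformed performance TP = 1 − |ε|/180 complements the mixture
view; its anchors are TP = 1 for a perfect report and an expectation of 0.5
under uniform guessing.

The second reading is generative. Visual processing passes through stages —
encoding, sensory memory (SM), attention, short-term memory (STM) — each of
which we model as adding Gaussian noise. Two facts make architectures
tractable: the convolution of Gaussians is Gaussian (means and variances
add), and routing probabilities multiply along a path. Hence:

* a single memory stage, or an SM → STM chain, reduces to **one** Gaussian +
  uniform (for the chain, σ² = σ²_SM(t) + σ²_STM);
* an architecture in which attention taps the stimulus *in parallel with*
  the decaying SM trace, both feeding STM, reduces to **two** Gaussians +
  uniform with weights ω₁ω₂ (SM route), ω₁(1−ω₂) (attention route) and
  1−ω₁ (guessing) — and only the SM-routed component's SD depends on the
  cue delay t;
* an architecture with two parallel SM → STM routes (nonselective vs
  selective transfer) also reduces to two Gaussians + uniform, with weights
  ω₁, ω₂, 1−ω₁−ω₂ — but there **both** component SDs depend on t.

The last point is the discriminating signature: BIC can say "two Gaussians",
but only the delay-dependence pattern of the two fitted SDs says which
architecture produced them. `reduce_model_ab()`, `reduce_model_c()` and
`reduce_model_d()` implement the reductions; `sigma_trend_test()` and
`model_c_vs_d_verdict()` implement the signature test.

Only SM decays on the timescale of a trial. We expose the decay as a
`decay_law(sigma0, sigma_inf, tau, form)` object. The literature constrains
the *fact* of decay (SD increases with delay over up to a second or so) but
not its functional form, so the form is configurable; the default is the
saturating exponential σ(t) = σ∞ − (σ∞ − σ0)·e^(−t/τ), which matches the
flattening seen in delay curves and keeps σ bounded. The decay law is used
only by the generator and the reductions — fitting never assumes it.

## Likelihood on a clipped domain

The error domain is bounded, and a Gaussian on (−180, 180] loses tail mass.
Two modes are provided. `"truncated_renormalized"` (default) divides each
Gaussian by its mass on the interval, so the mixture integrates to exactly 1
and the log-likelihood is a valid basis for BIC. `"plain"` uses raw Gaussian
densities — the common approximation that ignores clipping — and is provided
for comparability with analyses that use it; in that mode densities are
floored at 1e−300 before the log so outliers yield large finite penalties
rather than NaNs. For stage SDs up to ~30° the two modes are numerically
indistinguishable; the approximation degrades as SDs approach 90°, which the
test suite measures explicitly.

A related, deliberate asymmetry: the generator *wraps* stage noise onto the
domain (as an angular report would), while the likelihood *truncates*. For
the SD ranges of interest the difference is far below sampling noise — the
Kolmogorov–Smirnov checks in the suite confirm stage-wise sampling and the
reduced truncated mixtures agree at n = 10⁵ — but it is a model
approximation, not an identity.

## Estimation

`fit_mixture()` maximizes the likelihood with multi-start Nelder–Mead
simplex search (`stats::optim`), in an unconstrained parameterisation:

* σᵢ mapped to `sigma_bounds` through a logistic transform. The lower bound
  0.5° prevents spike components on repeated values; the default upper
  bound is 180°.
* the n + 1 weights (Gaussians + uniform) live on the simplex through a
  softmax with the uniform's logit pinned at 0;
* means are free, initialised at N(0, 10°), or fixed at 0 with
  `fix_means_at_zero` (2 instead of 3 free parameters per component).

Mixture likelihoods are multimodal, so the optimizer is restarted from
`n_starts` (default 20) stratified random initialisations: SDs log-uniform
on [2°, 90°], weights Dirichlet-uniform. The best start wins; all starts are
derived from one seed, so fits are bit-reproducible. `extra_starts` lets a
caller warm-start from existing specs — embedding an (n−1)-component fit
with a near-zero extra weight guarantees the larger model can never fit
worse in sample.

BIC is k·ln N − 2·ln L with k = 3n free parameters (2n with fixed means);
the uniform weight is derived, not counted. `compare_models()` fits each
candidate n with a shared seed policy and breaks BIC ties toward smaller n
(parsimony). A CDF least-squares objective (`fit_cdf_least_squares()`) is
provided alongside maximum likelihood because cumulative-distribution
fitting is common in this literature and the two should — and, on clean
data, do — agree; ML is the default because its likelihood feeds BIC
directly.

Degenerate inputs are flagged rather than hidden: a fit whose SD lands
within 0.05° of a bound, or whose data are a point mass, carries
`boundary = TRUE`. A pure-uniform fit reports intake 0 and *missing*
precision (not zero) in `summarize_condition()`.

### Bounded SDs for trend analysis

On a 360° domain a Gaussian with σ ≳ 60° is nearly flat, so the widest
component and the uniform can swap roles at realistic cell sizes; the fitted
"σ₂" then jumps to 100°+ with near-zero weight, which is noise, not memory.
For the per-cell fits feeding the trend analysis we therefore bound SDs at
60°, comfortably above the generative SDs (≤ ~35°) but below the
exchangeable regime. This is an analysis choice, stated here once, applied
everywhere the trend machinery is demonstrated.

## Trend tests and the architecture verdict

`sigma_trend_test()` asks whether a fitted component SD depends on the cue
delay, with subjects as blocks. Two instruments are computed:

* a one-way repeated-measures ANOVA (`stats::aov` with an
  `Error(subject)` stratum), sphericity-uncorrected, giving the
  conventional F((d−1), (d−1)(s−1)) — F(5, 20) for 6 delays and 5
  subjects — which matches how such analyses are conventionally reported;
* a within-subject permutation test of monotone trend. The statistic is the
  mean across subjects of the correlation between the SD and the *rank* of
  the delay; delay labels are permuted within subject (two-sided p). The
  rank form makes the statistic insensitive to a single degenerate cell
  fit, and the permutation reference requires no distributional assumptions
  — important with 5 subjects and a noisy per-cell estimator. Delays are
  also strongly skewed (0–1600 ms), so rank spacing is a better regressor
  than raw milliseconds.

The ANOVA is run on per-subject σ matrices (one fit per subject × delay),
which yields the printed degrees of freedom; averaging across observers
first would destroy them. `model_c_vs_d_verdict()` turns the two components'
p values into a label: exactly one significant → "C-consistent" (one
delay-dependent SD), both → "D-consistent", neither → "indeterminate";
α defaults to 0.05 and either instrument can be selected
(`use_permutation`). For small-n signature work we recommend — and the
acceptance suite uses — the permutation p.

## The synthetic-data generator

The behavioural data this methodology was developed on are not publicly
deposited, so `simulate_trials()` is a first-class module, not a fixture. It
samples the *block diagrams*, not the reduced mixtures: per trial it chooses
a route by the routing weights, draws each stage's Gaussian noise
sequentially (SM at σ_SM(t), then STM; or attention, then STM), sums and
wraps onto (−180, 180]; guessing draws uniformly. The chosen route is kept
as hidden ground truth, and the subject-adjusted reduced mixture of every
cell rides along as an attribute, so recovery tests can compare estimates
against the exact generative truth.

The packaged default (`emulate_study_dataset()`, scenario
`default_model_c_scenario()`) emulates a two-experiment design: set sizes
1–4 at zero delay, and set size 3 at delays 0, 100, 200, 400, 800, 1600 ms,
in single-report (SR) and first-full-report (FR1) conditions, 5 subjects,
300 trials per subject × condition × cell. Parameter choices, made once:

* SR routes half its non-guess trials through SM (ω₂ = 0.5) with
  σ_SM: 13° → 30° (τ = 400 ms); FR1 — where the observer reports the
  best-remembered, already-transferred item — routes only a quarter through
  SM with a milder ceiling (13° → 20°). Attention and STM SDs are 6° and 4°,
  time-stable. These place the reduced component SDs (≈7° and ≈14–30°) and
  weights in the ranges typical of published delay-curve analyses, and
  produce the qualitative signatures the analysis targets: Sigma1 flat in
  delay for both conditions, Sigma2 rising steeply for SR and mildly for
  FR1.
* Intake falls with set size (ω₁: 0.95, 0.85, 0.75, 0.65 for 1–4 disks)
  with a mild SD inflation, since each set size is fitted independently the
  effects are supplied as an explicit per-set-size map, not a law.
* Between-subject heterogeneity is log-normal (SD 10%) on stage SDs and
  logit-normal (SD 0.2) on routing weights — enough to make
  repeated-measures analyses meaningful, small enough that one subject's
  parameters do not change regime. Five subjects matches the F(5, 20)
  df structure of the analyses being emulated.
* Trials per cell defaults to 300 — a realistic multi-session
  psychophysics volume, and enough for stable 2-Gaussian fits.
* The parallel-routes demonstration scenario (no published parameter values
  exist for it) uses routes 6°→18° + 4° and 12°→32° + 6° with weights
  0.45/0.35, and 800 trials per cell in the demonstrations: its wide
  selective route needs larger cells for stable per-cell SD estimates.

What the generator does *not* emulate: actual motion trajectories and
deviations, response times, feedback, misbinding/swap errors, second and
later full-report responses, and any non-Gaussian stage noise. Passing
recovery tests on these data therefore shows the estimator and signature
machinery are sound under the model's own assumptions — it cannot show that
real data satisfy those assumptions.

## Problem sizes used by the verification suite

The acceptance suite checks: the TP anchors analytically; unit mass of 100
randomized truncated mixtures by quadrature (tolerance 1e−6); stage-wise
sampling vs reduced mixtures at n = 10⁵ per architecture (KS p > 0.01);
parameter recovery from the SM/attention/STM truth at N = 5000 over 20
seeds (median absolute weight error ≤ 0.05, SD error ≤ 15%); BIC selection
of the true order (1 vs 2, SDs 8° vs 30°) at N = 2000 in ≥ 80% of 20
replicates; signature recovery on 20 simulated SR datasets (Sigma1 flat and
Sigma2 rising in ≥ 80%, permutation test) plus parallel-routes datasets
yielding "D-consistent"; and byte-identical JSON from identical seeds.
Within-suite fits use 6–10 starts with means fixed at zero (the generative
truths are zero-mean), which the recovery tolerances above absorb.

## Known limitations

* Gaussian stages on a bounded domain are an approximation; for stage SDs
  beyond ~60° the truncated-Gaussian and uniform components become nearly
  exchangeable and per-cell fits degenerate. The 60° bound manages, but
  does not remove, this.
* Component labels are resolved by sorting on σ; when the two true SDs
  cross or nearly coincide, "Sigma1/Sigma2" trajectories can mix the
  underlying routes.
* The repeated-measures F is sphericity-uncorrected by design (to match
  conventional reporting); with 6 delay levels and 5 subjects it is
  anticonservative under sphericity violations — hence the permutation
  alternative.
* No misbinding component and at most five Gaussians; wrapped-normal (von
  Mises-style) circular densities are out of scope.
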