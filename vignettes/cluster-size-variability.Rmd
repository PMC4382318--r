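---
title: "Methods: power loss from cluster-size variability in CRTs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: power loss from cluster-size variability in CRTs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crtpowersim)
```

## The question

Sample-size calculations for cluster-randomized trials (CRTs) typically
assume a common cluster size $\mu$. When sizes vary around $\mu$, the trial
carries less information than the fixed-size formula credits it with, and
power falls below its nominal level. `crtpowersim` measures that loss by
simulation: it calibrates a design to exactly 80% power at fixed sizes,
re-estimates power under negative-binomially distributed sizes at a chosen
coefficient of variation (cv), and converts the resulting power curves into
the number of clusters actually required.

## Data-generating model

Outcomes are hierarchical normal:

$$Y_{jk} \mid X_k = \eta_k + \Delta X_k + \epsilon_{jk}, \qquad
\eta_k \sim N(0, \sigma^2_\eta), \quad
\epsilon_{jk} \sim N(0, \sigma^2_\epsilon),$$

with cluster-level intercepts $\eta_k$ shared by all individuals of cluster
$k$ and a cluster-constant binary arm indicator $X_k$. The between-cluster
variance $\sigma^2_\eta$ (BCV) and the intraclass correlation
$\mathrm{ICC} = \sigma^2_\eta / (\sigma^2_\eta + \sigma^2_\epsilon)$ are the
user-facing variance parameters; the residual variance is derived as
$\sigma^2_\epsilon = \mathrm{BCV}(1-\mathrm{ICC})/\mathrm{ICC}$
(`derive_residual_variance()`). Arms are assigned completely at random in a
forced 50/50 split (`assign_arms()`); with an odd number of clusters the
extra cluster goes to a random arm. Cluster sizes are drawn independently of
arm assignment.

## Effect-size calibration

`calibrate_effect_size()` solves the cluster-level t-based power relation
for the treatment effect:

$$\Delta = \sqrt{\frac{4\,(\sigma^2_\epsilon + \mu\,\mathrm{BCV})\,
(t_{\alpha/2} + t_\beta)^2}{\mu\, C^{80}}},$$

so that a trial with $C^{80}$ clusters of exactly $\mu$ participants has
power $1-\beta$ at two-sided level $\alpha$. Two numerical conventions are
deliberate:

* **The square root.** The right-hand side has the dimensions of
  $\Delta^2$ (it is the squared half-width of the cluster-level comparison),
  so $\Delta$ is its square root. The package verifies this self-consistency
  in its tests by plugging $\Delta$ back into the power relation and
  recovering $1-\beta$ exactly.
* **Degrees of freedom.** Both t-quantiles use $C^{80} - 2$ degrees of
  freedom — the error df of the two-sample comparison of cluster means,
  which is the natural cluster-level df for this design and matches the df
  of the Wald test used on the simulated trials. For the reference scenario
  ($\mu = 75$, ICC $= 0.006$, BCV $= 0.1$, $C^{80} = 60$) this yields
  $\Delta = 0.417$.

Because every grid parameter enters the calibration, the simulation isolates
the effect of size variability: changing $\mu$ or the ICC changes $\Delta$
too, holding nominal fixed-size power at 80%.

## Cluster-size generator

Variable sizes are negative binomial (the gamma–Poisson form, since the
dispersion is non-integer) with mean $\mu$ and fixed coefficient of
variation. Matching the first two moments gives the dispersion

$$r = \frac{\mu}{\mu\,cv^2 - 1},$$

valid when $\mu\,cv^2 > 1$ (`nb_size_parameter()`). At high variability the
distribution places substantial mass at zero — e.g. at $\mu = 20$,
$cv = 1.5$ a draw is 0 about 18% of the time — and a trial cannot contain an
empty cluster. `draw_cluster_sizes()` therefore enforces a **minimum size of
3 by shifting**: it draws from a negative binomial with mean $\mu - 3$ and
adds 3 to every draw, keeping the long-run mean exactly $\mu$.

Two further choices, made once:

* The dispersion is computed from the *pre-shift* mean $\mu - 3$ and the
  nominal cv. The shift then adds location without adding spread, so the
  realized cv of the shifted sizes is slightly below nominal (by a factor
  $(\mu-3)/\mu$ in standard deviation, at most 15% for the grid's smallest
  mean). Computing $r$ at the nominal mean instead changes the dispersion by
  well under 1% at the grid values, so the distinction is immaterial in
  practice, but the pre-shift convention keeps the drawn distribution
  exactly negative binomial with the stated mean.
* The shift is applied at **every** cv level, not only the highest; the
  zero-mass problem exists whenever sizes vary. `cv = 0` is the exact
  fixed-size degenerate case (every cluster has size $\mu$).

An alternative reading — truncating or resampling draws below 3 — was
considered and rejected: truncation inflates the realized mean and deflates
the realized cv, so the nominal variability level would no longer describe
the generated sets.

## Per-trial inference

Each simulated trial is tested for a treatment effect at level $\alpha$ with
a **random-intercept linear mixed model** fitted by REML, followed by a
two-sided Wald t-test of the treatment coefficient on $K - 2$ degrees of
freedom ($K$ = number of clusters) — the same df convention the calibration
uses, which keeps the fixed-size simulations centred on their nominal power.

Because the only fixed effect besides the intercept is cluster-constant, the
REML criterion depends on the data solely through per-cluster sufficient
statistics (sizes, means, and the pooled within-cluster sum of squares), and
profiling reduces the fit to a one-dimensional optimization over the
variance ratio. `crtpowersim` implements this profiled fit directly
(`fit_random_intercept()`): it is numerically the same REML solution a
general mixed-model routine finds — the test suite checks agreement with
`lme4::lmer` to ~5 significant digits on unbalanced trials — at roughly two
orders of magnitude less cost, which is what makes the replicate counts
below practical on a single core.

A **cluster-means mode** (unweighted two-sample t-test on per-cluster means,
pooled variance, $K-2$ df) is available as `method = "cluster-means"`. For
balanced equal-size designs it is the exact cluster-level equivalent of the
mixed model (the two can differ only when the between-cluster variance
estimate hits the zero boundary); for unbalanced designs it is less
powerful, because it cannot down-weight small, noisy clusters. It is the
fallback when the mixed fit fails numerically; fallback trials are counted
and reported (`n_fallback`), never converted to automatic rejections or
acceptances.

## Power estimation and random-number discipline

`estimate_power_fixed()` simulates `n_sims` trials (default 5000) with all
clusters at size $\mu$; `estimate_power_variable()` draws `n_sets` (default
2000) fresh size sets and simulates **one trial per size set**, so size-set
variability and outcome variability are averaged jointly — intentionally,
since both contribute to the power of a real trial with uncontrolled sizes.
Power is the exact rejection fraction, reported with its binomial
Monte-Carlo standard error $\sqrt{p(1-p)/n}$.

Every replicate runs in its own substream, seeded from a table of 31-bit
seeds derived deterministically from the master seed. Results are therefore
independent of execution order (worker-count invariant), and any single
trial can be replayed byte-identically in isolation (`replay_trial()`),
which is the intended debugging path for surprising rejections.

## Required clusters

`power_curve()` traces power over the actual cluster count $C^A$;
`interpolate_required()` finds the first adjacent pair of points straddling
the target (default 0.8), fits the line $\hat P = \hat a C + \hat b$ through
them, and solves for $\hat C$. Raw points are interpolated as-is — no
smoothing or isotonic adjustment — because the Monte-Carlo error of each
point is reported and the bracketing pair is typically well separated. A
curve that is non-monotone by more than twice the Monte-Carlo standard error
triggers a warning; multiple crossings use the first, scanning left to
right. A curve that starts at or above the target, or never reaches it,
yields a directional status flag rather than an extrapolated number:
extrapolation beyond the simulated range has no error control. The
inflation relative to the formula value is
$100(\hat C^{cv} - C^{80})/C^{80}$ (`percent_change()`).

## Study orchestration

`experiment_config()` holds the full design grid — 5 mean sizes × 7 ICCs ×
3 BCVs × 4 values of $C^{80}$, i.e. 420 parameter sets, crossed with actual
cluster counts 5–120 under two expansion rules ($C^A = 80$ only when
$C^{80} > 10$; $C^A \ge 100$ only when $C^{80} > 20$, since small designs
saturate power early), giving 3,255 curve points per variability level.
`run_study()` executes fixed and variable curves for every parameter set,
interpolates required clusters, and summarizes: correlation and paired mean
difference between the simulated fixed-size requirement and $C^{80}$, paired
increments between successive cv levels, and the median and range of the
percent inflation at each cv. Non-crossing curves are excluded from
summaries but counted and flagged, never silently dropped. Tables persist as
schema-versioned tab-separated text.

The full grid is a very large computation (hundreds of millions of model
fits at the default replicate counts). The package's own test suite and the
reproduction script therefore run the single reference parameter set at full
replicate depth (5000 fixed / 2000 variable per point) and exercise the grid
machinery on reduced grids (single parameter sets, a few hundred replicates
per point) — sizes chosen so the whole suite completes in a few minutes on
one core while keeping each stochastic check's Monte-Carlo error well inside
its assertion tolerance.

## What the generator does and does not emulate

The synthetic data match the model above exactly, so passing tests certify
the pipeline's internal consistency — calibration, generation, inference and
interpolation agree with each other and with closed forms. They do not
certify behaviour on real data, where cluster size may correlate with the
outcome or the effect (informative cluster size), outcomes may be skewed or
binary, arms may be allocated by matching or stratification, and intra-
cluster correlation may vary across clusters. None of these features are
modelled: the package's scope is equal-armed, continuous-outcome,
unmatched designs with sizes independent of treatment and outcome.

## Known limitations

* Required-cluster estimates inherit the Monte-Carlo error of the two
  bracketing power points divided by the local slope; near-flat curve
  segments (small designs, high ICC) give noisy $\hat C$.
* The cluster-means fallback changes the effective test for the (rare)
  trials where REML optimization fails; `n_fallback` should be checked
  before interpreting a power estimate.
* Total sample size is not held fixed across variability levels: a
  variable-size trial with the same number of clusters has a random total
  enrolment. This mirrors designs where sizes cannot be controlled, and is
  part of what is being measured, not a bias.
* The negative-binomial family with a hard minimum of 3 is one specific
  model of size variability; empirical size distributions with the same cv
  but different shape (e.g. bimodal clinic sizes) may erode power
  differently.
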