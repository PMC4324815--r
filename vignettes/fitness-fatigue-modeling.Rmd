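---
title: "Fitness-fatigue systems modeling of resistance-training responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitness-fatigue systems modeling of resistance-training responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitnessfatigue)
```

## The model

Impulse-response ("fitness-fatigue") systems models treat an organism as a
dynamical system whose input is the daily training dose and whose output is
performance. Every training impulse leaves two fading traces: a slowly
decaying positive one (adaptation) and a faster-decaying negative one
(fatigue). With daily doses $w_i$ (here: joules of potential work from
weighted ladder climbs) and performance in watts, the two-component model
predicts performance on day $n$ as

$$\hat p(n) = p_0
  + k_1 \sum_{i=1}^{n-1} w_i\, e^{-(n-i)/\tau_1}
  - k_2 \sum_{i=1}^{n-1} w_i\, e^{-(n-i)/\tau_2},$$

with gains $k_1, k_2$ (W per J, i.e. s$^{-1}$) and time constants
$\tau_1, \tau_2$ (days). Dropping the second component gives the
one-component model; letting the fatigue gain itself respond to accumulated
training through a further first-order filter,
$\Delta k_2(i) = k_3 \sum_{j \le i} w_j e^{-(i-j)/\tau_3}$, gives the
three-component model. The time step is fixed at one day, $w(0) = 0$, and
the convolution sums run over strictly earlier days, so same-day training
never influences same-day predicted performance.

Training work for a climb session is the potential work of the combined
centre of mass, $(m_{\text{load}} + m_{\text{rat}})\,g\,\Delta h\,N$, and
session performance is that work divided by total climbing time. $g$ is
fixed at 9.81 m s$^{-2}$ but exposed (`STANDARD_GRAVITY`, the `g` argument)
for sensitivity analyses.

### The sign of the third component

For the three-component model two conventions circulate for combining the
initial fatigue gain with its training-driven change: $k_2(i) = k_2(0) +
\Delta k_2(i)$ (fatigue grows when training accumulates beyond an optimum,
the physiologically motivated reading) and $k_2(i) = k_2(0) - \Delta
k_2(i)$. Both are implemented (`third_component_sign`, default `"plus"`);
under the minus convention the gain is floored at zero, since a negative
fatigue gain would invert the component's meaning. The fit linearises the
unfloored form; with the default convention the two coincide exactly.

## Joint ("mixed-effects") fitting

All animals in a cohort are fitted at once: the time constants are common
to the cohort, while the intercept $p_0$ and the gain factors are specific
to each animal, and the pooled residual sum of squares over all animals and
measured days is minimised. The per-animal parameters are free parameters
minimised jointly — no distributional shrinkage is imposed on them, because
the estimation target is exactly the pooled-RSS optimum.

At fixed time constants the model is *linear* in the intercept and gains,
so the fit profiles them out: each animal's coefficients are solved by
box-constrained linear least squares (an exact active-set enumeration over
at most $3^4$ configurations) inside an outer bounded quasi-Newton search
over the 1-3 time constants (variable projection). The outer gradient is
analytic via the envelope theorem, so no finite differencing touches the
inner solve. The outer search is multistarted (default 25 starts, drawn
log-uniformly within the time-constant bounds under the configured seed);
the lowest-RSS start wins, ties broken by start order.

Defaults, all configurable through `fit_config()`:

* time constants bounded to $[0.5, 60]$ days — below half a day the daily
  grid cannot resolve a component, above 60 days it barely decays within
  the 26-day program;
* gains bounded to $[0, 1]$ s$^{-1}$ and $p_0 \in [0, 10 \cdot \max p]$;
* no $\tau_1 > \tau_2$ ordering constraint: imposing one would hide the
  identifiability problems discussed below rather than solve them;
* convergence at relative objective change $10^{-10}$ or step $10^{-8}$;
* per-animal intercepts are *excluded* from the reported model degrees of
  freedom (see next section); `count_intercepts_in_df` flips this.

Richer variants are warm-started from poorer ones (`fit_all_variants()`):
because the profiled two-component RSS at $(\hat\tau_1, \cdot)$ can always
reproduce the one-component solution with $k_2 = 0$, warm-started nested
fits can only improve, and the nested F test below is well defined.

## Model comparison

Degrees of freedom follow the convention of counting one gain factor per
animal per component plus the shared time constants: $C\,R + C$ for $C$
components and $R$ animals — 12, 24 and 36 for an 11-animal cohort. With
$N$ pooled observations,

$$\mathrm{Adj.}R^2 = 1 - (1 - R^2)\frac{N-1}{N-\mathrm{df}-1}, \qquad
  F = \frac{R^2/\mathrm{df}}{(1-R^2)/(N-\mathrm{df}-1)},$$

and nested variants are compared by the F-ratio of the RSS decrease per
added df to the larger model's residual mean square. $R^2$ is computed
about the pooled grand mean of all observed performances (the conventional
total sum of squares of a single pooled regression); per-animal centring is
available (`per_rat_centering`) for exploring how much of the fit is
between-animal level differences. The residual mean square
$RSS/(N-\mathrm{df}-1)$ and its square root are both reported and labelled
(`mse`, `rmse`), since "standard error" is used ambiguously for either in
the literature. Normality of training loads and performances is checked by
Shapiro-Wilk (`normality_check()`, delegating to `stats::shapiro.test`).

## Response characteristics and influences

For the two-component model the response to a single unit bout is
$h(t) = k_1 e^{-t/\tau_1} - k_2 e^{-t/\tau_2}$. When $k_2 > k_1$ and
$\tau_1 > \tau_2$ performance dips, recovers at $t_n$, and peaks at $t_g$
with gain $p_g$ (closed forms in `response_characteristics()`). Parameter
draws can legitimately produce $k_2 < k_1$ (no dip): the affected
quantities are then returned as flagged `NA`, never as errors, and cohort
summaries average over the animals for which they exist — cohort values are
means of per-animal characteristics, not characteristics of mean
parameters, which matters because the formulas are nonlinear in the gains.

The influence decomposition classifies each (dose day $i$, performance day
$n$) term $E_i^n = k_1 w_i e^{-(n-i)/\tau_1} - k_2 w_i e^{-(n-i)/\tau_2}$
by its own sign and sums negative and positive terms separately into
fatigue and adaptation influences; by construction
$\mathrm{ip}(n) + \mathrm{in}(n) = \hat p(n) - p_0$ exactly, which the test
suite asserts to $10^{-10}$.

## The synthetic cohort generator

No climbing data ship with the package, so `generate_cohort()` emulates the
study design the package targets: 11 rats of initial mass
$0.277 \pm 0.015$ kg, 19 sessions over 4 weeks (5 consecutive training
days, 2 rest days), 10 repetitions of a 1 m climb per session, additional
load progressing from 50% to 150% of current body mass (the default
protocol table), performance generated from a two-component truth with
shared $\tau_1 = 5.31$ d, $\tau_2 = 4.3$ d and per-animal gains drawn from
truncated normals with mean (SD) 0.0186 (0.0134) and 0.0200 (0.0157)
s$^{-1}$, plus additive Gaussian observation noise. Choices the emulated
design leaves open, fixed once here:

* **Body-mass growth**: linear, 2 g/day — only the initial mass is
  specified by the design, but loads are percentages of current mass, so
  growth affects the input series; the default roughly connects the
  session-block mean loads implied by the protocol (about 288 g at week 1
  to 360 g at week 4).
* **Initial performance**: each rat's $p_0$ is the power of a 50%-load
  session at a per-climb time drawn uniformly from 8-14 s, giving the
  0.3-0.5 W scale the early sessions imply.
* **Plausibility screen**: climb times are backed out as $TW/p$; a rat
  whose implied per-climb time leaves 2-40 s (or whose noisy performance is
  non-positive) is redrawn, mirroring the physical limits of a 1 m climb.
* **Observation noise**: additive, homoscedastic, default SD 0.1 W. Two
  calibration targets compete here. Matching the fit quality reported for real
  cohorts of this design ($R^2 \approx 0.5$) would require noise on the order of the pooled signal
  SD ($\approx 0.8$ W), which is impossible under the plausibility screen:
  early-session performance sits near 0.35 W, so such noise drives
  performances negative and implied climb times out of band, and — more
  subtly — the screen then *selects* against fatigue-dominant animals
  ($k_2 > k_1$), flattening exactly the dip the two-component model exists
  to describe. The default is instead the largest noise at which that
  selection stays minor (the accepted $k_2 > k_1$ fraction stays near its
  noise-free value), which keeps the generated population faithful to the
  stated gain distribution; the fitted $R^2$ on such cohorts is then high
  (about 0.98) rather than near that benchmark. Consequences for what the tests
  show are discussed under Limitations.
* **Gain truncation**: gains are drawn by joint redraw until positive — a
  genuine truncated normal — rather than clamped at zero, which would
  create an atom of zero-response animals.
* **No gain correlation** is imposed by default (none is specified by the
  emulated design), but `k_correlation` exists because fitness and fatigue
  gains are often correlated in practice.

`recovery_experiment()` wraps the generate-fit-compare loop and records
relative errors of the shared time constants, mean gain errors, fit $R^2$
and (optionally) the 1-vs-2-component F decision per replicate.

## Numerical choices

* Convolutions are evaluated by $O(n)$ first-order recursions, implemented
  in closed form as rescaled cumulative sums (all terms positive, so the
  rescaling costs no relative precision; a sequential fallback guards
  extreme $n/\tau$). The $O(n^2)$ direct summation ships as
  `predict_direct()` and is the oracle the fast path is tested against at
  $10^{-10}$ relative tolerance.
* The inner box-constrained least squares is solved exactly; degenerate
  designs (an all-rest animal, collinear components at $\tau_1 = \tau_2$)
  fall back to a pivoted solve with aliased coefficients at zero and the
  fit flags the animal as not uniquely identified.
* Cohorts with fewer measured days than per-animal free parameters are
  refused with an "underdetermined" error rather than silently pinned at
  bounds.
* Seeds: every stochastic routine takes an explicit seed and restores the
  caller's RNG state; replicate seeds are derived from the master seed by
  seeded sampling.

## Problem sizes used by the shipped tests

The test suite exercises the statistical claims at sizes chosen to keep a
full run modest on one CPU: oracle and identity checks at 100 random cases
up to 60 days; response-formula checks at 50 random parameter sets against
a 5 ms grid; noiseless recovery on one replicate and noisy recovery on 20
replicates of the full 11-rat design; test size and power of the nested
comparison on 200 replicates each with 4 outer starts per fit plus nested
warm starts. The acceptance script repeats the pipeline at slightly
smaller replicate counts.

## Limitations

* **What passing tests do not show**: the generator produces additive
  homoscedastic noise, linear growth, a shared-$\tau$ truth and independent
  truncated-normal gains. Real climb data have heteroscedastic, likely
  multiplicative errors, correlated gains, and no guarantee of shared time
  constants; recovery results here quantify the estimator under the
  emulated design, not under real data. In particular the high $R^2$ of
  default synthetic cohorts means the model-comparison power observed in
  simulation should not be read as the power available at real-data noise
  levels.
* **Weak identifiability of the time-constant pair**: with wide gain
  bounds, the global pooled-LS optimum at realistic noise is sometimes a
  near-degenerate pair $\tau_1 \approx \tau_2$ with large opposing gains —
  the difference of two nearly equal exponentials imitating a
  $t\,e^{-t/\tau}$ response. This is a property of the estimator, not an
  optimizer failure; the multistart search finds such minima *because* it
  is global. Recovered $\tau_2$ in particular can be biased at noise even
  though noiseless recovery is exact. Tightening the gain bounds toward
  physiological magnitudes, or adding externally motivated constraints,
  are the remedies the configuration exposes.
* The plausibility screen truncates extreme animals even at zero noise
  (about half the nominal $k_2 > k_1$ draws survive it), so the *accepted*
  gain distribution is not exactly the nominal truncated normal.
* No continuous-time integration, no likelihood-based random effects, no
  information-criterion selection, and no training-program optimisation are
  provided; the estimation target is the pooled least-squares formulation
  throughout.
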