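# fitnessfatigue

Systems modeling of resistance-training responses for cohort experiments,
built around the ladder-climbing paradigm in rats: each training session is
a weighted 1 m climb, the session's **training work** (J) is the potential
work of the combined centre of mass, and **performance** (W) is that work
divided by total climbing time. Daily work amounts drive impulse-response
("fitness-fatigue", Banister-type) models of performance

    p(n) = p0 + k1 * SUM_{i<n} w_i exp(-(n-i)/tau1)        (one component)
                - k2 * SUM_{i<n} w_i exp(-(n-i)/tau2)      (two components)

plus a three-component variant whose fatigue gain k2(i) itself follows the
accumulated training through a further first-order filter. The package is
for experimentalists and modellers who want to fit these models *jointly*
to a whole cohort — shared time constants, per-animal intercepts and gains,
pooled least squares (the "mixed-effects" formulation) — and then ask the
standard downstream questions: does the fatigue component earn its degrees
of freedom (nested F tests), and what do the fitted parameters imply for
the response to a single training bout (time to recover `tn`, time to peak
`tg`, maximal gain per unit training `pg`, positive/negative influence
curves)?

What's inside:

* `climb_sessions()`, `training_work()`, `session_performance()`,
  `build_training_series()` — quantification of climb logs (CSV readers/
  writers included; masses in grams in files, kg internally).
* `predict_1comp/2comp/3comp()` — fast recursive forward simulation, with
  `predict_direct()` as the transparent O(n^2) cross-check.
* `fit_model()`, `fit_all_variants()` — bounded multistart variable
  projection minimising the pooled RSS; `fit_config()` controls bounds,
  starts, seed, tolerances.
* `model_df()`, `goodness_of_fit()`, `compare_nested()`,
  `model_comparison_table()`, `normality_check()` — df accounting,
  adjusted R², overall and nested F tests.
* `response_characteristics()`, `influence_decomposition()`,
  `cohort_influence_summary()` — single-bout characteristics and the
  per-day positive/negative influence decomposition.
* `cohort_design()`, `generate_cohort()`, `recovery_experiment()` — a
  seeded synthetic-cohort generator emulating the 11-rat, 19-session,
  50→150 %-body-mass progressive protocol, used for parameter-recovery
  and test-size/power studies.
* `run_pipeline()` — simulate (or read a session log), fit all variants,
  compare, analyse, writing every artifact as CSV/JSON.

## Worked example

```r
library(fitnessfatigue)

syn <- generate_cohort(cohort_design(), seed = 42)   # 11 simulated rats
fit <- fit_model(syn$cohort, "TWO_COMP", fit_config(n_starts = 12, seed = 1))
print(fit)
print(goodness_of_fit(fit, syn$cohort))
cohort_response_characteristics(fit)$summary
```

```
<synthetic_cohort> 11 rats x 19 sessions, TWO_COMP truth, noise_sd = 0.1 W, seed = 42
<ffm_fit TWO_COMP> 11 rats, N = 209
  shared: tau1 = 5.286 d, tau2 = 5.236 d
  RSS = 1.6717 W^2, df = 24, best of 12 starts
R2 = 0.961, Adj.R2 = 0.956, F(24, 184) = 191.32, p = 1.02e-116
residual MSE = 0.009085 W^2 (RMSE 0.09532 W)
  quantity        mean           sd n_defined
1       tn 1.908914442 1.1363928474         4
2       tg 5.232005358 2.1664321374         9
3       pg 0.001629962 0.0005585353         9
```

Reading this: the cohort was generated from a two-component truth with
tau1 = 5.31 d and tau2 = 4.3 d. The joint fit explains 96% of the pooled
performance variance with a residual of ~0.095 W (the injected noise was
0.1 W). The fitted tau pair illustrates the model's well-known weak
identifiability — at this seed the global least-squares optimum sits at a
near-degenerate tau1 ≈ tau2 pair even though tau1 lands near truth; see
the methods vignette for why and what the configuration offers against it.
The response summary gives cohort means of per-rat single-bout
characteristics: performance recovers ~1.9 d and peaks ~5.2 d after a
bout, gaining at most ~0.0016 W per unit (J) of training; `n_defined`
counts the rats for which each quantity exists (a rat with k2 < k1 never
dips, so its `tn` is undefined).

At the default population gains (k1 = 0.0186, k2 = 0.0200 s^-1, tau1 =
5.31 d, tau2 = 4.3 d):

```r
response_characteristics(0.0186, 5.31, 0.0200, 4.3)
#> tn = 1.641 d, tg = 6.41 d, pg = 0.001058 W
```

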