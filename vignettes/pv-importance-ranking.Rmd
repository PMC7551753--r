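---
title: "Ranking physiological-variable importance by leave-one-out AUC drop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking physiological-variable importance by leave-one-out AUC drop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvrank)
```

## The problem and the method

Prehospital and intensive-care staff monitor many physiological variables
(PVs) at once — vital signs such as heart rate, oxygen saturation and blood
pressures, and bedside labs such as glucose and pH. For a patient with a
*specific* suspected condition, which of these streams deserve the most
attention? `pvrank` answers this with a sensitivity-analysis design on
disease classifiers:

1. For each ICU stay, each PV's irregular time series is summarized by
   hand-engineered features (below), giving one feature vector per stay.
2. For `n` PVs, `n + 1` *PV sets* are designed: the full catalog, plus `n`
   leave-one-out sets each omitting exactly one PV (`design_pv_sets()`).
   With the default 17-PV catalog that is 18 sets, hence 18 experiments.
3. Under each PV set, one binary one-vs-rest logistic classifier per
   disease is fitted on the training side of a single stay-level split and
   scored on the held-out side by AUROC (`run_experiment_family()`). The
   *same* split is reused for every set, so AUC differences are
   attributable to the PV set alone.
4. The importance of PV `p` for disease `d` is the AUC drop
   `delta_p = AUC(all) - AUC(minus_p)`; PVs are ranked by `delta`
   descending (`rank_importance()`). Two diseases can then be compared by
   how many of their top-k PVs coincide (`compare_diseases()`).

The unit of analysis is one ICU stay: a stay carries per-PV measurement
series over `[0, duration]` and 24 binary disease labels (CCS-style
diagnosis groups). Labels co-occur, which is why the operative model is
one-vs-rest rather than a mutually exclusive 24-class head: per-disease
AUROC is only defined under the one-vs-rest reading. The strict multinomial
(softmax) model is nevertheless provided (`fit_multinomial()`) and reduces
exactly to the binary model at `K = 2`.

## Feature extraction

For each PV the series is cut into **7 sub-sequences defined on the time
axis** — the full stay and the first 10%, 25%, 50% and last 50%, 25%, 10%
of the stay duration — and each sub-sequence is summarized by **6 sample
statistics**: minimum, maximum, mean, standard deviation, skewness and the
number of measurements. That is 42 features per PV, 714 for the full
catalog. Conventions, all chosen for determinism and finiteness:

* Windows are *closed* intervals of relative time; a point exactly on a
  boundary (say at half the stay) belongs to every window it touches. The
  original description does not fix this choice; closed-closed is the
  simplest rule that keeps `n(first50) + n(last50) >= n(full)`.
* `std` is the population (n-denominator) form and skewness the moment
  coefficient `g1 = m3 / m2^{3/2}`, both defined at `n = 1`; constant or
  singleton series get `std = 0`, `skew = 0` rather than `NaN`.
* An empty window yields `NA` sentinels for the five value statistics and
  a genuine `0` for the count. Whether and how the original work imputed
  such gaps is unstated; here missing entries are replaced by the
  *training-row* column mean and all columns are then z-scored with
  training-row parameters (`impute_and_standardize()`), so a held-out row
  with a missing value receives exactly 0 and no test information leaks
  into the transform. The policy is isolated in one function so
  alternatives can be plugged in.
* Features are invariant to event order and to rescaling the clock, and
  the vectorized cohort path agrees exactly with the per-episode path —
  all property-tested.

## The classifier and its fitting

Each disease is classified by logistic regression
`P(y = 1 | x) = plogis(w \cdot x)` with `x` the standardized feature vector
plus intercept. The weights maximize the Bernoulli log-likelihood

`L(w) = sum_i [ y_i (w . x_i) - log(1 + exp(w . x_i)) ]`

minus a ridge penalty `lambda/2 ||w||^2` (intercept unpenalized), by
Newton's method with step halving, zero initialization, gradient-max-norm
tolerance `1e-8` and at most 200 iterations. The penalty (default
`lambda = 1` on standardized features) is not in the original description;
it guarantees a finite unique optimum under the quasi-complete separation
that 714 features on a few thousand stays invites. Strict concavity of the
penalized likelihood makes the solver initialization-independent — the
leave-one-out fits are therefore warm-started from the full-set fit purely
as a speed optimization (tested to change nothing but iteration count).
The fitter is verified against an exhaustive lattice search of the
penalized likelihood on a small fixed design.

AUROC is computed in the Mann–Whitney form with midrank tie correction —
the mean over (positive, negative) pairs of
`[s_pos > s_neg] + 0.5 [s_pos = s_neg]` — and is verified against the
literal pairwise-count oracle on thousands of random instances.

The train/held-out protocol of the original study (split size,
repetitions, in- vs out-of-sample AUC) is unstated; the package uses a
single seeded 70/30 stay-level split evaluated held-out, the conservative
reading. Whether the study ranked by `delta`, by raw leave-one-out AUC, or
by a significance criterion is also unstated; the three are
order-equivalent given a shared `AUC(all)`, and `pvrank` uses the raw
`delta` with ties broken by canonical catalog order.

## The synthetic cohort generator: what it emulates and what it does not

Real ICU extracts are access-controlled, so the package carries a
generator (`synthetic_config()`, `generate_cohort()`) whose point is not
clinical realism but *the statistical structure the ranking method
assumes*, with a known answer planted:

* Stay `s` has a latent level `z[s, p] ~ N(0, 1)` per PV. Observations are
  `mu_p + sigma_p (z + noise_sd * eps)` at homogeneous-Poisson times over
  the stay; disease labels are Bernoulli with log-odds
  `alpha_d + sum_p B[d, p] z[s, p]`. Because the effect acts through the
  stay-level latent — hence through the per-stay mean features — the
  planted magnitudes `|B[d, ]|` are the ground-truth importance order the
  pipeline must recover.
* Defaults state a plausible adult-ICU world, chosen once: marginals from
  a built-in physiology table (e.g. HR 85 ± 15 bpm, glucose
  130 ± 45 mg/dL; CRR categorical 0/1 at 15% abnormal), stay duration
  uniform on 24–120 h, `sampling_rate = 15` measurements per PV per stay
  (the catalog mixes near-hourly vitals with sparse labs),
  `missing_pv_prob = 0.05`, `noise_sd = 0.5` of the PV's SD, and
  intercepts `-1.5` giving ≈18% prevalence, typical of ICU phenotype
  groups. Values are clamped to the plausible range so a clean synthetic
  cohort passes cleaning untouched.
* Deliberately *not* modeled: waveform dynamics and autocorrelation,
  inter-PV correlation beyond the shared disease latents, treatments, and
  any region- or database-specific case mix. A green recovery test
  therefore establishes that the pipeline recovers importance *when the
  classifier is well-specified and the signal lives in stay-level
  means* — not that it would reproduce any particular hospital's
  rankings.
* `inject_artifacts()` corrupts a cohort with an exact, manifest-tracked
  number of blank stay ids, out-of-range values, negated timestamps and
  Fahrenheit temperatures, so the cleaning rules can be tested for exact
  removal and exact preservation.

## ETL conventions

Cohort selection keeps stays with age ≥ 16 (inclusive — "16 years or
above"), exactly one ICU stay in the admission, and no transfer; each
excluded stay is tallied under the first rule it violates so counts
conserve. Event cleaning drops blank stay ids, unknown variables, missing
values, missing/negative times and out-of-range values, converting
°F→°C, lb→kg and in→cm first when the unit field says so. The original
outlier thresholds are unpublished; the shipped range table
(`default_range_table()`, e.g. HR [0, 300] bpm, temperature [25, 45] °C,
pH [6.3, 8.0]) makes the unstated cleaning explicit and overridable.
Duplicate (stay, PV, time) points collapse to their mean — deterministic
and order-independent. The episode window is the full stay; whether the
original work capped it (e.g. at 48 h) is unknown, and the full stay is
the assumption least likely to discard signal.

## What the tests establish — and one stated criterion that cannot hold

Beyond the structural identities (42 features per PV, 18 sets from 17
PVs, published worked examples through `compare_diseases()`), two
simulation studies anchor the acceptance suite at `n_stays = 4000`:

* **Planted recovery.** With `B[d, Glu] = 1.5`, `B[d, HR] = 0.7` and all
  other effects zero, Glu must rank first and HR second in at least 90%
  of 20 seeds. Measured deltas are far from the noise floor
  (`delta_Glu ≈ 0.2`, `delta_HR ≈ 0.03`, others within ±0.005).
* **Null calibration.** With `B = 0`, held-out AUCs are centered at 0.5
  and no PV is systematically top-ranked across seeds. One stated
  per-cell band, however — *every* per-disease held-out AUC within
  0.5 ± 0.03 — is tighter than the sampling distribution of the statistic
  itself: a null held-out AUC is a Mann–Whitney U with
  `sd ≈ sqrt((m+n+1)/(12 m n)) ≈ 0.022` at ≈18% prevalence on 1200
  held-out stays, so ±0.03 is ≈1.4σ and the probability that all
  24 × 3 cells stay inside is about `0.84^72 ≈ 3·10⁻⁶`. The suite asserts
  the band as stated (it fails, honestly) alongside the attainable
  centered-mean and no-systematic-top-PV checks; the band was not
  widened, and the generator was not tuned toward it. The systematic
  top-PV check runs the experiment family on a 6-disease subset per seed
  to keep the suite inside its runtime budget; the world (cohort size,
  penalty, split) is unchanged.

## Numerical and degenerate-input choices

Logistic probabilities are clamped to the open unit interval at machine
precision; Newton Hessians get a `1e-12` ridge on the diagonal for
numerical definiteness; weights `mu(1-mu)` are floored at `1e-10`.
Diseases that are single-class on either side of the split are reported
with a reason, never silently dropped, and excluded from ranking. A
feature column observed in no training row is a hard error naming the
column. All randomness (generator, splits) flows through explicit seeds
via an RNG-state-preserving scope, so identical configurations are
bit-reproducible end to end — including the written CSV/JSON artifacts.

## Limitations

Importance here is predictive, not causal: a PV can rank high because it
proxies treatment intensity or case mix. Collinear PVs (e.g. the three
blood pressures) share signal, so removing one may barely move AUC even
when the group matters — the leave-*one*-out design understates grouped
importance, and a grouped leave-out is an extension point, not implemented.
AUC drops from a single split carry sampling noise of a few hundredths;
for real analyses the seed-resampling stability of a ranking should be
inspected before reading order into small deltas.
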