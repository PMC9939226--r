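---
title: "Location-stratified analysis of tumor response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Location-stratified analysis of tumor response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(stratburden)
```

## The problem

Solid-tumor drug trials conventionally summarise a patient's disease as a
single number: the RECIST 1.1 tumor burden, the sum of target-lesion sizes
(up to 5 lesions, at most 2 per organ), tracked from baseline to a
follow-up visit. For therapies whose effect differs between anatomical
sites — a primary breast tumor responding while liver metastases do not —
this pooling can mask real, location-specific drug activity. stratburden
implements the alternative: compute percent changes per location and per
lesion, compare treatment arms within each location, and summarise each
arm with a count-weighted mean of per-location responses.

The motivating setting is a two-arm HER2-positive metastatic breast cancer
trial (ASLAN001-003, varlitinib + capecitabine "VC" versus lapatinib +
capecitabine "LC") with per-lesion CT measurements: longest axial diameter
(LAD, mm), short axial diameter (SAD, mm) and segmented volume (mm³). The
package ships the study's published per-location Week-12 summaries
(`aslan_week12_summaries()`) and baseline counts
(`aslan_baseline_counts()`) as worked inputs; patient-level data were
never deposited, so individual-level analyses run on synthetic trials.

## The three response constructions

Let $s_{ij}(t)$ be the size of lesion $j$ of patient $i$ at time $t$ on
its *response axis*: the SAD for nodal (lymph-node) lesions, the LAD
otherwise, or the volume when the volumetric metric is requested. All
changes are percent changes from baseline,
$100\,(s(T) - s(0))/s(0)$, undefined (and excluded) when the baseline is
zero.

1. **RECIST burden** (`recist_burden_change()`): per patient, sizes of all
   target lesions are summed at each timepoint and the percent change of
   the sums is reported.
2. **Stratified burden** (`stratified_burden_change()`): the same sum, but
   within each anatomical location; a patient contributes one record per
   location where they have lesions — never an imputed zero.
3. **Independent lesions** (`lesion_level_changes()`): one percent change
   per lesion, ignoring patient membership.

Two conventions matter and are fixed explicitly. A lesion measured (or
recorded) at size 0 at an attended follow-up visit — including a lesion
whose follow-up row is simply absent while the patient has other follow-up
measurements — is a *disappearance* and contributes $-100\%$ (0 to the
burden sum). A patient with no follow-up rows at all has left the study
and is excluded, not imputed. These burdens satisfy exact identities that
the test suite enforces: per-location burdens add up to the RECIST burden,
and the baseline-burden-weighted mean of a patient's stratified changes
equals their RECIST change.

## The weighted response model

Per arm, with $N_\ell$ lesions evaluable at follow-up in location $\ell$
and mean lesion-level change $\overline{\Delta}_\ell$, the arm-level
response is

$$ R \;=\; \frac{\sum_\ell N_\ell\, \overline{\Delta}_\ell}{\sum_\ell N_\ell}. $$

`weighted_response()` computes $R$ from any table of counts and means;
`weighted_model()` builds those summaries from lesion-level records. On
the published Week-12 inputs this reproduces the reported arm responses:

```{r}
s <- aslan_week12_summaries()
sapply(split(s, list(s$arm, s$metric)), weighted_response)
```

Note that when the weights are the *realized* lesion counts of the same
records whose means are being weighted, $R$ reduces algebraically to the
arm's grand mean of lesion changes. The model's value lies in separating
the two ingredients: published (or externally chosen) location weights can
be combined with any set of per-location means, and the per-location means
are the quantities the stratified comparison tests.

The mean per-location change is the unweighted arithmetic mean of
lesion-level percent changes, not the percent change of summed sizes;
`location_summaries(as_location_sums = TRUE)` exposes the latter as an
alternative estimator for comparison, since large lesions dominate it.

### Inter-arm inference

`compare_arms_weighted()` tests the difference of arm responses by
permutation, with the two-sided p-value
$(1 + \#\{|\Delta^*| \ge |\Delta|\})/(1 + B)$. Two schemes:

* `permute = "lesion"` (default) shuffles arm labels within each location.
  This matches the model's own framework — lesions treated as independent
  units — and holds each arm's location mixture fixed, so mixture
  imbalance between arms cannot masquerade as a treatment effect.
* `permute = "patient"` re-randomises whole patients, lesions inheriting
  their patient's label. This respects within-patient correlation but
  tests the broader null that the patient-level arm label is
  exchangeable, location mixture included.

The distinction is not cosmetic. Lesions of one patient share a response
(the generator's patient random effect; in real data, shared biology), and
permuting lesions individually understates the variance of the observed
difference: in our simulations with a patient-effect SD of 15 points the
lesion-level scheme rejects a true null well above the nominal 5% rate,
while the patient-level scheme holds its size (this is verified in the
test suite). Use `"lesion"` when analysing or simulating lesions as
independent units — the assumption under which the model is defined — and
`"patient"` when patient-level clustering is a live concern. A chi-square
test on responder counts (change $\le -30\%$, the RECIST
partial-response cut) is reported alongside as a cruder but assumption-light
dichotomous comparison.

## Statistical kernels

The per-location proportion comparisons use Pearson's chi-square without
continuity correction (`pearson_chi_square()`); recomputing the published
baseline-mix tests from the printed counts reproduces the printed p-values
(0.16 breast, 0.07 lung, 0.6 liver, 1.0 lymph node) only without the
correction, which fixes the convention. Inter-arm response comparisons use
the two-sample Wilcoxon rank test (`mann_whitney()`): exact when the
pooled sample is at most 12 with no ties, otherwise the tie- and
continuity-corrected normal approximation (typical accuracy ~0.01 against
exact enumeration at the switch point; worst case about twice that).
Pairwise intra-arm location contrasts use Tukey Honest Significant
Differences (`tukey_hsd()`, Tukey–Kramer for unbalanced groups).
Heterogeneity is decomposed by `anova_eta_squared()`: sequential (Type I)
sums of squares in the fixed order location → patient →
location:patient, each term's $\eta^2$ being its share of the total sum
of squares. With singleton patient×location cells the interaction and
residual are partially confounded; fully aliased terms contribute zero
and the convention is declared rather than inferred. Levene
(median-centred) and Jarque–Bera checks are provided as ANOVA
prerequisites, and outliers follow the $1.5\times$IQR rule with type-7
(linear-interpolation) quartiles — both conventions configurable.

## Sensitivity analyses

`remove_outliers_and_retest()` flags extreme responses on the pooled
(both-arms) change distribution by default — "extreme response", not
"extreme for its arm"; per-arm detection is available — removes them, and
reports the inter-arm p-value before and after. The paper's second scheme,
rebalancing unequal lesion (or patient) counts per location, is
under-specified in the source; rather than a single arbitrary subsample,
`rebalance_lesion_counts()` / `rebalance_patient_counts()` repeatedly
subsample each arm×location cell down to the smaller arm's count
(default 1000 draws) and report the whole p-value distribution
(median, IQR). Published post-rebalancing p-values are therefore not
reproduction targets.

## The synthetic trial generator

`synthetic_config()` + `generate_trial()` produce measurement tables with
the structure the analyses assume, so the pipeline is testable end to end
and parameter recovery can be verified. Defaults are the study conditions:

* **Arms and mixtures**: 24/26 patients; per-arm location mixtures
  proportional to the published baseline counts (VC 12/7/9/6,
  LC 11/20/11/9 across breast/lung/liver/lymph node).
* **Lesions per patient**: 1–5 with probabilities .55/.25/.12/.05/.03
  (mean 1.76, matching ~88 lesions over 50 patients), locations drawn
  sequentially with the RECIST cap of 2 per location.
* **Baseline sizes**: log-normal LAD per location with breast primaries
  largest (medians 40/18/25/22 mm, log-SDs 0.30–0.45) — the published
  report shows right-skewed size distributions with breast largest but
  prints no fitted parameters, so these are the package's own choice of a
  realistic calibration, not a claim about the data. SAD = 0.8·LAD;
  volume = $\pi/6\,\mathrm{LAD}^3$ times a shape factor (0.6).
  Rejection sampling enforces measurability (LAD ≥ 10 mm, nodal
  SAD ≥ 15 mm).
* **Effects**: diameter change for lesion $j$ of patient $i$ in location
  $\ell$ is $\mu_{a\ell} + b_i + \varepsilon_{ij}$, truncated at $-100$,
  with $\mu$ defaulting to the published per arm×location diameter means,
  patient effect $b_i \sim N(0, 15^2)$ and lesion noise
  $\varepsilon \sim N(0, 10^2)$ (percentage points). The additive patient
  effect is the simplest structure consistent with a nonzero patient
  $\eta^2$.
* **Volume coupling**: with `isotropy = TRUE` (default) the volume change
  is exactly the cube law $100((1+d/100)^3-1)$ of the diameter change
  (plus optional noise); with `isotropy = FALSE` volume changes are drawn
  around the published volume means instead. Real tumors are not
  isotropic — the published diameter and volume means visibly violate the
  cube law — so volume-specific conclusions should be exercised in the
  non-isotropic mode.
* **Dropout**: each patient independently misses follow-up with
  probability 7/42, the published attrition (42 → 35 patients).

`true_weighted_response()` gives the exact expectation of the weighted
response under a configuration; the expected per-location counts are
computed by enumerating the capped sequential location draws rather than
read off the raw mixture, so the Monte-Carlo consistency check in the
test suite compares against the true expectation of the sampling scheme.
Truncation at $-100$ is ignored in this expectation; at the default
effect sizes the truncated mass is below 0.5% and the induced bias is on
the order of 0.01 percentage points.

What the generator does **not** emulate: tumor growth kinetics,
scanner/reader measurement error, inter-lesion correlation beyond the
shared patient effect, non-target lesions and new lesions, and any
relationship between baseline size and response (none was found in the
source study). Passing tests on synthetic data therefore validate the
*arithmetic and inference machinery*, not the clinical conclusions.

## Numerical and design choices

* Percent changes are relative to baseline (the study tracks a single
  follow-up); changes are bounded below by $-100$.
* Target selection (`select_targets()`) ranks eligible lesions by
  descending response-axis size with lexicographic lesion-id tie-breaks —
  a deterministic convention (greedy is optimal under the per-organ cap),
  not a reconstruction of how the original trial chose.
* Eligibility floors (10 mm LAD, 15 mm nodal SAD) follow RECIST 1.1,
  which the trial declares it applied; both are arguments.
* `filter_major_locations()` defaults to `min_count = 4`, which on the
  published mix excludes exactly the 3 miscellaneous lesions (88 → 85).
* Volumes are stored in mm³ and reported in cm³ in population summaries.
* Permutation and resampling p-values use the add-one estimator and a
  canonical record ordering, so results are reproducible from
  (seed, draw count) and invariant to row shuffles.

## Problem sizes used in the checks

The bundled verification suite runs parameter recovery at 200 patients
per arm over 20 seeds, Monte-Carlo consistency of the generator over 300
trials of 30 patients per arm, and the size of the permutation test over
1000 simulated null trials of 15 patients per arm at 199 permutations
each — scales chosen so each check's Monte-Carlo error is well below the
effect it guards against.
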