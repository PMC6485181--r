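---
title: "Designing and validating randomized recruitment for multicenter observational studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating randomized recruitment for multicenter observational studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

recruitsim implements, as reusable and testable machinery, the design of a
multicenter observational biomarker study in cystic fibrosis (CF):
concealment-preserving random-letter patient selection with adaptive
enrollment-speed control, a rule-based pulmonary-exacerbation case
definition with protocol sample scheduling, bootstrap power and
sample-size estimation for proportional-hazards and linear biomarker
endpoints, cohort-representativeness and seasonal-enrollment statistics,
and biospecimen processing/shipping quality control. Everything runs on
synthetic data produced by the package itself, so every component can be
exercised and audited without access to any patient registry.

## The random-letter selection scheme

Each potentially eligible patient in a recruitment block (one adult and
one pediatric block per center) is pre-assigned an i.i.d. uniform letter
of the alphabet. A block has a *threshold*: writing $k \in \{0, \dots,
26\}$ for the number of flagged letters, a patient is approached in
clinic only when their letter index is strictly earlier than $k$. The
threshold letter itself is **not** flagged; we adopted the strict
reading of "earlier than the threshold letter" and express the
threshold as the count $k$ precisely to remove the boundary ambiguity.
Because the letter is assigned before any clinic contact and is
independent of covariates by construction, clinic staff cannot select
patients by characteristics — inclusion is concealed and randomized,
and the expected flagged fraction is exactly $k/26$.

The initial threshold solves the planning equation: with pool size $N$,
consent (recruitment) rate $c$ and show rate $s$, expected enrollment is
$\frac{k}{26} N c s$, and `required_threshold()` returns the smallest
$k$ meeting the target. The planning defaults are $c = 0.53$ (a prior
recruitment rate) and $s = 0.90$ (allowing a 10% clinic no-show rate).
For example, a pool of 100 with a target of 20 needs $k = 11$: letters
A–K flagged, threshold letter L.

Letters are drawn i.i.d. *with replacement*; nothing in the scheme
requires distinct letters, and collisions are harmless because the
decision rule only compares each patient's own letter with the block
threshold.

## The enrollment-speed controller

Enrollment speed is reviewed at the end of study month 1 and quarterly
from study month 3. At each review, `adjust_threshold()` re-runs the
planning computation with current information:

* consent and show rates are re-estimated from the observed trace, with
  the empirical rates shrunk toward the planning values by a prior
  weight of 10 pseudo-observations. The shrinkage prevents wild swings
  at the first review, when a block may have a handful of approaches;
  10 pseudo-visits makes the data dominate as soon as a block has seen
  a few dozen visits. The rule is a design choice of this package — any
  stabilizer with the same limit behavior would do.
* the projected eventual enrollment at threshold $k$ is
  `enrolled + c·s·(undecided patients with letter < k)`, using the
  letter histogram of still-undecided patients. The histogram matters:
  once early letters have been consumed by decisions, the undecided
  pool is letter-skewed, and assuming uniformity would first freeze and
  then overshoot enrollment. The histogram is available to the
  coordinating statistician who assigned the letters, and using it
  preserves concealment because no patient characteristic enters the
  decision. When the histogram is not supplied the controller falls
  back to the uniform $\frac{k}{26} \cdot$ pool projection.
* the new threshold is the smallest $k$ whose projection reaches the
  remaining target. Comparing it with the threshold in force *is* the
  speed signal: a smaller recomputed $k$ means the current threshold
  over-delivers (enrollment too rapid, move the threshold earlier in
  the alphabet); a larger one means it under-delivers (too slow, move
  later); equality leaves it unchanged. Each history row records the
  rationale, so the direction rule is auditable after the fact.

Enrolled patients are never un-enrolled by a threshold decrease;
patients who declined are never re-approached; patients not yet
approached are re-evaluated against each new threshold. Simultaneous
visits are processed in lexicographic patient-id order so a replay is
bit-identical. Consent draws use one pre-drawn uniform per patient
(common random numbers), which makes total enrollment pathwise
non-decreasing in $k$ — a property the test suite asserts directly.

In simulations with a 1,000-patient block, a 150-patient target and a
true consent rate of 0.40 against the planned 0.53, the controller
brings final enrollment within ±15% of target in well over 90% of
runs. Two honest limitations: thresholds are integers, so a small block
(a few dozen patients) cannot express a fractional target and the
smallest-adequate-$k$ rule systematically rounds *up*, which in a
9-center simulation with 18 small blocks produces a mild (~10–20%)
aggregate overshoot; and enrollment between reviews is uncontrolled, so
a very front-loaded visit schedule can overshoot before the first
review.

`check_randomization_integrity()` provides the two audits a skeptical
reviewer would ask for: an exact replay (every recorded flag decision
must equal `is_flagged(letter, k in force)`, every enrollment must have
been flagged, shown and consented) and a covariate-exchangeability
permutation test comparing flagged and unflagged patients, whose
p-values are uniform under the design's null by construction.

## The pulmonary-exacerbation rule engine

The case definition is: at least one symptom (increased sputum, cough,
dyspnea, chest pain or tightness, hemoptysis, fever, chills,
arthralgias, fatigue) **and** at least one objective sign; respiratory
arrest or failure requiring mechanical ventilation qualifies regardless
of other criteria, and the site PI can force a borderline call either
way. The signs and the boundary conventions implemented:

| Sign | Rule |
|---|---|
| Lung-function drop | FEV₁ or FVC ≥ 10% below baseline (relative; exactly 10% counts) |
| Fever | temperature strictly > 38.4 °C |
| Hemoptysis | witnessed, strictly > 100 ml per episode |
| Hypoxemia | SaO₂ < 90% or PaO₂ < 60 mmHg despite usual oxygen |
| Adolescent desaturation | age 12–<18 and SaO₂ ≥ 5 points below baseline |
| Oxygen requirement | increased supplemental-oxygen need (boolean input) |
| Weight loss | ≥ 5% of baseline over ≤ 3 months (93 days) |

Strict versus weak inequalities follow the printed criteria: ">" for
temperature and hemoptysis, "≥" for the drop criteria. The 10%
lung-function drop is interpreted relative to baseline, the convention
in CF exacerbation criteria; a percentage-point reading is available
via `fev_drop_relative = FALSE`. Three months is fixed at 93 days and
the 48-hour collection window closes two calendar days after onset.
Criteria whose inputs are missing are *skipped and reported as
unevaluated*, never treated as absent — an important distinction for
audit trails.

"Mild exacerbation" has no quantitative definition in the source
protocol; we operationalize it as a one-sided presentation (symptoms
without signs, or signs without symptoms). This is deterministic,
reduces arbitrary misclassification, and makes the verdict lattice
stable < mild < exacerbation monotone: adding a symptom or sign can
never demote a verdict, which the tests assert by sweeping the truth
table exhaustively. Whether a mild call blocks enrollment is not
specified either; the default here is that it does, with an
adjudication flag for the site PI, configurable via `mild_blocks`.

## Bootstrap power and sample size

`bootstrap_power()` resamples patients (the resampling unit is the
patient row) with replacement from a pilot dataset, fits the endpoint
model — a Cox proportional-hazards model of the time-to-event outcome
on the biomarker, or least squares of a continuous outcome on the
biomarker — and reports the fraction of replicates in which the
biomarker coefficient is significant by a two-sided Wald test at level
$\alpha$. The two-sided choice is a package decision (the source
α-levels are stated without sidedness) and is configurable in effect
through $\alpha$. Non-converged or degenerate resamples (all censored,
zero-variance biomarker, diverging hazard estimate) are redrawn and
counted, with a cap of $10B$ attempts. `sample_size_search()` walks an
increasing grid and stops once the target power is met and confirmed at
the next grid point; the reported minimum is the first grid point
reaching the target, and an unreachable target returns a "grid
exhausted" status rather than an error.

Two closed forms serve as oracles. For the hazards model, the
Schoenfeld-type event count
$d = \lceil (z_{1-\alpha/2} + z_{\text{power}})^2 / (\beta^2
\sigma_x^2) \rceil$; for the linear model,
$n = \lceil (z_{1-\alpha/2} + z_{\text{power}})^2 \sigma^2 /
(\beta^2 \sigma_x^2) \rceil + 2$. With $\beta = 0.5$ per SD,
uncensored pilots, the bootstrap minimum lands within one grid step of
the 60 events ($\alpha = 0.01$, power 0.90) and 32 events
($\alpha = 0.05$, power 0.80) the formulas give, and null pilots
($\beta = 0$) estimate power within Monte-Carlo error of $\alpha$.
Printed sample-size tables from the original study depended on pilot
data that is not public; the package reproduces the machinery, not
those numbers.

## Cohort representativeness, seasonality, shipping QC

`compare_cohorts()` mirrors the registry-comparison table layout:
binary characteristics by Pearson χ² on the 2×2 table without
continuity correction (documented choice; the hand formula is then
exact), continuous ones by two-sided Welch t-test, counts by
quasi-Poisson regression on a cohort indicator. An adjusted mode
regresses each characteristic on the cohort indicator plus covariates
(site, age, sex, …) for users who want registry-style adjusted
p-values; with individual-level registry data unavailable, the package
makes no claim of reproducing any published adjusted p-values.

`seasonal_effects()` derives meteorological seasons (Dec–Feb Winter,
Mar–May Spring, Jun–Aug Summer, Sep–Nov Fall — the calendar is a
package choice, the source being silent) with Summer as the reference
level, fits one regression per characteristic (linear, logistic or
quasi-Poisson by type), and applies Bonferroni across the $m$
characteristics tested. On a noiseless cohort in which Fall enrollees
are exactly 8.7 years older, the Fall age contrast is exactly 8.7.

`paired_shipping_analysis()` handles split-sample shipping controls:
ordinary least squares of the shipped measurement on the immediate one,
per-pair elevation factors (shipped/immediate), their mean with a
normal-approximation 95% CI for the mean clipped below at zero, and
the maximum factor. Pairs with non-positive immediate values have an
undefined factor and are excluded with a warning. The CI method of the
published interval is unstated; the normal approximation on the factor
mean is this package's choice and is labeled as such in the output.

## Biospecimen workflow validation

`validate_timing()` enforces the processing protocol: collection ≤ 20
minutes, ≤ 60 minutes from collection start to initiation of laboratory
processing, and ≤ 3 hours from initiation to completion. The protocol's
"1–3 h to complete processing" is enforced as an upper bound only — the
lower end is descriptive. `make_labels()` renders aliquot labels as
`<ID>_<YYYYMMDD>_<fraction>_<sample#>_<aliquot#>` (the component list is
protocol, the format is ours) with a default plan of 1 L, 2 SA, 2 SB,
1 P aliquots — the protocol says "aliquots" without counts —, and
`parse_label()` inverts the rendering exactly, including participant
ids containing underscores. `assign_split_batches()` spreads each
sample's aliquots across shipments so that no single shipment loss can
destroy all material from any sample, balancing shipment sizes by
always filling the least-loaded shipments; single-aliquot samples are
flagged as unsatisfiable rather than erroring. `qc_sample()` flags oral
contamination at ≥ 5 squamous epithelial cells per low-power field and
low counting adequacy below 200 cells.

## The synthetic-data generator

`population_config()` fixes the study conditions: age ~ N(27, 12)
truncated at 12 years, FEV₁ percent predicted ~ N(80, 23) truncated to
(0, 150], 46% male, negative-binomial prior-year exacerbation counts
with mean 1 and SD 1.2 (overdispersed, matching the reported moments),
airway-infection prevalences at the reported annualized fractions, a
10% no-show rate and a 53% consent rate, and 9 centers whose pools
total 696 adults and 154 pediatric patients. Ages are drawn per block
from the doubly truncated marginal ([12, 18) pediatric, [18, ∞) adult)
so that configured block sizes and the age–block invariant hold
simultaneously. Two home-elevation presets are exposed — mean 1305 m
(SD 442) and mean 328 m (SD 112) — because cohort summaries of the same
region report both; the package does not adjudicate between them and
defaults to the registry-style preset. Truncated sampling is by
rejection (exact, no boundary atoms). Visits sit on a quarterly grid
with a random phase and ±7-day jitter; clinic schedules are otherwise
unspecified, and quarterly care is the CF norm. Exclusion flags
(transplant 2%, immunosuppression 1%, vulnerable status 2%) are
plausible desk-scale rates chosen once for the eligibility filter.

All randomness flows through one seeded generator per call; no
generator touches global RNG state, and identical configuration plus
seed reproduces byte-identical tables.

What the generator deliberately does **not** emulate: disease
progression, correlation between covariates (age and lung function are
independent here, which is false in real CF), seasonal structure in
patient characteristics, geography, or informative no-shows. Passing
tests therefore demonstrate that the *machinery* is correct under the
stated marginals — replay exactness, calibration, closed-form
agreement — not that any real cohort is representative. The
representativeness statistics are calibrated under a null where the
cohort truly is a random subset of the reference; real-data confounding
is out of scope.

## Numerical conventions and test scales

Degenerate inputs have defined behavior throughout: identical
proportions give χ² = 0 and p = 1 without touching the test routine;
two constant equal groups give t = 0, p = 1 by convention; zero
margins, contradictory overrides, out-of-order timestamps, and
infeasible rate/target combinations raise named errors. Permutation
p-values use the add-one estimator $(1 + \#\{|T^\ast| \ge |T|\}) /
(B + 1)$ with $B = 199$ by default. Equality at thresholds follows the
documented inequality conventions; floating-point comparisons in the
permutation test use a $10^{-12}$ guard.

The shipped test suite runs the full designs at desk scale, chosen once
as the package's own verification scale: 10,000-patient pools for the
distributional laws, 1,000 null simulations for p-value uniformity, 200
controller runs for the ±15% attainment property, B = 500 bootstrap
replicates against the closed forms, and 1,000 random cases for the
timing-validator oracle. `scripts/acceptance.R` re-runs the same
computations end to end from a single seed and writes the resulting
quantities as JSON.
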