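---
title: "Scoring sign-tracking, conditioned reinforcement and cocaine conditioning: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring sign-tracking, conditioned reinforcement and cocaine conditioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavca)
```

## The measurement problem

In autoshaping preparations a retractable lever is inserted for 8 s and
then a food pellet is delivered regardless of what the animal does. Rats
split into those that approach the predictive cue itself (sign-trackers),
those that approach the site of reward delivery (goal-trackers), and a
large intermediate group. The tendency is a stable individual trait and a
candidate marker of how strongly reward cues acquire incentive salience.
This package turns raw operant event logs into that phenotype, scores the
companion assays (conditioned reinforcement, cocaine conditioned cue
preference, cocaine contextual conditioning), and provides the inferential
battery those assays are conventionally analyzed with.

## The PavCA index

Each of the five sessions contributes 25 CS trials. Per session we compute

* **probability differential** — the fraction of trials with at least one
  lever deflection minus the fraction with at least one CS-period food-cup
  entry. "Probability" is deliberately the per-trial contact probability,
  not a response rate.
* **response bias** — (lever deflections − food-cup entries) /
  (lever deflections + food-cup entries) over the whole session, defined
  as 0 when the subject made no CS-period contact at all.
* **latency score** — (mean food-cup latency − mean lever latency) / 8.

The index is the arithmetic mean of the three, hence bounded in [−1, 1];
the terminal index averages sessions 4 and 5, where acquisition has
stabilized. Thresholds at ±0.5 give the GT / IN / ST classification.

Three decisions here were genuinely open:

* **Latency censoring.** A trial without contact contributes the full CS
  duration (8 s) to the mean latency. Any other rule (dropping such
  trials) lets the latency score escape [−1, 1] for partially responding
  subjects and makes the three components incommensurable; censoring also
  makes a fully non-responding subject land exactly on the bound.
* **The latency formula is read as a whole-difference quotient**,
  (food-cup latency − lever latency)/8, not food-cup − (lever/8). Only the
  former is bounded in [−1, 1] and consistent with the index's published
  range.
* **Boundary convention.** Exactly ±0.5 is assigned to the extreme
  phenotypes (GT at −0.5, ST at +0.5). The choice is measure-zero in
  practice but documented and deterministic, and the three intervals
  partition [−1, 1] exactly.

Inter-trial food-cup entries are reported (they index general activity and
carry the female-elevated activity signature) but never enter the index:
the index is CS-period behavior only. CS windows are half-open
[onset, offset): a contact at exactly the offset belongs to the interval.

## Conditioned reinforcement

Nosepokes into the active port produce 3-s presentations of the lever CS.
We treat the schedule as fixed-ratio 1 **with a lockout**: pokes during an
ongoing presentation count as pokes but do not queue further presentations.
This is the conventional reading of such procedures and is what makes
"lever presses per reinforcer" exceed 1. Subjects that never earn a
reinforcer have an undefined presses-per-reinforcer and are excluded
casewise from analyses of that measure only (their other CRF measures
remain). The incentive value index, (active − inactive) + lever presses,
is emitted alongside the raw counts because analyses in this literature
have used either the active−inactive difference or raw active counts; both
are available.

## Cocaine assays

**Cue preference (CCP).** The cocaine-paired floor is the one the subject
spent *less* time on during the pre-test (counter-conditioning); exact
ties are broken by a seeded draw so scoring is reproducible. The
preference change is **post − pre** time on the cocaine floor, so a
positive value means an increased preference after conditioning. Per-trial
cocaine and saline distances give the locomotor profile, and
sensitization is cocaine trial 4 − trial 1.

Counter-conditioning has a known artifact which the synthetic generator
reproduces on purpose: subjects with the strongest initial bias (in this
population, goal-trackers) have the most room to regress toward
indifference, so they show the largest mean preference gain even when the
conditioned shift itself is phenotype-independent.

**Contextual conditioning (CCC).** Eight days: habituation, saline
baseline, five cocaine days, then a drug-free test in the cocaine-paired
context. All contrasts are later-minus-earlier: acute activation
(day 3 − day 2), locomotor sensitization (day 7 − day 3, typically
*negative* here because forward locomotion gives way to stereotyped
headwaving at this dose), conditioned locomotion (day 8 − day 2), and the
three headwaving analogues. Subjects missing any day are flagged on read
and excluded casewise from all CCC analyses, with the count logged.

## The statistical battery

`mixed_rm_anova()` computes univariate mixed-design F tests by projecting
each subject's within-subject profile onto an orthonormal contrast basis:
for every subset *w* of within factors, the Kronecker product of
orthonormal factor contrasts (factors in *w*) and normalized unit vectors
(the rest) spans one error stratum, and every between-subject term is
tested there with a Type III hypothesis matrix under sum-to-zero coding.
Because the basis is orthonormal, sums of squares stay in the units of the
data and, on balanced designs, the term and error SS add up to the total
SS exactly; the test suite checks this and checks every statistic against
a brute-force summation oracle.

Choices worth stating:

* **No sphericity correction.** Plain univariate F with integer degrees of
  freedom; this matches how such designs are conventionally reported in
  this literature.
* **Type III with sum-to-zero contrasts**, because phenotype groups are
  unbalanced by construction (intermediates dominate).
* **η² is classical** (SS of the term over total SS), the conservative
  choice; partial η² is available via `eta = "partial"`.
* **Error strata**: between-subject error for between terms, the
  subject-by-*w* interaction for each within subset *w*. Tukey HSD probes
  should be fed the mean square and degrees of freedom of the stratum
  matching the probed term; `tukey_hsd_groups()` covers the common
  between-groups case.

`pca_varimax()` standardizes the variables, eigendecomposes the
correlation matrix, retains components with eigenvalue ≥ 1, and rotates
with Kaiser-normalized varimax written out as iterative planar rotations
(relative criterion tolerance 1e-6, cap 500 sweeps, error on
non-convergence). Rows are normalized to unit communality before rotation
and rescaled after, so communalities are invariant to machine precision.
Factors are sign-oriented so the dominant loading is positive and ordered
by rotated explained variance; loadings above 0.7 in absolute value are
flagged salient. The suite verifies the rotation against the reference
implementation in base R and against 1000 random orthogonal rotations.

## The synthetic cohort generator

Two standardized latent traits drive everything: incentive salience
(`theta_is`) and cocaine responsivity (`theta_cr`), bivariate normal with
correlation `trait_correlation_rho` (default 0 — the independence
structure under test; the null must be generable to know the pipeline does
not hallucinate coupling). Females get a +0.3 SD shift on `theta_is`
(more lever-directed) and a 1.3× multiplier on cocaine locomotion.

Mapping traits to behavior, per PavCA trial: lever contact is Bernoulli
with probability `plogis(0.85 + 1.6 · s · theta_is)` where `s` scales
session 1 to 0 and session 5 to 1 — session 1 is near-indifferent
(contact probability ≈ 0.7 for both targets regardless of trait) and the
terminal sessions are trait-saturated, reproducing the divergence of
phenotypes over training from a common start. Contact trials add
1 + Poisson deflections with a trait-scaled log-mean; first-contact
latencies are truncated-exponential on [0, 8] with a trait-scaled hazard;
food-cup behavior mirrors all three with −`theta_is`; inter-trial
food-cup entries are Poisson with a female-elevated rate. Inter-trial
intervals are uniform on 30–150 s, so a 25-trial session accumulates
37.5 min of inter-trial time in expectation. None of these distributional
forms is claimed to be empirically estimated; they are the minimal shapes
with the right supports and the right qualitative dynamics, and they are
exposed as constants rather than magic numbers.

The CRF generator honors the 3-s lockout mechanically (a poke stream is
replayed against it) and couples mean deflections per presentation to the
cohort-standardized terminal index with gain `sqrt(crf_coupling)` and a
residual chosen so the cohort r² between index and presses per reinforcer
realizes `crf_coupling` (default 0.43) up to sampling error — the Poisson
measurement variance of the ratio is budgeted into the residual rather
than added on top.

Cocaine locomotion is log-normal around a subject baseline with an acute
multiplier, a per-trial sensitization increment (CCP) or a decaying
factor plus geometrically growing headwave counts (CCC), a female
multiplier, and `exp(gain · theta_cr)`. The CCP pre-test bias grows with
goal-tracking (`pmax(0, −theta_is)`) and only half of it persists to the
post-test, which is what reproduces the counter-conditioning artifact
described above.

Determinism: every stage (traits, each task) draws from its own seed
derived from `master_seed`, with fixed subject ordering, so an identical
configuration reproduces the cohort byte for byte, and adding or removing
a task does not perturb the others.

**What the generator does not emulate** — and hence what green tests do
and do not show about real data: no within-session time courses beyond
the trial schedule, no pharmacokinetics (dose is metadata), no batch,
cohort-site or age effects, no drift across days beyond the programmed
dynamics, and measurement noise that is exactly the stated families. The
suite demonstrates that the *pipeline* recovers truth under a known
generative model (null preserved at rho = 0; coupling detected and
attenuation-consistent at rho = 0.6); it cannot certify distributional
robustness on real logs.

## Numerical conventions and degenerate inputs

Timestamps are at millisecond grain; serialized tables print `time_s`
with exactly three decimals, which is what makes writes byte-stable and
round-trips exact. Validation is total: malformed rows (negative times,
broken CS windows, schedule violations, out-of-window CS events) raise
located errors and are never coerced. Zero-contact sessions score 0/0/
censored rather than NA; zero-variance correlation inputs are flagged,
not silently dropped; a single retained component skips rotation;
quartiles use linear interpolation (type 7) and boxplot notches the
conventional 1.58·IQR/√n.

## Validation problem sizes

The shipped suite runs cohorts of 1500 subjects across 20 master seeds
for the null-independence and two-factor-recovery checks, 3 seeds at
rho = 0.6 for detection, one 1500-subject cohort for the conditioned
reinforcement calibration band, 60 replicate cohorts of 150 subjects for
confidence-interval coverage, 10,000 sessions for the schedule check, and
20 randomized small designs against the brute-force ANOVA oracle. These
sizes were chosen to keep Monte-Carlo error well inside the asserted
tolerances.

## Known limitations

* The ANOVA engine requires complete within-subject data (casewise
  exclusion, as in the emulated workflow) and crossed within factors; it
  is not a mixed-effects (REML) estimator and applies no sphericity
  correction by design.
* Tukey HSD assumes the supplied error stratum is homogeneous across
  groups (Tukey-Kramer for unequal sizes).
* PCA retention is the plain Kaiser rule; no parallel analysis.
* The generator's couplings are calibrated to cohort-level targets, not
  to subject-level trajectories; per-subject fits to real data are out of
  scope.
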