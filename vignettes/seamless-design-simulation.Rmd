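---
title: "Simulating a seamless phase II/III design with sequential dose selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a seamless phase II/III design with sequential dose selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seamsim)
```

## The design being simulated

`seamsim` simulates a seamless phase II/III trial in acute ischemic stroke
that compares three candidate doses of a thrombolytic (arms A, B, C at 0.10,
0.25 and 0.40 mg/kg) against an active comparator (arm D, rt-PA 0.9 mg/kg).
Two outcomes drive the design:

* the **rapid response** $X$, an ordered trichotomy observed within 24 h:
  symptomatic intracranial hemorrhage (ICH) $<$ neither (NEI) $<$ major
  neurological improvement (MNI);
* the **clinical outcome** $Y$, the 3-month modified Rankin scale
  trichotomized as poor (4–6, including death) $<$ neither (2–3) $<$ good
  (0–1).

Patients are randomized in matched sets of four (one per arm). The design has
three stages.

**1. Sequential elimination.** Each completed set of three candidate-arm rapid
responses adds 2 points to an arm's cumulative sum for MNI, 1 for NEI and 0
for ICH. The first time the largest cumulative sum is at least a *lead*
(default 6 points) ahead of the smallest, all arms attaining the minimum are
eliminated. When one arm remains it is selected. If no single arm survives
after $m = 150$ sets the procedure is truncated and selection passes to
clinical criteria.

**2. Promise or futility.** At 100–150 patients per continuing arm (as
dictated by selection timing), the selected dose is compared with the
comparator. Both endpoints — the poor- and good-outcome proportions — are
first tested with a continuity-corrected pooled $z$-test at the two-tailed
0.001 level. Otherwise a safety scenario is classified from the ICH-count
difference $d = \mathrm{candidate} - \mathrm{comparator}$: $d \le -2$
(Scenario 1, promising iff the candidate's poor proportion is no higher),
$|d| \le 1$ (Scenario 2, promising iff the poor proportion is at least 8
percentage points lower), $d \ge 2$ (Scenario 3, always unpromising). An
unpromising dose stops the trial with no hypothesis declared.

**3. Group-sequential phase III.** A promising dose continues 1:1 against the
comparator, with interim looks when the two continuing arms total 500, 1000
and 1500 patients (each endpoint tested two-tailed at 0.001, stopping on
rejection) and a terminal analysis at 1908 (954 per arm), each endpoint at
0.025 — the first stage of a Holm step-down at overall $\alpha = 0.05$, which
is also recorded in full for reporting.

The test statistic throughout is the pooled two-proportion $z$ with
half-integer continuity correction,
$$ z = \frac{\max\left(0,\; |\hat p_1 - \hat p_2| - \tfrac12\left(\tfrac1{n_1} + \tfrac1{n_2}\right)\right)}{\sqrt{\bar p (1-\bar p)\left(\tfrac1{n_1} + \tfrac1{n_2}\right)}}. $$
The protocol's site-stratified Mantel–Haenszel test is deliberately replaced
by this pooled test: site-stratified randomization makes the stratification
factor orthogonal to treatment under the null, so the two have essentially
identical null behavior, and the pooled form is what makes million-replicate
error studies feasible.

## What the type I error study estimates

Under a null scheme (identical clinical-outcome distribution in all four
arms) a replication contributes a type I error when any interim test rejects
at 0.001 or any terminal test rejects at 0.025. Futility stops without such a
rejection contribute none: the futility rules are part of the protocol, and
the error rate is defined under the protocol. When truncation leaves no
promising survivor, one surviving dose is chosen uniformly at random and
tested once at the 0.001 level before stopping, so that the "no winner"
branch cannot hide an error. The experiment-wise rate is unconditional — only
one hypothesis is ever tested per endpoint, because inferior doses are
removed by a selection procedure (on a different, correlated outcome), not by
hypothesis tests.

`estimate_type1_errors()` runs this accounting over an ensemble of null
schemes and reports per-scheme rates for the poor endpoint, the good
endpoint, either endpoint, and the four signed tails, plus the eight
descriptive statistics across schemes.

## The synthetic distribution schemes

A *distribution scheme* gives each arm a joint distribution of $(X, Y)$,
factored as $P[X \mid T]$ times $P[Y \mid X, T]$. Null schemes share one
$Y$-marginal across arms. The generator (`build_scheme_ensemble()`) draws,
uniformly over box-bounded regions of the simplex:

* $P[X \mid T]$ with $P[\mathrm{ICH}] \in [0.01, 0.12]$ and
  $P[\mathrm{MNI}] \in [0.05, 0.45]$ — anchored on typical 6% ICH rates with
  thrombolysis and the 16–36% MNI range seen in pilot dosing data;
* $P[Y]$ with $P[\mathrm{poor}] \in [0.20, 0.60]$ and
  $P[\mathrm{good}] \in [0.15, 0.55]$;
* conditionals $P[Y \mid X, T]$ per arm, subject to the **marginalization
  constraint** $\sum_x P[X = x \mid T]\, P[Y \mid X = x, T] = P[Y]$ (enforced
  to $10^{-10}$ component-wise) and the **clinical monotonicity constraint**:
  $P[\mathrm{poor} \mid X]$ non-increasing and $P[\mathrm{good} \mid X]$
  non-decreasing in $X$.

The conditional sampler draws the two extreme rows from the flat simplex
restricted to their monotone ordering, solves the middle row from the
marginalization identity, and accepts iff the solved row is a valid,
monotone-middle probability triple. This yields exact marginalization by
construction with broad coverage of the feasible set. Monotonicity is
non-strict, so the independence matrix (every row equal to the
$Y$-marginal) is admissible as a degenerate case. Rows for zero-probability
$X$ categories are set to the $Y$-marginal and excluded from the solve; they
are never sampled. The rejection cap defaults to $10^6$ candidates because
admissible $Y$-marginals with a nearly empty middle category (allowed by the
region bounds) squeeze the middle row into a sliver with acceptance rates
near $10^{-4}$; infeasibility inside the cap raises an error naming the
most-violated constraint.

Design choices where the design was genuinely open:

* **Region bounds.** The exact historical sampling regions are not published;
  the bounds above are this package's own clinically anchored choice and are
  config-overridable (`regions.*`), so alternative ensembles can be studied.
* **One $X$-marginal per scheme.** Within a scheme all four arms share one
  rapid-response marginal (`share_x = TRUE` default), while conditional
  matrices are drawn independently per arm. Sharing keeps the candidate arms
  exchangeable in the selection stage, which is the natural null; per-arm
  draws are available for sensitivity work.
* **Cascade elimination.** After eliminating the minimum-attaining arms the
  predicate is re-applied within the same set (`cascade = TRUE`): from sums
  (10, 4, 3) with lead 6, the trailing arm is eliminated and the remaining
  gap of 6 then eliminates the second arm too. The rationale is that the
  post-elimination state already satisfies the stated stopping criterion. A
  one-elimination-per-set variant is available as a switch; the replicated
  selection operating characteristics match the reference values under the
  cascade rule.
* **Stopping on interim rejection.** An interim rejection at 0.001 stops the
  simulated trial (it would constitute at least one type I error and trigger
  monitoring-board action); later looks are therefore not exposed. This is
  the conservative reading for later-look exposure and is switchable in
  principle by testing at the terminal stage only.
* **Residual ties** after the truncation criteria (lowest ICH rate, lowest
  poor, highest good) are broken uniformly at random from the design's RNG
  stream.
* **Continuity-correction clamping.** When the correction exceeds the
  observed $|\hat p_1 - \hat p_2|$ the statistic is clamped at zero rather
  than allowed to change sign; a pooled proportion of exactly 0 or 1 yields
  $p = 1$ and is flagged degenerate, so zero-variance data can never reject.
* **Median and mode of the selection time.** The published table does not
  define how truncated replications enter these summaries. The median is
  computed on $\min(N, m)$ — the observed stopping time — and the mode on
  non-truncated replications only, since otherwise the truncation atom at
  $m = 150$ would dominate schemes with appreciable no-winner probability
  while the reference table reports interior modes.

## Fixed-sample-size variant

`simulate_trial(design = "fss")` keeps the dose selection (forcing a uniform
random choice among survivors at truncation, a convention for a branch whose
historical handling is not published) but removes the promise/futility
examination and all interim looks, proceeding straight to one terminal
analysis per endpoint at 0.025 with 954 patients per arm. Comparing the two
modes on the same schemes isolates the design's two error mechanisms: the
selection stage inflates the "candidate looks better" tail, which the
continuity correction more than absorbs, and the futility rules remove the
bulk of null replications before any high-powered test is reached.

## Reproducibility and problem sizes

All randomness flows through R's RNG. Long studies reseed deterministically
per scheme from a master seed (`derive_seed()`), with separate named streams
for scheme generation, selection studies and trial replication, so
per-scheme results do not depend on how many schemes are run or in which
order a study is resumed. The replication inner loops are written in C++
(via Rcpp) and draw from the same RNG; `simulate_trial()` is a pure-R
reference implementation of a single replication built from the module-level
primitives, and the test suite cross-checks the two routes statistically.

The package's standard study sizes, chosen to characterize the design on a
single workstation, are 100,000 replications per scheme for selection
operating characteristics and a 200-scheme ensemble ($8 \times 5 \times 5$)
with 4,000 replications per scheme for the error studies; the ensemble and
replication counts scale directly (`ensemble.n_x/n_y/n_cond`, `--schemes`,
`--reps`) up to the reference study's $1000 \times 40{,}000$ shape.

```{r, eval = FALSE}
xm <- lfc_x_marginals(best = c(0.36, 0.06), inferior1 = c(0.16, 0.06))
estimate_selection_ocs(xm, reps = 100000, seed = 1)

ens <- build_scheme_ensemble(8, 5, 5, seed = 1)
estimate_type1_errors(ens, 4000, design = "gs", seed = 1)
```

## What passing simulations do and do not show

The generator emulates the *distributional* structure of the trial: ordered
trichotomous outcomes, arm-specific dependence between the early and late
endpoint, and clinically plausible marginals. It does not model enrollment
calendars, missing or delayed 3-month outcomes, site heterogeneity, or
protocol deviations — the error control demonstrated here is error control
*under the protocol*, with outcomes available when the schedule needs them.
Power properties are out of scope: the ensembles are null-only, and the
design's published power claims depend on baseline outcome distributions
that are not reproduced here. The three-arm selection stage is the only
configuration exercised against reference values; the elimination machinery
is written for $k$ arms but is untested beyond three.
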