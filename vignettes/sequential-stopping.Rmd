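---
title: "Sequential retirement of crowdsourced classification tasks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential retirement of crowdsourced classification tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdstop)
```

## The problem

Citizen-science image campaigns routinely assign the same task — "does this
satellite image contain cropland?" — to many volunteers, because a single
rating is unreliable. Volunteer labor is free but finite: every redundant
rating of an already-settled image is a rating not spent on a new one. The
question this package answers is *when to stop*: after each incoming
rating, should a task be retired as confidently classified, retired as
hopelessly contested, or kept in circulation?

## The model

Each task has a latent probability $\theta$ that a volunteer rates it
positive. Informative ratings are modelled as independent
Bernoulli($\theta$) draws; a third "maybe" option is allowed in the input
but carries no information and never enters the tally. With a conjugate
$\mathrm{Beta}(\alpha_0, \beta_0)$ prior on $\theta$ and a tally of
$n_+$ positive and $n_-$ negative ratings, the posterior is

$$\theta \mid \text{tally} \sim \mathrm{Beta}(\alpha_0 + n_+,\; \beta_0 + n_-).$$

The *disagreement rate* is the share of ratings on the minority side; its
posterior mean is $\min(\alpha, \beta)/(\alpha + \beta)$. The stopping
rule, however, is quantile-based — the mean is reported as descriptive
metadata only, because a mean close to the threshold says nothing about
how certain we are.

Writing $F$ for the posterior CDF, $D$ for the disagreement threshold and
$\gamma$ for the required certainty, `decide()` returns

* **NEGATIVE** when $F(D) \ge \gamma$ — the $\gamma$ quantile of $\theta$
  is at or below $D$;
* **POSITIVE** when $F(1-D) \le 1-\gamma$ — the $1-\gamma$ quantile is at
  or above $1-D$;
* **DEADLOCK** when $F(D) < (1-\gamma)/2$ and $F(1-D) > 1-(1-\gamma)/2$ —
  the central $\gamma$ credible interval lies strictly inside $(D, 1-D)$,
  so the crowd is confidently *split* and more votes are unlikely to
  produce a classification;
* **CONTINUE** otherwise.

For any $D < 0.5$ the three terminal conditions are mutually exclusive
(the test suite asserts this exhaustively on the $200 \times 200$ tally
grid rather than by proof).

## Parameters, defaults, and why

| parameter | default | meaning |
|---|---|---|
| `disagreement_threshold` (D) | 0.2 | largest tolerable minority share; 1 dissent in 5 is acceptable for most land-cover work |
| `certainty` (γ) | 0.95 | posterior probability required before retiring a task |
| `prior` | Beta(0.5, 0.5) | Jeffreys prior: weak, symmetric in the classes, slightly favouring decisive tasks over ambiguous ones |
| `rating_cap` | none | optional hard budget per task; see below |

At the defaults, the integer geometry of the rule works out to: a minimum
of **9 unanimous** ratings to classify, **10 evenly split** (5–5) ratings
to deadlock, and **36 majority** ratings to classify against 4 dissents.
These are not inputs; they fall out of the posterior arithmetic and are
recomputed by `boundary_table()`.

The lower-tail classification condition is stated with the $1-\gamma$
quantile (the 5th percentile at $\gamma = 0.95$ must clear $1-D$), so the
two classification conditions are exact mirror images under a symmetric
prior; the mirror-symmetry property in the test suite depends on this
reading.

## Numerical choices

* The rule is evaluated through `pbeta` (the regularized incomplete beta
  function) rather than `qbeta` inversion: the two are algebraically
  equivalent, and the CDF is better conditioned near 0 and 1.
  `decide(..., method = "quantile")` keeps the inverse-CDF route alive as
  a cross-check, and a test asserts agreement across configurations.
* Classification inequalities are non-strict ($\le$, $\ge$), deadlock
  inequalities strict ($<$). With continuous posteriors and integer
  tallies, exact equality at a threshold is measure-zero, so this is a
  convention rather than a substantive choice; what matters is that one
  CDF implementation is used throughout, which makes every boundary
  integer exactly reproducible with no floating-point epsilon.
* Boundary scans (`min_majority_for_classification`,
  `min_even_split_for_deadlock`) are bounded by an explicit
  `search_limit` (default 10 000) and report `NA` beyond it: tallies whose
  underlying rate sits near a threshold may genuinely never conclude, and
  an unbounded loop would hide that. The deadlock region is cached as a
  dense grid (`decision_grid`) rather than a per-dissent threshold,
  because deadlock is not characterised by a single minimum per dissent
  count; the grid is a cache of `decide()`, never a re-derivation, and an
  equivalence test probes it against the direct rule.

## Replay semantics

`replay_image()` re-runs history: it feeds a task's recorded ratings to
the rule one at a time and stops where the task *would* have been retired.
Design choices a user should know about:

* **Ordering.** Ratings are ordered by the order column (timestamp or
  sequence number) with input file order as the stable tie-break —
  real rating streams contain duplicate timestamps.
* **Savings denominator.** "Maybe" ratings are excluded both from tallies
  and from the savings denominator: `fraction_ratings_eliminated` is
  defined over informative ratings only, which keeps the efficiency
  multiplier $1/(1-\text{fraction eliminated})$ interpretable within the
  rule's own input space.
* **`rewidened` vs `changed`.** After the hypothetical stop, the replay
  keeps scoring the growing tally. `rewidened` records whether the
  condition that triggered the stop ever stops holding (the credible
  interval drifts back out of spec); `changed` whether a *different*
  terminal condition is ever satisfied. A POSITIVE–NEGATIVE switch is a
  *strong* change; classified–deadlock switches in either direction are
  *weak*. The two are reported independently: a conclusion can rewiden
  without ever changing.
* **`CAPPED` is its own outcome.** With a `rating_cap`, tasks withdrawn
  undecided at the cap are not folded into DEADLOCK, so capped and
  uncapped replays of the same campaign can be compared cleanly.
  `dissent_threshold_under_cap()` exposes the planning consequence of a
  cap: under the default thresholds and a 34-rating budget, any task that
  accumulates 4 dissenting ratings can be retired immediately, because
  classification would need $36 + 4 > 34$ ratings.
* **Percentiles** of the discrete ratings-to-conclusion counts use the
  "smallest $n$ covering at least the stated fraction of cases"
  convention, matching how count distributions are usually summarised in
  this setting.
* For CAPPED and UNRESOLVED stops there is no triggering condition, so
  `rewidened`/`changed` are `NA`; `final_outcome` still reports the first
  terminal verdict the continuation reaches, and `end_state` the verdict
  at the literal end of the stream.

## The synthetic campaign generator

`generate_synthetic_campaign()` is the package's stand-in for a real
campaign deposit. It emulates the structure such campaigns share: a
per-image latent $\theta$ drawn from a mixture concentrated near 0 and 1
(most imagery is easy) with a minority mid-range component (genuinely
ambiguous imagery); iid Bernoulli($\theta$) ratings; a right-skewed
ratings-per-image distribution (negative binomial, mean 23, size 5 —
matching the order of 20-odd ratings per image that large campaigns
accumulate); and a 5% "maybe" rate. The defaults are one-time choices of
what a realistic campaign looks like, not tuning knobs.

What it deliberately does **not** emulate: rater identity and skill
heterogeneity, fatigue and learning over a session, non-stationary
$\theta$ (imagery batches of varying difficulty), and correlated raters.
Tests that pass on synthetic campaigns therefore validate the *replay
machinery and the rule's own operating characteristics*, not the claim
that any particular real campaign will save a particular fraction of
ratings. Campaign-level statistics (fraction of ratings eliminated,
first-rating agreement, rewidening rates) are computed by the engine for
whatever input it is given; their values on real data require the real
data.

## The Monte-Carlo sweep

`run_sweep()` asks: if a task's true positive-rating probability is
$\theta$, what does the rule conclude, how fast, and how often wrongly?
Truth is implied by the thresholds — $\theta < D$ should end NEGATIVE,
$\theta > 1-D$ POSITIVE, anything strictly between DEADLOCK. The default
grid is $\theta = 0.01, \dots, 0.99$ in steps of 0.01 *minus the two
thresholds themselves*: exactly at $D$ the posterior can dither
arbitrarily long, and the cell says nothing useful about campaign design.

* **Seeding.** Each replicate's seed derives deterministically from the
  master seed and its (θ-index, replicate-index) pair via
  `(master * 1048573 + i * 9973 + j) mod 2147483629` — exact in double
  arithmetic, below $2^{31}$, and echoed into the output metadata so any
  single cell can be re-run in isolation.
* **Censoring.** A replicate that reaches `max_ratings` (default $10^6$,
  far beyond any plausible stopping time on the default grid) is recorded
  as CENSORED, reported separately, and excluded from both numerator and
  denominator of the misclassification rate and from the median
  ratings-to-conclusion. An infinite loop is not an acceptable failure
  mode for a simulation, so the bound is explicit rather than silent.
* **Acceleration.** Ratings are drawn and the rule evaluated in growing
  blocks, with tallies inside the precomputed decision grid resolved by
  lookup; the stopping point is identical to draw-by-draw evaluation
  (asserted on $10^4$ random probes).

Problem sizes used by the shipped tests: the full 97-point grid at 1000
replicates per cell for the operating-characteristic checks (about 15
seconds on one core), 2000 replicates for the $\theta \leftrightarrow
1-\theta$ mirror test, and a 20 000-image seed-pinned synthetic campaign
for the "no strong changes" replay property. These sizes give
three-standard-error resolution of a few percentage points on the rates
of interest, which matches the precision at which those rates are
meaningful for campaign design.

## Known limitations

* Binary tasks only. Multinomial or continuous-response extensions would
  need a different posterior family and are out of scope, as are
  rater-skill weighting and per-class asymmetric thresholds (the
  configuration object keeps `D` and `gamma` scalar precisely so an
  asymmetric variant could be added without breaking the interface).
* The rule assumes exchangeable, independent raters. Where raters see
  each other's answers, or difficulty drifts within a task's stream, the
  posterior is mis-calibrated in ways the replay engine will faithfully
  reproduce but not flag.
* Near-threshold tasks ($\theta \approx D$ or $1-D$) take arbitrarily
  long to conclude; `rating_cap` exists for exactly this case, at the
  cost of a fourth, undecided, outcome class.

## A worked example

```{r example}
decide(9, 0)
bt <- boundary_table(max_dissent = 4, grid_max = 50)
bt$min_majority
camp <- generate_synthetic_campaign(200, seed = 42)
res <- replay_campaign(camp)
summarize_campaign(res)
```
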