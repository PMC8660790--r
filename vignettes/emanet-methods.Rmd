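---
title: "Case-control dynamic networks for EMA data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-control dynamic networks for EMA data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emanet)
library(dplyr)
```

# The problem

Ecological momentary assessment (EMA) samples affect, context and behavior
several times a day on a smartphone — here, a 7 beeps/day x 7 days design
with four 1–7 Likert affect items (happy, sad, anxious, relaxed), minutes
spent at home in the past hour (0–60 in 15-minute steps), interaction
counts and partner-type indicators, and motivation for future interaction.
Case-control questions about *dynamics* — does sadness at one beep depress
happiness at the next? does being at home feed back into staying at home? —
cannot be answered with bivariate summaries. `emanet` implements the full
workflow: pooling per-subject series, estimating signed contemporaneous +
lagged partial-correlation networks per group with momentary conditional
independence (MCI) control, comparing groups with a network goodness-of-fit
R² and density, and making the usual "visual" feedback-loop reading of
such networks algorithmic.

Because raw clinical EMA data of this kind are rarely shareable, the
package is built around a first-class synthetic-data module: a structural
vector autoregression (SVAR) with planted, documented group structure so
every stage is testable end to end.

# Generative model

A panel is simulated per subject from

$$x_t = B_0 x_t + \sum_{\tau \ge 1} B_\tau x_{t-\tau} + \varepsilon_t,
  \qquad \varepsilon_t \sim N(0, \mathrm{diag}(\sigma^2)),$$

with $B_0$ strictly lower triangular under a declared causal order (no
contemporaneous cycles) and the companion matrix of
$(I-B_0)^{-1}B_\tau$ constrained to spectral radius < 1 (stationarity is
checked at construction; `simulate_panel()` refuses non-stationary
specifications). Each subject's trajectory discards a 50-step burn-in
(initialization transients at AR levels used here decay within ~10 steps;
50 is a comfortable margin). Latent values are standardized by their
stationary SD (from the model's Lyapunov equation) and mapped to
observation scales:

* Likert 1–7: `round(x * 1.5 + 4)`, clipped — mean 4, SD 1.5, so latent
  correlations survive discretization nearly intact;
* at-home minutes: affine to mean 30 / SD 15, rounded to 15-minute steps;
* counts 0–6: affine to mean 2 / SD 1.5, rounded and clipped;
* indicators: latent > 0 (a median split).

Missingness is MCAR at 9.16% by default — the overall missing fraction of
the study design this generator emulates. MCAR is the minimal assumption
given that only a global rate is known; response-latency, adherence and
missing-not-at-random mechanisms are deliberately out of scope.

## Group presets

`make_group_preset()` returns the two case-control fixtures. They are
*fixtures encoding the published loop structure*, not claims about the
population: the comparison-group ("HC_like") preset plants the adaptive
positive loops among happiness, relaxation and social motivation and a
self-correcting anxious–sad loop; the case-group ("SZ_like") preset plants
the mutually negative sad–happy loop, the relax–anxious–at-home cycle, the
self-reinforcing alone–at-home loop and the friends–happy negative loop,
with social motivation a highly connected sink (no positive-affect →
motivation link). Planted loop edges default to |b| = 0.3 with AR(1) = 0.4
— detectable at the pooled record counts of the emulated design (~3,700 to
5,600 records per group) at α = 0.01.

Around the loops, each preset carries supporting cross-lagged edges
(|b| = 0.2), lag-2 echoes (0.1) on exogenous-driver links, weak lag-2
self-terms (0.05) and a few contemporaneous coefficients (0.2), giving
between-variable densities near 1 — the scale of densities reported for
real EMA case-control networks, where values above 1 occur because a pair
can be linked at several lags. Coefficient geometry was finalized once,
for stationarity: an all-0.3 dense layout is explosive (spectral radius
1.23); the shipped presets sit at 0.94 (HC-like) and 0.91 (SZ-like). Two
of the seven comparison-group loop edges (the happy→relax and
social-motivation→happy "return" edges) are therefore at support strength.

The presets use 8 variables (4 affect, social motivation, at-home, alone,
friends). The full 15-variable EMA vocabulary exists in
`ema_variable_clusters()`; a cluster naming variables absent from a panel
errors informatively.

# Preprocessing

`concatenate_series()` pools subjects ordered by (subject, day, beep),
preserving relative order. The default `boundary_policy = "mask"` inserts
`tau_max` all-missing spacer rows between subjects so that **no lagged
sample spans two subjects** — naive concatenation (retained as
`"naive"` to mimic the simplest reading of pooled estimation) creates
spurious cross-subject lagged pairs. Lags are counted in survey steps;
two days = 14 steps at 7 beeps/day, and overnight gaps are treated as one
step (lags modeled as if continuous). Note one deliberate asymmetry: the
spacer width guards the *tested* pair for all lags up to `tau_max`;
conditioning values shifted beyond `tau_max` (a source-parent at lag
`tau + tau'`) can still originate from the preceding subject. Conditioning
on an independent value is harmless for test validity (it only wastes a
degree of freedom), so the spacer is not doubled.

`impute_midscale()` implements the midscale rule for sparsely answered
Likert items (missing → 4, the 1–7 midpoint, for user-listed variables —
the "sparse" set is a configuration, not an automatic rule, because no
threshold is prescribed); it is idempotent and never touches spacer rows.
`blank_counts_to_zero()` implements the survey-design rule that blank
partner counts mean "no interaction of this type".

`adf_test()` is an augmented Dickey–Fuller unit-root test with a constant
term (the series analyzed here have non-zero means but no trends, so the
constant-only variant is the right null), AIC lag selection up to the
Schwert bound, and MacKinnon (1994) response-surface p-values. It was
verified in development to agree with a reference statistics
implementation to full precision on fixed series; those frozen values are
asserted in the test suite. Missing values are dropped before testing;
p < 0.01 flags a series stationary.

# Network estimation

The engine follows the PC–MCI two-stage logic for lagged conditional
independence discovery with partial-correlation tests:

1. **Condition selection** (`pc_condition_selection()`): for each target,
   all (variable, lag 1..`tau_max`) candidates are screened iteratively;
   at iteration *k* each surviving candidate is tested conditional on its
   *k* strongest surviving co-candidates (by |partial correlation| from
   the previous iteration; removal happens after each full pass, so
   results do not depend on within-pass order), until no candidate has
   *k* co-candidates. The screening level `pc_alpha = 0.05` is laxer than
   the reporting level by design — screening must err towards keeping
   parents. Tie-breaks (|r| descending, then variable name, then lag) make
   the output deterministic and independent of column order.
2. **MCI link tests** (`mci_link_test()`): every ordered pair and lag
   1..`tau_max` (self-lags included) is tested conditional on the selected
   parents of the target (minus the tested link) *and* the time-shifted
   parents of the source — the conditioning that controls false positives
   from autocorrelation. Links with p < α = 0.01 are reported, with the
   partial correlation as the signed weight. No further multiple-testing
   correction is applied: the reporting convention is raw significance at
   0.01.
3. **Contemporaneous links**: each variable is residualized on its
   selected lagged parents; lag-0 links are the pairwise correlations of
   those residuals (degrees of freedom charged for both parent sets),
   kept at α and stored undirected — nothing here orients same-time
   associations, and the lag-collapsed figure convention treats them as
   symmetric. A full partial-correlation (inverse-covariance) network
   over the residuals was rejected on missing-data grounds: with ~9%
   MCAR per cell, listwise deletion across eight residual series (each
   already requiring its parents observed) retains well under 1% of rows.

Sample selection under missingness is strict: a row contributes to a test
only if the target, the lagged source and every conditioned value are
observed (verified against brute-force recomputation in the tests). All
tests run off one lagged embedding matrix; the partial correlation is
computed from the inverse covariance of (x, y, Z), with an explicit
residualization fallback when that matrix is rank-deficient.

`estimate_network()` warns (and proceeds) above 10 variables, the point
where power and interpretability degrade for designs of this size.

## What the estimator targets — and how recovery is scored

With contemporaneous mixing $B_0$, a lagged regression sees the *reduced
form*: the lag-$\tau$ dependency matrix is $(I-B_0)^{-1}B_\tau$, which
can contain pairs absent from the structural $B_\tau$ (a lagged parent
acting through a contemporaneous partner). `score_recovery()` therefore
scores:

* **precision** of estimated edges against the reduced-form dependency
  set (`reduced_form_links()`),
* **recall** and **sign agreement** against the planted structural links,

both at the directed-pair level (lagged: ordered pair, strongest-|weight|
lag; contemporaneous: unordered pair) — the edge concept of the
lag-collapsed network figures and of the R² expansion below. Scoring
individual (pair, lag) triples against structural matrices would penalize
the estimator for finding dependencies the generating model genuinely
implies, and — with coarse Likert/indicator measurement — for the
extra-lag shadows that conditioning on discretized parents leaves on
truly-linked pairs. Those shadows are a real and instructive limitation:
discretization breaks exact conditional independence, and the resulting
small systematic partial correlations become significant as n grows. On
undiscretized latent panels the false-link rate matches the α-level
expectation exactly.

# Group comparison metrics

Two networks over the same variables are expanded over identical
(pair, channel) slots — one lagged slot per ordered pair carrying the
signed weight of the strongest-|weight| significant link across lags
(summing over lags is available by option; *some* aggregation is required
because the published edge notation carries no lag index), one
contemporaneous slot per unordered pair, absent links contributing exactly
0 — and compared as

$$R^2 = 1 - \sum_{\text{slots}} (w^{A} - w^{B})^2,$$

a similarity (1 at identity, possibly negative, never clamped), not a
regression fit. Density is

$$D = \frac{\#\{\text{significant links}\}}{N(N-1)/2}$$

in the default count mode — the reading consistent with published densities
above 1, which require counting a pair once per significant lag; weight
mode (sum of |w|) is also shipped. Autoregressive self-links are excluded
from both metrics by default: the denominator N(N−1)/2 concerns
between-variable structure.

# Feedback loops

`collapse_to_summary()` reduces a network to a signed digraph: lagged
links become sign-of-weight directed edges (same-sign lags merge;
conflicting signs across lags yield parallel edges with a conflict flag),
contemporaneous links become sign-matched edge pairs, and a
contemporaneous edge duplicating a same-sign lagged edge merges into it.
`enumerate_loops()` finds all simple directed cycles up to `max_length = 4`
(the published loops have 2–3 distinct nodes; 4 keeps the report
interpretable and the search cheap) by DFS rooted at each cycle's
lexicographically smallest node, so each cycle is reported exactly once.
Cycles made solely of contemporaneous-derived edges are discarded by
default: a lag-0 association trivially forms a 2-cycle that is not
temporal feedback (a mixed cycle with at least one lagged edge is kept —
the published alone/at-home loop is exactly such a case).

## Classification

Feedback type is the product of edge signs: +1 self-reinforcing
(positive), −1 self-correcting (negative). For adaptivity the classifier
asks what the loop does to the states it contains, voting over non-context
member nodes by valence (default map: happy, relax, social motivation
positive; sad, anxious negative; location/partner variables neutral +
context):

* a **positive** (amplifying) loop can lock its members in at high
  intensity — likely **maladaptive** if any voter is a negative-valence
  state (negative affect persists), else likely **adaptive** if voters
  are positive-valence states, else mixed;
* a **negative** (dampening) loop erodes its members — likely
  **maladaptive** if it dampens any positive-valence state, else likely
  **adaptive** if it dampens negative affect, else mixed.

This valence-composition rule was chosen over a literal
perturbation-propagation rule after checking both against the full set of
nine published loop classifications: propagation labels the
anxious→sad→(reduced) anxious loop maladaptive (sadness rises on the way
around), while the published reading — which this rule reproduces for all
eight labeled loops — calls a negative loop among negative-affect states
adaptive because its net effect is to shut negative affect down.

Context nodes set the context flag but stay out of the vote, with one
documented special rule: a context-only loop (alone ⇄ at-home) is `mixed`
by default and is labeled by its context nodes' valences when the user
assigns them — the case-group configuration giving being-alone and
being-at-home negative valence reproduces the published "maladaptive"
reading of that loop. One published loop is labeled "coping strategy" in
its source — a category outside the positive/negative–adaptive/maladaptive
taxonomy; it is the same cycle (different rotation) as the
relax–anxious–at-home loop, so the classifier necessarily gives both one
label (maladaptive), and only its feedback type and context flag are
asserted against the source.

# Pipeline and reproducibility

`run_config()` + `run_pipeline()` bundle the whole analysis: simulate (or
read) one panel per group → pool with spacer masking → estimate per group
→ metrics → loops (with per-group valence overrides) → Table-1-style
descriptives; every random stage is seeded from the single configured seed
(default 20211209), and identical configurations produce identical
reports. `write_run_report()` materializes edge-list CSV + GraphML per
group, a JSON metrics report, loop CSVs, descriptives CSV and a log.
This package is a library, not a shell tool: the exported functions, the
acceptance script and this vignette are the interface, and the
configuration object plays the role a command line would.

Descriptives follow the conventions of published group tables: Cohen's d
by the pooled-SD formula, record-level n for EMA variables (the printed t
statistics of such tables are only attainable with record-level n),
subject-level n for demographics, and the 2×2 chi-square without
continuity correction (the uncorrected statistic reproduces the published
adherence test; the Yates-corrected one does not). Published effect sizes
whose formula cannot be recovered (e.g. a d of −2.06 for a 10.5-minute
difference with SDs of 24–28) are computed by the documented standard
formula and reported alongside, never asserted equal.

# Problem sizes and what the tests show

The test suite and acceptance script run: recovery on 10 seeded panels
per preset at 200 subjects × 49 beeps with 9.16% MCAR (the planted-loop
and precision/recall checks), null calibration on 20 seeded 5-variable
AR-only panels at 100 subjects, PC/MCI calibration on 5,000-point series,
ADF behaviour at n = 2,000, and an exhaustive 3-node plus seeded
4–5-node sweep of the cycle enumerator against a permutation oracle
(the full space of ≤5-node, ≤8-edge digraphs is ~2.6×10⁵ graphs; the
exhaustive 3-node space plus 200 random larger instances exercises every
code path at a fraction of the cost). These sizes were chosen as the
smallest at which the statistical claims are sharp.

Passing tests on synthetic panels show that the estimator recovers planted
reduced-form structure under Likert/indicator discretization, MCAR
missingness and subject pooling — they do not show that real EMA data meet
the model's assumptions (linearity, Gaussian innovations behind ordinal
scales, MCAR, no overnight-gap effects, stationarity across the week), and
group presets are published-structure fixtures, not population claims.

# Known limitations

* Contemporaneous links are unoriented, and no PCMCI+-style lag-0
  orientation or graphical-lasso alternative is provided.
* Conditional-independence tests are linear-Gaussian partial correlations;
  ordinal items are treated as interval-scaled.
* Discretization-induced conditional-independence violations produce
  extra-lag shadows on truly-linked pairs at large n (see the scoring
  discussion above).
* Night/day gaps are modeled as single steps; no loop-gain or
  stability analysis of the estimated VAR is attempted.
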