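---
title: "Perceptual tomography: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perceptual tomography: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomonet)
```

## The problem

Classical sociometric surveys ask people about their *own* ties, which makes
them expensive, burdensome, and sensitive to self-report bias. Perceptual
tomography takes the opposite route: it aggregates many light-weight
*third-party* reports. Each respondent is shown a random subset of `k` photos
from a roster of `n` community members and sorts them into three bins —
"close to me", "recognize but not close", "don't recognize". The recognized
members are then sorted into `B` clusters ("place people who you think are
close to each other into the same cluster"), and the respondent gives a
binary opinion on each recognized member for each of `M` community attributes
(e.g. "makes positive changes in the community"). Only the recognized bin
feeds the analysis; "close" placements are deliberately excluded so the
signal reflects perception of *others'* ties, not the respondent's ego
network.

From `m` such reports the package reconstructs

1. a **signed perceived network**: positive ties where significantly many
   respondents co-clustered a pair, and negative, "robust intransitive" ties
   where significantly many split a pair — statistical evidence of a
   perceived *non*-relationship, not of animosity;
2. **perceived attributes** `{-1, 0, +1}` per member and attribute;
3. a **structural-balance partition** of the signed network into classes,
   and multinomial-logit tests of whether class membership predicts
   perceived attributes.

## The null model and its calibration

Significance is measured against a blind-respondent null model: each
respondent recognizes every non-self member independently with probability
`gamma`, clusters uniformly at random over the `B` bins, and affirms
attribute `a` with probability `beta[a]`. Its `M + 5` parameters are
`n, m, k, B, gamma, beta`. `gamma` is calibrated by moment matching,
`sum(d_i) / (m k)` with `d_i` the recognition degree, and each `beta[a]` is
the affirmative fraction of recorded opinions.

For a random pair of members, the probability that one blind respondent
recognizes both and co-clusters them is

```
p = (1/B) * sum_r z_r * sum_l [ C(r,l) C(n-r, k-l) / C(n,k) ] * [ C(l,2) / C(n,2) ]
```

with `z_r` the binomial recognition pmf over `n - 1` others and `l` the
number of recognized members among the `k` shown (the inner sum runs over
`max(2, k + r - n) <= l <= min(r, k)`; an empty range contributes nothing).
The split probability is `q = (B - 1) p`. Aggregated over respondents, the
pair's co-cluster count `X` is `Bin(m, p)` and its split count `Y` is
`Bin(m, q)`. The tie cutoffs are the minimal integers whose strict lower
tails reach the confidence level:

```{r thresholds}
pars <- null_params(n = 393, m = 172, k = 40, B = 5, gamma = 0.7622)
dist <- pair_count_distributions(pars)
c(delta_plus = dist$delta_plus, delta_minus = dist$delta_minus)
c(conf_same = 100 * sum(dist$x_pmf[1:2]), conf_diff = 100 * sum(dist$y_pmf[1:3]))
```

At this operating point a pair needs `>= 2` co-placements for a positive tie
and `>= 3` split placements for a negative tie.

Numerical notes. All combinatorial terms are evaluated in log space
(`lchoose`, `dbinom(log = TRUE)`) — coefficients such as `C(393, 40)`
overflow double precision — and the double sum is exponentiated after
shifting by its running maximum. The recognition pmf deliberately uses
`n - 1` trials while the hypergeometric and pair terms use `n` (the
respondent's own photo can be drawn but never recognized); the simulator
reproduces exactly this convention, drawing the `k` shown photos from the
full roster and discarding a self draw. The threshold search compares the
accumulated strict CDF to `level - 1e-12` so that an exact boundary equality
is not lost to floating-point rounding. Pairs meeting *both* cutoffs are
recorded in a contested ledger and, by default, carry no edge
(`contested_null`); the resolving policies `positive_wins`/`negative_wins`
bracket the default's edge counts and are logged with the network.

## Perceived attributes

For member `i` with observer set `O_i` (respondents who placed `i` in the
recognized bin), the affirmation count for attribute `a` is compared with the
null expectation `beta[a] * |O_i|` by an exact one-sided binomial tail —
right-tailed above the expectation, left-tailed below, inconclusive at the
expectation or with no observers. Exact tails (no normal approximation) keep
the test well defined at the small observer counts typical of a `k/n`
sampling design. Raising the confidence level can only move decisions toward
inconclusive, and the one-sided gating means a member can never
simultaneously pass both tails.

## Balance partitioning

The signed network is partitioned into `K` classes by minimizing
`R = alpha_w * N_c + (1 - alpha_w) * P_c`, the weighted count of negative
within-class edges plus positive between-class edges; `R = 0` is perfect
structural balance. Defaults: `alpha_w = 0.5`, which lets the negative
(robust intransitive) ties shape the partition as strongly as the positive
ties, and `min_size = 3`, a minimal sociologically meaningful group.

The optimizer is a relocation method: repeated random feasible starts
(min-size seats dealt round-robin, remainder uniform), then steepest-descent
local search over single-node relocations and two-node exchanges, restricted
to moves that keep every class at the size floor. Relocation gains are
evaluated incrementally from per-node edge counts into each class, and
exchange gains as the sum of two relocation gains plus a shared-edge
correction, so each step costs `O(nK + n^2)` rather than a full re-score.
Every accepted move strictly decreases `R`, which bounds the search. Distinct
optima across repetitions are compared after canonical relabeling (classes
numbered by first appearance in node order); a trial is "unique" when all
repetitions agree on a single optimum, and model selection over a `K` sweep
prefers the lowest median `R`, then fewer non-unique trials, then smaller
`K`. A first-improvement mode trades a little solution quality for speed.

The local search is validated against `exhaustive_optimum()`, an enumeration
of all size-feasible partitions (restricted growth strings, guarded to 14
nodes): across hundreds of random signed graphs the heuristic attains the
enumerated optimum in over 99% of instances and can never report a lower
score.

## Class-attribute association

Each attribute's three-level outcome is regressed on `K - 1` class dummies
(reference: the largest class, configurable) by maximum-likelihood
multinomial logit with the inconclusive level as the outcome baseline. For
purely tabular designs the fit is saturated, so coefficients equal the
closed-form log odds ratios of the class-by-outcome table — the identity the
unit tests exploit. Empty cells (quasi-separation) are flagged rather than
penalized away, since the inflated estimate/standard-error pairs are
themselves informative about sparse attribute categories. No multiplicity
correction is applied across attributes.

## The synthetic-report simulator

The simulator exists so that every inferential stage can be tested against
known ground truth.

**Null regime.** Defaults mirror the field deployment that motivated the
method: `n = 393`, `m = 172`, `k = 40`, `B = 5`, `gamma = 0.7622`. Published
per-attribute affirmation rates are not available, so the default spreads 16
attributes over 0.10–0.70, a plausible range of community-opinion base
rates. Monte-Carlo frequencies from this generator match the analytic
`p`, `q` and the `X`/`Y` binomials within Monte-Carlo error, which is the
package's primary evidence that formulas and simulator implement the same
model.

**Planted regime.** A deliberately simple perception model — not a claim
about cognition, only a source of data with the structure the inference
assumes. Members belong to `K_true <= B` communities; an observer files a
recognized member under the member's community bin with probability `lambda`
and uniformly otherwise, with `lambda^2 = B (theta_in - theta_out) / (B - 1)`
capped at 1. This one-parameter mixture was chosen because it pins down the
three regimes that matter for validation: `theta_in = 1, theta_out = 0`
gives noiseless community sorting, equal thetas collapse exactly to the
blind null model, and the default (`theta_in = 0.9`, `theta_out = 0.1`,
`B = 5`) yields deterministic community bins. When the declared theta bounds
cannot be represented (possible when `theta_out > 1/B`), the constructor
warns with the induced rates. Attribute ground truth `Q` is drawn from
per-community role probabilities (default: one marker attribute per
community, 0.9 within / 0.1 elsewhere) and opinions from true/false-positive
rates 0.9/0.1; `close_prob` (default 0.1) diverts recognized members to the
"close" bin so the recognized-bin-only restriction of the tally stage is
exercised. The default recoverable regime is `n = 120`, `m = 120`, `k = 40`,
`B = 5`, `K_true = 4` equal communities, `gamma = 0.7622`.

Randomness is split into one stream per respondent, derived from the base
seed, so growing `m` leaves earlier respondents' reports untouched and
identical configurations write byte-identical files.

**What passing tests do and do not show.** The planted model has uniform
recognition, independent placements and homogeneous noise; real reports have
heterogeneous recognition rates, respondent-specific clustering styles and
correlated opinions. Recovery of planted structure therefore demonstrates
correctness of the inferential machinery under its own assumptions, not
field validity of the survey instrument.

## Problem sizes used in the checks

The bundled checks run at deliberately modest sizes chosen to exercise each
claim: the heuristic-versus-oracle comparison uses 200 random graphs of 6–12
nodes with 50 restarts; the Monte-Carlo oracle uses 3,000 simulated surveys
of an 8-member roster; end-to-end recovery uses 10 seeds of the default
planted regime with 10 restarts of the `K = 4` partition; type-I control
uses one full-scale null survey. Desk-scale clustering defaults are 10
trials of 100 repetitions; the field-scale 30 x 1000 protocol is available
through the same arguments.

## Known limitations

- The binomial pair model treats respondents and pairs as exchangeable; it
  ignores that a pair involving the respondent can never be co-clustered
  (the `C(l,2)/C(n,2)` term averages this out exactly in expectation, but
  pair-level distributions are a mixture rather than a single binomial).
- Calibration is global: one `gamma` for all respondents, one `beta` per
  attribute. Degree-corrected or heterogeneous-respondent nulls are out of
  scope.
- Edges are unweighted and undirected; contested pairs are excluded by
  default rather than modeled.
- Exact reproduction of published regression tables depends on one
  particular stochastic partition of one study's data; the regression engine
  is instead validated on closed-form and simulated cases.
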