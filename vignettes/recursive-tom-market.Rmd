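---
title: "Methods: recursive theory of mind in a buyer-seller market"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recursive theory of mind in a buyer-seller market}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tommarket)
```

## The model

Two agents meet once, over three stages. A buyer enters a T-maze with an
apple at distance `d(apple)` down one arm and an orange at distance
`d(orange)` down the other, consumes one item (stage 1), is observed doing
so by a seller who then posts prices (stage 2), and finally must purchase
one of the items at those prices (stage 3). Rewards, distances and prices
share one unit and one sum constraint `S`:
`r(apple) + r(orange) = d(apple) + d(orange) = m(apple) + m(orange) = S`.
Stage utilities are `U1(i) = r(i) - d(i)` and `U3(i) = r(i) - m(i)`; the
seller is paid `m(i3)` for the purchased item. The sum constraints are made
unviolable by construction: every pair is stored as its apple component
only, and the orange side is derived, never stored.

Choices are stochastic: the probability of taking the focal action is the
logistic of the inverse-temperature-scaled action-value difference,
`P = sigma(beta * (Q_i - Q_j))`. Because each pair of scalars sums to `S`,
the stage-1 and stage-3 value gaps reduce to `2*(r - d)` and `2*(r - m)`
respectively, so the naive policy has slope `2*beta` per reward unit.

The hierarchy alternates strictly. Each level is constructed from the
artifact exactly one level below and nothing else:

* **ToM(-1)** (naive buyer): stage utilities straight through the softmax
  at both choice points.
* **ToM(0)** (trusting seller): Bayesian inverse reinforcement learning --
  posterior over `r(apple)` proportional to the ToM(-1) likelihood of the
  observed first action times a uniform prior -- followed by
  revenue-maximising deterministic pricing against that posterior.
* **ToM(1)** (planning buyer): for each candidate first action it simulates
  the seller's IRL and pricing, then scores
  `Q(a1) = U1(a1) + E[U3 | prices the seller would set after a1]`, the
  expectation taken under its own stage-3 softmax. The expectation over the
  seller is degenerate because pricing is deterministic.
* **ToM(2)** (skeptical seller): the same IRL operation with the ToM(1)
  policy as likelihood. Wherever the ToM(1) choice is uninformative the
  posterior stays close to the prior and pricing stays flat.
* **ToM(3)** (cornered buyer): the same planning operation through the
  ToM(2) price table.

Because the nesting is strict and the state space finite, the literal
recursive simulation is replaced by memoized bottom-up tabulation; the two
are mathematically identical, and cost grows linearly rather than
exponentially in the number of levels. The entire pipeline is a
deterministic, closed-form function of the configuration: there is no
sampling anywhere, two builds are bit-identical, and `config_hash()` gives
that a checkable witness.

## Parameters

* `sum_total` (`S`, reward/money units, default 10): scale of the game.
* `grid_step` (default 0.5): the lattice spacing for preferences,
  distances and prices. The continuous formulation is discretised as
  probability-mass sums on `{0, step, ..., S}` with mass `1/n` per point --
  not Riemann sums with step weights -- so beliefs stay normalised exactly
  and divergences need no density convention. The default keeps the full
  default sweep (21 x 21 scenarios, five tables, seven metric curves) well
  under a second on one CPU.
* `beta` (unitless, default 0.5): softmax inverse temperature. One shared
  value serves every agent *and* every agent's model of every other agent;
  the model family nowhere distinguishes actor from modelled temperature,
  and a per-level override was deliberately not added -- a caller who wants
  an off-diagonal pairing can pass a modified configuration to any
  individual operation. `beta = 0` collapses every policy to coin flips
  (and every posterior to its prior); `beta -> infinity` approaches the
  step policy at `r = d`.
* `log_base` (default 2): all entropies and divergences are reported in
  bits; `exp(1)` switches to nats. The exported column name `value_bits`
  keeps its name either way.
* `pricing_objective` (default `"joint"`): see below.
* `max_level` (default 3): the recursion is generic and supports higher
  levels, but the behavioural claims of interest stop at ToM(3).

## Numerical choices

* **Pricing argmax and ties.** Prices are scanned over the full lattice;
  ties within `1e-12` are broken toward the price closest to `S/2`, then
  toward the lower price. This is deterministic and makes a
  mirror-symmetric revenue landscape price the two items equivalently,
  which is exactly the behaviour wanted from a seller whose posterior
  carries no label information.
* **Exact identity cases.** A likelihood constant in the preference is the
  Bayes identity: the posterior *is* the prior, and the update divergence
  is exactly zero. The implementation returns the prior object itself in
  that case instead of a renormalised copy, so the identity holds to the
  last bit rather than to rounding error. Likewise a policy column constant
  in `r` has exactly zero mutual information.
* **Degenerate evidence.** At finite `beta` the softmax never emits exact
  zeros, so hierarchy-produced tables cannot make an observation
  impossible. User-supplied tables can; the IRL update then fails loudly
  (`tommarket_degenerate_evidence_error`, with the offending distance and
  observation named when raised while tabulating a price table) rather
  than renormalising silently. The same philosophy applies to
  out-of-support divergences (`tommarket_support_error`).
* **`0 * log 0 = 0`** throughout the information-theoretic module.
* **Forced purchase.** Stage 3 has no opt-out action at any level.

## Design decisions

* **Joint versus chosen-only revenue.** The single-item statement of the
  pricing objective maximises `E[m(i) * P(buy i)]` for the queried item
  alone, yet the seller's reward pays the posted price of *whichever* item
  is bought. The default `"joint"` objective therefore maximises the full
  expectation -- both payoff branches -- which is the faithful expected
  value of the seller's reward; `"chosen_only"` is retained as a
  configuration switch for literal single-branch replication. Differences
  between the two are a documented diagnostic, not a bug.
* **The "more likely item" curve.** The belief-update curve conditions, at
  each distance, on the buyer choosing the closer item (the apple on the
  near half of the sweep, the orange beyond the midpoint, the equidistant
  tie resolved to the apple). By the mirror symmetry of the game the tie
  resolution is cosmetic.
* **Per-distance metrics.** Mutual information and policy discrepancy are
  reported per distance, marginalising the preference under the uniform
  prior -- the same prior the sellers use -- with no averaging over
  distances.
* **Distance cost.** The unit cost per step is 1; utilities subtract
  distances directly and no separate cost coefficient is modelled.

## What the checks do and do not show

The unit and property tests pin the implementation to independent oracles:
exhaustive game-tree enumeration for the planning values, a double-sum and
an entropy-decomposition route for the mutual information, brute-force
per-preference sums for both divergences, and the analytic limits at
`beta = 0` and large `beta`. These all agree to `1e-12`.

The end-to-end checks additionally assert a qualitative result surface for
this game that is commonly described at these conditions (`S = 10`,
`Delta = 0.5`, `beta = 0.5`): a bluff band in which the planning buyer
picks the nearby apple regardless of preference out to `d(apple) = 2`; an
indifference threshold at `d(apple) = 7` shifted only half a step, to 7.5;
trusting prices "just shy" of the distance walked (7.5 at `d = 8`); and
flat skeptical pricing with near-zero belief updates across the whole
bluff band.

Under the equations implemented here those descriptions are *mutually
inconsistent*, and the package deliberately leaves the unreachable ones
red in `test-acceptance.R` rather than bending the model to pass them. The
argument is short. Write `m(d, a1)` for the ToM(0) apple price at distance
`d` after observation `a1`; relabeling symmetry forces
`m(d, orange) = S - m(S - d, apple)`. For the bluff to dominate at
`d = 2` even for a buyer with `r(apple) = 0` (stage-1 cost 4), the price
spread `m(2, apple) - m(2, orange)` must exceed 4, which with trusting
pricing near 7.5 at `d = 8` requires `m(2, apple) > 6.5`. For the
threshold at `d = 7` to sit at 7.5, the stage-3 gain from bluffing must
stay below about 1.3, which requires `m(3, apple) < 4` -- a seller who
*discounts* an item below the uninformed price after watching the buyer
walk toward it. No Bayesian seller with a likelihood monotone in the
preference can produce both, whatever the softmax convention, pricing
objective (joint, single-branch, or per-item unconstrained) or forecast
sharpness; the bluff and threshold regions depend only on the sign of the
planning value gap, so no display temperature rescues them either. Under
the defaults the tabulated surface has a bluff band out to `d = 1`, a
threshold at `d = 7` of 9.0 (the value `scripts/acceptance.R` reports),
trusting prices of 7.0 at `d = 8`, and flat skeptical pricing out to
`d = 1.5` -- qualitatively the same deception-then-skepticism story, with
a stronger first-order bluff and a slightly narrower skeptical plateau.

The remaining signatures are reproduced and kept green: the planning buyer
strictly reduces the preference-action mutual information at every
distance in the near band; the skeptical seller's belief updates are
strictly smaller than the trusting seller's there, and the trusting
seller's update is strictly positive everywhere; and the
assumed-versus-actual policy divergence of the (ToM(2), ToM(3)) pair is
far below that of the (ToM(0), ToM(1)) pair -- the third-order buyer is
cornered.

## Limitations

* The environment is deterministic and single-shot: no stochastic
  dynamics, no repeated play, no learning across episodes, no belief over
  the opponent's *level* (each level models exactly the level below).
* All results are lattice tabulations; nothing is fitted to behavioural
  data, and the simulator makes no claim about how closely humans or other
  animals track these policies.
* Metrics condition on the uniform prior throughout; informative priors
  are representable (`irl_posterior()` takes any belief) but the shipped
  sweeps do not vary them.

## Problem sizes

Everything in the test suite and the acceptance script runs on the default
21-point lattice (levels -1 through 3; the most expensive object, a seller
table, is 21 distances x 2 observations x a 21-point price scan against a
21-point posterior) or on a deliberately coarse 3-point lattice where
brute-force enumeration is used as an oracle. A full default sweep with
figures takes a few seconds; the tabulation itself is tens of
milliseconds.
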