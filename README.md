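# tommarket

Deterministic simulator for a minimal buyer–seller signalling game in which
both agents carry a *recursive theory of mind*, plus the
information-theoretic instruments that make the resulting deception and
skepticism measurable. It is aimed at computational cognitive scientists and
multi-agent RL researchers who want a small, fully tabulated testbed where
opponent modelling, Bayesian inverse reinforcement learning and
information-theoretic analysis can be inspected down to every lattice cell.

## The game

Three stages, two items (an apple and an orange), one shared sum constraint
`S = 10` on preferences `r`, walking distances `d` and prices `m`
(`r(apple) + r(orange) = d(apple) + d(orange) = m(apple) + m(orange) = S`):

1. the buyer walks to one item and consumes it, earning
   `U1(i) = r(i) − d(i)`;
2. the seller observes that choice, knows the distances but not the
   preferences, and posts prices;
3. the buyer must buy one item, earning `U3(i) = r(i) − m(i)`; the seller is
   paid the posted price of whatever is bought.

All choices follow a two-action softmax with inverse temperature `β`
(`P = σ(β·ΔQ)`, default `β = 0.5`), and everything is tabulated on the
lattice `{0, Δ, …, S}` (default `Δ = 0.5`).

Agents alternate along a strict cognitive hierarchy:

| level | agent | construction |
|---|---|---|
| ToM(−1) | naive buyer | stage utilities straight through the softmax |
| ToM(0) | trusting seller | Bayesian IRL on the ToM(−1) policy, then revenue-maximising prices |
| ToM(1) | planning buyer | plans *through* the ToM(0) posterior and pricing (`Q = U1 + E[U3 | prices after a1]`) |
| ToM(2) | skeptical seller | same IRL, but with the ToM(1) policy as likelihood |
| ToM(3) | cornered buyer | plans through the ToM(2) prices |

Three diagnostics quantify the signalling (in bits by default):
`I(r; a1)`, the mutual information between preference and first action at a
given distance; `D_KL(p(r|a1) ‖ p(r))`, the strength of a seller's belief
update; and the expected divergence between a buyer's actual policy and the
policy its seller assumes, which scores how well deception lands.

## Worked example

The gambit: the apple is one step away but worthless to the buyer
(`r(apple) = 0`). A naive buyer mostly walks to the orange; the planning
buyer walks to the apple more often than not, purely to corrupt the
seller's inference and win a cheaper orange later.

```r
library(tommarket)
cfg <- tom_config()                      # S = 10, step 0.5, beta 0.5
h   <- build_hierarchy(cfg)
g   <- build_grid(cfg)

sc <- tom_scenario(d_apple = 1, r_apple = 0, cfg)
naive_stage1_policy(sc, cfg)
#> [1] 0.2689414
policy_table(h, 1)[match(0, g), match(1, g)]
#> [1] 0.5914328
planning_q(sc, price_table(h, 0), cfg)
#>  apple orange
#>  4.455  3.715      (rounded; the bluff path dominates)
```

The sellers react in kind — the trusting ToM(0) reads the walk as signal,
the skeptical ToM(2) refuses to:

```r
price_table(h, 0)[match(1, g), "apple"]   # ToM(0) raises the apple price
#> [1] 5.5
price_table(h, 2)[match(1, g), "apple"]   # ToM(2) keeps pricing flat
#> [1] 5
mutual_information(policy_table(h, -1), 1, config = cfg)  # naive leaks
#> [1] 0.2564702
mutual_information(policy_table(h, 1), 1, config = cfg)   # planner hides
#> [1] 0.08923152
```

A full sweep (every table, every metric curve, figures) from the shell:

```sh
inst/cli/tommarket all --out out/          # or: Rscript inst/cli/tommarket ...
```

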