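# psgame

Producer–scrounger games with a competitiveness–detection trade-off.

Foragers in groups either search for food (*produce*) or exploit others'
discoveries (*scrounge*), and individuals consistently differ in which
tactic they prefer. `psgame` models one candidate explanation: a skill
trade-off in which **strong** competitors (competitive weight 1, prey
detection probability δ ≤ 1) are better at monopolizing contested food,
while **weak** competitors (weight ω ≤ 1, detection 1) are better at
finding it. The package is for behavioural ecologists and evolutionary
game theorists who want the model's equilibrium predictions as tidy,
reproducible tables.

## The model

A group of `G` foragers holds the strong phenotype at frequency `p`; strong
and weak competitors play producer at frequencies `x` and `y`. A prey is
worth `F`; its finder keeps the finder's advantage `a` and the remainder
`F − a` is split by competitive weight among finder and joiners, e.g. for a
strong producer

    IP_strong = δa + δ(F − a)/(1 + W),   W = (G−1)[p(1−x) + ω(1−p)(1−y)]

with analogous expressions for weak producers and for scroungers (who join
every discovery). Two coupled processes are solved:

* **short term** — at fixed `p`, best-reply dynamics find the Nash tactic
  profile `(x*, y*)` where neither phenotype can gain by shifting its
  producer frequency; the specialization index `γ = |x* − y*|` summarises
  role differentiation;
* **long term** — each time step, 1% of the group is replaced by the
  phenotype with the higher mean payoff (`p → 0.99p ± 0.01`), iterated up
  to 1000 steps to the evolutionarily stable state `{p*, x*, y*}`.

The model is fully deterministic — no seeds, bit-identical reruns.

## Worked example

```r
library(psgame)

# tactic equilibrium at a half-strong group, Table-default parameters
solve_nash(eco_params(F = 10, a = 2, G = 10),
           pheno_params(omega = 0.8, delta = 0.8), p = 0.5)
#> Nash equilibrium at p = 0.5:
#>   x* (strong producer freq) = 0
#>   y* (weak producer freq)   = 0.628805
#>   gamma (specialization)    = 0.628805
#>   converged: TRUE in 6 sweeps; no-deviation check: pass

# long-term dynamics under a stronger trade-off (omega = 0.5)
run_evolution(eco_params(), pheno_params(omega = 0.5), t_max = 1000)
#> Producer-scrounger evolutionary trajectory (1000 steps)
#>   final state: p* = 0.746763, x* = 0, y* = 1, gamma = 1
```

At the default composition, strong competitors scrounge exclusively
(`x* = 0`) while weak competitors mix (`y* ≈ 0.63`): scrounging pays the
strong more because they win contested food. Under the long-term dynamic
with a stronger trade-off, the phenotypes coexist (`p* ≈ 0.75`) and
specialize completely — strong always scrounge, weak always produce
(`γ = 1`). With identical competitors (`omega = delta = 1`) the model
collapses to the classic equal-competitor game, whose producer frequency
`single_phenotype_equilibrium(eco_params())` ≈ 0.295 the two-phenotype
solver reproduces at every composition.

Sweep drivers regenerate whole response curves:

```r
run_sweep(sweep_spec("p", seq(0.05, 0.95, by = 0.05)))                  # composition
run_sweep(sweep_spec("a", c(0, 2, 4, 6), mode = "long_term"))           # finder's advantage
```

A command-line wrapper mirrors the R API
(`inst/scripts/psgame solve|evolve|sweep`, CSV out, YAML config, flags
override the file); see `?ps_main`.

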