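---
title: "A producer-scrounger game with a competitiveness-detection trade-off"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A producer-scrounger game with a competitiveness-detection trade-off}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psgame)
```

## The model

Social foragers can either search for food themselves (*produce*) or join
and exploit the discoveries of others (*scrounge*). The payoff to scrounging
is negatively frequency dependent: it pays when scroungers are rare and
collapses when everyone scrounges. `psgame` implements a deterministic,
two-phenotype version of this game in which the ability to steal food trades
off against the ability to find it:

* **strong** competitors have competitive weight 1 but detect prey only with
  probability $\delta \le 1$;
* **weak** competitors have competitive weight $\omega \le 1$ but detect
  prey with probability 1.

A group of fixed size $G$ contains the strong phenotype at frequency $p$.
Strong and weak competitors play producer at frequencies $x$ and $y$. Each
prey is worth $F$ energy units; its finder consumes the finder's advantage
$a$ exclusively, and the remainder $F-a$ is split among the finder and all
joining scroungers in proportion to competitive weight. With
$W = (G-1)\,[\,p(1-x) + \omega(1-p)(1-y)\,]$ the expected summed weight of
joining scroungers, the producing payoffs per time step are

$$I_{P,\mathrm{strong}} = \delta a + \delta (F-a)\frac{1}{1+W}, \qquad
  I_{P,\mathrm{weak}} = a + (F-a)\frac{\omega}{\omega+W}.$$

A scrounger joins every discovery. Discoveries arrive at expected rates
$pGx\delta$ (strong producers) and $(1-p)Gy$ (weak producers), and the focal
scrounger's share of each remainder has denominator
(focal weight + finder weight + $W_{-1}$), where
$W_{-1} = (G-2)\,[\,p(1-x) + \omega(1-p)(1-y)\,]$ is the expected weight of
the *other* joiners:

$$I_{S,\mathrm{strong}} = pGx\,\frac{\delta(F-a)}{2+W_{-1}}
  + (1-p)Gy\,\frac{F-a}{1+\omega+W_{-1}},$$
$$I_{S,\mathrm{weak}} = pGx\,\frac{\delta(F-a)\,\omega}{\omega+1+W_{-1}}
  + (1-p)Gy\,\frac{(F-a)\,\omega}{2\omega+W_{-1}}.$$

Two bookkeeping conventions deserve mention. First, all counts ($pGx$ and so
on) are continuous expected values; the model is an expected-payoff
recursion, not an agent-based simulation, and nothing is ever rounded to
integers. Second, $W_{-1}$ mixes the *population-average* phenotype over
$G-2$ individuals even though one excluded individual (the finder) has a
known phenotype; the payoffs are implemented exactly in the closed form
above, and this mild approximation is inherited by every result.

### Degenerate shares

A weight share $w_f/(w_f + W_{\mathrm{opp}})$ is defined as 1 when both the
focal weight and the opposing weight are zero: an uncontested claimant keeps
everything. This keeps the payoffs continuous at $a = F$ and at profiles
with no scroungers. The convention has one rough edge at exactly
$\omega = 0$: several zero-weight contestants each "monopolize" the same
remainder, so the prey-share accounting double-counts there. Prey-share
conservation (finder share plus joiner shares equals $F-a$) holds whenever
at most one claimant has zero weight; the test suite enumerates exactly
those integer contests, and sweep rows at $\omega = 0$ or $\delta = 0$ are
flagged `degenerate` in the output.

## Short-term process: the tactic equilibrium

At fixed composition $p$, `solve_nash()` finds the Nash profile
$(x^*, y^*)$ by best-reply dynamics: hold $x$ fixed, find the weak frequency
$y$ at which producing and scrounging pay a weak competitor the same, then
best-respond with $x$ given that $y$, and alternate until neither frequency
moves. `best_response()` evaluates the payoff gap $D(q) = I_P - I_S$ on a
101-point uniform grid of the own-phenotype frequency; if $D$ is positive
(negative) everywhere within a $10^{-9}$ energy tolerance the best response
is pure producing (scrounging), and otherwise each bracketed sign change is
refined with Brent's method (`stats::uniroot`) to $10^{-12}$. Should $D$
change sign more than once — the game's structure makes a single crossing
the expected case — the root nearest the previous iterate is taken and a
warning raised.

Numerical choices, all overridable through arguments:

| quantity | default | units | why |
|---|---|---|---|
| payoff-gap grid | 101 points | — | resolves any plausible multi-root structure; refinement does the precision work |
| root refinement | `uniroot`, tol $10^{-12}$ | frequency | payoffs are smooth in $q$ |
| fixed-point tolerance | $10^{-8}$ on $\max(|\Delta x|,|\Delta y|)$ | frequency | alternation cap 500 sweeps guards cycling |
| payoff-equality tolerance | $10^{-9}$ | energy | payoffs are $O(F)$, far above round-off |
| starting point | $x_{\mathrm{init}} = 1$ | frequency | the alternation is started from the all-produce strong profile; a different start is exposed for sensitivity checks |

The specialization index is $\gamma = |x^* - y^*|$: 0 when the phenotypes
behave identically, 1 when each is locked onto the opposite role. The
defining difference $x^* - y^*$ is non-positive under the trade-off
orientation (strong competitors always rely more on scrounging), and the
index is reported as the magnitude so it lives on $[0, 1]$.

Every solve is audited by `verify_no_profitable_deviation()`, a brute-force
oracle that enumerates 101 candidate unilateral deviations per phenotype and
checks none gains more than $10^{-6}$ energy units. A single deviant cannot
move the population profile, so its payoff is linear in its own mixing
probability; the enumeration makes the check explicit rather than relying on
that argument.

### The payoff-identical corner

At $\omega = \delta = 1$ the two phenotypes have identical payoff functions
and the game collapses to the classic equal-competitor game: payoffs depend
on $(x, y)$ only through the mean producer frequency
$m = p x + (1-p) y$. The Nash condition then pins down only $m$, so the
equilibrium set is a whole line segment and the best-reply alternation
parks wherever its starting point sends it. Reporting an arbitrary member
of that set would make the output discontinuous in $\omega$ and $\delta$
and would hide the equal-competitor reduction. `solve_nash()` therefore
applies the standard symmetric-game selection: when the phenotypes are
payoff-identical it returns the symmetric member $x = y = m$ of the
equilibrium set — after re-verifying that profile with the deviation
oracle, so the selection is checked, never assumed.
`single_phenotype_equilibrium()` solves the one-phenotype indifference
directly and provides the independent benchmark the reduction is tested
against.

## Long-term process: phenotype frequencies

Given the tactic equilibrium at time $t$, the mean phenotype payoffs are
$\bar I_{\mathrm{strong}} = x^* I_{P,\mathrm{strong}} +
(1-x^*) I_{S,\mathrm{strong}}$ and likewise for weak with $y^*$. Between
steps, 99% of the group survives and the replaced 1% adopts the phenotype
with the higher mean payoff:

$$p_{t+1} = \begin{cases}
  p_t & \bar I_{\mathrm{strong}} = \bar I_{\mathrm{weak}} \\
  0.99\,p_t + 0.01 & \bar I_{\mathrm{strong}} > \bar I_{\mathrm{weak}} \\
  0.99\,p_t - 0.01 & \bar I_{\mathrm{strong}} < \bar I_{\mathrm{weak}}
\end{cases}$$

Exact payoff equality is unattainable in floating point, so equality means
within $10^{-9}$ energy units. As printed, the rule is asymmetric: up-steps
move $p$ by $0.01(1-p)$ and down-steps by $0.01(1+p)$; both satisfy
$|p_{t+1} - 0.99\,p_t| = 0.01$. The down-branch can undershoot 0, which is
floored at 0, and the boundaries $p \in \{0, 1\}$ are treated as absorbing:
an extinct phenotype is not re-seeded. The rule itself is silent on
boundaries; flooring and absorption are this package's conventions, chosen
because $p$ is a proportion and replacement cannot resurrect a phenotype
that no longer exists.

`run_evolution()` couples the two processes for up to `t_max = 1000`
replacement updates (the model's standard horizon), warm-starting each Nash
solve from the previous step's $x^*$ — a pure efficiency device; a cold
start reproduces the trajectory to within the solver tolerance, and the
tests check it does. The run stops early and reports `ess_reached` when $p$
moves by at most $10^{-10}$ for 5 consecutive updates. Interior rest points
are typically *approached through* a persistent small oscillation: once the
favoured phenotype flips across the equilibrium, $p$ hops back and forth by
the 1% rule and never satisfies the stillness criterion, so an interior ESS
is usually reported as the final state of the full 1000-step run rather
than through early stopping. Only the fixed-point condition (equal payoffs,
or a boundary with the favoured phenotype fixed) is checked; no separate
invasion-stability analysis is performed.

There is no randomness anywhere in the package: trajectories, sweeps and
their CSVs are bit-identical across runs and platforms.

## What the dynamics predict

Three regimes, all reproduced by the test suite from sweep outputs rather
than asserted as numbers:

* **No trade-off, strong dominate** ($\delta = 1$, $\omega < 1$): strong
  competitors earn strictly more at every composition where weak are
  present; $p$ rises geometrically ($p_t = 1 - (1-p_0)\,0.99^t$) and the
  weak phenotype is effectively eliminated within 1000 steps.
* **No trade-off, weak dominate** ($\omega = 1$, $\delta < 1$): the mirror
  statement holds only where the weak phenotype strictly specializes on
  producing (large finder's advantage, e.g. $a = 8$). At the Table-default
  $a = 2$ the weak equilibrium is interior, and a subtle equality bites:
  with $\omega = 1$ the two phenotypes' scrounging payoffs are the *same
  function*, and interior weak play makes weak indifferent between tactics,
  so both mean payoffs equal the common scrounging payoff exactly and the
  composition freezes. This is the model's own arithmetic at these
  parameter values, not a numerical tolerance effect.
* **Trade-off** ($\omega, \delta$ both interior, $a$ small relative to
  $F$): the phenotypes coexist at an interior $p^*$ with full role
  specialization, $x^* = 0$, $y^* = 1$, $\gamma = 1$. The equilibrium
  share of strong competitors is larger where scrounging pays: small
  finder's advantage, larger groups.

## Sweeps and problem sizes

`run_sweep()` evaluates one parameter grid in `short_term` mode (a single
tactic equilibrium at fixed composition — the first-time-step prediction)
or `long_term` mode (a full evolutionary run per grid value). Default-style
grids follow the parameter ranges of the model description ($p$ in 0.05
steps; $\omega, \delta$ in 0.05 steps on $[0,1]$; $a$ on $[0, F]$;
$G \in \{5, 10, 20, 50\}$), and are fully configurable. The test suite
exercises composition and detection sweeps at full grid resolution, the
oracle audit on a $21 \times 21$ $(\omega, \delta)$ grid, and long-term
sweeps over $a \in \{0, 2, 4, 6\}$ at $G = 10$ and $G = 50$ with the full
1000-step horizon — small enough to run in well under a minute each, large
enough that every qualitative contrast is between computed rows, not
extrapolations.

## Limitations

The model is deterministic and mean-field: no finite-population drift, no
learning, no more than two phenotypes, and no within-bout stochasticity.
Payoffs use the population profile even for the focal deviant (exact in the
infinite-population reading of the expected-payoff equations, approximate
for literal small groups), and $W_{-1}$ ignores the finder's known
phenotype as described above. None of the trajectories say anything about
real foraging groups beyond what the payoff structure encodes; the tests
demonstrate internal consistency (oracle agreement, conservation,
reductions, monotone response patterns), not empirical adequacy.
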