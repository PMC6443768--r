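---
title: "Direct reciprocity and predictive updating on networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct reciprocity and predictive updating on networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netrecip)
```

## The model

A population of $N$ agents occupies the nodes of a static, connected,
undirected network.  Play proceeds in discrete rounds.  Each agent is
either a reciprocal cooperator (C) or an unconditional defector (D).  In a
played pairwise interaction the prisoner's dilemma applies: cooperation
delivers a benefit $b = r$ to the opponent at cost $c = 1$, so mutual
cooperation pays $r - 1$ to each side, an exploited cooperator loses $1$
while the defector collects $r$, and mutual defection pays nothing.  The
return $r = b/c$ is the single game parameter.

Cooperators have a third option, *abstention* (A): a temporary, targeted
refusal to play a specific neighbor.  Abstention is costless and payoff-less
for both sides, and a participating opponent can see it (the opponent showed
up; the abstainer did not), while the abstainer learns nothing.  Abstention
implements direct reciprocity: after being exploited by a neighbor, a
cooperator abstains from that neighbor and polls her again later, looking
for a change of mood.

### Engagement states

The per-edge, per-direction *abstention counter* $t_{ij}$ summarizes the
history of the $(i,j)$ relationship as seen by $i$.  Engagement is
$p_t = 1 - (1-\delta_d)^t$ for $t \ge 1$ and $p_0 = 1$: the probability
that the exploiter has revised strategy at least once in $t$ rounds, judged
at the *reciprocity-biased* update rate $\delta_d = (1 - d)\,\delta$.
Here $\delta \in (0,1)$ is the true per-round revision probability and
$d \in (d_{\min}, 1)$, $d_{\min} = -(1/\delta - 1)$, tunes the strength of
reciprocity: $d = 0$ is unbiased ("normal") reciprocity, $d > 0$ lengthens
abstention periods, $d < 0$ shortens them, and the two endpoints (no
reciprocity, $\delta_d = 1$; broken links, $\delta_d = 0$) are excluded.
An interaction is played iff both directions participate; at most one
direction of an edge is ever inhibited, and defectors always play.

The number $a$ of consecutive abstentions before re-engagement has law
$\Pr(a=0) = \delta_d$ and
$\Pr(a) = (1-\delta_d)^{a(a+1)/2}\,(1 - (1-\delta_d)^{a+1})$ for $a > 0$
(`abstention_pmf()`).  Its mean has no closed form;
`mean_abstention_length()` sums the series until the residual tail mass
drops below $10^{-12}$ (about $\sqrt{2\log(10^{12})/\delta_d}$ terms, e.g.
26 terms at $\delta_d = 0.1$).  The map $\delta_d \leftrightarrow
\langle a \rangle$ is strictly monotone, so either quantity can
parameterize reciprocity (`delta_d_from_mean()` inverts it numerically
with `uniroot` at tolerance $10^{-12}$).

### Predictive strategy update

After each round every agent independently revises with probability
$\delta$.  A reviser compares the incomes she expects to cumulate over the
next $h$ rounds under her current strategy and under the alternative,
freezing neighbors' strategies at their perceived values — with slow
updating ($\delta h \le 0.3$; the package warns beyond that) neighbor
revisions within the horizon are rare.  No discounting is applied over such
short horizons.

Perception uses only the counter pair of each edge.  A revising cooperator
treats a neighbor she abstains from ($t_{ij} > 0$) as a defector — possibly
wrongly, so cooperators can only *under*-count their cooperating neighbors —
and any other neighbor as a cooperator in the state $t_{ji}$ of that
neighbor's counter toward her.  A revising defector has full information:
an abstaining neighbor ($t_{ji} > 0$) is an exploited cooperator, everyone
else a defector.

Two forecast recursions propagate play probabilities over the horizon.
Against a permanent defector, starting from state $t_0$
(`forecast_play_with_defector()`):

$$P^{1} = p_{t_0}, \qquad
  P^{t+1} = P^{t}\,\delta_d + (1 - P^{t})\,\big((1-\delta_d)P^{t} + \delta_d\big),$$

a played round meaning exploitation and reset to $p_1 = \delta_d$, an
abstained round advancing the engagement state.  Against a cooperator
currently at state $t_{ji}$ (`forecast_play_with_cooperator()`):

$$P^{1} = p_{t_{ji}}, \qquad P^{t+1} = P^{t} + (1 - P^{t})\,p_{t_{ji}+t},$$

absorbed at full engagement once cooperation is re-established.  The
defector forecast converges, from any initialization, to the closed-form
limit (`p_cd_limit()`)

$$P_{\mathrm{CD}}^{\infty}
  = \frac{\sqrt{4\delta_d - 3\delta_d^2} - \delta_d}{2\,(1-\delta_d)}
  \approx \sqrt{\delta_d} \quad (\delta_d \text{ small}).$$

The expected gains of switching (`expected_gain_C()`,
`expected_gain_D()`) aggregate the horizon sums of these forecasts over the
perceived neighborhood; both are affine in $r$ for $h \ge 2$ with at least
one perceived cooperating neighbor, decreasing for the cooperator and
increasing for the defector, with positive and negative values respectively
at $r = 1$.  At $h = 1$ the two forecasts coincide at their
initialization, the $r$-terms cancel, and myopic best response always
defects — the multi-step horizon is essential for cooperation.  A reviser
switches only on a *strictly* positive gain; exact ties keep the current
strategy.

### A note on the defector forecast

The defector-side recursion propagates the *mean* play probability through
the abstention branch: conditional on having abstained, the agent's true
engagement state is branch-dependent, and abstention is more likely from
low-engagement states.  The recursion is therefore branch-exact for the
first two forecast steps from any state (and for a third step started at
state 0), but from the third step onward it is a mean-field approximation
to the exact branch-by-branch expectation.  The package's test suite
carries an independent play-tree oracle that enumerates the exact branch
process; it agrees with the gain formulas to $10^{-12}$ on the branch-exact
domain and documents a deviation of order $10^{-4}$–$10^{-2}$ (at
$\delta_d = 0.05$, horizon 3) beyond it.  Relatedly,
$P_{\mathrm{CD}}^{\infty}$ is the fixed point of the mean-field recursion,
not the renewal-theoretic long-run play frequency $1/(1 + \langle a
\rangle)$ of the simulated abstention process (0.2046 vs 0.1796 at
$\delta_d = 0.05$).  All analytic thresholds below follow the recursion and
its fixed point, which is what the agents themselves compute; the
simulation, by contrast, runs the exact counter process.

### Analytic thresholds and the infinite-horizon mode

With an infinite horizon the comparison collapses to a closed form: a
cooperator of degree $k$ perceiving $k_C$ cooperating neighbors remains C
iff

$$r \;>\; 1 + \frac{k}{k_C}\,
  \frac{P_{\mathrm{CD}}^{\infty}}{1 - P_{\mathrm{CD}}^{\infty}},$$

and the defector-to-cooperator switch obeys the same condition
(`remain_C_threshold()`; $k_C = 0$ means unconditional defection).  The
harshest case, $k = k_{\max}$ and $k_C = 1$, gives the infinite-horizon
fixation threshold `fixation_threshold_infinite()`.  `model_params(h =
Inf)` makes the dynamics use this rule directly, which is the natural mode
for experiments about the infinite-horizon predictions (see below).  We
extend the keep-on-tie convention to this mode — a cooperator exactly at
threshold keeps cooperating, a defector exactly at threshold keeps
defecting; ties occur with probability zero except in deliberately
calibrated experiments, where the convention reproduces the closed-form
race probabilities stated below.

For finite $h$ no closed form is printed; `fixation_threshold_bound()`
reconstructs a conservative bound numerically.  Both gains being affine in
$r$, it solves each gain's zero for the worst-case neighborhood — degree
$k_{\max}$, a single perceived cooperator — and maximizes over an
adversarial choice of abstention states: cooperator states in $\{0, 1\}$
and defector states up to the engagement saturation point
$\lceil \log(10^{-6})/\log(1-\delta_d) \rceil$, the states reachable in
finite runs.  The bound is intentionally pessimistic (at $h = 2$,
$k_{\max} = 4$, $\delta_d = 0.05$ it is about 70, driven by the
barely-re-engaged cooperating neighbor at state 1), decreases with $h$,
and approaches the infinite-horizon value; empirical fixation thresholds
from sweeps sit far below it.

## Simulation engine

`run_evolution()` executes the loop in compiled code: per round, one
participation draw per inhibited edge direction, counter updates, a
binomial draw of revisers, gain evaluation from the common post-round
state, and simultaneous application of all switches (cooperator-to-defector
engagement resets are applied before defector-to-cooperator ones, so a
neighbor that just defected is engaged at $p_1$).  The forecast horizon
sums entering the gains are computed once per run, in R, by the same
exported functions the unit tests check, and passed to the core as lookup
tables indexed by abstention state; counters are capped at the state where
engagement is within $10^{-12}$ of 1.  All randomness flows through R's
RNG, so a single `set.seed()` determines a run bit-for-bit; the experiment
runners expand a master seed into named per-replicate seeds so components
can be re-run independently.

Absorption is declared at all-D always, and at all-C once every counter has
relaxed to 0 *and* the remain-C condition holds at the run's horizon for
every node (with all counters at 0 the per-neighbor gain of defecting is
degree-independent, so this is a single scalar test).  Runs in mixed states
continue to the round budget.  `force_continue = TRUE` disables early
stopping, which is how the tests verify that absorbing states actually
absorb.  With the bounded-rationality knobs active (multiplicative Gaussian
noise on gains, random decision flips) no state is absorbing and runs use
their full budget.

## Networks and the synthetic study conditions

The generators produce the structures the model is studied on: `ring4`
(circulant ring, offsets 1 and 2), `square4` and `moore8` (4- and
8-neighbor square lattices), single-scale (Watts–Strogatz with full
rewiring), scale-free (Barabási–Albert), Holme–Kim (preferential attachment
with triad formation, for transitivity robustness checks), the star, and
the complete graph.  Three choices deserve note.

* Planar lattices use periodic boundaries, keeping every degree exactly 4
  or 8; since a periodic square lattice needs a perfect-square $N$, the
  lattice experiments use $N = 1024$ (side 32) as the closest practical
  stand-in for a four-digit population.
* The Watts–Strogatz rewiring is the original one: each node's outgoing
  stubs are kept and only the far endpoint is rewired.  Rewiring both
  endpoints at mean degree 4 strands isolated nodes almost surely and
  virtually never yields the connected single-scale graph intended.
  Connectivity is still checked, and the draw resampled if needed.
* Degree-rank placement breaks ties by ascending node index, making it
  deterministic.

Initial conditions follow the study protocol: 1% randomly placed
cooperators (10 on $N = 1024$ lattices), optionally degree-ranked placement
on heterogeneous networks, connected pairs, or a single seed.  The share of
initial cooperators with no cooperating neighbor is reported because
isolated cooperators defect at their first revision — invasion must come
from their converted neighbors.

What the synthetic conditions do *not* emulate: real populations update
neither synchronously nor with a homogeneous $\delta$, real contact
networks are dynamic, and human decisions are at best approximately
model-predictive.  Passing tests therefore certify the model's internal
laws and their documented consequences, not behavioral predictions for any
particular experiment with human subjects.

## Experiment runners and problem sizes

`sweep_return()` estimates the empirical thresholds from a return grid:
$r_{\mathrm{inv}}$, the smallest grid $r$ whose mean final cooperation
fraction exceeds the initial fraction, and $r_{\mathrm{fix}}$, the smallest
grid $r$ with every replicate absorbed at all-C.  Unabsorbed runs above 20%
cooperation are flagged as slow-fixation candidates.  The package's test
scale — 32×32 lattices, a half-unit grid over $r \in [1,6]$, 20 replicates,
$10^4$ rounds — is chosen to make the horizon and degree orderings of the
thresholds (lower with larger $h$, higher with larger $\langle k \rangle$)
statistically unambiguous while keeping a full sweep under a minute; a
publication-scale replication (1000-node networks, 100 initializations,
eight panels) is a matter of widening those arguments and is provided as
the `sweep` subcommand of the bundled CLI script rather than as a test.

`estimate_invasion_race()` and `estimate_single_seed_fixation()` probe
invasion from a *single* cooperating seed, and are run in the
infinite-horizon mode, whose closed-form race laws they check: at slow
updating the first-mover race gives a neighbor conversion before the seed's
defection with probability about $1 - 1/(k+1)$, and the central seed of a
star of $N$ nodes, at the ring's infinite-horizon threshold, fixates with
probability about $1/2 + 1/(2N)$.  These runs use $\delta = 0.005$ and
2000 replicates, giving binomial standard errors near 0.01.  At finite
horizons compatible with $\delta h \le 0.3$ the leaf-switch thresholds sit
above the calibrated return, so the experiment is only meaningful in the
infinite-horizon limit — one reason `h = Inf` is a first-class mode.  Note
the small-$\delta$ limit is approached slowly: the seed's perception of
converted neighbors lags by roughly the mean abstention length
($\approx 1/\sqrt{\delta_d}$ rounds), which biases the star estimate
slightly below the closed form at finite $\delta$.

`imitation_baseline_run()` provides the classical contrast: unconditional
strategies under the pairwise-comparison rule in its strong-selection limit
(copy a uniformly chosen neighbor iff her round payoff is strictly higher).
The deterministic copy-if-better limit is the standard strong-selection
reduction of the Fermi rule; it is implemented in plain vectorized R since
its runs end within a few hundred rounds.  Under it, 1% initial cooperators
on a 4-neighbor lattice go extinct even at returns far above the classical
$r > \langle k \rangle$ rule, while the predictive model fixates at the
same return — the package's central contrast.

## Numerical choices and degenerate inputs

* Series truncation for $\langle a \rangle$ at tail mass $10^{-12}$;
  abstention counters capped where $1 - p_t < 10^{-12}$.
* Gain ties (exactly zero) keep the current strategy; the infinite-horizon
  rule keeps on threshold equality, consistently.
* Revisions within a round are computed from the common post-round state
  and applied simultaneously; C→D engagement resets precede D→C ones.
* A cooperator abstaining in a round learns nothing about her opponent's
  intent: her counter advances regardless, and a cooperator who plays
  against an abstaining opponent keeps her own counter unchanged.
* Lattice preconditions are hard errors (non-square $N$ for planar kinds,
  $N < 5$ for the ring); disconnected generator draws are resampled with
  the seed advanced and a message; degenerate placements (`count_C = 0`,
  `count_C = N`) are valid and produce the corresponding monomorphic runs.
* `d` at either admissible endpoint is rejected, not clamped.

## Known limitations

* The defector-side forecast recursion is mean-field beyond its second
  step (see above); this is a property of the agents' prediction rule, not
  of the simulation.
* The finite-horizon fixation bound depends on the chosen adversarial
  state set; other reachability conventions give different (still
  conservative) bounds.
* The single-seed closed forms are small-$\delta$ asymptotics; at
  $\delta = 0.005$ the star probability carries a visible perception-lag
  bias of about one standard error.
* Imitation baseline: only the strong-selection deterministic limit is
  implemented; finite-intensity Fermi updating is out of scope.
* Payoffs are per-round; no cross-round accumulation or discounting is
  modeled anywhere.
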