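---
title: "Objective functions, enzyme-constrained FBA and replicative ageing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Objective functions, enzyme-constrained FBA and replicative ageing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agefba)
```

# The question

Flux balance analysis (FBA) predicts steady-state reaction fluxes in a
metabolic network by optimising an objective over the mass-balance
polytope.  The objective is a modelling choice, usually defended by
evolutionary hand-waving.  `agefba` connects that choice to a measurable
evolutionary quantity: the replicative lifespan (RLS) of a budding-yeast
mother cell — how many daughters she produces before dying — and the time
between consecutive divisions (the generation time).  The package couples
an enzyme-constrained FBA model to a damage-accumulation ODE with discrete,
asymmetric divisions, and lets the user swap objectives, flexibilities and
the parsimonious post-optimisation in and out to see how these ageing
observables respond.

# The metabolic core

The LP has variables $(\mathbf v, \mathbf e, e_\mathrm{pool})$: fluxes in
mmol gDW$^{-1}$ h$^{-1}$, enzyme usages in mmol gDW$^{-1}$, and the total
enzyme mass in g gDW$^{-1}$.  Constraints:

* mass balance $S\mathbf v = 0$ and flux bounds
  $\mathbf v_{\min} \le \mathbf v \le \mathbf v_{\max}$;
* per enzyme $i$, usage tied to its catalysed reactions through turnover
  numbers and subunit stoichiometries,
  $e_i = \sum_j (n_{ij}/k_{\mathrm{cat},ij})\, v_j$, with usage bounds
  $\mathbf e_{\min} \le \mathbf e \le \mathbf e_{\max}$;
* the mass coupling $e_\mathrm{pool} = \sum_i \mathrm{MW}_i\, e_i$ and the
  pool cap $0 \le e_\mathrm{pool} \le \sigma f P_\mathrm{tot}$, the product
  of average saturation, covered proteome fraction and total protein
  content.

Models are stored and solved in irreversible form.  Reversible reactions
are split at load time into forward/backward columns with the parent id
recorded, so that "reactions producing metabolite X" is a fixed set of
columns with nonnegative fluxes; the flux analytics merge the pairs back
(`collapse_fluxes()`) before comparing solutions.

Production-sum objectives (total ATP or NADH production) weight each
producing reaction by its stoichiometric coefficient, making the objective
a true production rate that is invariant to rescaling a reaction's
equation.  An unweighted variant (`weighted = FALSE`) is available for
sensitivity checks.

# Lexicographic optimisation, flexibilities and parsimony

A strategy is an ordered pair of objectives with flexibilities
$\epsilon_1, \epsilon_2 \in [0, 1]$ and a parsimony flag.  Stage 1 solves
the LP for the first objective; its optimum $z_1$ is locked into the
problem as $c^\top v \ge z_1(1-\epsilon_1)$ after a maximisation (or
$\le z_1(1+\epsilon_1)$ after a minimisation); stage 2, when present,
optimises the second objective over the locked polytope.  With the
parsimony flag set, a final stage minimises
$\sum_j v_j + \sum_i e_i$ — the L1 norm of fluxes and usages in
irreversible form — after locking the last objective at solver precision
($10^{-9}$ relative), so the parsimonious solution is the flux- and
enzyme-cheapest point among the (near-)optimal ones.  Flux and enzyme
terms carry equal unit weights; weighting usages by molecular weight is
available as a sensitivity option.

Inside the lifespan loop one more re-optimisation follows the regulation
step (below), because regulation tightens enzyme bounds and would
otherwise render the locked problem infeasible.  In that re-solve the
stage-2 lock is relaxed from solver precision to $\epsilon_2$.  For
single-objective strategies there is no stage-2 value to relax, so the
package composes the two flexibilities multiplicatively: the stage-1 lock
becomes $z_1(1-\epsilon_1)(1-\epsilon_2)$.  This keeps $\epsilon_1$
meaningful for single-objective strategies while still granting the
regulation step its own slack, and reduces to the two-stage convention
whenever a second objective exists.

Degenerate optima are a real concern when comparing "the" non-parsimonious
solution against the parsimonious one: LP solvers are free to return any
vertex of an optimal face.  The package therefore ships its own dense
two-phase simplex (in C++) with a fixed variable ordering, Dantzig pricing
and a switch to Bland's rule after a fixed iteration budget; pivoting is
fully deterministic, so identical inputs give bit-identical solutions and
sweeps are reproducible.  Correctness is checked in the test suite against
exhaustive vertex enumeration on every fixture polytope.

# Regulation layer

The signalling layer is a deliberately simple, pluggable stand-in for the
yeast nutrient- and stress-sensing network.  Optimal fluxes are
discretised into Boolean inputs (`glucose_high`, `respiring`, `ros_high`;
strict `>` comparisons against configurable thresholds), five pathways
(Snf1, PKA, TOR, Yap1, Sln1) are updated synchronously from a rule table,
and active pathways tighten the usage bounds of their target enzymes by a
regulation factor (default 0.04): down-targets get
$e_{\max} = e^*(1-0.04)$, up-targets
$e_{\min} = \max(e^*, b)(1+0.04)$, where $e^*$ is the anchor usage and
$b$ a small bootstrap level ($10^{-5}$ mmol gDW$^{-1}$) without which a
multiplicative induction could never lift a silent gene above zero.
Up-bounds are capped at the feasible ceiling — the whole pool divided by
the enzyme's molecular weight, or the usage at which its reactions
saturate their flux bounds, whichever is smaller.

Two choices matter dynamically.  First, the lifespan loop anchors the
bounds at the *previous* step's final solution, so a persistently active
pathway compounds at 4% per time step — a crude but effective model of a
transcriptional response building up over time.  In the reference cell
this is what makes the Yap1 branch ramp the catalase-like flux from its
bootstrap level up to the ROS production rate within a few simulated
hours.  Second, if the regulated re-optimisation is infeasible despite
the $\epsilon_2$ slack, the step falls back to the unregulated solution
(and the anchor resets), which self-limits the compounding at exactly the
level the network can support.  The default rule table wires glucose to
PKA/TOR (and Snf1 to its absence), ROS to Yap1, and respiratory activity
to Sln1; only the Yap1 (antioxidant induction) and Snf1 (respiratory
derepression) arms carry default transcriptional targets.  The full table
is configuration, so a published Boolean wiring can replace it without
code changes.

# Damage accumulation, division and death

The cell's proteome is split into intact and damaged fractions,
$P + D = 1$.  The right-hand sides are the simplest forms consistent with
the intended biology, each isolated behind its own function so refined
kinetics can be swapped in:

* **formation and repair**: $\dot D = f_m J_\mathrm{ROS} P + f_0 P - r_0 D$,
  $\dot P = -\dot D$, integrated by forward Euler at $dt = 0.01$ h.
  $J_\mathrm{ROS}$ is the *unneutralised* ROS flux: stoichiometry-weighted
  production minus antioxidant consumption, floored at zero — at steady
  state exactly the flux through the spontaneous (enzyme-free,
  protein-damaging) ROS decay.  $f_0 = 10^{-4}$ h$^{-1}$ and
  $r_0 = 5 \times 10^{-4}$ h$^{-1}$ are the reference non-metabolic
  formation and repair rates.
* **feedback on the metabolism**: the pool cap is scaled by the intact
  fraction, $\sigma f P_\mathrm{tot} P$, and the non-growth associated
  maintenance (NGAM) reaction gets the lower bound
  $n_0 + n_\mathrm{slope} D$ — damaged cells pay more to stay alive with
  less working proteome.
* **division**: biomass progress accumulates as $\int v_\mathrm{bio}\,dt$;
  when it reaches the division threshold, the damage mass is split so the
  mother retains fraction `retention` while intact protein splits evenly,
  and the mother's fractions are renormalised:
  $D' = rD / (rD + (1-D)/2)$.  Retention $> 0.5$ is the asymmetric-
  segregation ratchet that ages the mother at every division.  Daughters
  are counted (that is the RLS) but not simulated.
* **death**: the cell is dead when the stage-1 LP with the current
  damage-adjusted bounds is infeasible — the shrunken pool can no longer
  cover the grown maintenance demand.

Forward Euler is the standard choice in dynamic FBA because the state is
re-coupled to an optimisation at every step anyway; the step size is a
config field, and the suite checks that the damage fixed point
$D^* = f_0/(f_0 + r_0)$ (at $J_\mathrm{ROS} = 0$) is preserved exactly and
that the global discretisation error scales linearly in $dt$ (first-order
global, second-order local).

# The synthetic network

No public reference network ships with the enzyme data this model needs,
so the package generates one: a miniature central-carbon network (about 25
reactions, 16 metabolites, 20 enzymes) with the pathway structure the
analytics expect — glucose exchange, a glycolysis chain, a fermentation
branch (pyruvate decarboxylase plus two alcohol-dehydrogenase isoenzymes,
ethanol export), a respiration branch (mitochondrial pyruvate import, a
TCA chain, and oxidative phosphorylation resolved into complex I, complex
III, complex IV and ATP synthase), ROS produced at complex I in
proportion to the electron flux, catalase-like and glutathione-like
antioxidant reactions plus the spontaneous damaging decay, anaplerotic
oxaloacetate synthesis, a reversible NADH shuttle, a biomass reaction
drawing precursors and ATP through a ribosome-like enzyme, and the NGAM
drain.

Three orderings are built in deliberately:

* respiration yields more ATP per glucose (default 12, an *effective*
  yield) than fermentation (default 2);
* respiration is more enzyme-expensive per unit flux (the four
  respiratory complexes carry most of the cost) *and*, because the
  electron-transport chain is resolved into successive complexes, more
  flux-expensive per ATP than fermentation;
* fermentation capacity is finite (the pyruvate-decarboxylase bound),
  while glucose uptake is unbounded and limited only through the
  transporter's share of the enzyme pool.

The first two make the maximal-growth optimum Crabtree-like: the
enzyme-cheap fermentation route saturates first and respiration covers the
remaining ATP demand, producing ROS in proportion to growth.  The third is
what forces a respiratory contribution at all at high growth rates; with
unbounded glucose and no capacity bound the optimum would ferment
exclusively and never produce ROS, and the damage model would have nothing
metabolic to work with.  The flux-cost ordering decides what parsimony
does at relaxed growth: minimising total flux keeps the fermentation/
respiration mix and trims the overflow respiration (hence ROS) rather
than collapsing onto the glucose-efficient but flux- and ROS-heavy purely
respiratory solution.  Seeded randomness perturbs only kcat and molecular
weights within ±20% of the reference table; topology and stoichiometry
are fixed per preset, so pathway-level conclusions are stable across
seeds and a given preset generates byte-identical models.

## Calibration

The free ageing parameters — none of which the network itself pins down —
are calibrated by `calibrate_wildtype()`, a deterministic grid search that
accepts the first candidate whose simulated cell lies in the wildtype
window: 20-30 divisions and a mean generation time of 1.5-2.3 h, under
the reference strategy (parsimonious maximal growth, $\epsilon_1 = 0$,
$\epsilon_2 = 0.05$).  The packaged reference bundle
(`reference_cell()`) fixes:

| parameter | value | role |
|---|---|---|
| `f_m` | 0.022 gDW mmol$^{-1}$ | damage per unit unneutralised ROS flux |
| `retention` | 0.58 | mother's share of damage at division |
| `division_biomass` | 1.05 | biomass units per division (sets the ~1.4 h early generation time) |
| `ngam0`, `ngam_slope` | 1, 85 | maintenance demand and its damage coupling (sets the death point) |
| `f0`, `r0` | $10^{-4}$, $5\times10^{-4}$ h$^{-1}$ | reference non-metabolic rates, not calibrated |

The resulting life history is the intended wildtype phenotype: an early
fermentation-dominated maximal-growth phase (phase I), a slow decline as
the damage ratchet shrinks the pool and inflates maintenance, a
respiration-shifted phase II once growth has dropped 5% below its initial
plateau (plateau = mean growth over the first 5% of the lifetime; both
fractions configurable), lengthening generation times, and death by
infeasibility.  The division count and mean generation time are computed
by the test suite and the acceptance script, not quoted here.

# What the toy network does and does not show

Passing tests on the generated network demonstrate that the *machinery*
behaves as specified and that the qualitative orderings emerge from the
stated structural assumptions: strategies without maximal growth anywhere
do not divide; the parsimonious solution at large $\epsilon_1$ lives at
least as long as the plain one; adding maximal NGAM as a second objective
lengthens generation times by burning pool on respiration and its damage
consequences.  They do not show that a curated yeast genome-scale model
would produce the same flux rearrangements — pathway memberships, kcat
spectra and the Boolean wiring here are miniature stand-ins, and the
regulation rule content in particular is a placeholder for a published
wiring the user can drop in via configuration.

# Numerical choices and limitations

* Feasibility and optimality tolerances are $10^{-9}$; the parsimonious
  lock reuses this as the "solver precision" flexibility.
* The simplex is dense and two-phase; Bland's rule guarantees termination
  on the degenerate polytopes that locked stages routinely create.  Dense
  is the right regime for ~60-variable toy networks, not for genome-scale
  models.
* Lifespan simulations in the test suite use the 0.01 h default step and
  horizons of 40-150 h chosen as roughly twice the corresponding life
  expectancy; the sweep examples use reduced grids.  All are package
  defaults or documented arguments, reproducible from the test code.
* Ties between equally parsimonious optima are resolved by the pinned
  pivot order, not by any biological argument.
* The regulation layer's compounding response has a one-step delay and a
  sawtooth near its feasibility ceiling (ramp, infeasible proposal,
  fallback, re-ramp); both are artefacts of the anchor-and-fallback
  design, acceptable at $dt = 0.01$ h.
* `epsilon2` only matters when a regulation layer is attached; without
  one, no re-optimisation consumes it.
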