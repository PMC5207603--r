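---
title: "The fuzzyflock model: fuzzy-controlled prey under open-ended evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fuzzyflock model: fuzzy-controlled prey under open-ended evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzyflock)
```

## The model in one paragraph

`fuzzyflock` simulates a 2D world in which 100 prey agents try to stay alive
under predation.  Each prey perceives at most three aspects of its
surroundings -- one interacting conspecific (sampled with probability
inversely proportional to distance), the nearest predator, and the closest
point of a square living area -- and converts these crisp observations into
a desired heading change through a linguistic (Mamdani) fuzzy rule base.
The rule base is the agent's chromosome: when a prey dies (energy exhausted
or captured), it is replaced by an offspring whose rule base is the mutated
joint-set crossover of two energy-proportionally selected live parents.
Nothing in the fitness accounting rewards grouping directly; collective
behaviour (swarming, milling, polarized and dynamic motion) can only emerge
because it helps individuals survive.

## The fuzzy inference engine

### Data base

The data base is fixed; evolution touches only the rules.  Eight input
variables describe the three perceivable aspects (distance, relative
bearing and, for moving targets, relative heading), and one output variable
(`action.heading_change`) has five values from `hard left` to
`hard right`:

```{r}
head(fuzzy_database(), 8)
```

Each linguistic value is a triangular fuzzy number $\langle l, m, r\rangle$
with membership

$$\mu(x) = \max\!\left(\min\!\left(\frac{x-l}{m-l},\, \frac{r-x}{r-m}\right),\, 0\right),$$

except the angular values `behind`/`opposite`, which wrap on the circle
with period $c = 360$.  Two numerical conventions matter:

* **Degenerate shoulders.** Values such as $\langle 0, 0, 10\rangle$ and
  $\langle 90, 180, 180\rangle$ have a zero-width side; the $0/0$ side is
  taken as a crisp shoulder with membership 1, which is the evident intent
  of the edge values in the data base.
* **Periodic evaluation.** Taking the non-negative modulus of every
  difference separately can return ratios above 1 for points opposite the
  peak (both wrapped distances then exceed the half-widths).  The engine
  instead unwraps the query point and the triangle into one period frame
  anchored at $l$ and evaluates the plain triangle there, which reproduces
  every hand-derived value and is zero outside the wrapped support.
* **Distance clamping.** Distance universes end at 100 (the prey
  perception distance); inputs are clamped to $[0, 100]$ so the `far`
  shoulder stays flat at its peak.

### Inference

Crisp inputs are singleton fuzzy values.  Conjunction and implication use
the *product* t-norm, so a rule's activation is the product of its
antecedent membership degrees, and an activated consequent is the
consequent triangle rescaled by the activation.  Any rule naming an
unperceived (null) aspect does not fire.  Aggregation uses the
*probabilistic sum* $x \diamond y = x + y - xy$, evaluated pointwise as

$$S(x) = 1 - \prod_i \bigl(1 - a_i T_i(x)\bigr),$$

and the crisp output is the centre of gravity $\int x\,S(x)\,dx / \int
S(x)\,dx$.

```{r}
rb <- rule_base(list(
  fuzzy_rule(c(predator.relative_bearing = "left"), "right"),
  fuzzy_rule(c(predator.relative_bearing = "behind"), "none")
))
infer_heading_change(rb, perception_input(predator = c(50, -126, 0)))
```

Numerical choices: the defuzzification grid is uniform over
$[-180, 180]$ at 0.25 degrees (1441 points, trapezoidal quadrature).  This
reproduces the two-rule example above to well below 0.01 degrees while
keeping a single inference under a microsecond-scale budget inside the
simulator; the resolution is configurable (`world_config(resolution =)`),
and the test suite cross-checks against a 10-times-finer independent
quadrature.  When no rule fires the output set is identically zero and the
defuzzified output is defined as 0 -- the neutral "no turn" action.  A
single firing rule short-circuits to the consequent's precomputed centroid,
since the product-implication rescaling cancels in the centre of gravity.

### Angular conventions

Headings are degrees in $(-180, 180]$ with positive heading changes
turning **right**; a target's relative bearing is negative on the agent's
left (a predator rearward-left sits at bearing $-126$).  Relative heading
is the wrapped signed difference `other - own`.  Under a mirror reflection
of the scene these three quantities negate, so mirroring every agent and
swapping `left`/`right` in every rule base mirrors trajectories exactly;
this antisymmetry is enforced by tests at the level of bearings, single
inferences, rule-base bias and whole simulated trajectories.

## The world

Update steps are synchronous.  In one step: (1) every agent perceives the
*pre-step* world and computes its heading change; (2) headings are updated
by the full defuzzified change (no turn-rate cap -- outputs are already
bounded) and positions advance at constant speed (prey 2, single-target
predators 3, high-density-area predators 1.5); (3) every prey gains the
foraging reward (+1) and pays the collision penalty (-10, when its centre
lies within the sum of body radii of another prey, once per step) and the
wandering penalty (-10 for any step spent outside the 375-side living
square); (4) predators capture (single-target tactics remove their pursued
target within catch range and immediately reselect; high-density-area
predators remove every prey within their catch radius); (5) dead prey are
replaced in the same step, keeping the population at exactly `n_prey`; (6)
predator hunt timers count down and expired hunters leave, to re-enter
after a uniform random 600--1200 step interval at a random point 400 units
from the centre, heading inward, with a tactic drawn uniformly from the
four tactics at each entry.

Details that the description above leaves open were fixed as follows:

* *Most-central tactic*: the prey closest to the centroid of all prey the
  predator perceives (the classical selfish-herd reading), rather than a
  neighbour-count maximizer, which is already covered by the
  high-density-area tactic.
* *Most-isolated tactic*: the perceived prey whose nearest conspecific is
  farthest.
* *Predator pursuit controller*: the predators' drives are a fixed minimal
  rule base through the same inference engine -- bearing left turns left,
  ahead holds, right turns right, behind turns hard right (the asymmetric
  rear rule breaks the dead-lock of a target dead astern).
* *Ties*: target-selection ties break to the lowest agent index; the
  living-area border point of the exact centre breaks to the $+x$ edge.
* *Numerical floors*: inverse-distance interaction weights use
  $1/\max(d, 10^{-6})$; an agent exactly on its group centroid contributes
  0 to rotation.
* *Spawning*: newborns appear uniformly on the closed spawn disc (radius
  325) with uniform random headings and full initial energy.  The spawn
  radius exceeds the living-area half-side (187.5), so newborns can
  legitimately appear outside the square; this is the printed
  parameterization and is kept as-is.
* *Scheduling*: each predator slot starts off-world with an initial
  uniform random 600--1200 step countdown, so the 16 predators stagger in.

All randomness in a run flows through R's global RNG in a fixed documented
order (perception sampling per prey in index order, then replacement
draws, then predator scheduling), so `set.seed()` makes entire
evolutionary runs bit-reproducible.

## Evolution

The chromosome is the whole variable-length rule base (1 to 50 rules, 1 to
4 distinct-variable antecedents per rule).  Initial behaviour is random:
rule-base length uniform on 1..50, antecedent count uniform on 1..4,
variables without replacement, values and consequents uniform.  Fitness is
survivability, read as the parent's energy at the moment of replacement;
parents are drawn energy-proportionally without replacement from the live
population.  Crossover draws a uniform random offspring length and samples
that many rules uniformly *without replacement* from the concatenated
multiset of both parents' rules (a with-replacement variant would be a
one-line change in the operator and was deliberately not exposed, to keep
the operator exactly as specified).  Mutation fires with probability 0.02
per offspring, then either adds 1--3 fresh random rules (truncated at 50)
or removes 1--3 uniformly chosen rules (never below 1), each branch with
probability one half; mutation fires at most once per offspring and the
branches are exclusive, the simplest reading of "either ... or".  Offspring
length is bounded below by 1 because an empty rule base is a non-agent.

## Behaviour metrics

Polarization is the norm of the mean unit-velocity vector,
$p = \lVert \tfrac1n \sum_i \hat v_i\rVert$; rotation is the absolute mean
cross product of unit centroid-offset and unit velocity,
$m = \lvert \tfrac1n \sum_i \hat c_i \times \hat v_i \rvert$.  Groups are
connected components of the graph linking prey strictly closer than the
perception distance; singletons are stragglers, excluded on the local
scale but included in global-scale order parameters.  A group is polar (P)
when $p > 0.65$ and $m < 0.35$, milling (M) when $p < 0.35$ and
$m > 0.65$, swarming (S) when both are small, and in transition (T)
otherwise; boundary values are T because the defining inequalities are
strict.  Time-in-state accounting splits each step's unit weight equally
over the groups present; steps with no groups reduce the denominator.
Confidence intervals are percentile bootstraps of the mean (10,000
resamples by default).

Local density is deliberately a plug-in (`local_density(measure = )`).
The default -- the mean number of conspecifics within the perception
radius -- is simple and fast, but it has a known confound discussed under
*Limitations*.

## Validation protocol

`run_validation()` freezes evolution: each of 20 replicates places the
prey at random on the spawn disc with random headings, assigns rule bases
from the evolved pool (1:1 when sizes match), records per-step metrics
from step 900, and introduces a single predator at step 1800, running to
step 3600.  Replacements draw uniformly from the pool, since with
evolution off there is no parent selection to define inheritance.  One
predator (not the full 16-predator complement) is used because the
protocol studies the response of a stabilised group to *a* predator; the
complement is configurable.  The predator's tactic is drawn once per
replicate.  The behaviour class of a pool is the argmax of the
predator-free state-time proportions, with a dominant T reported as
dynamic (D).  `group_size_experiment()` repeats the predator-free window
for 30/70/150/300 agents drawn from the pool, yielding the joint
polarization--rotation density.

## What the scripted scenes do and do not show

`make_parallel()`, `make_mill()` and `make_swarm()` are geometric
fixtures: they pin down the order parameters and the classifier exactly (a
lane has $p = 1$, an evenly spaced tangential ring has $m = 1$ and $p = 0$
by symmetric cancellation, a large uniform blob has both parameters of
order $1/\sqrt n$).  `make_pursuit_scene()` reconstructs the worked
single-prey/single-predator configuration with the two-rule escape base;
the reconstruction is validated numerically (membership 0.6, output
54.375), not textually, because only those two values pin it down.  None
of these scenes emulate evolved behaviour statistically -- passing them
shows the measurement pipeline is correct, not that the model reproduces
any particular animal data.

## Problem sizes used by the tests

Full-scale evolutionary runs are 100 prey over $10^7$ steps, twenty
independent evolutions -- that is a cluster-scale experiment.  The test
suite instead exercises the same machinery at sizes a desk machine
handles: property suites on hundreds of random instances, conservation
and ledger checks over $10^3$-step worlds, and an evolutionary contrast of
5 seeds times $5\times10^4$ steps per arm (with and without predators)
under the standard configuration.  These sizes were chosen as the smallest
at which replacement, capture and selection are all exercised thousands of
times per run.

## Limitations

* **Local density conflates confinement with aggregation.**  With the
  neighbour-count-within-perception measure, merely surviving inside the
  375-square raises density relative to the step-0 spawn disc (the square
  is smaller than the disc), so predator-free control runs also show
  rising counts at reduced scale even though they evolve no coordinated
  grouping.  A density measure on a much smaller radius, or one
  normalised by the occupied area, would separate the two effects; the
  plug-in hook exists for exactly this reason, but the default is kept as
  the simple perception-radius count.
* **Reduced-scale evolution is qualitative.**  $5\times10^4$ steps sample
  the very beginning of the evolutionary trajectory; evolved pools at this
  scale are dominated by living-area survival, and the refined collective
  states need far longer runs.
* **The predator controller is minimal.**  Pursuit uses the four-rule
  bearing controller described above; richer preset predator behaviour
  (interception, persistence) is out of scope.
* **Perception is idealised**: no occlusion, no blind angle, no noise,
  metric-only gating.
* **The world is flat and bounded** by penalties rather than walls;
  agents can physically leave the square and pay for it.
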