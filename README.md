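# fuzzyflock

Why did collective motion evolve?  `fuzzyflock` is an artificial-life
laboratory for that question: prey agents whose movement drives are
human-readable fuzzy if-then rules evolve, under predation, in an
open-ended world where nothing rewards grouping directly.  The package is
aimed at researchers in computational ethology and collective-behaviour
modelling who want an inspectable (linguistic) alternative to
neuro-evolution, plus the standard measurement kit for the emergent
states.

## The model

Each of `n` prey perceives at most three aspects of the world, each gated
by a 100-unit perception distance: one interacting conspecific `i`
(sampled with probability proportional to `1/d`), the nearest predator,
and the closest point of a square living area.  The crisp observations
feed a Mamdani fuzzy rule base over a fixed data base of triangular fuzzy
numbers `<l, m, r>`,

    mu(x) = max(min((x - l)/(m - l), (r - x)/(r - m)), 0),

with periodic variants for the `behind`/`opposite` angular values.  Rules
fire with the product t-norm, activated consequents are aggregated with
the probabilistic sum `x + y - xy`, and the centre of gravity of the
aggregate is the agent's heading change for the step.  Prey gain energy
for living (+1 per step) and lose it for collisions (-10) and for leaving
the living area (-10); a prey at zero energy, or one captured by a
predator (four attack tactics: nearest, most isolated, most central,
high-density area), is replaced by an offspring of two
energy-proportionally selected parents via joint-set crossover of their
rule bases and a 2% add/remove rule mutation -- a steady-state,
Pittsburgh-coded genetic fuzzy system.

Collective states of the resulting groups are classified from the
polarization and rotation order parameters

    p = |1/n * sum_i v_i|,    m = |1/n * sum_i c_i x v_i|

(unit velocities `v_i`, unit centroid offsets `c_i`): polar `P`
(`p > 0.65`, `m < 0.35`), milling `M` (`p < 0.35`, `m > 0.65`), swarming
`S` (both low), transition `T` otherwise.

## Worked example

A single prey at the origin with a predator rearward-left at relative
bearing -126 degrees, steered by a two-rule escape base:

```r
library(fuzzyflock)

scene <- make_pursuit_scene(bearing = -126, distance = 50)
print(scene$rule_base)
#> <fuzzy rule base: 2 rules>
#>   IF predator relative bearing IS left THEN heading change IS right
#>   IF predator relative bearing IS behind THEN heading change IS none

tri_membership(-126, -180, -90, 0)   # activation of the first rule
#> [1] 0.6
st <- scene_to_state(scene, world_config(n_prey = 1))
inputs <- build_perception(1, st$state, st$cfg)
infer_heading_change(scene$rule_base, inputs)
#> [1] 54.375
```

The prey turns 54.375 degrees to the right: the `left` antecedent fires at
0.6 and pulls towards `right` (+90), the `behind` antecedent fires at 0.4
and pulls towards `none` (0), and the centre of gravity of their
probabilistic sum lands between them.

A reduced-scale evolutionary run with the standard world (100 prey, 16
predators), followed by the rule-base summary statistics:

```r
set.seed(42)
evo <- run_evolution(world_config(), steps = 20000, record_every = 2000)
print(evo)
#> <flock_evolution: 20000 steps, pool of 100 rule bases>
#> rule-base sizes: min 1 / median 20 / max 50
#> counts: captures=3470, collisions=47307, wanders=595519, energy_deaths=4492, births=7962

summarize_pool(evo$pool)
#> <pool_summary: 100 rule bases>
#> medians:
#> rho_living_area    rho_predator        rho_prey     specificity            bias
#>          0.3130          0.3099          0.3744          0.4310          0.5406
#>            size
#>          0.4000
```

`rho_*` are the attention proportions (the average share of rule
antecedents watching the living area, the predator and the conspecific;
they sum to 1), `specificity` is 0 for all-unary and 1 for all-4-antecedent
rules, `bias` is the turning-side preference (0.5 = none), and `size` is
the rule count over the 50-rule cap.  At this short scale the pool is
still close to its random initialisation; full-scale runs are 10^7 steps.
Evolved pools are validated with `run_validation()` (20 replicates,
predator-free window then a single predator) and summarized into
state-time proportions and a behaviour class (`P`/`M`/`S`/`D`).

A command-line front end with verbs `evolve`, `validate`, `rulestats`,
`snapshot` and `scenarios` lives at `inst/cli/fuzzyflock.R`.

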