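---
title: "Simulating feed-forward loops and information flow in a worker interaction network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating feed-forward loops and information flow in a worker interaction network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Social insect colonies coordinate without central control: workers meet,
antennate, share food, and those brief directed contacts carry the
information that regulates task allocation. Time-aggregated interaction
networks from such colonies repeatedly show an over-representation of the
*feed-forward loop* — the transitive triangle in which A signals to B and
C, and B signals to C — the same motif that dominates gene-regulatory
networks. `colonysim` implements an agent-based model for asking *which
kinds of among-individual behavioural variation produce this motif*, and
whether the variation that produces it also makes colony-wide information
flow faster or more efficient.

## The model

A colony of `n_agents` (default 100) point agents lives on a bounded
square nest of `grid_size` x `grid_size` patches (default 50 x 50). Each
agent carries two fixed traits:

* **Activity level** `A_i` (dimensionless, population mean `a_m = 1`).
  On every time step an agent is *active* iff an Exponential(mean 1)
  draw falls below `A_i`, i.e. with probability `1 - exp(-A_i)`. When
  activity varies, levels are i.i.d. Exponential(mean `a_m`) — most
  agents sluggish, a few hyperactive, as observed across ants, stingless
  bees and bumblebees. With `a_m = 1` the *population-average*
  activation probability of a variable population is exactly 1/2
  (`E[1 - e^-A] = a_m / (1 + a_m)`); a uniform population at `A_i = 1`
  is active with probability `1 - e^-1 ≈ 0.63`. We implement the gate
  exactly as stated and document rather than "fix" this asymmetry.
* **Turning index** `T_i` (degrees; population mean `t_m = 60`,
  comparable to ant walking paths). An active agent turns by
  `Normal(0, T_i)` degrees and advances half a patch (one body length)
  per step — a correlated random walk. High `T_i` means sinuous paths
  and strong spatial fidelity; low `T_i` means nearly ballistic paths
  that traverse the whole nest.

Five **behavioural conditions** control the trait joint distribution:
`uniform` (both traits fixed at their means — the spatially explicit
null), `activity_variable`, `ti_variable`, `uncorrelated` (both vary,
independently) and `correlated` (both vary, paired by perfectly opposite
rank: the most active agent walks the straightest path — a behavioural
syndrome).

After all agents have moved (in fresh random order), agents are visited
again in fresh random order for the **interaction phase**: an eligible
initiator picks one uniformly random partner within 0.5 patches (one
body length) and a directed event `(t, signaller, receiver)` is logged.
Under the default rules only currently active agents initiate and the
initiator signals outward; the `initiation_rule`/`direction_rule`
variants decouple activity from initiation (a fair 0.5 coin) and from
direction (a fair coin, or signalling with probability
`A_i / (A_i + A_j)`), and a `to_active` variant reverses the default
edge. The interaction log is the simulator's sole output and the sole
input to every analysis stage.

## From logs to networks and motifs

`aggregate_interactions()` counts events per ordered pair over a window
anchored at `t = 0`; `binarize_network()` applies the majority rule per
dyad (one-direction-only or strict majority gives an asymmetric edge;
equal nonzero counts give a mutual edge; a dyad with no events is
absent). `grow_to_density()` widens the window one step at a time until
the binary network holds a target number of edges — by default a mutual
dyad counts as *one* edge ("dyads" counting; "arcs" counting is a flag,
since either reading of an "edge" is defensible and the choice is
isolated). The experiment designs use one network per run, at targets
150–1500 (in steps of 150) for the density sweep and 1000 edges
elsewhere.

`triangle_census()` classifies every complete triangle (all three dyads
connected) into the seven directed classes 030T, 030C, 120D, 120U,
120C, 210, 300 (labels follow `igraph::triad_census()`, which the test
suite uses as an independent oracle alongside a brute-force isomorphism
enumeration). `triangle_transitivity()` computes
`t_tri = 4 * (p_t - 0.75)` where `p_t` is the proportion of triangles
that are transitive; 0 is the random-orientation expectation, 1 means
all transitive, −3 all cyclic.

**Mutual dyads in `t_tri`.** Two conventions exist: drop every triangle
containing a mutual dyad, or resolve each mutual dyad in both directions
at weight 1/2 so the seven classes contribute their orientation
fractions (030T 1, 030C 0, 120D/120U 1, 120C 1/2, 210 and 300 3/4). The
uniform condition produces many tied dyads (roughly a third of dyads at
1000 edges), so the two conventions diverge strongly for
activity-structured networks (≈ 0.55 weighted vs ≈ 0.82 exclusion for
activity-variable runs). Only the weighted form reproduces the
magnitudes this model is known for, so it is the default
(`mutual = "weighted"`), with `mutual = "exclude"` retained.

`tsp_profile()` standardizes each class count against a null ensemble —
by default 100 uniform-condition networks at the same edge count from
`make_null_ensemble()` — and scales the Z-vector to unit norm. Classes
with zero null variance and a matching observation get Z = 0; a
discrepant observation against a degenerate null is an error rather than
a silent infinity.

## Information diffusion

`simulate_diffusion()` replays a log in time order: the signaller of the
first event is the seed; a naive receiver of an event from an informed
signaller becomes informed immediately and can relay later in the *same*
step (events are atomic and ordered; inventing an end-of-step quarantine
buffer would add a rule the model description does not contain).
Transmission speed is `T50`, the earliest step with at least
`ceiling(n_agents / 2)` informed; efficiency is the number of
informed-signaller events up to and including `T50` (fewer = more
efficient). Runs that never reach 50% return `NA` and are excluded from
condition means with a warning.

Uniform-activity colonies (conditions `uniform` and `ti_variable`)
interact roughly 25% more often than variable-activity ones, so
`run_diffusion_experiment()` removes a uniformly random 20% of their
events before diffusion, equalizing interaction rates across conditions
without touching their patterning. `static_diffusion()` (synchronous
rounds on the binary network) is exploratory only.

## Numerical and design choices

* **Boundary handling** is the one genuinely consequential open choice.
  Preventing agents from crossing the nest wall can be implemented by
  per-axis clamping (agents slide along the wall), by truncating the
  step at the wall (agents press against it until turning noise frees
  them), or by reflecting the step and mirroring the heading. Sticky
  walls (clamp/truncate) make nearly ballistic walkers accumulate on the
  perimeter — under clamping, straight walkers form co-moving wall
  trains that can contribute nearly half of all events in a
  `ti_variable` run and inflate total contact rates by 20–50%, so the
  population contact rate becomes a function of the turning-index
  distribution. That artefact contradicts the behaviour this model
  family is meant to capture (straight walkers roaming the nest and
  linking regions, with contact rates insensitive to path shape), so
  the default is `boundary_rule = "reflect"`; `"truncate"` and
  `"clamp"` are available for sensitivity analysis.
* **Variable turning transform**: draws are reflected about the mean
  (`T_i = 2 t_m - x`, `x ~ Exp(mean t_m)`, redrawing negatives), giving
  a left-skewed distribution on `[0, 2 t_m]` — most agents sinuous, a
  few straight. The transform is isolated in `assign_turning()` so an
  alternative is a one-line swap.
* **Ties and degenerate cases**: the neighbour radius is inclusive
  (distance ≤ 0.5); equal dyad counts binarize to a mutual edge; a
  network with no triangles has undefined `t_tri` (`NA`, excluded with
  a logged count); an unreachable density target is an explicit error
  naming the achieved count; `thin_interactions()` removes exactly
  `round(fraction * n)` events.
* **Randomness**: one R RNG stream per run, seeded from the run's
  `seed`; experiment orchestrators derive independent per-run seeds
  from one master seed and record them, so any single run is
  re-creatable in isolation and identical seeds give byte-identical
  logs. Analysis stages (thinning, null ensembles) take their own
  seeds, so re-analysis never perturbs a simulation.
* **Statistical summaries**: the experiment designs are balanced, so
  condition effects are estimated by cell means and contrasts against
  the reference cell (`summarize_contrasts()`) and by ordinary
  least-squares fits with treatment coding (`fit_transitivity_model()`
  regresses `t_tri` on condition × standardized density;
  `fit_activity_model()` on condition × initiation × direction).
  Generalized least-squares machinery with heterogeneous variance
  structures and information-criterion model averaging would change
  standard errors, not these point estimates, and is deliberately out
  of scope.

## What the simulations do and do not emulate

The generator reproduces the statistical signatures of worker behaviour
that matter for network structure: heavy-tailed activity, left-skewed
path sinuosity, an optional negative syndrome between them, physical
contact within one body length, and activity-gated directed signalling.
It does not emulate pheromone fields, task semantics, walls or chambers
inside the nest, births/deaths, or any drift of traits over time
(traits are frozen per run). Passing tests therefore show that the
*mechanisms* — not any particular species — generate or destroy
feed-forward loops and speed or slow diffusion; parameterizing the model
to a real colony is a separate exercise, for which
`make_null_ensemble()` provides spatially explicit, size- and
density-matched null networks.

## Problem sizes

The test suite and the acceptance script run the full pipeline at the
reference scale (100 agents, 5000 steps) with 20–60 runs per condition
cell, which resolves transitivity means to about ±0.02 and log-scale
diffusion quantities to about ±0.04 (one standard error); unit and
property tests use 15–50 agents on smaller nests with matched density.
Trait-distribution checks use 10^5 draws.

## Known limitations

* The activation statement "half the population is active per step" is
  exact only for variable-activity populations; uniform populations at
  `A_i = 1` are active 63% of the time. Both facts are tested.
* `t_tri` is undefined on triangle-free networks; very sparse networks
  (density targets well below 150 edges on 100 agents) produce noisy
  transitivity estimates.
* The boundary rule and the turning transform are model choices, not
  measurements; both are exposed as arguments, and conclusions that
  hinge on wall behaviour should be checked under all three
  `boundary_rule` settings.
* Diffusion is a deterministic susceptible–informed process on the
  logged events; per-contact transmission probabilities below 1,
  forgetting, or multi-seed scenarios are out of scope.
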