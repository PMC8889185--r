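# colonysim

Agent-based simulation and network-motif analysis of worker interactions
in a model insect colony.

Social insect colonies coordinate through brief, directed worker-to-worker
contacts, and the time-aggregated networks those contacts form repeatedly
show an excess of **feed-forward loops** — transitive triangles A→B, A→C,
B→C, the signature motif of biological regulatory networks. `colonysim` is
for researchers in collective behaviour and network science who want to
ask *which kinds of among-individual behavioural variation generate that
motif*, and what the same variation does to the speed and efficiency of
information flow. It provides:

* an **agent-based simulator** (compiled core): activity-gated correlated
  random walks on a bounded 50 × 50 patch nest, with per-agent activity
  levels `A_i` (active on a step iff an Exp(mean 1) draw < `A_i`) and
  turning indices `T_i` (per-step heading change ~ Normal(0, `T_i`°)),
  under five trait conditions — uniform, activity-variable, TI-variable,
  uncorrelated, and a negatively rank-correlated behavioural syndrome —
  and four interaction initiation/direction rule variants;
* **network construction**: weighted time-aggregated networks from the
  event log, majority-rule binarization (ties → mutual edges), and
  windows grown to a target edge count;
* **motif statistics**: the census of the seven complete-triangle classes
  (030T … 300), triangle transitivity
  `t_tri = 4 (p_t − 3/4) ∈ [−3, 1]` with orientation-weighted handling
  of mutual dyads, and triad significance profiles (unit-norm Z-score
  vectors) against a spatially explicit uniform-condition null ensemble;
* **temporal diffusion**: susceptible–informed spread replayed over the
  time-ordered log, measuring `T50` (first step with ≥ 50% informed) and
  transmission efficiency (informed-signaller events until `T50`), with
  the 20%-thinning control that equalizes interaction rates across
  conditions.

Everything is tibble-in/tibble-out with `tidy()`/`glance()` methods and
`autoplot()` diagnostics; no external data is required.

## A worked example

```r
library(colonysim)

cfg <- sim_config(condition = "activity_variable", seed = 11)
log <- run_simulation(cfg)
cfg
#> <sim_config>
#>   100 agents, 5000 steps, 50 x 50 nest
#>   condition: activity_variable (a_m = 1, t_m = 60)
#>   initiation: by_activity, direction: active_outgoing, seed: 11
nrow(log)
#> [1] 8130

net <- grow_to_density(log, n_edges = 1000)   # first 2676 steps of the log
triangle_census(net)
#> 030T 030C 120D 120U 120C  210  300
#>  732   41  190  459  254  360   53
triangle_transitivity(net)
#> # A tibble: 1 × 4
#>   n_transitive n_cyclic   p_t t_tri
#>          <dbl>    <dbl> <dbl> <dbl>
#> 1        1818.     271. 0.870 0.481

glance(simulate_diffusion(log))
#> # A tibble: 1 × 6
#>   seed_agent n_agents threshold   t50 efficiency n_informed_final
#>        <int>    <int>     <dbl> <int>      <int>            <int>
#> 1         38      100        50   756        332              100
```

Reading the output: with heavy-tailed activity and activity-directed
signalling, 732 of the 773 fully unidirectional triangles are transitive
(feed-forward loops) versus 41 cyclic; the orientation-weighted
proportion `p_t = 0.87` sits far above the chance value 0.75, giving
`t_tri = 0.48` for this run (a uniform colony gives `t_tri ≈ 0`).
Information seeded at the first initiator reaches half the colony at step
756 after 332 outgoing interactions from informed workers.

Condition-level experiments wrap this pipeline:

```r
runs <- run_transitivity_experiment(runs_per_condition = 100, seed = 1)
tidy(runs)                       # cell means, sds, contrasts vs uniform
fit_transitivity_model(runs)     # OLS: t_tri ~ condition * std. density
autoplot(runs)

diff_runs <- run_diffusion_experiment(n_runs = 100, seed = 2)
tidy(diff_runs)                  # ln(T50) and ln(efficiency) contrasts
```

A thin command-line wrapper is installed with the package
(`system.file("cli", "colonysim", package = "colonysim")`) with
subcommands `simulate`, `netbuild`, `motifs`, `diffuse`.

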