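---
title: "Cognitive map learning: model, geometry and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cognitive map learning: model, geometry and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmlearn)
```

## The model

A cognitive map learner holds three linear maps: `Q` (`n_s x n_o`) embeds
observations into an `n_s`-dimensional state space, `V` (`n_s x n_a`) embeds
actions into the same space, and `W` (`n_a x n_s`) maps state-space
directions back to action space. For discrete worlds every node or cell
emits a one-hot observation and every action is one-hot, so the embeddings
are simply columns of `Q` and `V`.

Learning is self-supervised next-observation prediction. After executing
action $a_t$ in observation $o_t$ and receiving $o_{t+1}$, the model's
prediction is $\hat s_{t+1} = Q o_t + V a_t$, and the prediction error
$e = Q o_{t+1} - \hat s_{t+1}$ gates two local delta rules:

$$\Delta V = \eta_v \, e \, a_t^\top, \qquad
  \Delta Q = -\eta_q \, e \, o_{t+1}^\top.$$

At the fixed point, $Q o_{t+1} \approx Q o_t + V a_t$: an action's embedding
*is* the displacement it causes in state space. That single constraint,
applied over enough explored transitions, forces a remarkable geometry onto
the map. Because the columns of `V` start as independent Gaussian vectors in
high dimension, they are nearly orthogonal and of nearly equal length, and
both properties largely survive training. Summing the constraint along any
path telescopes: the difference between two observation embeddings
approximates the sum of the action embeddings of any path connecting them,
so (a) action sums around closed walks nearly cancel, and (b) by
Pythagoras over near-orthogonal steps, state-space distance grows like the
*square root* of the shortest-path length.

Planning exploits the same geometry with no further machinery. The utility
of each action for reaching goal observation $o^*$ is its scalar product
with the goal direction $d_t = Q o^* - Q o_t$, i.e. $u_t = V^\top d_t$;
actions on a path toward the goal have large positive utility because they
literally point toward it. Utilities are multiplied element-wise by the
environment's affordance vector $g_t$ (0 for unavailable actions, up to 1
for freely available ones), and a winner-take-all step picks the highest
eligibility. This is an *online* planner: each step costs one matrix-vector
product, and goal changes take effect instantly because the map itself is
goal-independent.

### The W map

Reading the utilities as $V^\top d_t$ requires transporting `V`'s weights.
The package therefore learns a separate map `W` that substitutes
$V^\top$, with two selectable rules (`w_rule` in `cml()`):

* `"transpose"` (default): the row of `W` belonging to the executed action
  tracks the observed state change,
  $\Delta W = \eta_w \, a_t (\Delta s - W^\top a_t)^\top$ with
  $\Delta s = Q o_{t+1} - Q o_t$. Its presynaptic input is the one-hot
  action, so the LMS stability condition $\eta \|x\|^2 < 2$ holds for any
  state scale, and the rule converges exactly to the role of $V^\top$ (the
  row becomes the mean observed displacement of that action). On the
  32-node benchmark its utilities agree with $V^\top d$ in argmax on 100%
  of node pairs.
* `"regression"`: $\Delta W = \eta_w (a_t - W \Delta s)\Delta s^\top$,
  regressing the executed action on the observed state change. This variant
  is kept for completeness but is not the default for two measured reasons.
  First, early in training $\|\Delta s\|^2 \approx 2 n_s$ (observation
  embeddings start as independent Gaussians), so at the default rates the
  stability bound is violated and `W` diverges. Second, even trained after
  `Q` and `V` have converged, its fixed point
  $E[a \Delta s^\top] E[\Delta s \Delta s^\top]^{-1}$ whitens the utility
  profile — all actions get equal gain, the two traversal directions of an
  edge (whose inputs are exact negatives) are merged into a symmetric
  compromise, and planned paths degrade measurably (length ratio ~1.17
  versus ~1.02 for the transpose rule on the benchmark).

### Action selection and affordances

`select_action()` excludes zero-affordance actions from the argmax rather
than letting them compete with eligibility 0. The distinction matters only
when every afforded action has negative utility: the product rule would
then select an action that cannot be executed. Ties are broken toward the
lowest action index, a documented arbitrary convention that makes the
winner-take-all step fully deterministic.

Edge costs enter through the affordances: a weighted graph assigns each
action the affordance `1/cost`, which biases selection toward cheap edges
while leaving the learned map untouched — costs can be changed on the fly
without relearning. During weighted planning the same action may not be
selected twice within an episode (`forbid_repeat_action`), which prevents
cheap-edge loops; the ban is scoped per episode.

## Environments and the synthetic study conditions

All data are generated in-package; the generators define the study
conditions rather than serving as mere test fixtures.

* **Random graphs** (`generate_random_graph()`): a random attachment
  spanning tree plus random edge additions until every node reaches the
  minimum degree, rejecting additions past the maximum; the construction
  guarantees connectivity and degree bounds (default 2–5 on 32 nodes, the
  benchmark condition). Across draws the all-pairs mean shortest path is
  3.44–3.50 with draw-to-draw standard deviation ~0.16, which is why
  benchmark quantities are averaged over several seeded replicates (5 in
  the tests, 8 in the acceptance script). Two directed actions per edge.
* **Small-world graphs**: complete clusters joined by single random bridge
  edges, chain topology by default (`"ring"` available); the bridges are
  the planning bottleneck.
* **Dead-end graphs**: a backbone cycle with pendant chains whose tips have
  degree 1; **multi-path graphs**: a lattice with many pairs of
  vertex-disjoint equal-length shortest paths.
* **2D grids** (`generate_grid()`): rectilinear (4 state-invariant actions)
  or hexagonal in axial coordinates (6 actions); the affordance module
  blocks only moves across the outer boundary. The sparse-exploration
  protocol (`sample_grid_exploration()`) holds out a seeded set of edges
  and redraws until every cell is visited and every action tried, so the
  map remains learnable while some transitions are never experienced.
* **Point mass** (`pointmass_env()`): a damped unit mass on the plane,
  observation `(x, y, vx, vy)`, 8 compass-direction force actions each held
  for 5 integration substeps (dt = 0.1, damping 2). The heavy damping makes
  an action's displacement nearly state-independent, which is the regime in
  which a linear next-state model is a good surrogate for legged-locomotion
  control; the full 29-component quadruped observation schema, torque
  remapping, joint-limit affordances, relative-target transform and
  `Q`-reconstruction regularizer are implemented so a physics backend can
  be wired in, but no rigid-body physics is simulated here.

What the generators deliberately do not emulate: observation noise or
aliasing (each node's code is exact), non-stationary environments, and for
the point mass any contact dynamics or orientation state. Passing tests
therefore demonstrate the learning and planning mechanism under clean
discrete codes and smooth point dynamics, not robustness to sensory noise
or to real actuator physics.

## Default parameters

| context | n_s | eta_q | eta_v | eta_w | init (Q; V, W) | replay sweeps |
|---|---|---|---|---|---|---|
| abstract graphs | 1000 | 0.1 | 0.01 | 0.01 | sd 1; 0.1 | 10 |
| 2D grids | 80 | 0.3 | 0.3 | 0.3 | sd 1; 0.1 | 200 |
| point mass | 128 | 0.005 | 0.02 | 0.02 | sd 0.1; 1 | 3 |

Graph exploration uses 200 random walks of 32 steps; grids use 22 walks of
length 3 (the sparse protocol) with 4 held-out edges; the point mass uses
150 babbling episodes of 20 random actions.

Notes on the non-obvious choices:

* **Grid learning rates (0.3).** At rate 0.5 for both `Q` and `V` the
  paired updates have combined per-transition gain 1.0: each transition
  exactly overwrites its own constraint, and over many sweeps the map
  drifts along unconstrained directions (`max |Q|` grows ~30x and planning
  degrades to 89/240 optimal pairs on the 4x4 maze). At 0.3 the updates
  contract, and 200 sweeps of the 66-transition buffer give 240/240
  Dijkstra-optimal pairs across seeds and both geometries. Rates anywhere
  below ~0.4 behave equivalently.
* **Column normalization of `V`** (`normalize_v`) is available and helps at
  small state dimensions, where the implicit normalization of random
  high-dimensional vectors is weak; it is off by default since the shipped
  presets work without it.
* **Step cap**: planning episodes stop at 4x the graph diameter; capped
  episodes count as failures and are excluded from mean lengths but
  reported in the success rate.
* **Learning during planning** is off for all benchmark evaluations
  (training and evaluation are separated); it can be enabled per call.
* **Point-mass rates** were chosen once for the continuous init scheme
  (small `sigma_q`, unit `sigma_v`): prediction error falls within 3
  sweeps and goal reaching succeeds across seeds; the reconstruction
  regularizer runs at 0.001 to keep position components represented in the
  state code.

## Numerical conventions

Degenerate inputs are rejected rather than silently repaired: infeasible
degree bounds, non-positive costs, empty replay buffers, rate-0 training
requests, non-closed cycle walks, and joint limits with `low >= high` all
raise errors. A held-out edge set that isolates part of an environment
triggers a learnability warning from the exploration sampler. No diagnostic
uses exact float equality; closure and orthogonality statements are made
with relative tolerances, and the distance-scaling diagnostic reports both
the pair-level correlation with $\sqrt{d}$ and the correlation of per-bin
mean distances (the square-root law is a statement about bin means; the
pair-level value is additionally diluted by within-bin spread).

Dijkstra (`dijkstra()`) is implemented directly with deterministic
lowest-node-id tie-breaking so that path identities are reproducible; its
distances are cross-checked against igraph's implementation in the test
suite. The evaluation harness samples ordered start-goal pairs uniformly
with start distinct from goal, seeded.

## Problem sizes

The shipped presets are desk-scale: 32-node graphs with ~43 edges and
`n_s = 1000` train in seconds (the replay sweep is implemented in C++);
grid and point-mass presets are smaller still. Benchmark statistics use
1000 evaluation pairs per graph and 5-8 graph replicates per reported
quantity, which brings the replicate-mean standard error below 0.1 actions.

## Known limitations

* The weighted-graph planner is greedy in the costs: reciprocal-cost
  affordances bias each single step, so it can take a cheap edge pointing
  slightly off-goal and pay for it later. Across graph draws the achieved
  cost exceeds the Dijkstra optimum by 4–16% (about 8% on average), and
  the repeat-action ban occasionally forces long detours once several
  actions are spent. This is a property of the method, not of training:
  the ratio is unchanged when training is extended fourfold.
* On general graphs nothing can be inferred about untried state-action
  pairs; generalization to unexplored transitions appears only in
  environments with state-invariant action structure (grids, point mass).
* The WTA step assumes a single agent and a static goal within a step;
  continuously moving targets are handled by rebuilding the target
  observation each step, as the point-mass controller does.
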