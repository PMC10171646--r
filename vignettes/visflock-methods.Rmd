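---
title: "Vision-based flocking with learned collision avoidance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vision-based flocking with learned collision avoidance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visflock)
```

`visflock` simulates a swarm of rectangular, self-propelled agents — the
default parameterisation describes marching locust nymphs, body 0.07 m by
0.01 m — that perceive their surroundings only through vision, and learns an
individual movement policy from which group-level flocking with collision
avoidance emerges. This vignette documents the model, every tunable that
matters, the numerical choices, and what the package's tests do and do not
establish.

## The agent and its retina

Agents live on a continuous 5 m x 5 m plane with periodic (toroidal)
boundaries. Each agent carries position $l$, velocity $v$, acceleration $a$,
a body rectangle of length $h$ along the heading and width $w$, and a metric
sensing radius $r$ (defaults: $h = 0.07$, $w = 0.01$, $r = 0.21$, all in
metres). Neighbours are the agents whose centres sit strictly within $r$
under the minimal-image convention; sensing works across the periodic seam.

The focal agent does not see coordinates. For each neighbour it measures the
retinal tuple
$$\gamma = (\psi, \dot\psi, \theta, \dot\theta),$$
where $\psi$ is the angle subtended by the neighbour's body rectangle (the
maximum over corner pairs of the angle between the focal-frame corner
vectors), $\theta = \arccos\big(\hat v_o \cdot \widehat{(l_n - l_o)}\big)$
is the unsigned angular position of its centre off the focal heading, and the
dotted quantities are one-step backward differences. Because $\theta$ comes
from an arccos it cannot distinguish left from right; we implement it as
printed and expose a `signed_theta` switch (off by default) for
sensitivity checks. A neighbour whose angular interval is *entirely* covered
by strictly nearer neighbours is invisible and dropped; partial occlusion is
ignored (the full geometric $\psi$ is kept), which matches the
all-or-nothing "fully latent" reading and avoids an area-reduction model the
data would not constrain.

Corner positions are built as
$l_n \pm (h/2)\,\hat v_n \pm (w/2)\,\hat v_n^\perp$ — the only layout that
produces an $h \times w$ rectangle aligned with the velocity. Agents whose
speed is momentarily zero keep their last moving heading for all geometric
purposes. If the focal centre ever lies inside a neighbour's rectangle the
view is fully occupied and $\psi = \pi$ (with a warning outside the bulk
simulation paths).

## States, actions, movement

The observation list is sorted by ascending $\theta$ (ties: distance, then
id), truncated to $k = 8$ neighbours, and each scalar is floored to a bin of
width 0.01 — radians for the angles, radians/step for the derivatives, which
are clipped to $[-\pi, \pi]$ first. Absent slots carry a sentinel bin, so
"alone" is itself a state. The paper's parameter table gives no unit for the
0.01; radians make the angular channels and their rates commensurate.

Actions are the 24 unit headings at multiples of 15 degrees. The movement
update is
$$a \leftarrow x,\qquad v \leftarrow v + \delta a,\qquad l \leftarrow l + v$$
with $\delta = 0.05$. Applied literally, this update lets speed drift without
bound (a 500-step random walk reaches speeds that cross the arena in a few
ticks). By default `visflock` therefore rescales the updated velocity to its
pre-update speed, so an action steers the heading only — consistent with a
heading-valued action space and the self-propelled-particle lineage of the
model. The raw additive update remains available (`speed_renorm = FALSE`);
the random-walk baseline scores reported by `scripts/acceptance.R` are
essentially identical under both (we measured the difference at < 0.01 on
every score). An agent stopped by a collision re-accelerates from rest to
speed $\delta$ on its next action.

Collisions are predicted one step ahead: a pair collides when their
post-move centre distance is at most $\max(h_1 + h_2, w_1 + w_2)/2$
(0.07 m at defaults). The protocol assigns roles by the front-half-plane
rule: an agent is *active* iff its partner lies in front of it; head-tail
contact stops the rammer and adds the rammer's velocity to the rammed
(leader) agent; frontal contact stops both. Mutual rear contact is geometric
ally possible here (agents are points for role purposes); we treat it as
both-active. Simultaneous collisions are resolved in ascending pair order
with velocity contributions taken from the pre-resolution snapshot, which
makes multi-collision ticks deterministic.

Each tick is synchronous: all agents sense the tick-start snapshot, choose
actions (in a random permutation — since perception is synchronous the
permutation only orders random draws), then all move, then collisions are
detected and resolved and the per-tick metrics recorded.

## Metrics and objective

Alignment disorder is
$$F = \frac{1}{2\pi}\,\overline{\Delta^2},$$
the mean squared angular deviation of headings from the population's
circular-mean heading, deviations wrapped to $(-\pi, \pi]$. $F = 0$ for a
perfectly aligned swarm; independent uniform headings give
$\pi^2/3/(2\pi) \approx 0.524$ in the large-population limit. At the default
population size of 30 the *sample* circular mean adapts to chance clusters
and the expected value drops to about 0.42 (Monte-Carlo, and visible in the
random-walk baseline, whose alignment score settles near $1 - 0.42 = 0.58$).
This finite-sample behaviour matters when comparing against published score
levels computed under a different algebraic reading of the alignment
deviation, which the source text leaves ambiguous.

The collision rate $C$ is the number of colliding pairs divided by the
largest possible number of simultaneous collisions,
$\lfloor |P|/2 \rfloor$ disjoint pairs, clipped to $[0,1]$. The combined
objective over a tick window is the time mean of
$\zeta F_t + (1-\zeta) C_t$ with $\zeta = 0.5$ (averaging, rather than
summing, keeps the score's complement in $[0,1]$ regardless of run length).
Scores are complements: `cm_score = 1 - F`, `ca_score = 1 - C`,
`cmca_score = 1 - (zeta F + (1-zeta) C)`, clipped into $[0,1]$.

## Learning: GA-planned Q-updates with KNN-guided sampling

The policy is a sparse tabular map from encoded states to 24 action values
with a uniform default row — observationally identical to initialising the
(astronomically large) full state space uniformly. Action selection is
stochastic, proportional to the row (a greedy mode exists); the update adds
`learning_rate * score` to the chosen entry. The learning rate is not given
in the source parameter table; we default to $\lambda = 0.1$, the usual
tabular magnitude, and store it in the policy archive. There is no
bootstrapped next-state term: the update is exactly additive.

The score comes from a genetic algorithm that plans the focal agent's next
$\eta = 5$ actions in a synthetic local scenario (a patch with $0..k$
neighbours placed uniformly in the sensing disc, velocity components
$\pm U[0, 0.15]$). Genes are length-$\eta$ action sequences; fitness is the
patch objective of a rollout in which the focal agent executes the gene and
neighbours move ballistically (constant velocity; a flag lets them follow
the current policy instead, at much higher cost). Rollouts run on an
unbounded patch, collisions are counted but not resolved, and the objective
averages the $\eta + 1$ snapshots including the initial state. The GA uses
population $\tau = 20$, $g = 10$ generations, single-point crossover with a
uniform cut on $[2, \eta]$, elitism `max(1, floor(0.05 tau)) = 1`, and
fitness-proportionate selection on the complement score. The "mutation mean
and standard deviation" (0.1, 0.05) parameterise a clipped-Gaussian
per-gene mutation *probability*; the mutation itself replaces one uniformly
chosen position with a different uniformly chosen action, which is the only
reading consistent with the stated operator. The planner returns the first
action of the best gene and the complement of its objective as the score.

A one-shot scenario has no past, but its velocities are known; the
derivative channels of the training state are therefore computed against
the scene rewound by one tick ($l - v$). In-world, a neighbour seen for the
first time gets zero derivatives; afterwards real backward differences.

Training alternates with validation: `z_validate` random scenarios are
rolled out for $\eta$ steps with *all* agents following the current policy,
scored by the patch objective's complement. A coarse descriptor — neighbour
count plus the binned $\psi, \theta$ of the nearest visible neighbour —
summarises each scenario; 10,000 uniform probe descriptors get
KNN-estimated performance ($y = 3$, inverse-distance weights, Euclidean
metric on range-normalised coordinates), and the L1-normalised deficiencies
$1 - \widehat{\text{perf}}$ form the sampling distribution for the next
training round, realised by rejection sampling (an exact inverse map from
states to scenarios does not exist). Training stops when the total
variation distance of that distribution from uniform falls to
$\kappa = 0.05$, or after `max_rounds` (default 10) rounds — a termination
guard the stop rule alone does not provide. The full descriptor state space
cannot be enumerated; probing the occupied low-dimensional projection is
the design compromise.

Testing runs full-population simulations (30 agents, 500 ticks) under the
learned policy and reports the mean combined score across replicates.

## Problem sizes and numerical choices

The package's own test and acceptance runs use these sizes, chosen so a
complete check runs on a desk machine:

* Baselines: 30 agents, 500 steps, 30 replicates (the study conditions).
* Reduced-scale learning: 5 rounds of 4 x 10^4 training scenarios
  (2 x 10^5 total) with 10^3 validation scenarios per round — three orders
  of magnitude below the full-scale prescription (10^7 per round), so only
  the *sign* of the learning trend and the trained-vs-random ordering are
  meaningful at this scale, not absolute trained scores.
* GA planning is exact-checked against brute force on a reduced instance
  ($\eta = 2$, 4 actions) where enumeration is feasible.

Numerical details: all angle comparisons clamp arccos arguments into
$[-1, 1]$; wrapped angular deviations map to $(-\pi, \pi]$; occlusion
coverage uses a 10^-12 slack when chaining arcs; ties in greedy selection
break to the lowest action index; ties in the GA ranking are stable. The
random-number stream is a single R stream per run, with independent named
sub-seeds derived from one master seed so that changing the replicate count
of one experiment never perturbs another.

## What the synthetic scenarios do and do not emulate

Training scenarios reproduce the geometry and velocity distribution of the
full-world initial conditions, but they are isolated patches: no boundary
wrap, no collision protocol during rollouts, ballistic neighbours, and no
persistent interaction history beyond the one-tick rewind. Passing the
training tests therefore shows that the planner and the update behave as
specified on the scenario distribution — it does not show that locusts (or
any real swarm) learn this way, nor that the reduced-scale policy matches
full-scale published scores. Equally, the agent-level metrics inherit the
ambiguities discussed above: the alignment score level depends on the
algebraic reading of the heading-variance formula, and the collision score
level depends on the normaliser of the collision count; both package
choices are documented and frozen, and the acceptance script reports what
they produce.

## Known limitations

* Unsigned $\theta$ discards left/right information; the learned policy can
  only respond symmetrically unless `signed_theta` is enabled (a deliberate
  deviation switch, off by default).
* Exact-match tabular lookup generalises poorly at reduced training scale:
  most in-world states with nonzero derivative bins are unseen and fall
  back to the uniform row. The learning signal at 2 x 10^5 samples is
  real but small; absolute trained-score levels require full-scale runs.
* The per-step disjoint-pair collision normaliser makes the collision score
  nearly saturated at the default density (~0.25 colliding pairs per tick
  among 15 possible), so baseline collision scores sit near 0.98 — far
  above some published values whose normalisation could not be
  reconstructed; see the package README for the numbers this code actually
  prints.
* 2D only; no walls or obstacles; homogeneous agents.
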