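---
title: "Cognitive swarming: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cognitive swarming: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogswarm)
```

## The model

`cogswarm` simulates groups of mobile agents whose coordination is
organized the way a hippocampal attractor-map network organizes place
cells. The analogy is: one agent = one place cell; the distance between
two mutually visible agents = the synaptic weight of their reciprocal
connection; relative motion = synaptic modification. A swarm
configuration is then an attractor map, and swarming is online Hebbian
learning.

Each of the $N_s$ neural units $i$ carries a position $x_i$, an
oscillation phase $\theta_i$, and an activation $p_i$. Every simulation
step performs one loop around the following cycle.

**Geometry to weights.** Pairwise visibility $V_{ij} \in \{0, 1\}$
requires line of sight in the polygonal arena and a range cutoff
$D_{\max} R$, where $R$ is the arena's *notional radius* (the radius of
the disk with the arena's allowable area; the scale-free lengths
$D_{\max}, \sigma, \kappa$ are all multiples of $R$). Distances map to a
recurrent weight matrix through a Gaussian kernel,
$W_{ij} = V_{ij} \exp(-D_{ij}^2 / \sigma_{\mathrm{eff}}^2)$, and to
feedforward reward weights through an exponential kernel,
$W^r_{ik} = V^r_{ik} \exp(-D^r_{ik} / \kappa_{\mathrm{eff}})$, whose
slower tail supports long-range reward approach.

**Inputs, activation, phase.** Three leaky integrators track sensory-cue
conjunctions ($\tau_c \dot c = V^c \circ V^{c*} - c$), reward visibility
($\tau_r \dot r = V^r - r$), and pairwise phase synchrony
($\tau_q \dot q_{ij} = V_{ij} \cos(\theta_j - \theta_i) - q_{ij}$). Net
inputs are gain-weighted, visibility-normalized averages with gains
$g_c + g_r + g_s = 1$; activation is the linear rectification
$p = [I_c + I_r + I_q]_+$, which is bounded in $[0, 1]$; and activation
drives the phase, $\dot\theta = 2\pi(\omega_0 + \omega_I p)$, coupling
firing intensity to spike timing the way phaser cells do.

**Learning to motion.** The weights are perturbed once per step by an
Oja-rule update,
$W'_{ij} = W_{ij} + \Delta t\, \eta V_{ij} p_i (q_{ij} - p_i W_{ij})$
(and its reward analogue with $r_{ik}$), whose quadratic activation term
divisively normalizes the weights: synchrony pushes weights up
(attraction), anti-synchrony and the $-p_i^2 W_{ij}$ depression push
them down (a baseline repulsion). The perturbed weights are inverted
back into *desired* distances, the per-unit average of signed
unit-vector demands gives positional offsets, the swarm and reward
offsets are mixed with weight $\alpha$, and a wall-proximity kernel
$\beta = e^{-d/\lambda}$ deflects offsets along the inward wall normal.
The offsets move each unit's internal field location $x_s$; the physical
agent chases $x_s$ through a momentum filter, a tanh speed limit derived
from a kinetic-energy cap $E_{\max}$, a second barrier deflection, and
collision resolution.

**Two modes.** In *multi-agent* mode the $N = N_s$ units are the
physical agents. In *single-entity* mode a single physical agent owns
$N_s$ virtual ("cognitive") particles that carry the entire neural
dynamics among themselves; the agent chases the cubic-activation-weighted
average of the particles it can see, and only visible particles learn
(and, by default, move). Reward capture in this mode is triggered by the
*agent's* contact and silences the reward for all particles.

## Parameters

Defaults (see `?swarm_params` for the full list): $\Delta t = 0.01$ s,
duration 180 s, $N = N_s = 300$, $D_{\max} = \sigma = \kappa = 1.0$
(times the notional radius), $E_{\max} = 3 \times 10^3$ kg pt$^2$/s$^2$,
$\mu = 0.9$, mean multi-agent mass 0.3 kg, single-entity mass 3 kg,
$\eta = \eta_r = 1$, $\omega_0 = 0$, $\omega_I = 1$ cycles/s,
$(g_c, g_r, g_s) = (0.4, 0.2, 0.4)$,
$(\tau_c, \tau_r, \tau_q) = (0.5, 0.5, 0.1)$ s, contact radius
$d_{\mathrm{rad}} = 0$ (capture disabled), $\alpha = 0.5$,
$\lambda = 20$ points.

Parameters that matter most in practice: $\sigma$ sets the interaction
range in units of arena size (larger $\sigma$ keeps distant units
coupled); $\kappa$ sets how far rewards reach; the gain triple trades
off cue-anchored place preference, reward approach, and synchrony-driven
swarming; $d_{\mathrm{rad}} > 0$ makes rewards consumable, which
releases the swarm from reward attractors and is the main lever on
exploration.

## Design choices

Several points are deliberate package decisions where the model
formulation leaves room:

* **Offset sign (`sign_convention`).** The default `"functional"`
  convention moves a unit *toward* a neighbor (or reward) whose desired
  distance is *below* the actual one, so that weight growth under
  synchrony produces attraction and the Oja depression produces
  repulsion; `"as_printed"` negates the coefficient for comparison. The
  functional convention is the one under which the attraction/repulsion
  and reward-approach tests hold.
* **Swarm kernel inversion (`kernel_inverse`).** The default `"exact"`
  uses the strict inverse $D' = \sigma\sqrt{-\log W'}$ of the Gaussian
  kernel. The alternative `"sqrt2"` retains an extra $\sqrt 2$
  ($D' = \sqrt{-2\sigma^2 \log W'}$). Because the weights are rebuilt
  from geometry every step and perturbed only once, the $\sqrt 2$ form
  inflates every desired distance by $\approx 41\%$ regardless of
  synchrony, which swamps the learning perturbation and turns even
  fully synchronized pairs repulsive; the exact inverse makes the
  attraction/repulsion boundary exactly $q_{ij} = p_i W_{ij}$, which is
  the behavior the learning rule is built to express. Round-trip
  identities are therefore stated (and tested) under `"exact"`.
* **Cue input normalization.** The net cue input averages the cue
  signals of *currently visible* cues
  ($I_c = g_c \sum_k V^c_{ik} c_{ik} / \sum_k V^c_{ik}$). Summing decayed
  traces of currently invisible cues while normalizing by the visible
  count would let $I_c$ exceed $g_c$ after visibility changes and break
  the $p \in [0,1]$ bound; masking keeps every net input a convex
  average times its gain.
* **Weight clamping.** After learning, weights are clamped to
  $[10^{-6}, 1]$ so the kernel inversions stay finite; the floor encodes
  a saturated "maximal desired distance".
* **Collision handling.** Barrier deflection softens but cannot prevent
  wall crossings at finite $\Delta t$, so a crossing step stops at the
  hit point retracted by $10^{-3}$ points and loses its wall-normal
  velocity component. Internal-field locations are clipped the same way
  so every neural position stays in the allowable interior, where
  line-of-sight and wall queries are meaningful.
* **Zero-visibility convention.** Every visibility-normalized average
  with an empty visible set evaluates to 0, never NaN.
* **Frozen invisible particles.** In single-entity mode, particles out
  of the agent's sight have their learning masked; the
  `freeze_invisible_particles` flag (default on) additionally zeroes
  their positional offsets so they stay put until seen again.
* **Boundary conventions.** Points exactly on a wall are not allowable;
  line-of-sight chords are shrunk inward by $10^{-6}$ points before
  intersection testing so endpoint grazing is resolved deterministically
  (touching a wall or an obstacle vertex counts as blocked).
* **Phase units.** Frequencies are configured in cycles/s and converted
  to radians internally; phases are kept wrapped to $[0, 2\pi)$.

## Numerical scheme

The input integrators and the phase use forward Euler at
$\Delta t = 0.01$ s. Since $\Delta t < \tau$ for every time constant,
each Euler step is a convex combination, which confines $c, r$ to
$[0, 1]$ and $q$ to $[-1, 1]$ without clipping. The update order within
a step is fixed and synchronous: couplings and kernels from the previous
step's positions, then input integration, activation and phase, the Oja
perturbation, inversion, offsets, internal-field motion, agent
kinematics, and finally reward capture. The tanh speed limit keeps
kinetic energy below $E_{\max}$; for astronomically large demanded
speeds tanh rounds to 1 in double precision, so the cap can be attained
to machine precision but never exceeded. Coincident points contribute
zero offset (no NaN unit vectors). Any non-finite state aborts the run
with the offending step index. Given a configuration and a seed, runs
are bitwise reproducible; all randomness (masses, spawn positions,
phases, cue-preference sampling) flows from one seeded generator.

## Synthetic environments

Two parametric generators stand in for environment files:

* `make_multireward_arena()` — a 700 x 500-point rectangle whose outer
  wall carries partial-wall protrusions that fragment it into a large
  central region plus northwest, southwest, and southeast corner
  compartments, one reward in each; 7 cues at seeded random interior
  locations; spawn disks in the southwest corner (first, so the
  single-entity agent starts there), the center, and the northeast.
* `make_hairpin_maze()` — an 885 x 519-point rectangle partitioned into
  5 hallways by 4 dividers with alternating top/bottom gaps (one
  connected hairpin corridor); rewards centered in hallways 1, 3, and 5;
  4 spawn disks spread over the hallways; 7 seeded cues.

The generators emulate the *topology* of the environments the model was
designed for — compartments, occlusion, corridors — not any particular
coordinates: cue positions are random (seeded), wall proportions are
package choices, and real vector-drawn environments would differ in
detail. Consequently, tests that pass in these arenas demonstrate the
controller's qualitative behaviors (synchrony-driven attraction, reward
rings, capture-released exploration) rather than quantitative agreement
with any specific environment; absolute capture counts and times depend
strongly on doorway geometry and are expected to vary.

## Test and verification scale

The test suite exercises full runs at reduced scale, a package choice
that keeps the suite fast while preserving the phenomena: bound
invariants over 20 seeded 30-s runs with 50 agents in both generated
arenas; the contact-radius sweep with $d_{\mathrm{rad}} \in
\{0, 1, 4, 10, 15\}$ points over 10 common seeds, 100 virtual particles,
and 60-s runs; ring formation over 10 seeded 60-s runs with 100 agents
in a single-reward arena. Vectorized operations are checked against
per-pair loop oracles at $N \le 5$ to $10^{-12}$, and kernel round trips
to $10^{-12}$.

The 60-s horizon is deliberately aggressive for full three-reward
navigation: with the default energy cap the agent's top speed is
$\sqrt{2 E_{\max}/m} \approx 44.7$ points/s, so visiting all three
compartments costs tens of seconds of pure travel. Full-capture success
within 60 s is therefore rare at any contact radius, and the sweep's
value lies in the ordering of success and capture counts across radii,
not their absolute levels.

## Known limitations

* The oscillation is a single noiseless global rhythm; no drift or
  per-agent perturbation is modeled.
* Agents are point particles: they may overlap, and there is no heading
  or torque dynamics, nor actuation noise.
* Connectivity ignores Dale's law, as is usual for parsimonious
  attractor-map formulations.
* Environments are static 2-D polygons; moving walls and 3-D spaces are
  out of scope.
* Formation detection quantifies rings (circular-circular correlation
  between bearing and phase) and reports a collinearity statistic for
  line segments, but "line segment" has no principled threshold and is
  not used for acceptance decisions.
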