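# cogswarm

Cognitive swarming: a simulator for hippocampally inspired swarm control
in which **inter-agent distances are synaptic weights**. Mutually visible
agents are treated as reciprocally connected place cells: the distance
between them maps through a Gaussian kernel to a recurrent weight
`W[i,j] = V[i,j] exp(-D[i,j]^2 / σ²)` (and through an exponential kernel
to feedforward reward weights), an oscillatory Oja-rule learning step

```
W'[i,j] = W[i,j] + Δt η V[i,j] p_i (q[i,j] - p_i W[i,j])
```

perturbs the weights using each agent's activation `p_i = [I_c + I_r +
I_q]_+` and the phase-synchrony input `τ_q q̇[i,j] = V[i,j]
cos(θ_j - θ_i) - q[i,j]`, and the perturbed weights are inverted back
into *desired* distances that drive motion. Synchronized neighbors pull
weights up (attraction); the quadratic Oja depression supplies baseline
repulsion. Activation also drives each agent's phase
(`θ̇ = 2π(ω₀ + ω_I p)`), closing a loop between attractor-map dynamics
and oscillatory phase coding that produces emergent phase-sorted rings,
line formations, and reward-directed navigation.

The package is for computational neuroscientists and swarm-robotics
researchers who want a tested, deterministic implementation of this
controller with:

* polygonal 2-D arenas (walls, occlusion, line-of-sight visibility,
  cues, rewards, spawn disks) plus generators for a fragmented
  **multi-reward arena** and a 5-hallway **hairpin maze**;
* **multi-agent** mode (N physical agents) and **single-entity** mode
  (one agent guided by an internal swarm of virtual particles);
* **reward capture** with a contact radius that releases the swarm from
  reward attractors;
* seeded, bitwise-reproducible runs, parameter sweeps with common
  seeds, and metrics for the emergent structure (Kuramoto order,
  reward-centered phase-ring score, capture statistics, coverage,
  visibility clusters).

## Worked example

```r
library(cogswarm)

a <- make_multireward_arena(seed = 0)
a
#> <swarm_arena 'multireward'>
#>   outer ring: 28 vertices; holes: 0; wall segments: 28
#>   cues: 7  rewards: 3  spawn disks: 3
#>   notional radius: 328.24 points

# single-entity navigation with capturable rewards (12-point contact
# radius); the agent spawns in the southwest compartment
p <- swarm_params(N = 1, N_s = 100, duration = 180, sigma = 4,
                  kappa = 1.5, g_c = 0.2, g_r = 0.3, g_s = 0.5,
                  d_rad = 12)
rec <- run_swarm(a, p, "single_entity", seed = 3,
                 stop_when_all_captured = TRUE)
capture_statistics(rec)
#> $times
#>   reward  time
#> 1     NW 119.6
#> 2     SW  17.1
#> 3     SE 145.9
#> $success
#> [1] TRUE
```

The agent captured the southwest reward first (17.1 s, nearest its spawn
disk), then crossed the arena to the southeast (145.9 s) and northwest
(119.6 s — NW fell on the way) compartments; `success` means all three
rewards were contacted within their 12-point radius. With `d_rad = 0`
rewards stay attractive after contact and the agent typically remains
trapped at the first reward it finds. Run-level structure metrics:

```r
kuramoto_order(rec$theta[nrow(rec$theta), ])   # phase synchrony in [0,1]
coverage(rec, a, cell_size = 25)               # fraction of arena visited
structure_report(rec, a)                       # per-frame time series
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/cogswarm.R make-env multireward --seed 0 --out arena.json
Rscript inst/cli/cogswarm.R run --arena arena.json --seed 1 --out run1
Rscript inst/cli/cogswarm.R sweep --arena arena.json --param d_rad \
        --values 0,1,4,10,15 --n-seeds 10 --out sweep1
```

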