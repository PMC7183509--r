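# Neural state of the swarm: visibility/distance couplings, kernel weights,
# input dynamics, activation, phase, and the Oja-rule learning updates.
# All functions are pure and operate on plain matrices/vectors so that the
# vectorized forms can be checked against per-pair loop oracles.

#' Refresh geometric coupling matrices
#'
#' Recomputes, from current positions, the inter-unit visibility matrix `V`
#' (line of sight and within `D_max` times the notional radius), inter-unit
#' distances `D`, unit-reward and unit-cue visibility (`V_r`, `V_c`; line
#' of sight only, no range cutoff) with their distances, and - in
#' single-entity mode - the agent-to-particle visibility mask `V_delta`.
#' Reward visibility entries for already-captured rewards are forced to 0
#' and never re-enabled.
#'
#' @param pos n x 2 matrix of neural unit positions (agents in multi-agent
#'   mode, virtual particles in single-entity mode).
#' @param arena a `swarm_arena`.
#' @param params a `swarm_params`.
#' @param captured logical matrix (n x n_rewards) of captured flags, or
#'   NULL for none.
#' @param agent_pos optional 1 x 2 physical agent position (single-entity
#'   mode); enables `V_delta`.
#' @return list with `V`, `D`, `V_r`, `D_r`, `V_c`, `D_c`, and optionally
#'   `V_delta`.
#' @export
refresh_geometry_couplings <- function(pos, arena, params,
                                       captured = NULL, agent_pos = NULL) {
  pos <- to_points(pos)
  dmax <- params$D_max * notional_radius(arena)
  pv <- cpp_pairwise_vis(pos, arena$segments, params$eps_los, dmax)
  cue_xy <- as.matrix(arena$cues[, c("x", "y")])
  rew_xy <- as.matrix(arena$rewards[, c("x", "y")])
  cv <- cpp_cross_vis(pos, cue_xy, arena$segments, params$eps_los)
  rv <- cpp_cross_vis(pos, rew_xy, arena$segments, params$eps_los)
  if (!is.null(captured) && length(captured) > 0) rv$V[captured] <- 0L
  out <- list(V = pv$V, D = pv$D, V_r = rv$V, D_r = rv$D,
              V_c = cv$V, D_c = cv$D)
  if (!is.null(agent_pos)) {
    dv <- cpp_cross_vis(to_points(agent_pos), pos, arena$segments,
                        params$eps_los)
    out$V_delta <- as.integer(dv$V[1, ])
  }
  out
}

#' Gaussian swarm kernel: weights from distances
#'
#' `W[i,j] = V[i,j] * exp(-D[i,j]^2 / sigma_eff^2)`.
#'
#' @param V visibility matrix (0/1).
#' @param D distance matrix, points.
#' @param sigma_eff swarm kernel scale in points (already multiplied by the
#'   notional radius).
#' @return weight matrix in `[0, 1]`.
#' @export
swarm_kernel <- function(V, D, sigma_eff) {
  stopifnot(sigma_eff > 0)
  V * exp(-(D / sigma_eff)^2)
}

#' Exponential reward kernel: weights from distances
#'
#' `W_r[i,k] = V_r[i,k] * exp(-D_r[i,k] / kappa_eff)`.  The exponential
#' decays more slowly than the Gaussian at long range, supporting
#' long-range reward approach.
#'
#' @param V_r unit-reward visibility (0/1).
#' @param D_r unit-reward distances, points.
#' @param kappa_eff reward kernel scale in points.
#' @return weight matrix in `[0, 1]`.
#' @export
reward_kernel <- function(V_r, D_r, kappa_eff) {
  stopifnot(kappa_eff > 0)
  V_r * exp(-D_r / kappa_eff)
}

#' One Euler step of the sensory-cue input dynamics
#'
#' `tau_c * dc/dt = V_c * V_cstar - c` (elementwise): cue inputs relax
#' toward 1 for cues that are both visible and preferred, and decay toward
#' 0 otherwise.
#'
#' @param cmat current cue inputs (n x n_cues).
#' @param V_c cue visibility (0/1).
#' @param V_cstar fixed cue preferences (0/1).
#' @param tau_c time constant, s.
#' @param dt time step, s (must be < `tau_c`).
#' @return updated cue inputs.
#' @export
step_cue_inputs <- function(cmat, V_c, V_cstar, tau_c, dt) {
  cmat + (dt / tau_c) * (V_c * V_cstar - cmat)
}

#' One Euler step of the reward input dynamics
#'
#' `tau_r * dr/dt = V_r - r`: all units respond equally to visible
#' rewards.
#'
#' @param rmat current reward inputs (n x n_rewards).
#' @param V_r reward visibility (0/1).
#' @param tau_r time constant, s.
#' @param dt time step, s.
#' @return updated reward inputs.
#' @export
step_reward_inputs <- function(rmat, V_r, tau_r, dt) {
  rmat + (dt / tau_r) * (V_r - rmat)
}

#' One Euler step of the recurrent (phase-coupled) input dynamics
#'
#' `tau_q * dq[i,j]/dt = V[i,j] * cos(theta[j] - theta[i]) - q[i,j]`: the
#' cosine of pairwise phase differences provides positive input for
#' synchrony and negative input for anti-synchrony.
#'
#' @param q current recurrent inputs (n x n).
#' @param V visibility (0/1).
#' @param theta phases, radians.
#' @param tau_q time constant, s.
#' @param dt time step, s.
#' @return updated recurrent inputs.
#' @export
step_recurrent_inputs <- function(q, V, theta, tau_q, dt) {
  # cos(theta_j - theta_i) via the angle-difference identity (one BLAS call)
  ph <- cbind(cos(theta), sin(theta))
  cosd <- tcrossprod(ph)
  q + (dt / tau_q) * (V * cosd - q)
}

#' Gain-modulated, visibility-normalized net inputs
#'
#' Per unit: the cue input averages the cue signals of currently visible
#' cues, the reward input averages weight-modulated reward signals over
#' visible rewards, and the recurrent input averages weight-modulated
#' phase-synchrony signals over visible neighbors.  A unit with no visible
#' source of a given class receives 0 for that class (never NaN).
#'
#' @param cmat,rmat,q input matrices (see the step functions).
#' @param W,W_r kernel weight matrices.
#' @param V_c,V_r,V visibility matrices.
#' @param gains list or vector with `g_c`, `g_r`, `g_s`.
#' @return list with per-unit vectors `I_c`, `I_r`, `I_q`.
#' @export
net_inputs <- function(cmat, rmat, q, W, W_r, V_c, V_r, V, gains) {
  norm_sum <- function(num, vis) {
    den <- rowSums(vis)
    s <- rowSums(num)
    ifelse(den > 0, s / den, 0)
  }
  list(I_c = gains$g_c * norm_sum(V_c * cmat, V_c),
       I_r = gains$g_r * norm_sum(W_r * rmat, V_r),
       I_q = gains$g_s * norm_sum(W * q, V))
}

#' Linear-rectified activation
#'
#' `p = max(0, I_c + I_r + I_q)`.  Because each net input is a gain-scaled
#' average of quantities bounded by 1, the activation lies in `[0, 1]`
#' whenever the gains sum to 1.
#'
#' @param I_c,I_r,I_q per-unit net inputs.
#' @return activation vector.
#' @export
activation <- function(I_c, I_r, I_q) {
  pmax(0, I_c + I_r + I_q)
}

#' Advance oscillation phases
#'
#' `theta <- wrap(theta + 2*pi*(omega0 + omegaI * p) * dt)`.  Frequencies
#' are in cycles/s; the phase itself is kept in radians in `[0, 2*pi)`.
#'
#' @param theta phases, radians.
#' @param p activations.
#' @param omega0 baseline frequency, cycles/s.
#' @param omegaI max activation-driven frequency increase, cycles/s.
#' @param dt time step, s.
#' @return updated phases in `[0, 2*pi)`.
#' @export
advance_phase <- function(theta, p, omega0, omegaI, dt) {
  (theta + 2 * pi * (omega0 + omegaI * p) * dt) %% (2 * pi)
}

#' Oja-rule update of the swarm weights
#'
#' `W'[i,j] = W[i,j] + dt*eta*V[i,j]*mask[i]*p[i]*(q[i,j] - p[i]*W[i,j])`.
#' The quadratic activation term divisively normalizes the weights
#' (bounding them near `q/p`), which translates into a baseline repulsion
#' between units once the weights are inverted back into distances.
#'
#' @param W kernel weights.
#' @param p activations.
#' @param q recurrent inputs.
#' @param V visibility.
#' @param eta learning rate.
#' @param dt time step, s.
#' @param mask per-unit 0/1 learning mask (1 in multi-agent mode; the
#'   agent-to-particle visibility in single-entity mode).
#' @return updated weights (not yet clamped).
#' @export
oja_update_swarm <- function(W, p, q, V, eta, dt, mask = 1) {
  W + dt * eta * V * (mask * p) * (q - p * W)
}

#' Oja-rule update of the reward weights
#'
#' `W_r'[i,k] = W_r[i,k] + dt*eta_r*V_r[i,k]*mask[i]*p[i]*(r[i,k] -
#' p[i]*W_r[i,k])`.
#'
#' @param W_r reward kernel weights.
#' @param p activations.
#' @param rmat reward inputs.
#' @param V_r reward visibility.
#' @param eta_r learning rate.
#' @param dt time step, s.
#' @param mask per-unit 0/1 learning mask.
#' @return updated weights (not yet clamped).
#' @export
oja_update_reward <- function(W_r, p, rmat, V_r, eta_r, dt, mask = 1) {
  W_r + dt * eta_r * V_r * (mask * p) * (rmat - p * W_r)
}

#' Clamp learned weights into an invertible range
#'
#' Restricts weights to `[w_min, 1]` so that the kernel inversions are
#' finite; a weight at the floor encodes the maximal desired distance
#' (saturated repulsion).
#'
#' @param W weight matrix.
#' @param w_min clamp floor in (0, 1).
#' @return clamped weights.
#' @export
clamp_weights <- function(W, w_min) {
  vec <- !is.matrix(W)
  if (vec) W <- matrix(W)
  out <- cpp_clamp_unit(W, w_min)
  if (vec) as.vector(out) else out
}
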