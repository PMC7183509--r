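# Motion control: kernel inversion to desired distances, offset
# aggregation, barrier-aware embedding, kinematic filtering, and
# single-entity guidance.

#' Invert the Gaussian swarm kernel into desired distances
#'
#' With `form = "exact"` (default) the strict inverse of the swarm kernel
#' is used, `D' = sigma_eff * sqrt(-log W')`; with `form = "sqrt2"` an extra
#' sqrt(2) scale is retained, `D' = sqrt(-2 * sigma_eff^2 * log W')`.
#'
#' @param W_prime clamped learned weights in `[w_clamp_min, 1]`.
#' @param sigma_eff swarm kernel scale, points.
#' @param form `"exact"` or `"sqrt2"`.
#' @return desired distance matrix, points.
#' @export
invert_swarm_kernel <- function(W_prime, sigma_eff,
                                form = c("exact", "sqrt2")) {
  form <- match.arg(form)
  vec <- !is.matrix(W_prime)
  if (vec) W_prime <- matrix(W_prime)
  out <- cpp_invert_gauss(W_prime, sigma_eff,
                          if (form == "exact") 1 else sqrt(2))
  if (vec) as.vector(out) else out
}

#' Invert the exponential reward kernel into desired distances
#'
#' `D_r' = -kappa_eff * log(W_r')`, the exact inverse of the reward
#' kernel.
#'
#' @param W_r_prime clamped learned reward weights in `[w_clamp_min, 1]`.
#' @param kappa_eff reward kernel scale, points.
#' @return desired distance matrix, points.
#' @export
invert_reward_kernel <- function(W_r_prime, kappa_eff) {
  vec <- !is.matrix(W_r_prime)
  if (vec) W_r_prime <- matrix(W_r_prime)
  out <- cpp_invert_exp(W_r_prime, kappa_eff)
  if (vec) as.vector(out) else out
}

# The offset aggregation core (row-normalized sums of coefficient-scaled
# unit vectors) lives in compiled code: cpp_offsets().

#' Swarm positional offsets from desired inter-agent distances
#'
#' Averages, over visible neighbors, displacement demands along the unit
#' vector toward each neighbor.  Under the default `"functional"` sign
#' convention the coefficient is `(D - D')`, so a unit approaches a
#' neighbor whose desired distance is below the actual one; the
#' `"as_printed"` convention negates it.  Units with no visible neighbor,
#' and coincident pairs, contribute zero.
#'
#' @param D_prime desired distances, points.
#' @param D actual distances, points.
#' @param V visibility (0/1).
#' @param x unit positions (n x 2).
#' @param sign_convention `"functional"` or `"as_printed"`.
#' @return n x 2 matrix of offsets `f`, points.
#' @export
swarm_offset <- function(D_prime, D, V, x,
                         sign_convention = c("functional", "as_printed")) {
  sign_convention <- match.arg(sign_convention)
  coef <- if (sign_convention == "functional") D - D_prime else D_prime - D
  cpp_offsets(coef, V, x, x, 2)
}

#' Reward-oriented positional offsets
#'
#' Analogous to [swarm_offset()] with unit vectors toward reward locations
#' and normalization by the visible-reward count (no factor 2).
#'
#' @param D_r_prime desired unit-reward distances, points.
#' @param D_r actual unit-reward distances, points.
#' @param V_r reward visibility (0/1).
#' @param x unit positions (n x 2).
#' @param reward_xy reward positions (n_rewards x 2).
#' @param sign_convention `"functional"` or `"as_printed"`.
#' @return n x 2 matrix of offsets `f_r`, points.
#' @export
reward_offset <- function(D_r_prime, D_r, V_r, x, reward_xy,
                          sign_convention = c("functional", "as_printed")) {
  sign_convention <- match.arg(sign_convention)
  coef <- if (sign_convention == "functional") D_r - D_r_prime
          else D_r_prime - D_r
  cpp_offsets(coef, V_r, x, reward_xy, 1)
}

#' Combine swarm and reward offsets
#'
#' `dx = alpha * f + (1 - alpha) * f_r`.
#'
#' @param f swarm offsets (n x 2).
#' @param f_r reward offsets (n x 2).
#' @param alpha mixing weight in `[0, 1]`.
#' @return n x 2 combined offsets.
#' @export
combine_offsets <- function(f, f_r, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  alpha * f + (1 - alpha) * f_r
}

#' Barrier-aware embedding of positional offsets
#'
#' Blends each offset with an inward wall-normal deflection according to
#' the wall-proximity kernel `beta = exp(-d / lambda)` evaluated at the
#' offset's anchor point: `dx_b = (1 - beta) * dx + beta * |dx| * n`.
#' Far from walls the offset passes through unchanged; at a wall it is
#' fully deflected inward.
#'
#' @param dx n x 2 offsets, points.
#' @param pos n x 2 anchor positions (the internal field locations).
#' @param arena a `swarm_arena`.
#' @param lambda wall kernel constant, points.
#' @return n x 2 barrier-aware offsets.
#' @export
barrier_embed_offset <- function(dx, pos, arena, lambda) {
  wq <- cpp_wall_query(to_points(pos), arena$segments)
  beta <- exp(-wq[, 1] / lambda)
  mag <- sqrt(rowSums(dx^2))
  cbind((1 - beta) * dx[, 1] + beta * mag * wq[, 2],
        (1 - beta) * dx[, 2] + beta * mag * wq[, 3])
}

#' Tanh speed limiting from a kinetic-energy cap
#'
#' `v_max = sqrt(2 * E_max / m)` per agent and
#' `v_k = v_max * tanh(|v_mu| / v_max) * v_mu / |v_mu|` (zero velocity maps
#' to zero).  The resulting kinetic energy is strictly below `E_max`.
#'
#' @param v_mu n x 2 momentum-filtered velocities.
#' @param v_max per-agent speed caps (length n), points/s.
#' @return n x 2 speed-limited velocities.
#' @export
speed_limit <- function(v_mu, v_max) {
  sp <- sqrt(rowSums(v_mu^2))
  scale <- ifelse(sp > 0, v_max * tanh(sp / v_max) / sp, 0)
  v_mu * scale
}

#' Full kinematic update of the physical agents
#'
#' Chase velocity toward the internal field (`v_s = (x_s - x) / dt`, or a
#' supplied guidance velocity), momentum filter
#' `v_mu = mu*v + (1-mu)*v_s`, tanh speed limiting from the kinetic-energy
#' cap, barrier-normal deflection at the agent position, position update,
#' and collision resolution (an agent whose step segment crosses a wall
#' stops just short of the wall with its wall-normal velocity removed;
#' positions remain allowable at all times).
#'
#' @param x n x 2 agent positions.
#' @param v n x 2 agent velocities.
#' @param x_s n x 2 internal field locations (ignored when `v_s` given).
#' @param m agent masses, kg (length n or 1).
#' @param arena a `swarm_arena`.
#' @param params a `swarm_params`.
#' @param v_s optional guidance velocity (n x 2) overriding the chase
#'   velocity.
#' @return list with updated `x` and `v`.
#' @export
kinematic_update <- function(x, v, x_s, m, arena, params, v_s = NULL) {
  dt <- params$dt
  if (is.null(v_s)) v_s <- (x_s - x) / dt
  v_mu <- params$mu * v + (1 - params$mu) * v_s
  v_max <- sqrt(2 * params$E_max / m)
  v_k <- speed_limit(v_mu, v_max)
  wq <- cpp_wall_query(to_points(x), arena$segments)
  beta <- exp(-wq[, 1] / params$lambda_wall)
  mag <- sqrt(rowSums(v_k^2))
  v_new <- cbind((1 - beta) * v_k[, 1] + beta * mag * wq[, 2],
                 (1 - beta) * v_k[, 2] + beta * mag * wq[, 3])
  x_new <- x + v_new * dt
  res <- cpp_resolve_collisions(x, x_new, v_new, arena$segments, 1e-3)
  x_new <- res$x; v_new <- res$v
  bad <- !cpp_points_allowable(x_new, c(list(arena$outer_ring),
                                        arena$hole_rings))
  if (any(bad)) {  # corner cases: revert and stop
    x_new[bad, ] <- x[bad, , drop = FALSE]
    v_new[bad, ] <- 0
  }
  list(x = x_new, v = v_new)
}

#' Single-entity guidance velocity
#'
#' The agent chases a cubic-activation-weighted average of its visible
#' virtual particles:
#' `v_s = sum_i V_delta[i] * p[i]^3 * (x_s[i,] - x) / (dt * sum_j
#' V_delta[j] * p[j]^3)`; if no visible particle is active the velocity is
#' zero.  Cubing the activation compresses low-activation particles toward
#' zero so the agent commits to the most highly activated cluster.
#'
#' @param V_delta 0/1 agent-to-particle visibility (length n).
#' @param p particle activations.
#' @param x_s particle positions (n x 2).
#' @param x agent position (length 2 or 1 x 2).
#' @param dt time step, s.
#' @return 1 x 2 guidance velocity, points/s.
#' @export
single_entity_guidance <- function(V_delta, p, x_s, x, dt) {
  w <- V_delta * p^3
  s <- sum(w)
  x <- as.numeric(x)
  if (s <= 0) return(matrix(0, 1, 2))
  matrix(c(sum(w * (x_s[, 1] - x[1])), sum(w * (x_s[, 2] - x[2]))) / (dt * s),
         1, 2)
}
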