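# Simulation driver: initialization, the per-step update pipeline,
# recording, and parameter sweeps.

make_step_cache <- function(arena, params) {
  R_not <- notional_radius(arena)
  list(R_not = R_not,
       sigma_eff = params$sigma * R_not,
       kappa_eff = params$kappa * R_not,
       dmax_eff = params$D_max * R_not,
       segs = arena$segments,
       rings = c(list(arena$outer_ring), arena$hole_rings),
       cue_xy = unname(as.matrix(arena$cues[, c("x", "y")])),
       reward_xy = unname(as.matrix(arena$rewards[, c("x", "y")])))
}

#' Initialize a swarm state
#'
#' Velocities, input signals, and activations start at zero; phases are
#' uniform on `[0, 2*pi)`; positions are sampled uniformly within the
#' spawn disks (intersected with the allowable interior, disks assigned
#' round-robin; the whole interior is used if the arena has no spawn
#' disks); cue preferences are fixed by sampling, for each unit, one
#' uniform allowable location and marking every cue visible from it.  In
#' multi-agent mode each agent's internal field starts at its own
#' position and masses are drawn uniformly from
#' `[1 - mass_jitter, 1 + mass_jitter] * m_mean_multi`; in single-entity
#' mode the single agent (mass `m_single`) starts in the first spawn disk
#' and the virtual particles are spread round-robin over all disks.  All
#' randomness comes from `seed`.
#'
#' @param arena a `swarm_arena`.
#' @param params a `swarm_params`.
#' @param mode `"multi_agent"` or `"single_entity"`.
#' @param seed integer seed.
#' @return a `swarm_state` list.
#' @export
initialize_swarm <- function(arena, params, mode = c("multi_agent",
                                                     "single_entity"),
                             seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "multi_agent" && params$N != params$N_s)
    stop("multi-agent mode requires N == N_s", call. = FALSE)
  set.seed(seed)
  N_s <- params$N_s
  N <- if (mode == "multi_agent") params$N else 1L
  n_c <- nrow(arena$cues); n_r <- nrow(arena$rewards)
  disks <- arena$spawn_disks
  sample_spawn <- function(n) {
    if (nrow(disks) == 0) return(sample_allowable(arena, n))
    idx <- ((seq_len(n) - 1L) %% nrow(disks)) + 1L
    out <- matrix(NA_real_, n, 2)
    for (d in unique(idx)) {
      rows <- which(idx == d)
      out[rows, ] <- sample_allowable(arena, length(rows),
                                      center = c(disks$x[d], disks$y[d]),
                                      radius = disks$radius[d])
    }
    out
  }
  if (mode == "multi_agent") {
    m <- params$m_mean_multi *
      runif(N, 1 - params$mass_jitter, 1 + params$mass_jitter)
    x <- sample_spawn(N)
    x_s <- x
  } else {
    m <- params$m_single
    x <- sample_spawn(1L)
    x_s <- sample_spawn(N_s)
  }
  theta <- runif(N_s, 0, 2 * pi)
  if (n_c > 0) {
    locs <- sample_allowable(arena, N_s)
    V_cstar <- cpp_cross_vis(locs, unname(as.matrix(arena$cues[, c("x", "y")])),
                             arena$segments, params$eps_los)$V
  } else {
    V_cstar <- matrix(0L, N_s, 0)
  }
  structure(list(
    mode = mode, t = 0, step = 0L,
    x = x, v = matrix(0, N, 2), m = m,
    theta = theta, p = numeric(N_s),
    x_s = x_s,
    cmat = matrix(0, N_s, n_c), rmat = matrix(0, N_s, n_r),
    q = matrix(0, N_s, N_s),
    V_cstar = V_cstar,
    captured = matrix(FALSE, N_s, n_r),
    capture_events = data.frame(reward = character(0), agent = integer(0),
                                time = numeric(0))),
    class = "swarm_state")
}

#' Apply the reward-capture rule
#'
#' With a positive contact radius, a unit entering the radius of a reward
#' captures it: in multi-agent mode only that (agent, reward) pair is
#' deactivated; in single-entity mode the reward is deactivated for all
#' virtual particles once the physical agent makes contact.  Captured
#' entries are permanent: the set of captured rewards is non-decreasing
#' and the corresponding reward visibility stays 0.  A non-positive
#' `d_rad` disables capture entirely (fixed rewards).
#'
#' @param captured logical matrix (units x rewards) of current flags.
#' @param dist distance matrix to rewards: units x rewards (multi-agent)
#'   or 1 x rewards (single-entity agent distances).
#' @param d_rad contact radius, points.
#' @param mode `"multi_agent"` or `"single_entity"`.
#' @return list with updated `captured` and `events`, an index matrix of
#'   newly captured (unit, reward) pairs.
#' @export
apply_reward_capture <- function(captured, dist, d_rad, mode) {
  if (d_rad <= 0 || ncol(captured) == 0)
    return(list(captured = captured,
                events = matrix(integer(0), 0, 2)))
  if (mode == "single_entity") {
    hit_k <- which(dist[1, ] <= d_rad & !captured[1, ])
    events <- cbind(rep(1L, length(hit_k)), hit_k)
    if (length(hit_k) > 0) captured[, hit_k] <- TRUE
  } else {
    new <- dist <= d_rad & !captured
    events <- which(new, arr.ind = TRUE)
    captured <- captured | new
  }
  list(captured = captured, events = unname(events))
}

#' Advance the simulation by one time step
#'
#' Executes the synchronous update pipeline: geometric couplings from the
#' previous step's positions; kernel weights; Euler steps of the cue,
#' reward, and recurrent input dynamics; net inputs, activation, and phase
#' advance; the Oja learning perturbation (masked by agent-to-particle
#' visibility in single-entity mode) with clamping; kernel inversion to
#' desired distances; offset aggregation, mixing, and barrier-aware
#' embedding; internal-field update (collision-clipped); agent kinematics
#' (chase or cubic-activation guidance, momentum, speed limit, barrier
#' deflection, collision resolution); and reward capture.
#'
#' @param state a `swarm_state`.
#' @param arena a `swarm_arena`.
#' @param params a `swarm_params`.
#' @param cache optional precomputed geometry cache (internal; built
#'   automatically when absent).
#' @return the updated `swarm_state`.
#' @export
swarm_step <- function(state, arena, params, cache = NULL) {
  if (is.null(cache)) cache <- make_step_cache(arena, params)
  dt <- params$dt
  single <- state$mode == "single_entity"
  pos <- if (single) state$x_s else state$x
  n <- nrow(pos)

  # (1) geometry couplings
  pv <- cpp_pairwise_vis(pos, cache$segs, params$eps_los, cache$dmax_eff)
  V <- pv$V; D <- pv$D
  V_c <- if (ncol(state$cmat) > 0)
    cpp_cross_vis(pos, cache$cue_xy, cache$segs, params$eps_los)$V
  else matrix(0L, n, 0)
  if (ncol(state$rmat) > 0) {
    rv <- cpp_cross_vis(pos, cache$reward_xy, cache$segs, params$eps_los)
    V_r <- rv$V; D_r <- rv$D
    if (any(state$captured)) V_r[state$captured] <- 0L
  } else {
    V_r <- matrix(0L, n, 0); D_r <- matrix(0, n, 0)
  }
  V_delta <- NULL
  if (single)
    V_delta <- as.integer(cpp_cross_vis(state$x, pos, cache$segs,
                                        params$eps_los)$V[1, ])

  # (2) kernel weights from current geometry
  W <- swarm_kernel(V, D, cache$sigma_eff)
  W_r <- reward_kernel(V_r, D_r, cache$kappa_eff)

  # (3) input dynamics (forward Euler)
  state$cmat <- step_cue_inputs(state$cmat, V_c, state$V_cstar,
                                params$tau_c, dt)
  state$rmat <- step_reward_inputs(state$rmat, V_r, params$tau_r, dt)
  state$q <- step_recurrent_inputs(state$q, V, state$theta, params$tau_q, dt)

  # (4) net inputs, activation, phase
  ni <- net_inputs(state$cmat, state$rmat, state$q, W, W_r, V_c, V_r, V,
                   params)
  p <- activation(ni$I_c, ni$I_r, ni$I_q)
  state$p <- p
  state$theta <- advance_phase(state$theta, p, params$omega0, params$omegaI,
                               dt)

  # (5) Oja learning perturbation, clamped into the invertible range
  mask <- if (single) V_delta else 1
  Wp <- clamp_weights(oja_update_swarm(W, p, state$q, V, params$eta, dt,
                                       mask),
                      params$w_clamp_min)
  Wrp <- clamp_weights(oja_update_reward(W_r, p, state$rmat, V_r,
                                         params$eta_r, dt, mask),
                       params$w_clamp_min)

  # (6) kernel inversion to desired distances
  Dp <- invert_swarm_kernel(Wp, cache$sigma_eff, params$kernel_inverse)
  Drp <- if (ncol(Wrp) > 0) invert_reward_kernel(Wrp, cache$kappa_eff)
         else Wrp

  # (7) offsets, mixing, barrier embedding at the internal field locations
  f <- swarm_offset(Dp, D, V, pos, params$sign_convention)
  f_r <- if (ncol(V_r) > 0)
    reward_offset(Drp, D_r, V_r, pos, cache$reward_xy,
                  params$sign_convention)
  else matrix(0, n, 2)
  dx <- combine_offsets(f, f_r, params$alpha)
  dxb <- barrier_embed_offset(dx, state$x_s, arena, params$lambda_wall)
  if (single && params$freeze_invisible_particles)
    dxb[V_delta == 0L, ] <- 0

  # (8) move the internal fields, clipped so they stay allowable
  xs_new <- state$x_s + dxb
  moved <- which(dxb[, 1] != 0 | dxb[, 2] != 0)
  if (length(moved) > 0) {
    res <- cpp_resolve_collisions(state$x_s[moved, , drop = FALSE],
                                  xs_new[moved, , drop = FALSE],
                                  matrix(0, length(moved), 2),
                                  cache$segs, 1e-3)
    xs_new[moved, ] <- res$x
    bad <- !cpp_points_allowable(xs_new[moved, , drop = FALSE], cache$rings)
    if (any(bad))
      xs_new[moved[bad], ] <- state$x_s[moved[bad], , drop = FALSE]
  }
  state$x_s <- xs_new

  # (9) physical agent kinematics
  if (single) {
    v_s <- single_entity_guidance(V_delta, p, state$x_s, state$x, dt)
    ku <- kinematic_update(state$x, state$v, NULL, state$m, arena, params,
                           v_s = v_s)
  } else {
    ku <- kinematic_update(state$x, state$v, state$x_s, state$m, arena,
                           params)
  }
  state$x <- ku$x; state$v <- ku$v

  # (10) reward capture from the updated agent positions
  if (params$d_rad > 0 && ncol(state$captured) > 0) {
    rx <- cache$reward_xy
    dmat <- sqrt(outer(state$x[, 1], rx[, 1], "-")^2 +
                 outer(state$x[, 2], rx[, 2], "-")^2)
    cap <- apply_reward_capture(state$captured, dmat, params$d_rad,
                                state$mode)
    state$captured <- cap$captured
    if (nrow(cap$events) > 0) {
      state$capture_events <- rbind(
        state$capture_events,
        data.frame(reward = arena$rewards$id[cap$events[, 2]],
                   agent = as.integer(cap$events[, 1]),
                   time = state$t + dt))
    }
  }

  state$t <- state$t + dt
  state$step <- state$step + 1L
  if (anyNA(state$x) || any(!is.finite(state$x)) ||
      any(!is.finite(state$p)) || any(!is.finite(state$x_s)))
    stop(sprintf("non-finite state at step %d", state$step), call. = FALSE)
  state
}

#' Run a full simulation
#'
#' Initializes (unless an initial state is supplied), iterates
#' [swarm_step()] for `duration / dt` steps, and records the state every
#' `record_every` steps (frame 0 is always recorded).
#'
#' @param arena a `swarm_arena`.
#' @param params a `swarm_params`.
#' @param mode `"multi_agent"` or `"single_entity"`.
#' @param seed integer seed (drives all randomness).
#' @param record_every recording cadence in steps.
#' @param init_state optional `swarm_state` to start from instead of
#'   [initialize_swarm()].
#' @param stop_when_all_captured end the run early once every reward has
#'   been captured.
#' @param stop_dist_to_reward end the run early once the physical agent
#'   comes within this distance (points) of any reward (NULL disables).
#' @return a `swarm_record`: list with `time`, arrays `x`, `v` (frames x
#'   agents x 2), `theta`, `p` (frames x units), `x_s` (frames x units x
#'   2), `captures` (data.frame), and run metadata.
#' @export
run_swarm <- function(arena, params = swarm_params(),
                      mode = c("multi_agent", "single_entity"), seed = 1L,
                      record_every = 10L, init_state = NULL,
                      stop_when_all_captured = FALSE,
                      stop_dist_to_reward = NULL) {
  mode <- match.arg(mode)
  if (is.null(init_state))
    state <- initialize_swarm(arena, params, mode, seed)
  else state <- init_state
  cache <- make_step_cache(arena, params)
  n_steps <- as.integer(round(params$duration / params$dt))
  n_frames <- n_steps %/% record_every + 1L
  N <- nrow(state$x); N_s <- length(state$theta)
  rec <- list(time = numeric(n_frames),
              x = array(NA_real_, c(n_frames, N, 2)),
              v = array(NA_real_, c(n_frames, N, 2)),
              theta = matrix(NA_real_, n_frames, N_s),
              p = matrix(NA_real_, n_frames, N_s),
              x_s = array(NA_real_, c(n_frames, N_s, 2)))
  store <- function(fr, s) {
    rec$time[fr] <<- s$t
    rec$x[fr, , ] <<- s$x; rec$v[fr, , ] <<- s$v
    rec$theta[fr, ] <<- s$theta; rec$p[fr, ] <<- s$p
    rec$x_s[fr, , ] <<- s$x_s
  }
  store(1L, state)
  fr <- 1L
  rew_xy <- cache$reward_xy
  for (k in seq_len(n_steps)) {
    state <- swarm_step(state, arena, params, cache)
    if (k %% record_every == 0L) {
      fr <- fr + 1L
      store(fr, state)
    }
    if (stop_when_all_captured && ncol(state$captured) > 0 &&
        all(apply(state$captured, 2, any))) break
    if (!is.null(stop_dist_to_reward) && nrow(arena$rewards) > 0) {
      dmin <- min(sqrt((rew_xy[, 1] - state$x[1, 1])^2 +
                       (rew_xy[, 2] - state$x[1, 2])^2))
      if (dmin <= stop_dist_to_reward) break
    }
  }
  used <- seq_len(fr)
  structure(list(
    time = rec$time[used],
    x = rec$x[used, , , drop = FALSE], v = rec$v[used, , , drop = FALSE],
    theta = rec$theta[used, , drop = FALSE],
    p = rec$p[used, , drop = FALSE],
    x_s = rec$x_s[used, , , drop = FALSE],
    captures = state$capture_events,
    captured = state$captured,
    final_state = state,
    mode = mode, seed = seed, record_every = record_every,
    params = params, arena_name = arena$name,
    n_rewards = nrow(arena$rewards), reward_ids = arena$rewards$id,
    steps_run = state$step, t_end = state$t),
    class = "swarm_record")
}

#' @export
print.swarm_record <- function(x, ...) {
  cat(sprintf("<swarm_record '%s' %s seed=%d>\n", x$arena_name, x$mode,
              x$seed))
  cat(sprintf("  %d steps (%.2f s), %d frames, %d agents, %d units\n",
              x$steps_run, x$t_end, length(x$time), dim(x$x)[2],
              ncol(x$theta)))
  cat(sprintf("  captures: %d of %d rewards\n",
              length(unique(x$captures$reward)), x$n_rewards))
  invisible(x)
}

#' Sweep a parameter over seeded repetitions
#'
#' Runs `length(values) * length(seeds)` simulations, reusing the same
#' seed list for every parameter value so conditions are compared under
#' common random numbers.  Each row reports the first capture time of
#' every reward (NA if never captured) and whether all rewards were
#' captured.
#'
#' @param arena a `swarm_arena`.
#' @param params base `swarm_params`.
#' @param mode simulation mode.
#' @param param name of the parameter to vary.
#' @param values vector of parameter values.
#' @param n_seeds number of seeds (used when `seeds` is NULL).
#' @param seeds explicit integer seed vector shared across values.
#' @param record_every recording cadence (coarse by default; the sweep
#'   keeps summaries only).
#' @param stop_when_all_captured end each run at full capture.
#' @return data.frame with one row per run: `value`, `seed`, `success`,
#'   and one `t_capture_<reward id>` column per reward.
#' @export
sweep_swarm <- function(arena, params, mode, param, values, n_seeds = 10L,
                        seeds = NULL, record_every = 50L,
                        stop_when_all_captured = TRUE) {
  if (!param %in% names(params))
    stop("unknown parameter: ", param, call. = FALSE)
  if (is.null(seeds)) seeds <- seq_len(n_seeds)
  rows <- list()
  for (val in values) {
    prm <- params
    prm[[param]] <- val
    prm <- validate_params(prm)
    for (s in seeds) {
      rec <- run_swarm(arena, prm, mode, seed = s,
                       record_every = record_every,
                       stop_when_all_captured = stop_when_all_captured)
      cs <- capture_statistics(rec)
      row <- data.frame(value = val, seed = s, success = cs$success)
      tc <- setNames(as.list(cs$times$time), paste0("t_capture_",
                                                    cs$times$reward))
      rows[[length(rows) + 1L]] <- cbind(row, as.data.frame(tc))
    }
  }
  do.call(rbind, rows)
}
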