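test_that("spatial kernels match their closed forms", {
  expect_equal(swarm_kernel(1L, 0, 10), 1)
  expect_equal(swarm_kernel(0L, 5, 10), 0)
  expect_equal(swarm_kernel(1L, 10, 10), exp(-1), tolerance = 1e-12)
  expect_equal(reward_kernel(1L, 0, 10), 1)
  expect_equal(reward_kernel(1L, 10, 10), exp(-1), tolerance = 1e-12)
  # exponential outlasts the Gaussian beyond the kernel scale
  expect_gt(reward_kernel(1L, 20, 10), swarm_kernel(1L, 20, 10))
})

test_that("input dynamics step toward their fixed points at the Euler rate", {
  # one Euler step from zero with everything visible and preferred
  expect_equal(step_cue_inputs(0, 1L, 1L, tau_c = 0.5, dt = 0.01), 0.02)
  # fixed point is invariant
  expect_equal(step_cue_inputs(1, 1L, 1L, 0.5, 0.01), 1)
  # invisible cue decays geometrically
  expect_equal(step_cue_inputs(0.5, 0L, 1L, 0.5, 0.01), 0.98 * 0.5)
  expect_equal(step_reward_inputs(0, 1L, 0.5, 0.01), 0.02)
  expect_equal(step_reward_inputs(1, 1L, 0.5, 0.01), 1)
  expect_equal(step_reward_inputs(0.25, 0L, 0.5, 0.01), 0.98 * 0.25)
  # recurrent inputs settle on cos of the phase difference
  V <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  for (dth in c(0, pi, pi / 2)) {
    q <- matrix(cos(dth) * V, 2, 2)  # claimed fixed point
    q2 <- step_recurrent_inputs(q, V, c(0, dth), tau_q = 0.1, dt = 0.01)
    expect_equal(q2, q, tolerance = 1e-12)
  }
  # convexity keeps q in [-1, 1] for dt < tau
  st <- random_state_matrices(6, seed = 2)
  q <- st$q
  for (k in 1:200)
    q <- step_recurrent_inputs(q, st$V, st$theta, 0.1, 0.01)
  expect_true(all(q >= -1 & q <= 1))
})

test_that("net inputs are gain-bounded averages with a zero-visibility
           convention", {
  gains <- list(g_c = 0.4, g_r = 0.2, g_s = 0.4)
  n <- 3
  ones <- matrix(1L, n, n); diag(ones) <- 0L
  # cues at fixed point, all visible and preferred -> I_c attains g_c
  ni <- net_inputs(matrix(1, n, 2), matrix(1, n, 1), ones, ones,
                   matrix(1, n, 1), matrix(1L, n, 2), matrix(1L, n, 1),
                   ones, gains)
  expect_equal(ni$I_c, rep(0.4, n))
  # no visible rewards -> I_r is 0, not NaN
  ni0 <- net_inputs(matrix(1, n, 2), matrix(1, n, 1), ones, ones,
                    matrix(1, n, 1), matrix(1L, n, 2), matrix(0L, n, 1),
                    ones, gains)
  expect_equal(ni0$I_r, rep(0, n))
  # single visible neighbor with W = 1 and q = -1 -> I_q = -g_s
  V <- matrix(0L, 2, 2); V[1, 2] <- V[2, 1] <- 1L
  W1 <- matrix(as.numeric(V), 2, 2)  # W carries the visibility factor
  niq <- net_inputs(matrix(0, 2, 0), matrix(0, 2, 0), matrix(-1, 2, 2),
                    W1, matrix(0, 2, 0), matrix(0L, 2, 0),
                    matrix(0L, 2, 0), V, gains)
  expect_equal(niq$I_q, c(-0.4, -0.4))
})

test_that("activation is rectified and bounded by the gain sum", {
  expect_equal(activation(-0.1, -0.05, -0.05), 0)
  expect_equal(activation(0.4, 0.2, 0.4), 1)
  gains <- list(g_c = 0.4, g_r = 0.2, g_s = 0.4)
  for (s in 1:20) {
    st <- random_state_matrices(5, seed = s)
    W <- swarm_kernel(st$V, st$D, 40)
    W_r <- reward_kernel(st$V_r, matrix(runif(10, 0, 80), 5, 2), 40)
    ni <- net_inputs(st$cmat, st$rmat, st$q, W, W_r, st$V_c, st$V_r, st$V,
                     gains)
    p <- activation(ni$I_c, ni$I_r, ni$I_q)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("phase advances at the activation-modulated rate and wraps", {
  expect_equal(advance_phase(1.3, 0, 0, 1, 0.01), 1.3)
  expect_equal(advance_phase(0, 1, 0, 1, 0.01), 0.02 * pi,
               tolerance = 1e-12)
  th <- advance_phase(2 * pi - 1e-3, 1, 0, 1, 0.01)
  expect_true(th >= 0 && th < 2 * pi)
})

test_that("Oja updates match the loop oracle, fix their stated fixed
           points, and converge geometrically", {
  expect_equal(oja_update_swarm(0.5, 0, 0.3, 1L, 1, 0.01), 0.5)
  # fixed point W = q / p
  expect_equal(oja_update_swarm(0.5, 0.8, 0.4, 1L, 1, 0.01), 0.5)
  expect_equal(oja_update_reward(0.5, 0.8, 0.4, 1L, 1, 0.01), 0.5)
  for (s in 1:5) {
    st <- random_state_matrices(4, seed = s)
    W <- swarm_kernel(st$V, st$D, 50)
    mask <- rbinom(4, 1, 0.5)
    expect_equal(oja_update_swarm(W, st$p, st$q, st$V, 1.3, 0.01, mask),
                 oracle_oja_swarm(W, st$p, st$q, st$V, 1.3, 0.01, mask),
                 tolerance = 1e-12)
  }
  # frozen-(p, q) iteration converges geometrically to q/p
  p <- 0.8; q <- 0.4; w <- 0.9
  errs <- numeric(2000)
  for (k in 1:2000) {
    w <- clamp_weights(oja_update_swarm(w, p, q, 1L, 1, 0.01), 1e-6)
    errs[k] <- abs(w - q / p)
  }
  expect_lt(errs[2000], 1e-4)
  ratios <- errs[2:50] / errs[1:49]
  expect_true(all(abs(ratios - (1 - 0.01 * p^2)) < 1e-9))
})

test_that("reward capture follows the contact-radius rule in both modes", {
  cap0 <- apply_reward_capture(matrix(FALSE, 2, 2),
                               matrix(c(0.1, 5, 3, 0.2), 2, 2),
                               d_rad = 0, mode = "multi_agent")
  expect_false(any(cap0$captured))  # d_rad = 0: fixed rewards
  capm <- apply_reward_capture(matrix(FALSE, 2, 2),
                               matrix(c(11, 50, 50, 13), 2, 2),
                               d_rad = 12, mode = "multi_agent")
  expect_identical(capm$captured,
                   matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  # single entity: agent contact deactivates the whole column
  caps <- apply_reward_capture(matrix(FALSE, 5, 2),
                               matrix(c(11, 40), 1, 2),
                               d_rad = 12, mode = "single_entity")
  expect_true(all(caps$captured[, 1]))
  expect_false(any(caps$captured[, 2]))
  # permanence: a captured flag is never cleared by another call
  cap2 <- apply_reward_capture(caps$captured, matrix(c(500, 40), 1, 2),
                               d_rad = 12, mode = "single_entity")
  expect_true(all(cap2$captured[, 1]))
})

test_that("geometry couplings: symmetry, range cutoff convention, and
           capture masking", {
  R_not <- 100 / sqrt(pi)
  prm <- swarm_params(D_max = 50 / R_not)  # cutoff at exactly 50 points
  sq <- square_arena(100, rewards = data.frame(id = "R", x = 90, y = 90))
  pos <- rbind(c(10, 10), c(40, 50), c(10, 10 + 50))  # pair 1-3 at d = 50
  cp <- refresh_geometry_couplings(pos, sq, prm)
  expect_identical(cp$V, t(cp$V))
  expect_identical(diag(cp$V), rep(0L, 3))
  expect_equal(cp$D, as.matrix(dist(pos)), ignore_attr = TRUE)
  expect_equal(cp$V[1, 3], 1L)  # distance exactly D_max * R: still visible
  pos2 <- pos; pos2[3, 2] <- pos2[3, 2] + 0.001
  expect_equal(refresh_geometry_couplings(pos2, sq, prm)$V[1, 3], 0L)
  # captured rewards stay invisible through refreshes
  cap <- matrix(c(FALSE, TRUE, FALSE), 3, 1)
  cp2 <- refresh_geometry_couplings(pos, sq, prm, captured = cap)
  expect_equal(cp2$V_r[2, 1], 0L)
  expect_equal(cp2$V_r[1, 1], 1L)
  # loop oracle for V: line of sight + range, excluding self
  mr <- make_multireward_arena(seed = 6)
  set.seed(3)
  pts <- sample_allowable(mr, 12)
  prm2 <- swarm_params(D_max = 0.5)
  cp3 <- refresh_geometry_couplings(pts, mr, prm2)
  dmax <- 0.5 * notional_radius(mr)
  for (i in 1:12) for (j in 1:12) {
    expected <- as.integer(i != j &&
      sqrt(sum((pts[i, ] - pts[j, ])^2)) <= dmax &&
      line_of_sight(pts[i, ], pts[j, ], mr))
    expect_identical(cp3$V[i, j], expected)
  }
})
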