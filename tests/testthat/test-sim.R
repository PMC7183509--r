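test_that("initialization follows the stated protocol and is
           seed-deterministic", {
  a <- make_multireward_arena(seed = 1)
  prm <- swarm_params(N = 12, N_s = 12)
  st <- initialize_swarm(a, prm, "multi_agent", seed = 5)
  expect_true(all(point_allowable(st$x, a)))
  expect_true(all(st$v == 0))
  expect_true(all(st$p == 0))
  expect_true(all(st$cmat == 0) && all(st$rmat == 0) && all(st$q == 0))
  expect_true(all(st$theta >= 0 & st$theta < 2 * pi))
  expect_identical(st$x, st$x_s)  # internal fields start at the agent
  expect_true(all(st$m >= 0.15 & st$m <= 0.45))  # 0.3 kg +/- 50%
  st2 <- initialize_swarm(a, prm, "multi_agent", seed = 5)
  expect_identical(st, st2)
  expect_false(identical(st$x, initialize_swarm(a, prm, "multi_agent",
                                                seed = 6)$x))
  # positions honor the spawn disks (round-robin assignment)
  disks <- a$spawn_disks
  idx <- ((seq_len(12) - 1) %% 3) + 1
  d2 <- (st$x[, 1] - disks$x[idx])^2 + (st$x[, 2] - disks$y[idx])^2
  expect_true(all(d2 <= disks$radius[idx]^2))
  # a cue visible from everywhere is preferred by every agent
  sq <- square_arena(100, cues = data.frame(id = "c1", x = 50, y = 50))
  st3 <- initialize_swarm(sq, swarm_params(N = 8, N_s = 8), "multi_agent",
                          seed = 1)
  expect_true(all(st3$V_cstar == 1L))
  # mode constraints
  expect_error(initialize_swarm(a, swarm_params(N = 5, N_s = 6),
                                "multi_agent"), "N == N_s")
  sing <- initialize_swarm(a, swarm_params(N = 1, N_s = 20),
                           "single_entity", seed = 2)
  expect_equal(nrow(sing$x), 1)
  expect_equal(nrow(sing$x_s), 20)
  expect_true(all(point_allowable(sing$x_s, a)))
  expect_equal(sing$m, 3.0)
})

test_that("a lone agent with no inputs is a fixed point of the step", {
  sq <- square_arena(200)
  prm <- swarm_params(N = 1, N_s = 1)
  st <- initialize_swarm(sq, prm, "multi_agent", seed = 1)
  x0 <- st$x; th0 <- st$theta
  for (k in 1:50) st <- swarm_step(st, sq, prm)
  expect_identical(st$x, x0)
  expect_identical(st$theta, th0)
  expect_true(all(st$v == 0))
  expect_true(all(st$p == 0))
})

test_that("synchrony drives attraction and anti-synchrony prevents it", {
  sq <- square_arena(400, cues = data.frame(id = "c1", x = 200, y = 390),
                     spawn_disks = data.frame(x = c(150, 250), y = 200,
                                              radius = 5))
  prm <- swarm_params(N = 2, N_s = 2, duration = 1, mass_jitter = 0)
  base <- initialize_swarm(sq, prm, "multi_agent", seed = 1)
  base$x <- rbind(c(170, 200), c(230, 200))
  base$x_s <- base$x
  dist_series <- function(phases) {
    st <- base
    st$theta <- phases
    rec <- run_swarm(sq, prm, "multi_agent", seed = 1, init_state = st,
                     record_every = 10)
    sqrt(rowSums((rec$x[, 1, ] - rec$x[, 2, ])^2))
  }
  din <- dist_series(c(1, 1))
  expect_true(all(diff(din) < 0))       # strict approach within 1 s
  danti <- dist_series(c(0, pi))
  expect_true(all(diff(danti) >= 0))    # no approach under anti-synchrony
})

test_that("a lone multi-agent with a visible reward approaches it
           monotonically", {
  sq <- square_arena(400,
                     rewards = data.frame(id = "R", x = 300, y = 200),
                     spawn_disks = data.frame(x = 80, y = 200, radius = 1))
  prm <- swarm_params(N = 1, N_s = 1, duration = 20, g_c = 0, g_r = 0.5,
                      g_s = 0.5)
  rec <- run_swarm(sq, prm, "multi_agent", seed = 3, record_every = 20)
  d <- sqrt((rec$x[, 1, 1] - 300)^2 + (rec$x[, 1, 2] - 200)^2)
  step_len <- max(sqrt(rowSums(rec$v[, 1, ]^2))) * prm$dt * 20
  moving <- d > max(5, step_len)
  expect_true(all(diff(d)[moving[-length(moving)]] < 0))
  expect_lt(min(d), 5)
})

test_that("run bookkeeping: step counts, cadence, and bitwise
           determinism", {
  a <- make_multireward_arena(seed = 2)
  prm <- swarm_params(N = 10, N_s = 10, duration = 1)
  rec <- run_swarm(a, prm, "multi_agent", seed = 9, record_every = 10)
  expect_equal(rec$steps_run, 100)
  expect_equal(length(rec$time), 11)          # frame 0 + every 10 steps
  expect_equal(rec$time, seq(0, 1, by = 0.1), tolerance = 1e-9)
  rec2 <- run_swarm(a, prm, "multi_agent", seed = 9, record_every = 10)
  expect_identical(rec$x, rec2$x)
  expect_identical(rec$theta, rec2$theta)
  expect_identical(rec$x_s, rec2$x_s)
})

test_that("short runs in both arenas preserve every state invariant", {
  for (gen in list(function() make_multireward_arena(seed = 3),
                   function() make_hairpin_maze(seed = 3))) {
    a <- gen()
    prm <- swarm_params(N = 15, N_s = 15, duration = 3, d_rad = 12)
    rec <- run_swarm(a, prm, "multi_agent", seed = 4, record_every = 25)
    expect_true(all(rec$p >= 0 & rec$p <= 1))
    expect_true(all(rec$theta >= 0 & rec$theta < 2 * pi))
    ke <- 0.5 * sweep(rec$v[, , 1]^2 + rec$v[, , 2]^2, 2,
                      rec$final_state$m, "*")
    expect_true(all(ke <= prm$E_max * (1 + 1e-12)))
    for (fr in seq_along(rec$time))
      expect_true(all(point_allowable(matrix(rec$x[fr, , ], ncol = 2), a)))
    fs <- rec$final_state
    expect_true(all(fs$cmat >= 0 & fs$cmat <= 1))
    expect_true(all(fs$rmat >= 0 & fs$rmat <= 1))
    expect_true(all(fs$q >= -1 & fs$q <= 1))
  }
})

test_that("sweeps reuse the seed list across values and summarize
           captures", {
  sq <- square_arena(300,
                     rewards = data.frame(id = "R", x = 250, y = 150),
                     spawn_disks = data.frame(x = 60, y = 150, radius = 20))
  prm <- swarm_params(N = 1, N_s = 1, duration = 10, g_c = 0, g_r = 0.5,
                      g_s = 0.5)
  res <- sweep_swarm(sq, prm, "multi_agent", "d_rad", values = c(0, 10),
                     n_seeds = 2)
  expect_equal(nrow(res), 4)
  expect_equal(res$seed, c(1, 2, 1, 2))
  expect_true(all(res$success %in% c(TRUE, FALSE)))
  # d_rad = 0 disables capture entirely
  expect_true(all(!res$success[res$value == 0]))
  expect_true(all(is.na(res$t_capture_R[res$value == 0])))
  # at d_rad = 10 the lone agent drives straight in and captures
  expect_true(all(res$success[res$value == 10]))
  expect_error(sweep_swarm(sq, prm, "multi_agent", "no_such", 1, 1),
               "unknown parameter")
})

test_that("configuration files round-trip and reject unknown keys", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("sigma: 2.0", "g_c: 0.2", "g_r: 0.3", "g_s: 0.5",
               "mode: single_entity", "seed: 7"), cfg)
  got <- read_config(cfg)
  expect_equal(got$params$sigma, 2.0)
  expect_equal(got$mode, "single_entity")
  expect_equal(got$seed, 7)
  writeLines("not_a_parameter: 1", cfg)
  expect_error(read_config(cfg), "unknown parameter")
  cfgj <- tempfile(fileext = ".json")
  writeLines('{"kappa": 6.6, "record_every": 5}', cfgj)
  expect_equal(read_config(cfgj)$params$kappa, 6.6)
  unlink(c(cfg, cfgj))
})

test_that("records round-trip through the on-disk layout", {
  sq <- square_arena(300,
                     rewards = data.frame(id = "R", x = 250, y = 150),
                     spawn_disks = data.frame(x = 60, y = 150, radius = 20))
  prm <- swarm_params(N = 2, N_s = 2, duration = 1, g_c = 0, g_r = 0.5,
                      g_s = 0.5, d_rad = 200)
  rec <- run_swarm(sq, prm, "multi_agent", seed = 1, record_every = 20)
  dir <- tempfile()
  write_record(rec, dir)
  back <- read_record(dir)
  expect_equal(back$config$seed, 1)
  expect_equal(back$config$params$d_rad, 200)
  nf <- length(rec$time)
  expect_equal(nrow(back$states), nf * (2 + 2))  # agents + fields per frame
  ag <- back$states[back$states$kind == "agent" & back$states$id == 1, ]
  expect_equal(ag$x, rec$x[, 1, 1], tolerance = 1e-12)
  expect_equal(nrow(back$captures), nrow(rec$captures))
  unlink(dir, recursive = TRUE)
})
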