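# Fixture arenas and independent oracles used across the suite.

square_arena <- function(side = 100, cues = NULL, rewards = NULL,
                         spawn_disks = NULL, holes = list(),
                         name = "square") {
  arena(rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)),
        hole_rings = holes, cues = cues, rewards = rewards,
        spawn_disks = spawn_disks, name = name)
}

# square split by a thin full-height divider (two almost-disconnected bays)
divided_arena <- function(side = 100) {
  square_arena(side,
               holes = list(rbind(c(side / 2 - 1, 1), c(side / 2 + 1, 1),
                                  c(side / 2 + 1, side - 1),
                                  c(side / 2 - 1, side - 1))),
               name = "divided")
}

# the single-reward arena used for ring-formation runs
single_reward_arena <- function(side = 500) {
  square_arena(side,
               cues = data.frame(id = paste0("c", 1:7),
                                 x = c(30, 470, 250, 30, 470, 130, 370) *
                                   side / 500,
                                 y = c(30, 30, 470, 250, 250, 470, 30) *
                                   side / 500),
               rewards = data.frame(id = "R", x = side / 2, y = side / 2),
               spawn_disks = data.frame(x = c(0.24, 0.76) * side,
                                        y = c(0.24, 0.76) * side,
                                        radius = 0.1 * side),
               name = "single_reward")
}

# --- independent oracles -------------------------------------------------

# allowable-area estimate by counting grid points at `res` spacing
raster_area <- function(arena, res = 1) {
  bb <- apply(arena$outer_ring, 2, range)
  gx <- seq(bb[1, 1] + res / 2, bb[2, 1], by = res)
  gy <- seq(bb[1, 2] + res / 2, bb[2, 2], by = res)
  gr <- as.matrix(expand.grid(gx, gy))
  sum(point_allowable(gr, arena)) * res^2
}

# number of connected components of the allowable interior, by flood fill
# over a grid of allowable cells (4-neighborhood)
grid_components <- function(arena, res = 8) {
  bb <- apply(arena$outer_ring, 2, range)
  gx <- seq(bb[1, 1] + res / 2, bb[2, 1], by = res)
  gy <- seq(bb[1, 2] + res / 2, bb[2, 2], by = res)
  nx <- length(gx); ny <- length(gy)
  gr <- cbind(rep(gx, times = ny), rep(gy, each = nx))
  ok <- matrix(point_allowable(gr, arena), nx, ny)
  lab <- matrix(0L, nx, ny)
  comp <- 0L
  for (start in which(ok & lab == 0L)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cx <- (cur - 1L) %% nx + 1L; cy <- (cur - 1L) %/% nx + 1L
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        mx <- cx + d[1]; my <- cy + d[2]
        if (mx < 1 || mx > nx || my < 1 || my > ny) next
        k <- (my - 1L) * nx + mx
        if (ok[k] && lab[k] == 0L) {
          lab[k] <- comp
          queue <- c(queue, k)
        }
      }
    }
  }
  comp
}

# line-of-sight by dense sampling of interior points along the chord
los_sampling_oracle <- function(a, b, arena, spacing = 0.1) {
  len <- sqrt(sum((b - a)^2))
  if (len == 0) return(TRUE)
  tt <- seq(0, 1, length.out = max(3, ceiling(len / spacing)))
  tt <- tt[-c(1, length(tt))]
  pts <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
  all(point_allowable(pts, arena))
}

# brute-force point-to-segment distance over all wall segments
wall_query_oracle <- function(p, arena) {
  segs <- arena$segments
  best <- Inf
  for (s in seq_len(nrow(segs))) {
    a <- segs[s, 1:2]; b <- segs[s, 3:4]
    e <- b - a; ee <- sum(e^2)
    t <- if (ee > 0) max(0, min(1, sum((p - a) * e) / ee)) else 0
    d <- sqrt(sum((p - a - t * e)^2))
    if (d < best) best <- d
  }
  best
}

# per-pair loop versions of the vectorized operations
oracle_net_inputs <- function(cmat, rmat, q, W, W_r, V_c, V_r, V, gains) {
  n <- nrow(V)
  I_c <- I_r <- I_q <- numeric(n)
  for (i in seq_len(n)) {
    nc <- sum(V_c[i, ]); nr <- sum(V_r[i, ]); nv <- sum(V[i, ])
    if (nc > 0) I_c[i] <- gains$g_c * sum(V_c[i, ] * cmat[i, ]) / nc
    if (nr > 0) I_r[i] <- gains$g_r * sum(W_r[i, ] * rmat[i, ]) / nr
    if (nv > 0) I_q[i] <- gains$g_s * sum(W[i, ] * q[i, ]) / nv
  }
  list(I_c = I_c, I_r = I_r, I_q = I_q)
}

oracle_oja_swarm <- function(W, p, q, V, eta, dt, mask = rep(1, nrow(W))) {
  out <- W
  for (i in seq_len(nrow(W)))
    for (j in seq_len(ncol(W)))
      out[i, j] <- W[i, j] +
        dt * eta * V[i, j] * mask[i] * p[i] * (q[i, j] - p[i] * W[i, j])
  out
}

oracle_swarm_offset <- function(D_prime, D, V, x) {
  n <- nrow(x)
  f <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    nv <- sum(V[i, ])
    if (nv == 0) next
    acc <- c(0, 0)
    for (j in seq_len(n)) {
      if (V[i, j] == 0) next
      u <- x[j, ] - x[i, ]
      nu <- sqrt(sum(u^2))
      if (nu == 0) next
      acc <- acc + (D[i, j] - D_prime[i, j]) * u / nu
    }
    f[i, ] <- acc / (2 * nv)
  }
  f
}

oracle_reward_offset <- function(D_r_prime, D_r, V_r, x, reward_xy) {
  n <- nrow(x)
  f <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    nv <- sum(V_r[i, ])
    if (nv == 0) next
    acc <- c(0, 0)
    for (k in seq_len(nrow(reward_xy))) {
      if (V_r[i, k] == 0) next
      u <- reward_xy[k, ] - x[i, ]
      nu <- sqrt(sum(u^2))
      if (nu == 0) next
      acc <- acc + (D_r[i, k] - D_r_prime[i, k]) * u / nu
    }
    f[i, ] <- acc / nv
  }
  f
}

oracle_guidance <- function(V_delta, p, x_s, x, dt) {
  num <- c(0, 0); den <- 0
  for (i in seq_along(p)) {
    w <- V_delta[i] * p[i]^3
    num <- num + w * (x_s[i, ] - x)
    den <- den + w
  }
  if (den <= 0) return(matrix(0, 1, 2))
  matrix(num / (dt * den), 1, 2)
}

# random coupled state with all invariants satisfied (for property tests)
random_state_matrices <- function(n, n_c = 3, n_r = 2, seed = 1) {
  set.seed(seed)
  x <- matrix(runif(2 * n, 10, 90), n, 2)
  D <- as.matrix(dist(x))
  V <- matrix(rbinom(n * n, 1, 0.7), n, n)
  V <- V * t(V); diag(V) <- 0L
  cmat <- matrix(runif(n * n_c), n, n_c)
  rmat <- matrix(runif(n * n_r), n, n_r)
  q <- matrix(runif(n * n, -1, 1), n, n)
  V_c <- matrix(rbinom(n * n_c, 1, 0.7), n, n_c)
  V_r <- matrix(rbinom(n * n_r, 1, 0.7), n, n_r)
  theta <- runif(n, 0, 2 * pi)
  p <- runif(n)
  list(x = x, D = D, V = V, cmat = cmat, rmat = rmat, q = q,
       V_c = V_c, V_r = V_r, theta = theta, p = p)
}
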