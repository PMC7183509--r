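# Metrics for the emergent phenomena: phase synchrony, reward-centered
# phase rings, capture statistics, trajectory coverage, and visibility
# clusters.

#' Kuramoto order parameter
#'
#' The modulus of the mean unit phasor, `Mod(mean(exp(1i * theta)))`, in
#' `[0, 1]`; equals 1 iff all phases coincide.
#'
#' @param theta phase vector, radians.
#' @return scalar order parameter.
#' @export
kuramoto_order <- function(theta) {
  stopifnot(length(theta) >= 1)
  Mod(mean(exp(1i * theta)))
}

#' Reward-centered phase-ring score
#'
#' Fisher-Lee circular-circular correlation between the bearing angle of
#' each unit about `center` and its oscillation phase, over units inside
#' the annulus `[r_min, r_max]`.  A phase-sorted ring (phase increasing
#' with bearing) scores +1; phase decreasing with bearing scores -1.  The
#' score is invariant to global phase rotation and to rigid rotation of
#' the positions about the center.  Fewer than 4 annulus members yields NA
#' (no-value, not an error).
#'
#' @param x unit positions (n x 2).
#' @param theta unit phases, radians.
#' @param center ring center (length 2).
#' @param r_min,r_max annulus radii, points.
#' @param n_perm if > 0, a permutation p-value for |score| is computed by
#'   shuffling phases against bearings.
#' @return list with `score`, `n` (annulus members), and `p_value` (NA
#'   unless `n_perm > 0`).
#' @export
ring_phase_score <- function(x, theta, center, r_min, r_max,
                             n_perm = 0L) {
  d <- sqrt((x[, 1] - center[1])^2 + (x[, 2] - center[2])^2)
  keep <- which(d >= r_min & d <= r_max)
  if (length(keep) < 4)
    return(list(score = NA_real_, n = length(keep), p_value = NA_real_))
  phi <- atan2(x[keep, 2] - center[2], x[keep, 1] - center[1])
  th <- theta[keep]
  score <- fisher_lee_cor(phi, th)
  p_val <- NA_real_
  if (n_perm > 0) {
    null <- replicate(n_perm, abs(fisher_lee_cor(phi, sample(th))))
    p_val <- (1 + sum(null >= abs(score))) / (n_perm + 1)
  }
  list(score = score, n = length(keep), p_value = p_val)
}

# Fisher-Lee circular-circular correlation over all pairs.
fisher_lee_cor <- function(a, b) {
  n <- length(a)
  da <- outer(a, a, "-"); db <- outer(b, b, "-")
  up <- upper.tri(da)
  num <- sum(sin(da[up]) * sin(db[up]))
  den <- sqrt(sum(sin(da[up])^2) * sum(sin(db[up])^2))
  if (den == 0) return(0)
  num / den
}

#' Capture statistics of a run
#'
#' First capture time of each reward (NA if never captured) and an
#' all-rewards success flag.
#'
#' @param record a `swarm_record`.
#' @return list with `times` (data.frame reward/time) and `success`.
#' @export
capture_statistics <- function(record) {
  ids <- record$reward_ids
  times <- rep(NA_real_, length(ids))
  if (nrow(record$captures) > 0) {
    first <- tapply(record$captures$time, record$captures$reward, min)
    times[match(names(first), ids)] <- as.numeric(first)
  }
  list(times = data.frame(reward = ids, time = times,
                          stringsAsFactors = FALSE),
       success = length(ids) > 0 && !anyNA(times))
}

#' Fraction of the allowable interior visited
#'
#' Grids the arena bounding box at `cell_size`, keeps cells whose centers
#' are allowable, and reports the fraction of those cells containing at
#' least one recorded agent position.
#'
#' @param record a `swarm_record` (agent trajectories are used).
#' @param arena the `swarm_arena` the record was produced in.
#' @param cell_size grid cell edge, points.
#' @return coverage fraction in `[0, 1]`.
#' @export
coverage <- function(record, arena, cell_size = 20) {
  stopifnot(cell_size > 0)
  bb <- apply(arena$outer_ring, 2, range)
  gx <- seq(bb[1, 1], bb[2, 1], by = cell_size)
  gy <- seq(bb[1, 2], bb[2, 2], by = cell_size)
  centers <- as.matrix(expand.grid(x = gx + cell_size / 2,
                                   y = gy + cell_size / 2))
  ok <- point_allowable(centers, arena)
  cell_of <- function(px, py)
    paste(findInterval(px, gx), findInterval(py, gy))
  total <- cell_of(centers[ok, 1], centers[ok, 2])
  nf <- length(record$time)
  ax <- as.vector(record$x[, , 1]); ay <- as.vector(record$x[, , 2])
  visited <- unique(cell_of(ax, ay))
  length(intersect(visited, unique(total))) / length(unique(total))
}

#' Visibility-graph cluster labels
#'
#' Connected components of the symmetric visibility graph.
#'
#' @param x unit positions (n x 2; used only for its row count).
#' @param V 0/1 visibility matrix.
#' @return integer component labels (a partition of the units).
#' @export
cluster_decomposition <- function(x, V) {
  g <- igraph::graph_from_adjacency_matrix(V != 0, mode = "max")
  as.integer(igraph::components(g)$membership)
}

#' Per-cluster frequency-locking score
#'
#' The standard deviation, within each cluster, of per-unit mean phase
#' velocities (rad/s, from unwrapped phase differences across recorded
#' frames).  0 means a perfect frequency lock.
#'
#' @param theta_history frames x units phase matrix, radians.
#' @param labels cluster labels from [cluster_decomposition()].
#' @param dt_frame time between recorded frames, s.
#' @return named numeric vector, one score per cluster label.
#' @export
frequency_locking <- function(theta_history, labels, dt_frame) {
  dth <- diff(theta_history)
  dth <- (dth + pi) %% (2 * pi) - pi  # unwrap
  omega <- colMeans(dth) / dt_frame
  vapply(split(omega, labels), stats::sd, 0)
}

#' Collinearity score of a point set
#'
#' `1 - lambda2 / lambda1` of the position covariance eigenvalues: 1 for
#' points on a line, 0 for an isotropic cloud.  Reported for descriptive
#' use (line-segment formations have no standard geometric threshold).
#'
#' @param x positions (n x 2), n >= 3.
#' @return scalar in `[0, 1]`.
#' @export
collinearity_score <- function(x) {
  if (nrow(x) < 3) return(NA_real_)
  ev <- eigen(stats::cov(x), symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) return(NA_real_)
  1 - ev[2] / ev[1]
}

#' Time-resolved structure report of a run
#'
#' For each recorded frame: the Kuramoto order parameter, the best
#' reward-centered ring score (over rewards, annulus
#' `annulus * notional radius`), the number of visibility clusters, and
#' the cumulative coverage fraction.
#'
#' @param record a `swarm_record`.
#' @param arena the arena the record was produced in.
#' @param params the parameters used (for the visibility range).
#' @param annulus inner/outer annulus radii as fractions of the notional
#'   radius.
#' @param cell_size coverage grid cell edge, points.
#' @return data.frame with one row per frame.
#' @export
structure_report <- function(record, arena, params = record$params,
                             annulus = c(0, 0.15), cell_size = 20) {
  R_not <- notional_radius(arena)
  rew <- arena$rewards
  nf <- length(record$time)
  out <- data.frame(time = record$time, kuramoto_r = NA_real_,
                    ring_score = NA_real_, n_clusters = NA_integer_)
  for (fr in seq_len(nf)) {
    th <- record$theta[fr, ]
    out$kuramoto_r[fr] <- kuramoto_order(th)
    pos <- matrix(record$x_s[fr, , ], ncol = 2)
    if (record$mode == "multi_agent") pos <- matrix(record$x[fr, , ],
                                                    ncol = 2)
    best <- NA_real_
    for (k in seq_len(nrow(rew))) {
      sc <- ring_phase_score(pos, th, c(rew$x[k], rew$y[k]),
                             annulus[1] * R_not, annulus[2] * R_not)
      if (!is.na(sc$score) && (is.na(best) || abs(sc$score) > abs(best)))
        best <- sc$score
    }
    out$ring_score[fr] <- best
    cpl <- refresh_geometry_couplings(pos, arena, params)
    out$n_clusters[fr] <- max(cluster_decomposition(pos, cpl$V))
  }
  out
}
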