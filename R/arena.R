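#' Construct a polygonal simulation arena
#'
#' An arena is a closed outer polygon with optional interior obstacle
#' polygons ("hole rings"), plus point-like sensory cues, point-like reward
#' locations, and circular initialization regions ("spawn disks").  All
#' coordinates are continuous 2-D Cartesian, y increasing upward, in
#' arbitrary length units referred to as points.  The allowable interior is
#' the set of locations inside the outer ring and outside every hole ring;
#' points exactly on a wall are not allowable.
#'
#' @param outer_ring numeric matrix (n x 2) of polygon vertices, in order,
#'   without repeating the first vertex.
#' @param hole_rings list of vertex matrices for interior obstacles.
#' @param cues data.frame with columns `id`, `x`, `y` (may have zero rows).
#' @param rewards data.frame with columns `id`, `x`, `y`.
#' @param spawn_disks data.frame with columns `x`, `y`, `radius`.
#' @param name character label for the arena.
#' @return An object of class `swarm_arena`.
#' @export
arena <- function(outer_ring, hole_rings = list(),
                  cues = NULL, rewards = NULL, spawn_disks = NULL,
                  name = "arena") {
  outer_ring <- as_ring(outer_ring)
  hole_rings <- lapply(hole_rings, as_ring)
  cues <- as_point_table(cues, "cue")
  rewards <- as_point_table(rewards, "reward")
  if (is.null(spawn_disks)) {
    spawn_disks <- data.frame(x = numeric(0), y = numeric(0),
                              radius = numeric(0))
  }
  a <- structure(
    list(outer_ring = outer_ring, hole_rings = hole_rings,
         cues = cues, rewards = rewards, spawn_disks = spawn_disks,
         name = name),
    class = "swarm_arena")
  a$segments <- ring_segments(c(list(outer_ring), hole_rings))
  validate_arena(a)
  a
}

as_ring <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (ncol(m) != 2 || nrow(m) < 3)
    stop("a polygon ring needs an n x 2 matrix with n >= 3", call. = FALSE)
  # drop a repeated closing vertex if present
  if (all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  dimnames(m) <- NULL
  m
}

as_point_table <- function(d, what) {
  if (is.null(d))
    return(data.frame(id = character(0), x = numeric(0), y = numeric(0),
                      stringsAsFactors = FALSE))
  d <- as.data.frame(d)
  if (!all(c("id", "x", "y") %in% names(d)))
    stop(sprintf("%s table needs columns id, x, y", what), call. = FALSE)
  d$id <- as.character(d$id)
  d[, c("id", "x", "y")]
}

# All wall segments (outer + holes) as an S x 4 matrix (x1,y1,x2,y2).
ring_segments <- function(rings) {
  segs <- lapply(rings, function(r) {
    n <- nrow(r)
    cbind(r, r[c(2:n, 1), , drop = FALSE])
  })
  do.call(rbind, segs)
}

# Signed shoelace area; magnitude returned.
polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Simplicity check: no two non-adjacent edges intersect.
ring_is_simple <- function(ring) {
  n <- nrow(ring)
  segs <- ring_segments(list(ring))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_intersect(segs[i, ], segs[j, ])) return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(s1, s2) {
  d1 <- s1[3:4] - s1[1:2]; d2 <- s2[3:4] - s2[1:2]
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  qp <- s2[1:2] - s1[1:2]
  if (den == 0) {
    if (qp[1] * d1[2] - qp[2] * d1[1] != 0) return(FALSE)
    rr <- sum(d1^2)
    if (rr == 0) return(FALSE)
    t0 <- sum(qp * d1) / rr
    t1 <- t0 + sum(d2 * d1) / rr
    lo <- min(t0, t1); hi <- max(t0, t1)
    return(hi >= 0 && lo <= 1)
  }
  t <- (qp[1] * d2[2] - qp[2] * d2[1]) / den
  u <- (qp[1] * d1[2] - qp[2] * d1[1]) / den
  t >= 0 && t <= 1 && u >= 0 && u <= 1
}

validate_arena <- function(a) {
  if (!ring_is_simple(a$outer_ring))
    stop("outer ring is self-intersecting", call. = FALSE)
  area <- polygon_area(a$outer_ring)
  for (h in a$hole_rings) area <- area - polygon_area(h)
  if (!is.finite(area) || area <= 0)
    stop("arena has non-positive allowable area", call. = FALSE)
  pts <- rbind(as.matrix(a$cues[, c("x", "y")]),
               as.matrix(a$rewards[, c("x", "y")]),
               as.matrix(a$spawn_disks[, c("x", "y")]))
  if (nrow(pts) > 0 && !all(point_allowable(pts, a)))
    stop("a cue, reward, or spawn-disk center lies outside the allowable interior",
         call. = FALSE)
  invisible(a)
}

#' @export
print.swarm_arena <- function(x, ...) {
  cat(sprintf("<swarm_arena '%s'>\n", x$name))
  cat(sprintf("  outer ring: %d vertices; holes: %d; wall segments: %d\n",
              nrow(x$outer_ring), length(x$hole_rings), nrow(x$segments)))
  cat(sprintf("  cues: %d  rewards: %d  spawn disks: %d\n",
              nrow(x$cues), nrow(x$rewards), nrow(x$spawn_disks)))
  cat(sprintf("  notional radius: %.2f points\n", notional_radius(x)))
  invisible(x)
}

#' Plot an arena
#'
#' @param x a `swarm_arena`.
#' @param ... passed to [graphics::plot].
#' @export
plot.swarm_arena <- function(x, ...) {
  close_ring <- function(r) rbind(r, r[1, ])
  o <- close_ring(x$outer_ring)
  graphics::plot(o, type = "l", asp = 1, xlab = "x (points)",
                 ylab = "y (points)", main = x$name, ...)
  for (h in x$hole_rings) graphics::polygon(close_ring(h), col = "grey30")
  if (nrow(x$spawn_disks) > 0) {
    th <- seq(0, 2 * pi, length.out = 64)
    for (i in seq_len(nrow(x$spawn_disks)))
      graphics::lines(x$spawn_disks$x[i] + x$spawn_disks$radius[i] * cos(th),
                      x$spawn_disks$y[i] + x$spawn_disks$radius[i] * sin(th),
                      lty = 2, col = "steelblue")
  }
  if (nrow(x$cues) > 0)
    graphics::points(x$cues$x, x$cues$y, pch = 17, col = "purple")
  if (nrow(x$rewards) > 0)
    graphics::points(x$rewards$x, x$rewards$y, pch = 8, col = "goldenrod")
  invisible(x)
}

#' Notional radius of an arena
#'
#' The radius of the disk whose area equals the arena's allowable interior
#' area (outer-ring area minus hole areas, by the shoelace formula).  The
#' scale-free model parameters (visibility range, kernel scales) are
#' multiplied by this length.
#'
#' @param arena a `swarm_arena`.
#' @return length in points.
#' @export
notional_radius <- function(arena) {
  area <- polygon_area(arena$outer_ring)
  for (h in arena$hole_rings) area <- area - polygon_area(h)
  if (area <= 0) stop("invalid arena: allowable area <= 0", call. = FALSE)
  sqrt(area / pi)
}

#' Test whether points lie in the allowable interior
#'
#' Even-odd rule over the outer ring and all hole rings; a point exactly on
#' a wall segment is not allowable.
#'
#' @param p numeric vector of length 2, or an n x 2 matrix of points.
#' @param arena a `swarm_arena`.
#' @return logical vector.
#' @export
point_allowable <- function(p, arena) {
  p <- to_points(p)
  cpp_points_allowable(p, c(list(arena$outer_ring), arena$hole_rings))
}

to_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  p
}

#' Line-of-sight test between two points
#'
#' True when the open segment between `a` and `b` crosses no wall segment.
#' To resolve grazing contacts (an endpoint exactly on a wall vertex), the
#' tested segment is shrunk inward at both ends by `eps` before
#' intersection testing.
#'
#' @param a,b positions (length-2 numeric vectors).
#' @param arena a `swarm_arena`.
#' @param eps inward endpoint nudge, points.
#' @return logical scalar.
#' @export
line_of_sight <- function(a, b, arena, eps = 1e-6) {
  v <- cpp_cross_vis(to_points(a), to_points(b), arena$segments, eps)
  v$V[1, 1] == 1L
}

#' Distance and inward normal of the nearest wall
#'
#' For each query point, the minimum point-to-segment distance over all
#' wall segments, and the unit vector from the nearest wall point toward
#' the query point (the interior-pointing normal for allowable points).
#' Equidistant walls are broken by the lowest segment index.
#'
#' @param p position or n x 2 matrix of positions.
#' @param arena a `swarm_arena`.
#' @return data.frame with columns `distance`, `nx`, `ny`, `segment`.
#' @export
wall_query <- function(p, arena) {
  q <- cpp_wall_query(to_points(p), arena$segments)
  data.frame(distance = q[, 1], nx = q[, 2], ny = q[, 3],
             segment = as.integer(q[, 4]))
}

# Uniform samples over the allowable interior (optionally restricted to a
# disk), by rejection from the bounding box / disk.
sample_allowable <- function(arena, n, center = NULL, radius = NULL,
                             max_tries = 10000L) {
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  bb <- apply(arena$outer_ring, 2, range)
  tries <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 16L)
    if (is.null(center)) {
      cand <- cbind(runif(m, bb[1, 1], bb[2, 1]), runif(m, bb[1, 2], bb[2, 2]))
    } else {
      r <- radius * sqrt(runif(m))
      th <- runif(m, 0, 2 * pi)
      cand <- cbind(center[1] + r * cos(th), center[2] + r * sin(th))
    }
    ok <- cpp_points_allowable(cand, c(list(arena$outer_ring), arena$hole_rings))
    keep <- which(ok)
    if (length(keep) > 0) {
      take <- keep[seq_len(min(length(keep), n - got))]
      out[(got + 1):(got + length(take)), ] <- cand[take, , drop = FALSE]
      got <- got + length(take)
    }
    tries <- tries + m
    if (tries > max_tries && got == 0L)
      stop("sampling region has empty allowable intersection", call. = FALSE)
    if (tries > 100L * max_tries)
      stop("rejection sampling failed to fill the request", call. = FALSE)
  }
  out
}
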