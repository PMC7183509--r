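# Parametric environment generators.  Both emit fully validated arenas and
# are bit-reproducible for a given seed; the caller's RNG state is restored
# on exit.

with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Seeded cue placement: allowable, away from walls, mutually separated.
place_cues <- function(a, n_cues, wall_margin = 25, min_sep = 60,
                       max_tries = 4000L) {
  pts <- matrix(NA_real_, 0, 2)
  tries <- 0L
  while (nrow(pts) < n_cues) {
    cand <- sample_allowable(a, 1L)
    tries <- tries + 1L
    if (tries > max_tries)
      stop("cue placement failed after bounded retries", call. = FALSE)
    if (wall_query(cand, a)$distance < wall_margin) next
    if (nrow(pts) > 0 &&
        min(sqrt(rowSums((pts - matrix(cand, nrow(pts), 2, byrow = TRUE))^2))) <
          min_sep) next
    pts <- rbind(pts, cand)
  }
  data.frame(id = paste0("cue", seq_len(n_cues)), x = pts[, 1], y = pts[, 2])
}

#' Generate a fragmented multi-reward arena
#'
#' A rectangular arena of roughly 500-point height whose outer wall carries
#' inward partial-wall protrusions that fragment it into a large central
#' region plus northwest, southwest, and southeast corner compartments.
#' Each corner compartment holds one reward; seven sensory cues are placed
#' at seeded random interior locations; three circular spawn disks
#' (southwest first, then center, then northeast) provide initialization
#' regions.
#'
#' @param seed integer seed controlling cue placement.
#' @param width,height outer dimensions in points.
#' @param wall_thickness thickness of the partial walls, points.
#' @param n_cues number of sensory cues.
#' @return a `swarm_arena`.
#' @export
make_multireward_arena <- function(seed = 0L, width = 700, height = 500,
                                   wall_thickness = 12, n_cues = 7L) {
  t <- wall_thickness
  W <- width; H <- height
  # counterclockwise outer ring with partial walls folded into the boundary
  ring <- rbind(
    c(0, 0),
    # bottom edge with two upward walls (SW and SE compartment dividers)
    c(260, 0), c(260, 120), c(260 + t, 120), c(260 + t, 0),
    c(430, 0), c(430, 120), c(430 + t, 120), c(430 + t, 0),
    c(W, 0),
    # right edge with one leftward wall (SE compartment ceiling)
    c(W, 178), c(500, 178), c(500, 178 + t), c(W, 178 + t),
    c(W, H),
    # top edge with one downward wall (NW compartment divider)
    c(260 + t, H), c(260 + t, 380), c(260, 380), c(260, H),
    c(0, H),
    # left edge with two rightward walls (NW floor, SW ceiling)
    c(0, 310 + t), c(200, 310 + t), c(200, 310), c(0, 310),
    c(0, 178 + t), c(200, 178 + t), c(200, 178), c(0, 178))
  rewards <- data.frame(
    id = c("NW", "SW", "SE"),
    x = c(70, 70, 630) * W / 700,
    y = c(430, 80, 80) * H / 500)
  spawn <- data.frame(
    x = c(110, 350, 600) * W / 700,
    y = c(90, 250, 420) * H / 500,
    radius = c(45, 50, 45))
  with_local_seed(seed, {
    a <- arena(ring, rewards = rewards, spawn_disks = spawn,
               name = "multireward")
    a$cues <- place_cues(a, n_cues)
    validate_arena(a)
    a
  })
}

#' Generate a hairpin maze
#'
#' A rectangle partitioned into parallel hallways by full-height divider
#' walls with alternating top/bottom gaps, so that the hallways form one
#' connected hairpin corridor.  Rewards are centered in the requested
#' hallways, spawn disks in a spread of hallways, and cues at seeded random
#' interior locations.
#'
#' @param width,height outer dimensions in points.
#' @param n_hallways number of hallways (>= 2).
#' @param rewards_in integer hallway indices (1-based from the left) that
#'   receive one reward each.
#' @param seed integer seed controlling cue placement.
#' @param wall_thickness divider thickness, points.
#' @param gap vertical extent of each divider gap; default 90% of the
#'   hallway width, capped at 150 points.
#' @param n_cues number of sensory cues.
#' @param n_spawn number of spawn disks.
#' @param min_clearance smallest acceptable hallway width, points.
#' @return a `swarm_arena`.
#' @export
make_hairpin_maze <- function(width = 885, height = 519, n_hallways = 5L,
                              rewards_in = c(1L, 3L, 5L), seed = 0L,
                              wall_thickness = 12, gap = NULL,
                              n_cues = 7L, n_spawn = 4L,
                              min_clearance = 30) {
  if (n_hallways < 2) stop("n_hallways must be >= 2", call. = FALSE)
  t <- wall_thickness
  W <- width; H <- height
  nd <- n_hallways - 1L
  hall_w <- (W - nd * t) / n_hallways
  if (hall_w < min_clearance)
    stop("hallway width below agent-clearance threshold", call. = FALSE)
  if (is.null(gap)) gap <- min(150, 0.9 * hall_w)
  x_left <- function(i) i * hall_w + (i - 1) * t   # divider i left face
  bottom_dividers <- which(seq_len(nd) %% 2L == 1L)  # gap at top
  top_dividers <- which(seq_len(nd) %% 2L == 0L)     # gap at bottom
  ring <- matrix(c(0, 0), 1, 2)
  for (i in bottom_dividers) {
    xl <- x_left(i)
    ring <- rbind(ring, c(xl, 0), c(xl, H - gap), c(xl + t, H - gap),
                  c(xl + t, 0))
  }
  ring <- rbind(ring, c(W, 0), c(W, H))
  for (i in rev(top_dividers)) {
    xl <- x_left(i)
    ring <- rbind(ring, c(xl + t, H), c(xl + t, gap), c(xl, gap), c(xl, H))
  }
  ring <- rbind(ring, c(0, H))
  hall_cx <- (seq_len(n_hallways) - 1) * (hall_w + t) + hall_w / 2
  if (any(rewards_in < 1 | rewards_in > n_hallways))
    stop("rewards_in indices out of range", call. = FALSE)
  reward_y <- seq(0.2, 0.8, length.out = max(length(rewards_in), 2))[
    seq_along(rewards_in)] * H
  rewards <- data.frame(id = paste0("R", seq_along(rewards_in)),
                        x = hall_cx[rewards_in], y = reward_y)
  spawn_in <- unique(round(seq(1, n_hallways, length.out = n_spawn)))
  spawn <- data.frame(x = hall_cx[spawn_in], y = H / 2,
                      radius = min(60, 0.35 * hall_w))
  with_local_seed(seed, {
    a <- arena(ring, rewards = rewards, spawn_disks = spawn, name = "hairpin")
    a$cues <- place_cues(a, n_cues)
    validate_arena(a)
    a
  })
}
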