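# Arena exchange format: a small JSON dialect.  Round trips are lossless to
# full double precision (written with digits = NA).

#' Write an arena to JSON
#'
#' @param arena a `swarm_arena`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_arena <- function(arena, path) {
  ring_to_list <- function(r) lapply(seq_len(nrow(r)),
                                     function(i) c(r[i, 1], r[i, 2]))
  pts_to_list <- function(d) lapply(seq_len(nrow(d)), function(i)
    list(id = d$id[i], x = d$x[i], y = d$y[i]))
  disks_to_list <- function(d) lapply(seq_len(nrow(d)), function(i)
    list(x = d$x[i], y = d$y[i], radius = d$radius[i]))
  obj <- list(
    name = arena$name,
    outer_ring = ring_to_list(arena$outer_ring),
    hole_rings = lapply(arena$hole_rings, ring_to_list),
    cues = pts_to_list(arena$cues),
    rewards = pts_to_list(arena$rewards),
    spawn_disks = disks_to_list(arena$spawn_disks))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an arena from JSON
#'
#' @param path file written by [write_arena()] (or hand-authored in the
#'   same dialect).
#' @return a validated `swarm_arena`.
#' @export
read_arena <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  list_to_ring <- function(l)
    do.call(rbind, lapply(l, function(p) c(p[[1]], p[[2]])))
  list_to_pts <- function(l) {
    if (length(l) == 0)
      return(data.frame(id = character(0), x = numeric(0), y = numeric(0)))
    data.frame(id = vapply(l, function(p) as.character(p$id), ""),
               x = vapply(l, function(p) as.numeric(p$x), 0),
               y = vapply(l, function(p) as.numeric(p$y), 0))
  }
  list_to_disks <- function(l) {
    if (length(l) == 0)
      return(data.frame(x = numeric(0), y = numeric(0), radius = numeric(0)))
    data.frame(x = vapply(l, function(p) as.numeric(p$x), 0),
               y = vapply(l, function(p) as.numeric(p$y), 0),
               radius = vapply(l, function(p) as.numeric(p$radius), 0))
  }
  arena(list_to_ring(obj$outer_ring),
        hole_rings = lapply(obj$hole_rings, list_to_ring),
        cues = list_to_pts(obj$cues),
        rewards = list_to_pts(obj$rewards),
        spawn_disks = list_to_disks(obj$spawn_disks),
        name = if (is.null(obj$name)) "arena" else obj$name)
}
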