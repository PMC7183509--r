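# On-disk form of a simulation record: a directory with a JSON config
# snapshot, a long per-frame state table, and a capture-events table.

#' Write a simulation record to a directory
#'
#' Creates `dir` containing `config.json` (parameters, mode, seed,
#' cadence), `states.csv` (one row per recorded frame and entity; physical
#' agents carry velocity, internal fields/particles carry phase and
#' activation), and `captures.csv`.
#'
#' @param record a `swarm_record`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_record <- function(record, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(params = unclass(record$params), mode = record$mode,
              seed = record$seed, record_every = record$record_every,
              arena = record$arena_name, steps_run = record$steps_run,
              reward_ids = record$reward_ids)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  nf <- length(record$time)
  N <- dim(record$x)[2]; N_s <- ncol(record$theta)
  agents <- data.frame(
    time = rep(record$time, each = N),
    kind = "agent",
    id = rep(seq_len(N), nf),
    x = as.vector(t(matrix(record$x[, , 1], nrow = nf))),
    y = as.vector(t(matrix(record$x[, , 2], nrow = nf))),
    vx = as.vector(t(matrix(record$v[, , 1], nrow = nf))),
    vy = as.vector(t(matrix(record$v[, , 2], nrow = nf))),
    theta = NA_real_, p = NA_real_)
  fields <- data.frame(
    time = rep(record$time, each = N_s),
    kind = "field",
    id = rep(seq_len(N_s), nf),
    x = as.vector(t(matrix(record$x_s[, , 1], nrow = nf))),
    y = as.vector(t(matrix(record$x_s[, , 2], nrow = nf))),
    vx = NA_real_, vy = NA_real_,
    theta = as.vector(t(record$theta)),
    p = as.vector(t(record$p)))
  states <- rbind(agents, fields)
  states <- states[order(states$time, states$kind, states$id), ]
  write.csv(states, file.path(dir, "states.csv"), row.names = FALSE)
  write.csv(record$captures, file.path(dir, "captures.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a simulation record directory
#'
#' @param dir directory written by [write_record()].
#' @return list with `config`, `states` (data.frame), `captures`
#'   (data.frame).
#' @export
read_record <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  states <- read.csv(file.path(dir, "states.csv"),
                     stringsAsFactors = FALSE)
  cap_path <- file.path(dir, "captures.csv")
  captures <- if (file.exists(cap_path) && file.size(cap_path) > 1)
    read.csv(cap_path, stringsAsFactors = FALSE)
  else data.frame(reward = character(0), agent = integer(0),
                  time = numeric(0))
  list(config = cfg, states = states, captures = captures)
}
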