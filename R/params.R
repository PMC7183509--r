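#' Model parameters for the swarming controller
#'
#' Returns the full parameter set with its default values; any parameter
#' can be overridden by name.  Scale-free lengths (`D_max`, `sigma`,
#' `kappa`) are expressed as multiples of the arena's notional radius (see
#' [notional_radius()]) and converted to points at run time;
#' `d_rad` and `lambda_wall` are absolute lengths in points.  Oscillation
#' frequencies are in cycles/s and converted to radians internally.
#'
#' @param ... named overrides of the defaults listed below.
#'
#' @details Defaults:
#' \describe{
#'   \item{dt}{0.01 s, integration time step.}
#'   \item{duration}{180 s, total simulated time.}
#'   \item{N}{300, physical agents (multi-agent mode); 1 in single-entity
#'     mode.}
#'   \item{N_s}{300, internal fields (multi-agent) or virtual particles
#'     (single-entity).}
#'   \item{D_max}{1.0, max inter-agent visibility range (x notional
#'     radius).}
#'   \item{E_max}{3e3 kg points^2/s^2, max kinetic energy.}
#'   \item{mu}{0.9, momentum coefficient of agent motion.}
#'   \item{m_mean_multi}{0.3 kg, mean agent mass (multi-agent).}
#'   \item{m_single}{3.0 kg, agent mass (single-entity).}
#'   \item{sigma}{1.0, spatial scale of swarm interaction (x notional
#'     radius).}
#'   \item{kappa}{1.0, spatial scale of reward interaction (x notional
#'     radius).}
#'   \item{eta, eta_r}{1.0, learning rates for swarm / reward connections.}
#'   \item{omega0}{0.0 cycles/s, baseline oscillation frequency.}
#'   \item{omegaI}{1.0 cycles/s, max activation-driven frequency increase.}
#'   \item{g_c, g_r, g_s}{0.4 / 0.2 / 0.4, input gains for cues, rewards,
#'     and recurrent swarming; they must sum to 1.}
#'   \item{tau_c, tau_r, tau_q}{0.5 / 0.5 / 0.1 s, input time constants.}
#'   \item{d_rad}{0.0 points, reward contact radius; values <= 0 disable
#'     reward capture (rewards stay attractive).}
#'   \item{alpha}{0.5, mixing weight of swarm vs. reward offsets.}
#'   \item{lambda_wall}{20 points, wall-proximity kernel constant.}
#'   \item{w_clamp_min}{1e-6, weight clamp floor that keeps the kernel
#'     inversions finite; clamped values encode saturated repulsion.}
#'   \item{sign_convention}{"functional" (approach a neighbor when the
#'     desired distance is below the actual one) or "as_printed".}
#'   \item{kernel_inverse}{"exact" (strict inverse of the Gaussian swarm
#'     kernel) or "sqrt2" (retains an extra sqrt(2) scale).}
#'   \item{mass_jitter}{0.5, half-width of the uniform relative mass spread
#'     around `m_mean_multi` (0 gives identical masses).}
#'   \item{freeze_invisible_particles}{TRUE; in single-entity mode,
#'     particles out of the agent's line of sight receive zero positional
#'     offset in addition to having their learning masked.}
#'   \item{eps_los}{1e-6 points, inward nudge for line-of-sight tests.}
#' }
#' @return an object of class `swarm_params` (a named list).
#' @export
swarm_params <- function(...) {
  p <- list(
    dt = 0.01, duration = 180, N = 300L, N_s = 300L,
    D_max = 1.0, E_max = 3e3, mu = 0.9,
    m_mean_multi = 0.3, m_single = 3.0,
    sigma = 1.0, kappa = 1.0, eta = 1.0, eta_r = 1.0,
    omega0 = 0.0, omegaI = 1.0,
    g_c = 0.4, g_r = 0.2, g_s = 0.4,
    tau_c = 0.5, tau_r = 0.5, tau_q = 0.1,
    d_rad = 0.0, alpha = 0.5, lambda_wall = 20,
    w_clamp_min = 1e-6,
    sign_convention = "functional",
    kernel_inverse = "exact",
    mass_jitter = 0.5,
    freeze_invisible_particles = TRUE,
    eps_los = 1e-6)
  over <- list(...)
  if (length(over) > 0) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("all parameter overrides must be named", call. = FALSE)
    unknown <- setdiff(names(over), names(p))
    if (length(unknown) > 0)
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(over)] <- over
  }
  p$N <- as.integer(p$N); p$N_s <- as.integer(p$N_s)
  validate_params(structure(p, class = "swarm_params"))
}

validate_params <- function(p) {
  stopifnot(p$dt > 0, p$duration > 0, p$N >= 1, p$N_s >= 1)
  if (abs(p$g_c + p$g_r + p$g_s - 1) > 1e-9)
    stop("input gains g_c + g_r + g_s must sum to 1", call. = FALSE)
  if (p$mu < 0 || p$mu > 1) stop("mu must be in [0, 1]", call. = FALSE)
  if (p$alpha < 0 || p$alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  if (any(c(p$tau_c, p$tau_r, p$tau_q) <= 0))
    stop("time constants must be positive", call. = FALSE)
  if (p$dt >= min(p$tau_c, p$tau_r, p$tau_q))
    stop("dt must be smaller than every input time constant", call. = FALSE)
  if (p$w_clamp_min <= 0 || p$w_clamp_min >= 1)
    stop("w_clamp_min must lie strictly between 0 and 1", call. = FALSE)
  if (!p$sign_convention %in% c("functional", "as_printed"))
    stop("sign_convention must be 'functional' or 'as_printed'", call. = FALSE)
  if (!p$kernel_inverse %in% c("exact", "sqrt2"))
    stop("kernel_inverse must be 'exact' or 'sqrt2'", call. = FALSE)
  if (p$sigma <= 0 || p$kappa <= 0 || p$E_max <= 0)
    stop("sigma, kappa, E_max must be positive", call. = FALSE)
  p
}

#' @export
print.swarm_params <- function(x, ...) {
  cat("<swarm_params>\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read a run configuration file
#'
#' Reads a YAML or JSON file whose keys match [swarm_params()] field names,
#' plus the optional reserved keys `mode`, `seed`, and `record_every`.
#' Unknown keys are errors.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return a list with elements `params` (a `swarm_params`), `mode`,
#'   `seed`, `record_every` (the latter three may be NULL if absent).
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  # keep YAML-1.1 boolean-like keys (N, y, no, ...) as literal strings
  keep_bool_keys <- list("bool#yes" = function(x)
                           if (x %in% c("true", "True", "TRUE")) TRUE else x,
                         "bool#no" = function(x)
                           if (x %in% c("false", "False", "FALSE")) FALSE
                           else x)
  raw <- if (ext %in% c("yaml", "yml"))
           yaml::read_yaml(path, handlers = keep_bool_keys)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("config must be .yaml, .yml, or .json", call. = FALSE)
  reserved <- c("mode", "seed", "record_every")
  extra <- raw[intersect(names(raw), reserved)]
  prm <- raw[setdiff(names(raw), reserved)]
  params <- do.call(swarm_params, prm)
  list(params = params,
       mode = extra$mode, seed = extra$seed,
       record_every = extra$record_every)
}
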