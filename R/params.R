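#' Global heading/speed dynamics parameters
#'
#' Constants of the heading-direction dynamic (damping, goal attraction,
#' obstacle repulsion and their distance/angle decays) and the speed
#' relaxation time constant. These are shared across interaction classes;
#' the per-class variation lives in [agent_speed_params()].
#'
#' @param b heading damping coefficient (1/time), `b >= 0`.
#' @param k_g goal attraction gain (1/time^2).
#' @param k_o obstacle repulsion gain (1/time^2). Default 0: the bundled
#'   interaction classes define no repulsion parameters.
#' @param c1 attraction distance-decay rate (1/length), `c1 >= 0`.
#' @param c2 distance-independent attraction floor (dimensionless).
#' @param c3 repulsion angular-decay rate (1/radian), `c3 >= 0`.
#' @param c4 repulsion distance-decay rate (1/length), `c4 >= 0`.
#' @param tau speed relaxation time constant (time), `tau > 0`.
#'
#' @return An object of class `global_dynamics_params` (a named list).
#' @seealso [heading_acceleration()], [step_agent()], [load_global_config()]
#' @export
#' @examples
#' global_dynamics_params()
global_dynamics_params <- function(b = 3.25, k_g = 7.5, k_o = 0,
                                   c1 = 0.4, c2 = 0.4, c3 = 6.5, c4 = 0.8,
                                   tau = 0.5) {
  p <- list(b = b, k_g = k_g, k_o = k_o, c1 = c1, c2 = c2, c3 = c3,
            c4 = c4, tau = tau)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("global dynamics parameter '", nm, "' must be a finite scalar")
  }
  if (b < 0) stop("b must be >= 0")
  if (tau <= 0) stop("tau must be > 0")
  if (c1 < 0 || c3 < 0 || c4 < 0) stop("c1, c3, c4 must be >= 0")
  structure(p, class = "global_dynamics_params")
}

#' Per-agent speed-drive parameters
#'
#' Parameters of the distance-dependent speed drive
#' \eqn{F(d) = c_5 / (1 + e^{-c_6 (d - c_7)}) - c_8 e^{-k d} + c_9}
#' and the noise gain of the stochastic speed dynamic. One bundle per
#' agent; the rows of the bundled interaction-class catalog are pairs of
#' these.
#'
#' @param k exponential decay rate of the `c8` term (1/length), `k >= 0`.
#' @param k_eps additive speed-noise gain (speed units), `k_eps >= 0`.
#' @param c5 sigmoid amplitude (speed units).
#' @param c6 sigmoid steepness (1/length), `c6 >= 0`.
#' @param c7 sigmoid midpoint distance (length).
#' @param c8 exponential-term amplitude (speed units).
#' @param c9 baseline speed offset (speed units).
#'
#' @return An object of class `agent_speed_params` (a named list).
#' @seealso [speed_drive()], [interaction_catalog()]
#' @export
#' @examples
#' # agent 1 of the "Chasing" class: sigmoid midpoint at distance 7
#' agent_speed_params(c5 = 1, c6 = 10, c7 = 7)
agent_speed_params <- function(k = 0, k_eps = 0, c5 = 0, c6 = 0, c7 = 0,
                               c8 = 0, c9 = 0) {
  p <- list(k = k, k_eps = k_eps, c5 = c5, c6 = c6, c7 = c7, c8 = c8,
            c9 = c9)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("speed parameter '", nm, "' must be a finite scalar")
  }
  if (k < 0) stop("k must be >= 0")
  if (k_eps < 0) stop("k_eps must be >= 0")
  if (c6 < 0) stop("c6 must be >= 0")
  structure(p, class = "agent_speed_params")
}

#' Instantaneous state of one agent
#'
#' Position, heading direction (wrapped to `(-pi, pi]`), heading angular
#' velocity and signed propagation speed. Negative speed means the agent
#' retreats along its heading (several interaction classes rely on this).
#'
#' @param x,y position (length units).
#' @param phi heading direction (radians); wrapped on construction.
#' @param phi_dot heading angular velocity (radians/time).
#' @param s signed propagation speed (length/time).
#'
#' @return An object of class `agent_state` (a named list).
#' @seealso [step_agent()]
#' @export
agent_state <- function(x, y, phi, phi_dot = 0, s = 0) {
  st <- list(x = x, y = y, phi = phi, phi_dot = phi_dot, s = s)
  for (nm in names(st)) {
    v <- st[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("state field '", nm, "' must be a finite scalar")
  }
  st$phi <- wrap_angle(phi)
  structure(st, class = "agent_state")
}

#' Goal context of an agent
#'
#' Direction and distance from the agent to its current goal (a via
#' point for agent 1, the other agent's position for agent 2).
#'
#' @param psi_g direction from agent to goal (radians); wrapped.
#' @param d_g Euclidean distance to the goal (length), `d_g >= 0`.
#' @return An object of class `goal_context`.
#' @export
goal_context <- function(psi_g, d_g) {
  if (!is.finite(psi_g) || !is.finite(d_g)) stop("goal context must be finite")
  if (d_g < 0) stop("d_g must be >= 0")
  structure(list(psi_g = wrap_angle(psi_g), d_g = d_g),
            class = "goal_context")
}

#' Goal context from two points
#'
#' @param pos agent position, numeric length-2 `(x, y)`.
#' @param target goal position, numeric length-2.
#' @return A [goal_context()].
#' @export
goal_context_from <- function(pos, target) {
  dx <- target[1] - pos[1]
  dy <- target[2] - pos[2]
  goal_context(atan2(dy, dx), sqrt(dx * dx + dy * dy))
}

#' Obstacle context of an agent
#'
#' Directions and distances of the obstacles currently repelling the
#' agent's heading. Empty by default; the bundled classes use none.
#'
#' @param psi_o directions to obstacles (radians).
#' @param d_o distances to obstacles (length), all `>= 0`.
#' @return An object of class `obstacle_context`.
#' @export
obstacle_context <- function(psi_o = numeric(0), d_o = numeric(0)) {
  if (length(psi_o) != length(d_o))
    stop("psi_o and d_o must have equal length")
  if (length(d_o) && (any(!is.finite(psi_o)) || any(!is.finite(d_o))))
    stop("obstacle context must be finite")
  if (any(d_o < 0)) stop("all obstacle distances must be >= 0")
  structure(list(psi_o = as.numeric(psi_o), d_o = as.numeric(d_o),
                 count = length(d_o)),
            class = "obstacle_context")
}

#' Read global dynamics parameters and integration settings from JSON
#'
#' The config file holds the fields of [global_dynamics_params()] plus an
#' optional integration step `dt`, all under their own names.
#'
#' @param path JSON file; defaults to the bundled configuration.
#' @return A list with elements `params` ([global_dynamics_params()]) and
#'   `dt` (numeric or `NULL`).
#' @export
load_global_config <- function(path = system.file("extdata",
                                                  "global_dynamics.json",
                                                  package = "dyadsim")) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  want <- c("b", "k_g", "k_o", "c1", "c2", "c3", "c4", "tau")
  missing <- setdiff(want, names(cfg))
  if (length(missing))
    stop("global config is missing key(s): ", paste(missing, collapse = ", "))
  list(params = do.call(global_dynamics_params, cfg[want]),
       dt = if ("dt" %in% names(cfg)) as.numeric(cfg$dt) else NULL)
}
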