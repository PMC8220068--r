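#' Wrap an angle to (-pi, pi]
#'
#' Angular errors in the heading dynamics are always wrapped before they
#' multiply anything, otherwise the attraction and repulsion terms would
#' be discontinuous at crossings of +/- pi.
#'
#' @param theta angle(s) in radians; must be finite.
#' @return `theta` modulo `2*pi`, mapped into `(-pi, pi]`.
#' @export
#' @examples
#' wrap_angle(3 * pi)   # pi
#' wrap_angle(-pi)      # pi (half-open convention)
wrap_angle <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta)))
    stop("theta must be finite")
  theta - 2 * pi * ceiling((theta - pi) / (2 * pi))
}

#' Goal attraction term of the heading dynamics
#'
#' Angular acceleration pulling the heading toward the goal direction:
#' \eqn{A = -k_g \, \Delta \, (e^{-c_1 d_g} + c_2)} with
#' \eqn{\Delta = \mathrm{wrap}(\phi - \psi_g)}. The attraction stiffens
#' as the goal gets closer (the exponential) but never vanishes at long
#' range (the `c2` floor).
#'
#' @param phi current heading (radians).
#' @param goal a [goal_context()].
#' @param p a [global_dynamics_params()].
#' @return Angular acceleration (radians/time^2).
#' @export
attraction <- function(phi, goal, p) {
  delta <- wrap_angle(phi - goal$psi_g)
  -p$k_g * delta * (exp(-p$c1 * goal$d_g) + p$c2)
}

#' Obstacle repulsion term of the heading dynamics
#'
#' Each obstacle pushes the heading away from its own direction with a
#' strength that decays both in angular separation (rate `c3`) and in
#' distance (rate `c4`); contributions sum over obstacles and are scaled
#' by the gain `k_o`.
#'
#' @param phi current heading (radians).
#' @param obstacles an [obstacle_context()].
#' @param p a [global_dynamics_params()].
#' @return Angular acceleration (radians/time^2); 0 for an empty context.
#' @export
repulsion <- function(phi, obstacles, p) {
  if (obstacles$count == 0L) return(0)
  delta <- wrap_angle(phi - obstacles$psi_o)
  p$k_o * sum(delta * exp(-p$c3 * abs(delta)) * exp(-p$c4 * obstacles$d_o))
}

#' Heading angular acceleration
#'
#' The full second-order heading dynamic: damping plus goal attraction
#' plus obstacle repulsion,
#' \eqn{\ddot\phi = -b \dot\phi + A(\phi, \psi_g) + R(\phi, \psi_o)}.
#'
#' @param state an [agent_state()].
#' @param goal a [goal_context()].
#' @param obstacles an [obstacle_context()].
#' @param p a [global_dynamics_params()].
#' @return Angular acceleration (radians/time^2).
#' @export
heading_acceleration <- function(state, goal, obstacles, p) {
  -p$b * state$phi_dot + attraction(state$phi, goal, p) +
    repulsion(state$phi, obstacles, p)
}

#' Distance-dependent speed drive F(d)
#'
#' The target speed the stochastic speed dynamic relaxes toward:
#' \eqn{F(d) = c_5/(1 + e^{-c_6 (d - c_7)}) - c_8 e^{-k d} + c_9}.
#' The sigmoid/exponential mixture is flexible enough to express
#' pursuit (speed up when far), retreat (negative F at short range) and
#' constant-speed travel, which is what distinguishes the interaction
#' classes. The value may be negative: negative speed is retreat and is
#' deliberately not clamped.
#'
#' @param d distance to the goal (length), `d >= 0`. Vectorized.
#' @param sp an [agent_speed_params()].
#' @return Drive value(s) in speed units.
#' @export
#' @examples
#' # Chasing, agent 1: sigmoid midpoint at d = 7 gives F = 0.5
#' speed_drive(7, agent_speed_params(c5 = 1, c6 = 10, c7 = 7))
speed_drive <- function(d, sp) {
  if (!is.numeric(d) || any(!is.finite(d))) stop("d must be finite")
  if (any(d < 0)) stop("d must be >= 0")
  sp$c5 / (1 + exp(-sp$c6 * (d - sp$c7))) - sp$c8 * exp(-sp$k * d) + sp$c9
}

# Core one-step update on bare scalars; shared by step_agent() and the
# trajectory-generation loop. Explicit Euler on (phi, phi_dot),
# Euler-Maruyama on s, unicycle kinematics on (x, y). Returns
# c(x, y, phi, phi_dot, s).
.step_values <- function(x, y, phi, phi_dot, s, psi_g, d_g,
                         psi_o, d_o, p, sp, dt, noise) {
  acc <- -p$b * phi_dot -
    p$k_g * wrap_angle(phi - psi_g) * (exp(-p$c1 * d_g) + p$c2)
  if (length(d_o)) {
    delta <- wrap_angle(phi - psi_o)
    acc <- acc +
      p$k_o * sum(delta * exp(-p$c3 * abs(delta)) * exp(-p$c4 * d_o))
  }
  drive <- sp$c5 / (1 + exp(-sp$c6 * (d_g - sp$c7))) -
    sp$c8 * exp(-sp$k * d_g) + sp$c9
  c(x + dt * s * cos(phi),
    y + dt * s * sin(phi),
    wrap_angle(phi + dt * phi_dot),
    phi_dot + dt * acc,
    s + (dt / p$tau) * (drive - s) + (sp$k_eps / p$tau) * sqrt(dt) * noise)
}

#' Advance one agent by one integration step
#'
#' Discretizes the continuous dynamics with the simplest scheme
#' consistent with a first-order SDE: explicit Euler for the heading
#' system, Euler-Maruyama for the speed
#' (`s' = s + (dt/tau) * (F(d_g) - s) + (k_eps/tau) * sqrt(dt) * z`),
#' and unicycle kinematics for position
#' (`x' = x + dt * s * cos(phi)`, `y' = y + dt * s * sin(phi)`).
#' The update is fully explicit (all right-hand sides use the incoming
#' state) and the returned heading is re-wrapped. Speed never sees the
#' obstacle context: only the heading dynamic does.
#'
#' @param state an [agent_state()].
#' @param goal a [goal_context()].
#' @param obstacles an [obstacle_context()]; empty by default.
#' @param p a [global_dynamics_params()].
#' @param sp an [agent_speed_params()].
#' @param dt integration step (time), `dt > 0`.
#' @param noise_draw a standard-normal deviate driving the speed noise;
#'   pass 0 for a deterministic step.
#' @return The advanced [agent_state()].
#' @export
step_agent <- function(state, goal, obstacles = obstacle_context(),
                       p, sp, dt, noise_draw = 0) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a positive finite scalar")
  if (!is.finite(noise_draw)) stop("noise_draw must be finite")
  v <- .step_values(state$x, state$y, state$phi, state$phi_dot, state$s,
                    goal$psi_g, goal$d_g, obstacles$psi_o, obstacles$d_o,
                    p, sp, dt, noise_draw)
  agent_state(x = v[1], y = v[2], phi = v[3], phi_dot = v[4], s = v[5])
}
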