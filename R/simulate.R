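#' Simulation configuration
#'
#' Arena geometry, integration settings and the via-point process
#' controls for trajectory-pair generation.
#'
#' @param arena arena bounds as `c(xmin, xmax, ymin, ymax)` (length
#'   units); must have positive area. Default a 20 x 20 square centred
#'   at the origin.
#' @param dt integration step (time). Default 0.01.
#' @param duration total simulated time. Default 10.
#' @param via_min_dist minimum distance of a freshly sampled via point
#'   from agent 1's current position; closer samples are rejected.
#' @param via_capture_radius distance at which the current via point
#'   counts as reached and a new one is drawn.
#' @param seed integer RNG seed; every random element of a run (initial
#'   conditions, via points, speed noise) derives from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(arena = c(-10, 10, -10, 10), dt = 0.01,
                              duration = 10, via_min_dist = 5,
                              via_capture_radius = 0.5, seed = 1L) {
  if (length(arena) != 4L || any(!is.finite(arena)) ||
      arena[2] <= arena[1] || arena[4] <= arena[3])
    stop("arena must be c(xmin, xmax, ymin, ymax) with positive area")
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.finite(via_min_dist) || via_min_dist < 0)
    stop("via_min_dist must be >= 0")
  if (!is.finite(via_capture_radius) || via_capture_radius < 0)
    stop("via_capture_radius must be >= 0")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  structure(list(arena = as.numeric(arena), dt = dt, duration = duration,
                 via_min_dist = via_min_dist,
                 via_capture_radius = via_capture_radius, seed = seed),
            class = "simulation_config")
}

#' Derive a child RNG seed from a base seed and integer keys
#'
#' Deterministic multiplicative-congruential mixing modulo 2^31 - 1, so
#' every (class, realization) pair of a dataset gets its own
#' reproducible seed below 2^31.
#'
#' @param seed base integer seed.
#' @param ... integer keys (e.g. class index, realization index).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  keys <- c(as.numeric(seed), vapply(list(...), as.numeric, numeric(1)))
  if (any(!is.finite(keys))) stop("seed and keys must be finite")
  x <- 0
  for (k in keys) x <- (x * 48271 + k + 11) %% 2147483647
  as.integer(x)
}

# Draw n standard normals from a private stream without disturbing the
# caller's RNG state.
.seeded_normals <- function(seed, n) {
  has <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (has) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  stats::rnorm(n)
}

#' Sample a via point for agent 1
#'
#' Uniform over the arena, conditioned by rejection on lying at least
#' `via_min_dist` from the agent's current position.
#'
#' @param current_pos numeric length-2 current position of agent 1.
#' @param config a [simulation_config()].
#' @param max_attempts rejection-sampling budget before the
#'   configuration is declared degenerate.
#' @return Numeric length-2 via point. Uses (and advances) the current
#'   R RNG stream; seed it for reproducibility.
#' @export
sample_via_point <- function(current_pos, config, max_attempts = 1000L) {
  a <- config$arena
  for (i in seq_len(max_attempts)) {
    pt <- c(stats::runif(1, a[1], a[2]), stats::runif(1, a[3], a[4]))
    if (sqrt(sum((pt - current_pos)^2)) >= config$via_min_dist)
      return(pt)
  }
  stop("degenerate configuration: no via point at distance >= ",
       config$via_min_dist, " found in ", max_attempts, " attempts")
}

#' Generate one coupled trajectory pair
#'
#' Integrates both agents of an interaction class over
#' `duration / dt` steps. Agent 1 steers toward its current via point
#' and draws a fresh one whenever within `via_capture_radius`; agent 2's
#' goal is agent 1's instantaneous position. The speed noise of the two
#' agents comes from independent substreams derived from the seed, so a
#' pair is exactly reproducible from `(class, seed)` alone. Initial
#' positions are uniform over the arena, initial headings uniform over
#' `(-pi, pi]`, initial speed and heading rate zero.
#'
#' @param spec an [interaction_class_spec()].
#' @param config a [simulation_config()].
#' @return An object of class `trajectory_pair`: list with `class_name`,
#'   `t` (time grid, length `n_steps + 1`), `agent1`/`agent2`
#'   (data.frames with columns `x, y, phi, phi_dot, s`), `via_points`
#'   (matrix), `seed`, `dt`, `arena`.
#' @export
#' @examples
#' cat <- interaction_catalog()
#' pair <- generate_pair(cat[["Chasing"]],
#'                       simulation_config(duration = 2, seed = 7))
#' nrow(pair$agent1)  # 201 states on the 0.01 grid
generate_pair <- function(spec, config) {
  if (!inherits(spec, "interaction_class_spec"))
    stop("spec must be an interaction_class_spec")
  if (!inherits(config, "simulation_config"))
    stop("config must be a simulation_config")
  n <- as.integer(round(config$duration / config$dt))
  if (n < 1L) stop("duration must cover at least one step")
  dt <- config$dt
  p <- spec$global_params
  sp1 <- spec$agent1
  sp2 <- spec$agent2

  z1 <- .seeded_normals(derive_seed(config$seed, 1L), n)
  z2 <- .seeded_normals(derive_seed(config$seed, 2L), n)
  set.seed(derive_seed(config$seed, 3L))

  a <- config$arena
  X1 <- Y1 <- PH1 <- PD1 <- S1 <- numeric(n + 1L)
  X2 <- Y2 <- PH2 <- PD2 <- S2 <- numeric(n + 1L)
  X1[1] <- stats::runif(1, a[1], a[2]); Y1[1] <- stats::runif(1, a[3], a[4])
  X2[1] <- stats::runif(1, a[1], a[2]); Y2[1] <- stats::runif(1, a[3], a[4])
  PH1[1] <- wrap_angle(stats::runif(1, -pi, pi))
  PH2[1] <- wrap_angle(stats::runif(1, -pi, pi))

  via <- sample_via_point(c(X1[1], Y1[1]), config)
  via_points <- list(via)
  none <- numeric(0)

  for (i in seq_len(n)) {
    dx <- via[1] - X1[i]; dy <- via[2] - Y1[i]
    d1 <- sqrt(dx * dx + dy * dy)
    if (d1 <= config$via_capture_radius) {
      via <- sample_via_point(c(X1[i], Y1[i]), config)
      via_points[[length(via_points) + 1L]] <- via
      dx <- via[1] - X1[i]; dy <- via[2] - Y1[i]
      d1 <- sqrt(dx * dx + dy * dy)
    }
    v1 <- .step_values(X1[i], Y1[i], PH1[i], PD1[i], S1[i],
                       atan2(dy, dx), d1, none, none, p, sp1, dt, z1[i])
    ex <- X1[i] - X2[i]; ey <- Y1[i] - Y2[i]
    v2 <- .step_values(X2[i], Y2[i], PH2[i], PD2[i], S2[i],
                       atan2(ey, ex), sqrt(ex * ex + ey * ey),
                       none, none, p, sp2, dt, z2[i])
    if (any(!is.finite(v1)) || any(!is.finite(v2)))
      stop("simulation diverged (non-finite state) at step ", i,
           " of class '", spec$name, "'")
    X1[i + 1L] <- v1[1]; Y1[i + 1L] <- v1[2]; PH1[i + 1L] <- v1[3]
    PD1[i + 1L] <- v1[4]; S1[i + 1L] <- v1[5]
    X2[i + 1L] <- v2[1]; Y2[i + 1L] <- v2[2]; PH2[i + 1L] <- v2[3]
    PD2[i + 1L] <- v2[4]; S2[i + 1L] <- v2[5]
  }

  structure(list(
    class_name = spec$name,
    t = dt * (0:n),
    agent1 = data.frame(x = X1, y = Y1, phi = PH1, phi_dot = PD1, s = S1),
    agent2 = data.frame(x = X2, y = Y2, phi = PH2, phi_dot = PD2, s = S2),
    via_points = do.call(rbind, via_points),
    seed = config$seed,
    dt = dt,
    arena = a),
    class = "trajectory_pair")
}

#' @export
print.trajectory_pair <- function(x, ...) {
  cat("Trajectory pair: class '", x$class_name, "', ",
      length(x$t), " samples at dt = ", x$dt,
      " (", max(x$t), " time units), seed ", x$seed, ", ",
      nrow(x$via_points), " via point(s)\n", sep = "")
  invisible(x)
}

#' Validate the internal consistency of a trajectory pair
#'
#' Checks series lengths against the time grid, finiteness, heading
#' wrapping, and that positions stay inside the arena expanded by the
#' travel bound `duration * max(|s|)` — the dynamics impose no walls, so
#' retreat-style classes legitimately leave the arena, but never faster
#' than their own top speed allows.
#'
#' @param pair a `trajectory_pair`.
#' @return `pair`, invisibly; stops on violation.
#' @export
validate_trajectory_pair <- function(pair) {
  if (!inherits(pair, "trajectory_pair")) stop("not a trajectory_pair")
  n <- length(pair$t)
  for (ag in c("agent1", "agent2")) {
    df <- pair[[ag]]
    if (nrow(df) != n)
      stop(ag, " series length ", nrow(df), " != time grid length ", n)
    if (any(!is.finite(as.matrix(df)))) stop(ag, " contains non-finite values")
    if (any(df$phi <= -pi - 1e-9 | df$phi > pi + 1e-9))
      stop(ag, " heading not wrapped to (-pi, pi]")
  }
  tol <- max(pair$t) * max(abs(pair$agent1$s), abs(pair$agent2$s))
  a <- pair$arena
  for (ag in c("agent1", "agent2")) {
    df <- pair[[ag]]
    if (any(df$x < a[1] - tol | df$x > a[2] + tol |
            df$y < a[3] - tol | df$y > a[4] + tol))
      stop(ag, " leaves the arena by more than the travel bound ", tol)
  }
  invisible(pair)
}

#' Build a dataset of trajectory pairs
#'
#' `n_realizations` independent runs of every class in the catalog.
#' Realization `r` of class `c` runs with the derived seed
#' `derive_seed(seed, c, r)`, so every pair is reproducible on its own
#' and realizations differ in via points, initial conditions and noise.
#'
#' @param catalog a list of [interaction_class_spec()] (default the
#'   bundled catalog).
#' @param n_realizations runs per class, `>= 1`.
#' @param config a [simulation_config()]; its `seed` is the dataset base
#'   seed.
#' @return A list of `trajectory_pair` objects of length
#'   `length(catalog) * n_realizations`, named `"<class>_r<r>"`.
#' @export
build_dataset <- function(catalog = interaction_catalog(),
                          n_realizations = 5L,
                          config = simulation_config()) {
  n_realizations <- as.integer(n_realizations)
  if (is.na(n_realizations) || n_realizations < 1L)
    stop("n_realizations must be >= 1")
  out <- vector("list", length(catalog) * n_realizations)
  nms <- character(length(out))
  k <- 0L
  for (ci in seq_along(catalog)) {
    for (r in seq_len(n_realizations)) {
      k <- k + 1L
      cfg <- config
      cfg$seed <- derive_seed(config$seed, ci, r)
      out[[k]] <- generate_pair(catalog[[ci]], cfg)
      nms[k] <- paste0(catalog[[ci]]$name, "_r", r)
    }
  }
  names(out) <- nms
  out
}
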