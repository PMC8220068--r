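# Independent brute-force oracles and small simulation helpers used
# across the suite. Kept deliberately naive (explicit loops) so they
# share no code path with the implementation they check.

# Loop-based recall/precision/F1.
oracle_metrics <- function(M) {
  n <- nrow(M)
  recall <- precision <- f1 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rs <- 0; for (j in seq_len(n)) rs <- rs + M[i, j]
    if (rs > 0) recall[i] <- M[i, i] / rs
    cs <- 0; for (j in seq_len(n)) cs <- cs + M[j, i]
    if (cs > 0) precision[i] <- M[i, i] / cs
    if (!is.na(recall[i]) && !is.na(precision[i]) &&
        recall[i] + precision[i] > 0)
      f1[i] <- 2 * precision[i] * recall[i] / (precision[i] + recall[i])
  }
  list(recall = recall, precision = precision, f1 = f1)
}

# Loop-based pairwise mislabeling probability.
oracle_pms <- function(M) {
  n <- nrow(M)
  tot <- 0
  for (k in seq_len(n)) for (l in seq_len(n)) if (l != k) tot <- tot + M[k, l]
  P <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    P[i, j] <- (M[i, j] + M[j, i]) / tot
  P
}

# Integrate a single agent toward a fixed goal point with step_agent();
# returns the state series as a data.frame.
simulate_to_goal <- function(state, goal_pos, p, sp, dt, duration,
                             noise = NULL) {
  n <- round(duration / dt)
  if (is.null(noise)) noise <- rep(0, n)
  out <- matrix(NA_real_, n + 1, 5,
                dimnames = list(NULL, c("x", "y", "phi", "phi_dot", "s")))
  out[1, ] <- unlist(state)
  for (i in seq_len(n)) {
    g <- goal_context_from(c(state$x, state$y), goal_pos)
    state <- step_agent(state, g, obstacle_context(), p, sp, dt, noise[i])
    out[i + 1, ] <- unlist(state)
  }
  as.data.frame(out)
}

# Frozen reference values for catalog spot checks: class, agent, field, value.
catalog_spot_checks <- function() {
  data.frame(
    class = c("Avoiding", "Avoiding", "Avoiding", "Bumping", "Chasing",
              "Chasing", "Fighting", "Fighting", "Meeting", "Playing",
              "Pulling", "Pushing", "Tug of War", "Tug of War", "Walking"),
    agent = c("agent1", "agent2", "agent2", "agent1", "agent1",
              "agent2", "agent1", "agent2", "agent2", "agent2",
              "agent1", "agent2", "agent1", "agent1", "agent2"),
    field = c("c8", "c5", "c8", "k_eps", "c6",
              "c7", "k", "k_eps", "c5", "c7",
              "c8", "c9", "k_eps", "c8", "c5"),
    value = c(3, 0.4, 2.7, 0.9, 10,
              7, 0.1, 1, 0.22, 10,
              2.6, 2.5, 0.2, 6, 0.22))
}
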