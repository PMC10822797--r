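# Shared fixtures and independent oracles for the test suite.

default_params <- function(...) model_params(...)

# Deterministic terminal energy of an open-loop schedule via the exact
# energy recursion (independent of the simulator's vectorized path).
recursed_terminal_energy <- function(schedule, params,
                                     charge = !isFALSE(schedule$charge_migration_cost)) {
  e <- initial_energy(params)
  for (k in seq_len(schedule$N)) {
    e <- step_energy(e, schedule$z_path[k], schedule$actions[k], params,
                     charge_migration = charge)
  }
  e
}

# Wrap a raw action vector as a schedule object (for enumeration tests).
as_test_schedule <- function(actions, params) {
  z <- cumsum(c(0L, as.integer(actions)))
  stopifnot(all(z %in% 0:1))
  structure(
    list(actions = as.integer(actions), z_path = z, windows = NULL,
         dt = params$dt, N = length(actions), charge_migration_cost = TRUE,
         label = "enum"),
    class = c("schedule", "behavior")
  )
}

# All admissible open-loop action sequences of length N (toggle-or-stay
# at each step; 2^N sequences).
enumerate_action_seqs <- function(N) {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), N))
  lapply(seq_len(nrow(grid)), function(i) {
    tog <- unlist(grid[i, ], use.names = FALSE)
    z <- 0L
    a <- integer(N)
    for (k in seq_len(N)) {
      a[k] <- if (tog[k]) (if (z == 0L) 1L else -1L) else 0L
      z <- z + a[k]
    }
    a
  })
}

# Exact expected Trajectory Score of an open-loop schedule started at a
# fixed x0, by full quadrature-tree propagation of the cross-shore state
# (energy and depth are deterministic open-loop).  Mirrors the model
# exactly -- reflection at the shore, optional clamp at x_max -- with no
# value-function interpolation, so it is an independent oracle for the DP.
open_loop_value_tree <- function(actions, x0, params, weights,
                                 n_quad = 9L, x_max = Inf) {
  quad <- larvadisp:::.gauss_hermite_normal(n_quad)
  N <- length(actions)
  z <- cumsum(c(0L, actions))
  e <- numeric(N + 1L)
  e[1L] <- initial_energy(params)
  for (k in seq_len(N)) {
    e[k + 1L] <- step_energy(e[k], z[k], actions[k], params)
  }
  dtT <- params$dt / params$T
  xs <- x0
  ws <- 1
  reward <- 0
  for (k in seq_len(N)) {
    t <- (k - 1L) * params$dt
    outside <- !in_high_predation(rep(t, length(xs)), xs, rep(z[k], length(xs)),
                                  params)
    reward <- reward + sum(ws * dtT * (weights$p_pred * outside +
                                         weights$p_starve * (e[k] > 0)))
    mu <- layer_advection(params, z[k]) * params$dt
    sig <- sqrt(2 * layer_diffusivity(params, z[k]) * params$dt)
    xs <- abs(outer(xs, sig * quad$nodes + mu, "+"))
    xs <- pmin(as.vector(xs), x_max)
    ws <- as.vector(outer(ws, quad$weights))
  }
  terminal <- weights$p_settle * (1 - settling_penalty(xs)) +
    weights$p_meta * (1 - metamorphosis_penalty(e[N + 1L]))
  reward + sum(ws * terminal)
}

# Random admissible schedule from random disjoint surface windows.
random_schedule <- function(params, max_windows = 4L) {
  N <- n_steps(params)
  dt <- params$dt
  k <- sample.int(max_windows, 1L)
  edges <- sort(sample(seq_len(N), min(2L * k, N)))
  windows <- list()
  i <- 1L
  while (i + 1L <= length(edges)) {
    a <- edges[i] * dt
    b <- edges[i + 1L] * dt
    if (length(windows) == 0L ||
        a > windows[[length(windows)]][2] + dt / 2) {
      windows[[length(windows) + 1L]] <- c(a, b)
    }
    i <- i + 2L
  }
  schedule_from_windows(windows, params)
}
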