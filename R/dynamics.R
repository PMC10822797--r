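#' Draw larval states at spawning
#'
#' Larvae spawn at `t = 0` in the bottom layer from a uniform random
#' cross-shore position inside the nearshore habitat, carrying the
#' maintenance budget `G * T` plus the surplus/deficit `S`.
#'
#' @param params a [model_params()] object.
#' @param n number of larvae to draw (uses the current RNG stream).
#' @return A data frame with columns `t`, `X`, `Z`, `E` and `n` rows.
#' @export
draw_initial_state <- function(params, n = 1L) {
  e0 <- initial_energy(params)  # errors on nonviable S + G*T
  data.frame(t = 0, X = stats::runif(n), Z = 0L, E = e0)
}

#' One energy-budget update
#'
#' Applies the discrete energy recursion: feeding at rate `F` while the
#' surface layer is held, maintenance drain `G`, and a migration cost `V`
#' per nonzero depth change, with the result clipped to `[0, E_max]`
#' (the zero branch is checked first, matching the model's starvation
#' bookkeeping).  `z_held` is the layer occupied during the step
#' `[t, t + dt)`; the depth change takes effect at `t + dt`.
#'
#' @param E energy reserves (vectorized).
#' @param z_held layers held during the step, 0/1.
#' @param action depth changes in `{-1, 0, +1}`.
#' @param params a [model_params()] object.
#' @param charge_migration charge the `V` cost?  `FALSE` for passive
#'   drifting, whose layer switches are turbulent rather than swum.
#' @return Updated energy reserves.
#' @export
step_energy <- function(E, z_held, action, params, charge_migration = TRUE) {
  cost <- if (charge_migration) params$V * abs(action) else 0
  e1 <- E + (params$F * z_held - params$G) * params$dt - cost
  pmin(pmax(e1, 0), params$E_max)
}

#' One cross-shore random-walk update
#'
#' Advection-diffusion step in the layer held during `[t, t + dt)`:
#' `X' = X + U_z * dt + xi * sqrt(2 * K_z * dt)`.  The coastline at
#' `X = 0` is a reflecting (zero-flux) boundary, implemented as
#' `|X'|`; there is no offshore boundary in simulation.
#'
#' @param X offshore distances (vectorized).
#' @param z_held layers held during the step, 0/1.
#' @param xi standard normal deviates, one per larva.
#' @param params a [model_params()] object.
#' @param reflect reflect at the shore?  Disable only for the symmetry
#'   diagnostics of the test suite (larvae may then take `X < 0`).
#' @return Updated offshore distances.
#' @export
step_position <- function(X, z_held, xi, params, reflect = TRUE) {
  x1 <- X + layer_advection(params, z_held) * params$dt +
    xi * sqrt(2 * layer_diffusivity(params, z_held) * params$dt)
  if (reflect) abs(x1) else x1
}

#' Simulate a Monte-Carlo ensemble of larval trajectories
#'
#' Runs `sim$n_reps` larvae forward from spawning to settlement under one
#' behavior.  At each step the behavior is queried for a depth change,
#' energy and position are updated using the layer held during the step,
#' and the depth change takes effect at the next step.  The RNG layout is
#' fixed: after seeding, initial positions are drawn first, then the
#' normal deviate matrix in (larva, step) order, then (for passive
#' drifting only) the vertical uniforms - so ensembles are bit-reproducible
#' and behaviors sharing a seed share their cross-shore noise (common
#' random numbers).
#'
#' @param behavior a schedule, [passive_process()], or optimal-policy
#'   behavior (see [as_behavior()]).
#' @param params a [model_params()] object.
#' @param sim a [sim_config()].
#' @param reflect reflect at the shore (see [step_position()]).
#' @return An object of class `trajectory_ensemble`: matrices `X`, `Z`,
#'   `E` of dimension `n_reps x (N + 1)`, `actions` of dimension
#'   `n_reps x N`, plus `times`, `params` and the behavior label.
#' @export
#' @examples
#' p <- model_params()
#' ens <- simulate_ensemble(make_archetype("dvm", p), p, sim_config(1, 50))
#' range(ens$E[, ncol(ens$E)])   # deterministic terminal energy 1.294
simulate_ensemble <- function(behavior, params, sim, reflect = TRUE) {
  stopifnot(inherits(behavior, "behavior"), inherits(params, "model_params"),
            inherits(sim, "sim_config"))
  N <- n_steps(params)
  n <- sim$n_reps
  if (inherits(behavior, "schedule") && behavior$N != N) {
    stop("schedule has ", behavior$N, " steps but params imply N = ", N)
  }
  set.seed(sim$seed)
  init <- draw_initial_state(params, n)
  X <- matrix(NA_real_, n, N + 1L)
  E <- matrix(NA_real_, n, N + 1L)
  Z <- matrix(NA_integer_, n, N + 1L)
  A <- matrix(NA_integer_, n, N)
  X[, 1L] <- init$X; E[, 1L] <- init$E; Z[, 1L] <- 0L
  # (larva, step)-ordered draws: row r of xi holds larva r's deviates
  xi <- matrix(stats::rnorm(n * N), nrow = n, byrow = TRUE)
  uu <- if (inherits(behavior, "passive_process")) {
    matrix(stats::runif(n * N), nrow = n, byrow = TRUE)
  }
  charge <- !isFALSE(behavior$charge_migration_cost)
  for (k in seq_len(N)) {
    z <- Z[, k]
    a <- if (inherits(behavior, "schedule")) {
      rep(behavior$actions[k], n)
    } else if (inherits(behavior, "passive_process")) {
      passive_step(z, behavior, uu[, k])
    } else if (inherits(behavior, "policy_behavior")) {
      policy_lookup(behavior$solution, (k - 1L) * params$dt, X[, k], z, E[, k])
    } else {
      stop("unsupported behavior class: ", paste(class(behavior), collapse = "/"))
    }
    znext <- z + a
    bad <- which(znext < 0L | znext > 1L)
    if (length(bad)) {
      stop(sprintf(
        "inadmissible action %d at t = %g for state (X = %.4g, Z = %d, E = %.4g)",
        a[bad[1]], (k - 1L) * params$dt, X[bad[1], k], z[bad[1]], E[bad[1], k]))
    }
    A[, k] <- a
    E[, k + 1L] <- step_energy(E[, k], z, a, params, charge_migration = charge)
    X[, k + 1L] <- step_position(X[, k], z, xi[, k], params, reflect = reflect)
    Z[, k + 1L] <- znext
  }
  structure(
    list(times = (0:N) * params$dt, X = X, Z = Z, E = E, actions = A,
         params = params, behavior = behavior_label(behavior),
         seed = sim$seed),
    class = "trajectory_ensemble"
  )
}

#' Simulate a single larval trajectory
#'
#' Convenience wrapper around [simulate_ensemble()] for one larva.
#'
#' @inheritParams simulate_ensemble
#' @param seed RNG seed for this larva.
#' @return An object of class `trajectory`: vectors `times`, `X`, `Z`,
#'   `E` (length `N + 1`) and `actions` (length `N`).
#' @export
simulate_trajectory <- function(behavior, params, seed = 1L, reflect = TRUE) {
  ens <- simulate_ensemble(behavior, params, sim_config(seed, 1L),
                           reflect = reflect)
  structure(
    list(times = ens$times, X = ens$X[1L, ], Z = ens$Z[1L, ],
         E = ens$E[1L, ], actions = ens$actions[1L, ], params = params,
         behavior = ens$behavior),
    class = "trajectory"
  )
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  n <- nrow(x$X)
  cat(sprintf("Trajectory ensemble: %d larvae x %d states ('%s', seed %d)\n",
              n, ncol(x$X), x$behavior, x$seed))
  cat(sprintf("  X_T: median %.3g [%.3g, %.3g];  E_T: median %.3g\n",
              stats::median(x$X[, ncol(x$X)]),
              stats::quantile(x$X[, ncol(x$X)], 0.25),
              stats::quantile(x$X[, ncol(x$X)], 0.75),
              stats::median(x$E[, ncol(x$E)])))
  invisible(x)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Larval trajectory ('%s'): %d states, X_T = %.3g, E_T = %.4g\n",
              x$behavior, length(x$times), x$X[length(x$X)], x$E[length(x$E)]))
  invisible(x)
}

#' Export trajectories as long-format CSV
#'
#' Columns `rep,t,X,Z,E,dZ`; `dZ` is empty on each larva's final row
#' (there is no decision at `t = T`).
#'
#' @param ens a [simulate_ensemble()] result (or a single trajectory).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(ens, path) {
  if (inherits(ens, "trajectory")) {
    d <- data.frame(rep = 1L, t = ens$times, X = ens$X, Z = ens$Z, E = ens$E,
                    dZ = c(ens$actions, NA_integer_))
  } else {
    stopifnot(inherits(ens, "trajectory_ensemble"))
    n <- nrow(ens$X); m <- ncol(ens$X)
    d <- data.frame(
      rep = rep(seq_len(n), each = m),
      t = rep(ens$times, times = n),
      X = as.vector(t(ens$X)),
      Z = as.vector(t(ens$Z)),
      E = as.vector(t(ens$E)),
      dZ = as.vector(t(cbind(ens$actions, NA_integer_)))
    )
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
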