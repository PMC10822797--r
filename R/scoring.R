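#' High-predation region membership
#'
#' Under the nearshore scheme, predation is elevated over the nearshore
#' strip `X <= 1` in both layers at all times.  Under the diurnal scheme it
#' is elevated in the surface layer during daylight; the daylight window is
#' evaluated half-open (`[0.25, 0.75)` of each day at defaults) on
#' step-start times so that exactly half of each day counts as daylight on
#' the dt grid.
#'
#' @param t times since spawning, days (vectorized).
#' @param X offshore distances.
#' @param Z depth layers, 0/1.
#' @param params a [model_params()] object.
#' @return Logical vector: in the high-predation region?
#' @export
in_high_predation <- function(t, X, Z, params) {
  switch(params$predation_scheme,
    nearshore = X <= 1,
    diurnal = {
      clock <- t %% 1
      Z == 1 & clock >= params$daylight_window[1] - 1e-9 &
        clock < params$daylight_window[2] - 1e-9
    },
    stop("unknown predation scheme: ", params$predation_scheme)
  )
}

# Exposure accounting shared by single-trajectory and ensemble scoring:
# each interval [t, t+dt) is attributed to its step-start state, so the
# first N of the N+1 recorded states carry the running exposure and the
# terminal state contributes only through the settling/metamorphosis
# penalties.
.frac_outside <- function(times, X, Z, params) {
  N <- length(times) - 1L
  k <- seq_len(N)
  if (is.matrix(X)) {
    tm <- matrix(times[k], nrow(X), N, byrow = TRUE)
    inreg <- in_high_predation(tm, X[, k, drop = FALSE], Z[, k, drop = FALSE],
                               params)
    rowSums(!inreg) * params$dt / params$T
  } else {
    sum(!in_high_predation(times[k], X[k], Z[k], params)) * params$dt / params$T
  }
}

.frac_fed <- function(E, params) {
  N <- if (is.matrix(E)) ncol(E) - 1L else length(E) - 1L
  if (is.matrix(E)) {
    rowSums(E[, seq_len(N), drop = FALSE] > 0) * params$dt / params$T
  } else {
    sum(E[seq_len(N)] > 0) * params$dt / params$T
  }
}

#' Predation-avoidance subscore
#'
#' Fraction of the larval duration spent outside the high-predation
#' region, accumulated over step-start states.
#'
#' @param traj a `trajectory` from [simulate_trajectory()].
#' @param params a [model_params()] object.
#' @return A fraction in `[0, 1]`.
#' @export
predation_subscore <- function(traj, params) {
  stopifnot(inherits(traj, "trajectory"))
  .frac_outside(traj$times, traj$X, traj$Z, params)
}

#' Starvation-avoidance subscore
#'
#' Fraction of the larval duration with a positive energy reserve,
#' accumulated over step-start states.
#'
#' @inheritParams predation_subscore
#' @return A fraction in `[0, 1]`.
#' @export
starvation_subscore <- function(traj, params) {
  stopifnot(inherits(traj, "trajectory"))
  .frac_fed(traj$E, params)
}

#' Settling-location penalty
#'
#' Zero inside the nearshore habitat (`X_T <= 1`), approaching 1 as the
#' larva ends arbitrarily far offshore: `1 - 1/X_T` for `X_T > 1`.
#'
#' @param X_T terminal offshore distances (vectorized).
#' @return Penalties in `[0, 1)`.
#' @export
settling_penalty <- function(X_T) {
  stopifnot(all(X_T >= 0))
  ifelse(X_T > 1, 1 - 1 / X_T, 0)
}

#' Metamorphosis-energy penalty
#'
#' Zero when the larva ends with at least one metamorphosis-cost unit of
#' energy, rising linearly to 1 as `E_T` falls to zero.
#'
#' @param E_T terminal energy reserves (vectorized).
#' @return Penalties in `[0, 1]`.
#' @export
metamorphosis_penalty <- function(E_T) {
  stopifnot(all(E_T >= 0))
  ifelse(E_T < 1, 1 - E_T, 0)
}

#' The Trajectory Score
#'
#' Composite fitness functional of one simulated trajectory: the convex
#' combination `J = p_pred J_pred + p_starve J_starve + p_settle J_settle
#' + p_meta J_meta`, where the running subscores are the fractions of the
#' larval duration outside the high-predation region and with positive
#' energy, and the terminal subscores are one minus the settling and
#' metamorphosis penalties.  Up to a monotone transformation, `J` is the
#' log-probability that a larva following this trajectory survives through
#' metamorphosis.
#'
#' @param traj a `trajectory` from [simulate_trajectory()].
#' @param weights a [score_weights()] object.
#' @param params a [model_params()] object.
#' @return An object of class `score_breakdown` with fields `J`, `J_pred`,
#'   `J_starve`, `J_settle`, `J_meta`, `phi_settle`, `phi_meta`, `weights`
#'   and `scheme`.
#' @export
trajectory_score <- function(traj, weights, params) {
  stopifnot(inherits(traj, "trajectory"), inherits(weights, "score_weights"))
  j_pred <- predation_subscore(traj, params)
  j_starve <- starvation_subscore(traj, params)
  phi_s <- settling_penalty(traj$X[length(traj$X)])
  phi_m <- metamorphosis_penalty(traj$E[length(traj$E)])
  j_settle <- 1 - phi_s
  j_meta <- 1 - phi_m
  J <- weights$p_pred * j_pred + weights$p_starve * j_starve +
    weights$p_settle * j_settle + weights$p_meta * j_meta
  structure(
    list(J = J, J_pred = j_pred, J_starve = j_starve, J_settle = j_settle,
         J_meta = j_meta, phi_settle = phi_s, phi_meta = phi_m,
         weights = weights, scheme = params$predation_scheme),
    class = "score_breakdown"
  )
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf("Trajectory Score (%s scheme): J = %.4f\n", x$scheme, x$J))
  cat(sprintf("  J_pred = %.4f, J_starve = %.4f, J_settle = %.4f, J_meta = %.4f\n",
              x$J_pred, x$J_starve, x$J_settle, x$J_meta))
  invisible(x)
}

#' Score every replicate of an ensemble
#'
#' Vectorized [trajectory_score()] over a Monte-Carlo ensemble.
#'
#' @param ens a [simulate_ensemble()] result.
#' @param weights a [score_weights()] object.
#' @param params a [model_params()] object.
#' @return A data frame with one row per replicate and columns `rep`, `J`,
#'   `J_pred`, `J_starve`, `J_settle`, `J_meta`, `X_T`, `E_T`.
#' @export
score_ensemble <- function(ens, weights, params) {
  stopifnot(inherits(ens, "trajectory_ensemble"),
            inherits(weights, "score_weights"))
  j_pred <- .frac_outside(ens$times, ens$X, ens$Z, params)
  j_starve <- .frac_fed(ens$E, params)
  X_T <- ens$X[, ncol(ens$X)]
  E_T <- ens$E[, ncol(ens$E)]
  j_settle <- 1 - settling_penalty(X_T)
  j_meta <- 1 - metamorphosis_penalty(E_T)
  J <- weights$p_pred * j_pred + weights$p_starve * j_starve +
    weights$p_settle * j_settle + weights$p_meta * j_meta
  data.frame(rep = seq_along(J), J = J, J_pred = j_pred, J_starve = j_starve,
             J_settle = j_settle, J_meta = j_meta, X_T = X_T, E_T = E_T)
}
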