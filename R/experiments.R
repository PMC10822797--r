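#' Monte-Carlo summary of one behavior
#'
#' Simulates an ensemble, scores every replicate, and aggregates the
#' composite score and subscores into means and quartiles, plus the
#' fraction of replicates ending inside the habitat (`X_T <= 1`) and with
#' enough energy for metamorphosis (`E_T >= 1`).
#'
#' @param behavior a behavior object.
#' @param params a [model_params()] object.
#' @param weights a [score_weights()] object.
#' @param sim a [sim_config()].
#' @return A one-row data frame of class `behavior_summary`.
#' @export
evaluate_behavior <- function(behavior, params, weights = score_weights(),
                              sim = sim_config()) {
  stopifnot(sim$n_reps >= 2L)
  ens <- simulate_ensemble(behavior, params, sim)
  sc <- score_ensemble(ens, weights, params)
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  cols <- c("J", "J_pred", "J_starve", "J_settle", "J_meta")
  out <- data.frame(behavior = behavior_label(behavior),
                    scheme = params$predation_scheme,
                    n_reps = sim$n_reps, stringsAsFactors = FALSE)
  for (cl in cols) {
    q <- qs(sc[[cl]])
    out[[paste0("mean_", cl)]] <- mean(sc[[cl]])
    out[[paste0("q25_", cl)]] <- q[1]
    out[[paste0("q50_", cl)]] <- q[2]
    out[[paste0("q75_", cl)]] <- q[3]
  }
  out$frac_settled <- mean(sc$X_T <= 1)
  out$frac_energized <- mean(sc$E_T >= 1)
  class(out) <- c("behavior_summary", class(out))
  out
}

#' Sweep an environmental parameter across behaviors
#'
#' Evaluates each behavior at each value of the swept parameter (`U`,
#' current strength, or `F`, feeding rate).  Within a sweep cell all
#' behaviors share the same seed, so they see common random numbers - a
#' variance-reduction device that sharpens behavior orderings.  Optimal
#' policies can be re-solved at every parameter value.
#'
#' @param name `"U"` or `"F"`.
#' @param values strictly increasing parameter values.
#' @param behaviors named list of behavior objects; entries equal to the
#'   string `"optimal"` are re-solved per value via [solve_policy()].
#' @param params baseline [model_params()]; all other fields held fixed.
#' @param weights a [score_weights()] object.
#' @param sim a [sim_config()].
#' @param solver optional list of [solve_policy()] arguments (`grids
#'   settings`, `n_quad`) used when re-solving.
#' @return A data frame (class `sweep_table`) with columns `param`,
#'   `value` and one [evaluate_behavior()] row per (value, behavior).
#' @export
sweep_parameter <- function(name = c("U", "F"), values, behaviors, params,
                            weights = score_weights(), sim = sim_config(),
                            solver = list()) {
  name <- match.arg(name)
  stopifnot(is.numeric(values), length(values) >= 1L,
            all(diff(values) > 0), is.list(behaviors), length(behaviors) >= 1L)
  if (is.null(names(behaviors))) names(behaviors) <- paste0("b", seq_along(behaviors))
  rows <- list()
  for (v in values) {
    p <- do.call(update_params, c(list(params), stats::setNames(list(v), name)))
    for (nm in names(behaviors)) {
      b <- behaviors[[nm]]
      if (identical(b, "optimal")) {
        sol <- do.call(solve_policy,
                       c(list(params = p, weights = weights,
                              keep_values = "initial"), solver))
        b <- as_behavior(sol)
      }
      s <- evaluate_behavior(b, p, weights, sim)
      s$behavior <- nm
      rows[[length(rows) + 1L]] <- cbind(data.frame(param = name, value = v), s)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Minimal feeding rate for a complication-free metamorphosis
#'
#' For an open-loop schedule the energy path is deterministic, and when no
#' clipping occurs the terminal energy obeys the identity
#' `E_T = E_0 + F * tau - G * T - V * m`, where `tau` is the surface
#' residency (days) and `m` the migration count.  The threshold is the
#' smallest `F` with `E_T >= 1`, in closed form
#' `F* = (1 - E_0 + G*T + V*m) / tau`, verified against the exact energy
#' recursion; it is also reported rounded to the nearest 0.05, the
#' precision at which such thresholds are customarily quoted.
#'
#' @param schedule an open-loop schedule.
#' @param params a [model_params()] object.
#' @return A list with `F_star`, `F_rounded`, `tau_surface`,
#'   `n_migrations`.
#' @export
#' @examples
#' p <- model_params()
#' feeding_threshold(make_archetype("ovm", p), p)$F_rounded   # 0.25
feeding_threshold <- function(schedule, params) {
  stopifnot(inherits(schedule, "schedule"))
  tau <- surface_time(schedule)
  if (tau <= 0) stop("nonfeeding schedule has no threshold")
  m <- n_migrations(schedule)
  e0 <- initial_energy(params)
  v <- if (isFALSE(schedule$charge_migration_cost)) 0 else params$V
  f_star <- max(0, (1 - e0 + params$G * params$T + v * m) / tau)
  # confirm the closed form against the exact recursion (guards against
  # clipping en route, which would break the identity)
  pf <- update_params(params, F = f_star)
  e <- e0
  for (k in seq_len(schedule$N)) {
    e <- step_energy(e, schedule$z_path[k], schedule$actions[k], pf,
                     charge_migration = !isFALSE(schedule$charge_migration_cost))
  }
  if (abs(e - 1) > 1e-9 && f_star > 0) {
    warning(sprintf(
      "energy clipping along the path: recursion gives E_T = %.6g at F* = %.6g",
      e, f_star))
  }
  list(F_star = f_star, F_rounded = round(f_star / 0.05) * 0.05,
       tau_surface = tau, n_migrations = m)
}

#' Compare subscores across behaviors and predation schemes
#'
#' Evaluates the optimal policy, passive drifting, and the DVM, OVM and
#' Hybrid archetypes under both predation schemes, with one ensemble per
#' cell (common seed across behaviors within a scheme).
#'
#' @param params a [model_params()] object; its `predation_scheme` field
#'   is overridden per row.
#' @param weights a [score_weights()] object.
#' @param sim a [sim_config()].
#' @param solutions optional named list with elements `nearshore` and/or
#'   `diurnal` holding pre-solved [solve_policy()] results; missing
#'   schemes are solved here.
#' @param solver optional list of extra [solve_policy()] arguments.
#' @return A data frame with one [evaluate_behavior()] row per
#'   (scheme, behavior).
#' @export
compare_subscores <- function(params, weights = score_weights(),
                              sim = sim_config(), solutions = NULL,
                              solver = list()) {
  rows <- list()
  for (scheme in c("nearshore", "diurnal")) {
    p <- update_params(params, predation_scheme = scheme)
    sol <- solutions[[scheme]]
    if (is.null(sol)) {
      sol <- do.call(solve_policy,
                     c(list(params = p, weights = weights,
                            keep_values = "initial"), solver))
    }
    behaviors <- list(optimal = as_behavior(sol),
                      passive = passive_process(),
                      dvm = make_archetype("dvm", p),
                      ovm = make_archetype("ovm", p),
                      hybrid = make_archetype("hybrid", p))
    for (nm in names(behaviors)) {
      rows[[length(rows) + 1L]] <-
        evaluate_behavior(behaviors[[nm]], p, weights, sim)
    }
  }
  do.call(rbind, rows)
}
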