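#' Model parameters for the two-layer dispersal model
#'
#' Collects the biological and environmental constants of the dispersal
#' model.  All distances are scaled by the width of the nearshore
#' post-larval habitat and all energies by the cost of a complication-free
#' metamorphosis, so the defaults below are dimensionless rates per day.
#'
#' @param T larval duration in days.  Default 20; short and long life
#'   histories use 6 and 80.
#' @param dt decision time step in days.  Default 1/8 day, slightly shorter
#'   than one vertical migration.  `T/dt` must be a whole number.
#' @param U offshore advection of the surface layer, habitat widths per
#'   day.  `U = 0` is still water, `U = 1` the default upwelling case.
#' @param K cross-shore eddy diffusivity of the surface layer, habitat
#'   widths squared per day.  `K = 0` is accepted as a degenerate
#'   noise-free mode used by the test suite; the biological scenarios all
#'   have `K > 0`.
#' @param alpha ratio of bottom-layer to surface-layer current strength and
#'   diffusivity (roughly the depth ratio of the two layers), in `[0, 1]`.
#'   The bottom layer moves onshore at `-alpha * U` with diffusivity
#'   `alpha * K`.
#' @param S initial energy surplus (or deficit, if negative) relative to
#'   the maintenance requirement `G * T`, in metamorphosis-cost units.
#' @param G maintenance and growth energy expenditure rate, units per day.
#' @param F surface feeding rate, units per day; 0 for nonfeeding larvae,
#'   0.2 low food (default), 0.5 high food.
#' @param V energetic cost of one vertical migration in either direction.
#' @param E_max maximum energy reserve.
#' @param predation_scheme where elevated predation acts: `"nearshore"`
#'   (the strip `X <= 1`, both layers, all day) or `"diurnal"` (the surface
#'   layer during daylight).
#' @param daylight_window clock interval of elevated diurnal predation as
#'   fractions of a day; default `c(0.25, 0.75)` is 06:00-18:00, evaluated
#'   half-open on the dt grid so exactly half of each day is daylight.
#'
#' @return An object of class `model_params`.
#' @seealso [layer_advection()], [layer_diffusivity()], [n_steps()]
#' @export
#' @examples
#' p <- model_params()
#' n_steps(p)              # 160 decision steps
#' layer_advection(p, 0)   # bottom layer drifts onshore at -0.25
model_params <- function(T = 20, dt = 0.125, U = 1, K = 0.2, alpha = 0.25,
                         S = 0, G = 0.1, F = 0.2, V = 0.004, E_max = 5,
                         predation_scheme = c("nearshore", "diurnal"),
                         daylight_window = c(0.25, 0.75)) {
  predation_scheme <- match.arg(predation_scheme)
  stopifnot(is.numeric(T), length(T) == 1L, T > 0,
            is.numeric(dt), length(dt) == 1L, dt > 0,
            is.numeric(U), length(U) == 1L, U >= 0,
            is.numeric(K), length(K) == 1L, K >= 0,
            is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1,
            is.numeric(S), length(S) == 1L,
            is.numeric(G), length(G) == 1L, G >= 0,
            is.numeric(F), length(F) == 1L, F >= 0,
            is.numeric(V), length(V) == 1L, V >= 0,
            is.numeric(E_max), length(E_max) == 1L, E_max > 0,
            is.numeric(daylight_window), length(daylight_window) == 2L)
  n <- T / dt
  if (abs(n - round(n)) > 1e-9) {
    stop("T/dt must be a positive integer (got ", T, "/", dt, ")")
  }
  if (daylight_window[1] < 0 || daylight_window[2] > 1 ||
      daylight_window[1] >= daylight_window[2]) {
    stop("daylight_window must be an increasing interval within [0, 1]")
  }
  structure(
    list(T = T, dt = dt, U = U, K = K, alpha = alpha, S = S, G = G, F = F,
         V = V, E_max = E_max, predation_scheme = predation_scheme,
         daylight_window = daylight_window),
    class = "model_params"
  )
}

#' Update selected fields of a parameter set
#'
#' Convenience wrapper used by the sweep drivers: returns a revalidated
#' copy of `params` with the named fields replaced.
#'
#' @param params a [model_params()] object.
#' @param ... named fields to replace (e.g. `U = 0`, `F = 0.5`).
#' @return A new `model_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "model_params"))
  repl <- list(...)
  if (length(repl) == 0L) return(params)
  if (is.null(names(repl)) || any(names(repl) == "")) {
    stop("all replacement fields must be named")
  }
  unknown <- setdiff(names(repl), names(unclass(params)))
  if (length(unknown)) stop("unknown parameter field(s): ",
                            paste(unknown, collapse = ", "))
  args <- unclass(params)
  args[names(repl)] <- repl
  do.call(model_params, args)
}

#' Number of decision steps
#'
#' @param params a [model_params()] object.
#' @return Integer `N = T/dt` (160 at defaults).
#' @export
n_steps <- function(params) {
  as.integer(round(params$T / params$dt))
}

#' Layer-wise advection and diffusivity
#'
#' The surface layer (`z = 1`) moves offshore at `U` with diffusivity `K`;
#' the bottom layer (`z = 0`) moves onshore at `-alpha * U` with
#' diffusivity `alpha * K`.
#'
#' @param params a [model_params()] object.
#' @param z depth layer, 0 (bottom) or 1 (surface); vectorized.
#' @return Numeric vector of advection velocities (habitat widths per day)
#'   or diffusivities (habitat widths^2 per day).
#' @export
layer_advection <- function(params, z) {
  stopifnot(all(z %in% c(0, 1)))
  ifelse(z == 1, params$U, -params$alpha * params$U)
}

#' @rdname layer_advection
#' @export
layer_diffusivity <- function(params, z) {
  stopifnot(all(z %in% c(0, 1)))
  ifelse(z == 1, params$K, params$alpha * params$K)
}

#' Energy reserve at spawning
#'
#' Larvae spawn with the maintenance requirement `G * T` plus the surplus
#' or deficit `S`, clipped to `[0, E_max]`.  A nonpositive `S + G * T`
#' would mean the larva is born starving and is rejected.
#'
#' @param params a [model_params()] object.
#' @return Initial energy `E_0`.
#' @export
initial_energy <- function(params) {
  e0 <- params$S + params$G * params$T
  if (e0 <= 0) {
    stop("nonviable initial energy: S + G*T = ", e0, " <= 0")
  }
  min(max(e0, 0), params$E_max)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Two-layer larval dispersal parameters\n")
  cat(sprintf("  T = %g d, dt = %g d (N = %d steps)\n", x$T, x$dt, n_steps(x)))
  cat(sprintf("  U = %g, K = %g, alpha = %g\n", x$U, x$K, x$alpha))
  cat(sprintf("  S = %g, G = %g, F = %g, V = %g, E_max = %g\n",
              x$S, x$G, x$F, x$V, x$E_max))
  cat(sprintf("  predation: %s (daylight %.2f-%.2f)\n",
              x$predation_scheme, x$daylight_window[1], x$daylight_window[2]))
  invisible(x)
}

#' Trajectory Score weights
#'
#' Nonnegative weights on the four subscores (predation avoidance,
#' starvation avoidance, settling location, terminal energy).  They arise
#' from normalizing the unobservable mortality-rate constants of the
#' underlying survival model, so they must sum to 1.  Defaults weigh all
#' four needs equally.
#'
#' @param p_pred,p_starve,p_settle,p_meta nonnegative weights summing to 1.
#' @return An object of class `score_weights`.
#' @export
score_weights <- function(p_pred = 0.25, p_starve = 0.25,
                          p_settle = 0.25, p_meta = 0.25) {
  w <- c(p_pred, p_starve, p_settle, p_meta)
  stopifnot(is.numeric(w), length(w) == 4L, all(w >= 0))
  if (abs(sum(w) - 1) > 1e-12) {
    stop("score weights must sum to 1 (got ", format(sum(w), digits = 17), ")")
  }
  structure(list(p_pred = p_pred, p_starve = p_starve,
                 p_settle = p_settle, p_meta = p_meta),
            class = "score_weights")
}

#' Monte-Carlo simulation settings
#'
#' Bundles the RNG seed and replicate count.  The seed fully determines
#' the ensemble: one standard-normal cross-shore deviate is drawn per larva
#' per step (larva-major order), after the initial positions, so identical
#' seed + behavior + parameters give bit-identical ensembles.
#'
#' @param seed integer RNG seed.
#' @param n_reps number of Monte-Carlo larvae.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_reps = 1000L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(n_reps), length(n_reps) == 1L, n_reps >= 1)
  structure(list(seed = as.integer(seed), n_reps = as.integer(n_reps)),
            class = "sim_config")
}
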