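#' Build an open-loop schedule from surface-residency windows
#'
#' A schedule prescribes one depth change per decision step.  Windows are
#' inclusive time intervals `[a, b]` (days since spawning, on the dt grid)
#' during which the larva holds the surface layer: the ascent is charged at
#' `a - dt` and the descent at `b`, so the larva occupies the surface for
#' every grid time in `[a, b]`.  A window starting at `a = 0` is encoded by
#' ascending at `t = 0` (the larva always spawns in the bottom layer), and
#' windows are clipped at the decision horizon `T - dt`: a clipped window
#' charges its ascent but no descent.
#'
#' @param windows list of numeric length-2 vectors `c(start, end)`; may be
#'   empty (larva stays in the bottom layer).
#' @param params a [model_params()] object.
#' @param label optional behavior label carried into summaries.
#' @return An object of class `c("schedule", "behavior")` with fields
#'   `actions` (length `N`), `z_path` (implied layers, length `N + 1`),
#'   `windows`, and `charge_migration_cost = TRUE`.
#' @export
#' @examples
#' p <- model_params()
#' s <- schedule_from_windows(list(c(0.125, 4)), p)   # the OVM archetype
#' surface_time(s)   # 4 days
#' n_migrations(s)   # 2
schedule_from_windows <- function(windows, params, label = "schedule") {
  stopifnot(inherits(params, "model_params"), is.list(windows))
  dt <- params$dt
  N <- n_steps(params)
  on_grid <- function(x) abs(x / dt - round(x / dt)) < 1e-9
  if (length(windows)) {
    ok <- vapply(windows, function(w) {
      is.numeric(w) && length(w) == 2L && w[1] <= w[2]
    }, logical(1))
    if (!all(ok)) stop("each window must be a numeric c(start, end) with start <= end")
    starts <- vapply(windows, `[`, numeric(1), 1L)
    ends <- vapply(windows, `[`, numeric(1), 2L)
    if (!all(on_grid(starts)) || !all(on_grid(ends))) {
      stop("window endpoints must lie on the dt grid (dt = ", dt, ")")
    }
    if (any(starts < 0) || any(starts > params$T)) {
      stop("window starts must lie within [0, T]")
    }
    o <- order(starts)
    starts <- starts[o]; ends <- ends[o]
    if (length(starts) > 1L && any(starts[-1] <= ends[-length(ends)])) {
      stop("surface windows overlap")
    }
  } else {
    starts <- ends <- numeric(0)
  }
  times <- (0:N) * dt
  z <- rep(0L, N + 1L)
  for (i in seq_along(starts)) {
    z[times >= starts[i] - 1e-9 & times <= ends[i] + 1e-9] <- 1L
  }
  z[1L] <- 0L  # spawning is always in the bottom layer
  actions <- as.integer(diff(z))
  structure(
    list(actions = actions, z_path = z,
         windows = Map(c, starts, ends),
         dt = dt, N = N, charge_migration_cost = TRUE, label = label),
    class = c("schedule", "behavior")
  )
}

#' The named vertical-swimming archetypes
#'
#' Constructs the three active archetypes for the default 20-day larval
#' duration:
#' \describe{
#'   \item{ovm}{ontogenetic vertical migration: surface residence for the
#'     first four days (`[dt, 4]`), bottom thereafter; 2 migrations.}
#'   \item{dvm}{diel vertical migration: surface each night from 21:00 to
#'     03:00 (windows `[k + 0.875, k + 1.125]`, k = 0..19, clipped at the
#'     horizon); 7.25 surface-days and 39 migrations at dt = 1/8.}
#'   \item{hybrid}{nightly surface visits 18:00-06:00 for the first 8 days
#'     (windows `[k + 0.75, k + 1.25]`, k = 0..7); 5 surface-days and 16
#'     migrations.}
#' }
#' Clock convention: spawning occurs at midnight, so 06:00 on day k is
#' `t = k + 0.25`.  Window endpoints are inclusive surface-held steps.
#'
#' @param name one of `"ovm"`, `"dvm"`, `"hybrid"`.
#' @param params a [model_params()] object with `T = 20` (the published
#'   archetypes are defined for the medium larval duration; build other
#'   horizons explicitly with [schedule_from_windows()]).
#' @return A schedule, as from [schedule_from_windows()].
#' @export
make_archetype <- function(name = c("ovm", "dvm", "hybrid"), params) {
  name <- match.arg(name)
  stopifnot(inherits(params, "model_params"))
  if (abs(params$T - 20) > 1e-9) {
    stop("archetype '", name, "' is defined for T = 20 days; ",
         "use schedule_from_windows() for other larval durations")
  }
  windows <- switch(name,
    ovm = list(c(params$dt, 4)),
    dvm = lapply(0:19, function(k) c(k + 0.875, k + 1.125)),
    hybrid = lapply(0:7, function(k) c(k + 0.75, k + 1.25))
  )
  schedule_from_windows(windows, params, label = name)
}

#' Total surface residency and migration count of a schedule
#'
#' `surface_time` is `dt` times the number of decision steps held in the
#' surface layer (step-start accounting over steps `0 .. N-1`; the
#' terminal state does not feed).  `n_migrations` counts nonzero depth
#' changes.
#'
#' @param schedule a schedule object.
#' @return Days of surface residency, or an integer migration count.
#' @export
surface_time <- function(schedule) {
  stopifnot(inherits(schedule, "schedule"))
  schedule$dt * sum(schedule$z_path[seq_len(schedule$N)] == 1L)
}

#' @rdname surface_time
#' @export
n_migrations <- function(schedule) {
  stopifnot(inherits(schedule, "schedule"))
  sum(schedule$actions != 0L)
}

#' Passive drifting as a two-state vertical Markov chain
#'
#' Passive larvae have no active depth control; their vertical position is
#' shuffled by turbulence.  We model this as a per-step Markov chain:
#' from the bottom the larva surfaces with probability `q_up`, from the
#' surface it sinks with probability `q_down`.  The defaults give a
#' stationary surface occupancy `q_up / (q_up + q_down) = 0.2`, matching
#' the relative thickness `alpha / (1 + alpha)` of the surface layer at
#' `alpha = 0.25`, with a mean surface sojourn of two steps (6 h).
#' Because the movement is not active swimming, the migration energy cost
#' `V` is waived by default.
#'
#' @param q_up per-step bottom-to-surface switch probability.
#' @param q_down per-step surface-to-bottom switch probability.
#' @param charge_migration_cost charge `V` per layer switch?  Default
#'   `FALSE` (turbulent displacement, not swimming).
#' @return An object of class `c("passive_process", "behavior")`.
#' @export
passive_process <- function(q_up = 0.125, q_down = 0.5,
                            charge_migration_cost = FALSE) {
  stopifnot(q_up >= 0, q_up <= 1, q_down >= 0, q_down <= 1)
  structure(list(q_up = q_up, q_down = q_down,
                 charge_migration_cost = charge_migration_cost,
                 label = "passive"),
            class = c("passive_process", "behavior"))
}

#' One vertical move of the passive process
#'
#' Draws the depth change for larvae currently in layers `z` using the
#' current RNG stream (or the supplied uniform deviates `u`, used by the
#' vectorized simulator so the draw order is reproducible).
#'
#' @param z current layers, 0/1 (vectorized).
#' @param proc a [passive_process()].
#' @param u optional uniform(0,1) deviates, one per larva.
#' @return Integer depth changes in `{-1, 0, +1}`, admissible for each `z`.
#' @export
passive_step <- function(z, proc, u = stats::runif(length(z))) {
  stopifnot(inherits(proc, "passive_process"), all(z %in% c(0, 1)),
            length(u) == length(z))
  ifelse(z == 0L, as.integer(u < proc$q_up), -as.integer(u < proc$q_down))
}

behavior_label <- function(behavior) {
  if (!is.null(behavior$label)) behavior$label else class(behavior)[1L]
}

#' @export
print.schedule <- function(x, ...) {
  cat(sprintf("Open-loop schedule '%s': %d steps, %g surface-days, %d migrations\n",
              behavior_label(x), x$N, surface_time(x), n_migrations(x)))
  invisible(x)
}

#' @export
print.passive_process <- function(x, ...) {
  cat(sprintf("Passive vertical process: q_up = %g, q_down = %g (stationary surface occupancy %.3g)\n",
              x$q_up, x$q_down,
              if (x$q_up + x$q_down > 0) x$q_up / (x$q_up + x$q_down) else 0))
  invisible(x)
}

#' Read or write a schedule as CSV
#'
#' The on-disk format is two columns, `t` (decision time, days) and `dZ`
#' (the depth change taken at `t`), one row per decision step.
#'
#' @param schedule a schedule object.
#' @param path file path.
#' @param params a [model_params()] object (for reading).
#' @return `read_schedule_csv` returns a schedule; `write_schedule_csv`
#'   returns `path` invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "schedule"))
  d <- data.frame(t = (seq_len(schedule$N) - 1L) * schedule$dt,
                  dZ = schedule$actions)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path, params) {
  d <- utils::read.csv(path)
  stopifnot(all(c("t", "dZ") %in% names(d)))
  N <- n_steps(params)
  if (nrow(d) != N) {
    stop("schedule has ", nrow(d), " rows but params imply N = ", N)
  }
  actions <- as.integer(d$dZ[order(d$t)])
  z <- cumsum(c(0L, actions))
  if (any(z < 0L | z > 1L)) stop("schedule implies layers outside {0, 1}")
  structure(
    list(actions = actions, z_path = z, windows = NULL, dt = params$dt,
         N = N, charge_migration_cost = TRUE, label = "schedule"),
    class = c("schedule", "behavior")
  )
}
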