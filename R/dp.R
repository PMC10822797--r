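# Gauss-Hermite quadrature for a standard normal variate (Golub-Welsch).
# Returns nodes xi_q and weights w_q with sum(w) = 1, so that
# E[f(xi)] ~ sum_q w_q f(xi_q) for xi ~ N(0, 1).
.gauss_hermite_normal <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = 1))
  k <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  off <- sqrt(k / 2)
  J[cbind(k, k + 1L)] <- off
  J[cbind(k + 1L, k)] <- off
  eg <- eigen(J, symmetric = TRUE)
  ord <- order(eg$values)
  list(nodes = sqrt(2) * eg$values[ord],
       weights = eg$vectors[1L, ord]^2 / sum(eg$vectors[1L, ]^2))
}

#' Discretization grids for the dynamic program
#'
#' Uniform grids over offshore distance and energy.  The default offshore
#' extent follows the rule `X_max >= 1 + U*T + 6*sqrt(2*K*T)` (habitat
#' width plus maximal advection plus six diffusive standard deviations),
#' rounded up to a multiple of 10, so that the flat-value clamp at the
#' offshore edge truncates a negligible amount of probability mass.
#'
#' @param params a [model_params()] object.
#' @param dx offshore grid spacing (habitat widths), default 0.1.
#' @param de energy grid spacing (metamorphosis-cost units), default
#'   0.0125; must divide `E_max`.  The default equals the per-step
#'   maintenance increment `G * dt` of the standard parameterization, so
#'   the (nearly deterministic) energy dimension propagates along grid
#'   nodes and repeated linear interpolation does not diffuse the value
#'   function across the metamorphosis kink at `E = 1`.
#' @param x_max offshore extent; defaults to the rule above.  A smaller
#'   user-supplied value triggers a warning.
#' @return An object of class `state_grids` with fields `x`, `e`, `dx`,
#'   `de`, `x_max`.
#' @export
#' @examples
#' g <- build_grids(model_params())   # x_max = 40, 401 x 101 nodes
#' length(g$e)                        # 101 energy nodes
build_grids <- function(params, dx = 0.1, de = 0.0125, x_max = NULL) {
  stopifnot(inherits(params, "model_params"), dx > 0, de > 0)
  rule <- 1 + params$U * params$T + 6 * sqrt(2 * params$K * params$T)
  if (is.null(x_max)) {
    x_max <- 10 * ceiling(rule / 10)
  } else if (x_max < rule) {
    warning(sprintf(
      "x_max = %g is below the recommended extent %.3g; offshore truncation may bias values",
      x_max, rule))
  }
  nxm <- x_max / dx
  nem <- params$E_max / de
  if (abs(nxm - round(nxm)) > 1e-8) stop("dx must divide x_max")
  if (abs(nem - round(nem)) > 1e-8) stop("de must divide E_max")
  structure(
    list(x = seq(0, x_max, length.out = round(nxm) + 1L),
         e = seq(0, params$E_max, length.out = round(nem) + 1L),
         dx = dx, de = de, x_max = x_max),
    class = "state_grids"
  )
}

#' Terminal reward of the dynamic program
#'
#' The value at the settlement time `t = T` is the terminal part of the
#' Trajectory Score, `p_settle * (1 - phi_settle(X)) + p_meta *
#' (1 - phi_meta(E))`; it does not depend on the depth layer.
#'
#' @param grids a [build_grids()] object.
#' @param weights a [score_weights()] object.
#' @return A matrix of dimension `length(grids$x) x length(grids$e)`.
#' @export
terminal_value <- function(grids, weights) {
  stopifnot(inherits(grids, "state_grids"), inherits(weights, "score_weights"))
  vx <- weights$p_settle * (1 - settling_penalty(grids$x))
  ve <- weights$p_meta * (1 - metamorphosis_penalty(grids$e))
  outer(vx, rep(1, length(grids$e))) + outer(rep(1, length(grids$x)), ve)
}

# Sparse transition operators.  For each held layer z, A[[z+1]] is the
# nx-by-nx expected-interpolation operator over the reflected, clamped
# Gauss-Hermite image of each x node (rows sum to 1).  For each (z, action)
# the ne-by-ne operator B maps value columns through the deterministic
# energy update with linear interpolation.  The Bellman expectation is then
# E[V'] = A %*% V %*% B, a pair of sparse-dense products per candidate
# action.
.dp_precompute <- function(grids, params, weights, n_quad) {
  q <- .gauss_hermite_normal(n_quad)
  x <- grids$x; nx <- length(x)
  e <- grids$e; ne <- length(e)
  A <- vector("list", 2L)
  for (z in 0:1) {
    mu <- layer_advection(params, z) * params$dt
    sig <- sqrt(2 * layer_diffusivity(params, z) * params$dt)
    xp <- abs(outer(x, sig * q$nodes + mu, "+"))      # reflect at the shore
    xp <- pmin(xp, grids$x_max)                        # flat clamp offshore
    lo <- findInterval(xp, x)
    lo <- pmin(pmax(lo, 1L), nx - 1L)
    w <- (xp - x[lo]) / grids$dx
    wq <- matrix(q$weights, nx, n_quad, byrow = TRUE)
    i <- rep.int(seq_len(nx), 2L * n_quad)
    A[[z + 1L]] <- Matrix::sparseMatrix(
      i = i, j = c(as.vector(lo), as.vector(lo + 1L)),
      x = c(as.vector(wq * (1 - w)), as.vector(wq * w)),
      dims = c(nx, nx))
  }
  B <- list(`0` = vector("list", 2L), `1` = vector("list", 2L))
  acts <- list(c(0L, 1L), c(0L, -1L))  # admissible actions per layer
  for (z in 0:1) {
    for (j in 1:2) {
      a <- acts[[z + 1L]][j]
      ep <- e + (params$F * z - params$G) * params$dt - params$V * abs(a)
      ep <- pmin(pmax(ep, 0), params$E_max)
      lo <- findInterval(ep, e)
      lo <- pmin(pmax(lo, 1L), ne - 1L)
      w <- (ep - e[lo]) / grids$de
      B[[z + 1L]][[j]] <- Matrix::sparseMatrix(
        i = c(lo, lo + 1L), j = rep.int(seq_len(ne), 2L),
        x = c(1 - w, w), dims = c(ne, ne))
    }
  }
  list(A = A, B = B, acts = acts,
       epos = as.numeric(e > 0), nx = nx, ne = ne)
}

# Running reward accrued over [t, t+dt) at the pre-decision state:
# (dt/T) * (p_pred * 1[outside high-predation region] + p_starve * 1[E>0]).
# Returned as one nx-by-ne matrix per layer.
.step_reward <- function(t, grids, params, weights, epos = as.numeric(grids$e > 0)) {
  nx <- length(grids$x); ne <- length(grids$e)
  base <- params$dt / params$T
  out <- switch(params$predation_scheme,
    nearshore = {
      o <- as.numeric(grids$x > 1)
      list(o, o)
    },
    diurnal = {
      clock <- t %% 1
      day <- clock >= params$daylight_window[1] - 1e-9 &&
        clock < params$daylight_window[2] - 1e-9
      list(rep(1, nx), rep(as.numeric(!day), nx))
    })
  lapply(out, function(o) {
    outer(base * weights$p_pred * o, rep(1, ne)) +
      outer(rep(1, nx), base * weights$p_starve * epos)
  })
}

# One backward-induction sweep given precomputed operators.
# Vn: nx x ne x 2 array of values at t + dt; r: list of per-layer reward
# matrices at t.  Ties between staying and migrating break toward staying:
# migration requires an improvement beyond 1e-12, so policies are
# deterministic and mathematically tied actions (which can differ by an
# ulp through interpolation-weight rounding) resolve to "stay".
.backup_step <- function(Vn, r, pre) {
  nx <- pre$nx; ne <- pre$ne
  V <- array(NA_real_, c(nx, ne, 2L))
  P <- array(0L, c(nx, ne, 2L))
  for (z in 0:1) {
    zi <- z + 1L
    acts <- pre$acts[[zi]]
    ev <- vector("list", 2L)
    for (j in 1:2) {
      zp <- z + acts[j]
      ev[[j]] <- as.matrix(pre$A[[zi]] %*% (Vn[, , zp + 1L] %*% pre$B[[zi]][[j]]))
    }
    take <- ev[[2L]] > ev[[1L]] + 1e-12
    best <- ev[[1L]]
    best[take] <- ev[[2L]][take]
    V[, , zi] <- r[[zi]] + best
    p <- P[, , zi]
    p[take] <- acts[2L]
    P[, , zi] <- p
  }
  if (!all(is.finite(V))) {
    idx <- which(!is.finite(V), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at node (ix = %d, ie = %d, z = %d)",
                 idx[1L], idx[2L], idx[3L] - 1L))
  }
  list(values = V, policy = P)
}

#' One Bellman backup
#'
#' Computes the value and greedy policy at decision time `t` from the
#' value slice at `t + dt`: running reward at the pre-decision state plus
#' the maximal quadrature expectation of the interpolated future value
#' over the admissible depth changes.  Expectations over the cross-shore
#' noise use fixed-node Gauss-Hermite quadrature; future values are
#' bilinearly interpolated in `(X, E)`; the shore reflects and the
#' offshore edge clamps with a flat value extension.
#'
#' @param V_next value at `t + dt`: an `nx x ne x 2` array (or an
#'   `nx x ne` matrix, e.g. from [terminal_value()], taken as
#'   layer-independent).
#' @param t decision time, days.
#' @param grids a [build_grids()] object.
#' @param params a [model_params()] object.
#' @param weights a [score_weights()] object.
#' @param n_quad number of quadrature nodes (default 9).
#' @return A list with `values` (`nx x ne x 2` array) and `policy`
#'   (integer array of the same shape, codes -1/0/+1).
#' @export
bellman_backup <- function(V_next, t, grids, params, weights, n_quad = 9L) {
  if (is.matrix(V_next)) {
    V_next <- array(c(V_next, V_next), c(nrow(V_next), ncol(V_next), 2L))
  }
  stopifnot(length(dim(V_next)) == 3L,
            dim(V_next)[1] == length(grids$x),
            dim(V_next)[2] == length(grids$e))
  pre <- .dp_precompute(grids, params, weights, n_quad)
  r <- .step_reward(t, grids, params, weights, pre$epos)
  .backup_step(V_next, r, pre)
}

#' Solve for the optimal swimming policy by backward induction
#'
#' Maximizes the expected Trajectory Score over closed-loop depth-change
#' policies on the discretized `(t, X, E, Z)` state space, sweeping from
#' the terminal reward at `t = T` back to spawning.  The solver is
#' deterministic: expectations use fixed Gauss-Hermite nodes and ties
#' break toward not migrating.
#'
#' @param params a [model_params()] object.
#' @param weights a [score_weights()] object.
#' @param grids a [build_grids()] object.
#' @param n_quad quadrature nodes for the cross-shore noise (default 9).
#' @param keep_values `"all"` stores the full value array (one
#'   `nx x ne x 2` slice per time, ~100 MB at default grids); `"initial"`
#'   keeps only the `t = 0` and terminal slices.
#' @return An object of class `dp_solution`: `policy` (list of `N`
#'   integer arrays), `values` (list of `N + 1` slices, `NULL` where
#'   dropped), plus `grids`, `params`, `weights`, `n_quad`.
#' @export
#' @examples
#' \donttest{
#' p <- model_params(predation_scheme = "diurnal")
#' sol <- solve_policy(p, keep_values = "initial")
#' mean_initial_value(sol)   # expected score from the spawning distribution
#' }
solve_policy <- function(params, weights = score_weights(),
                         grids = build_grids(params), n_quad = 9L,
                         keep_values = c("all", "initial")) {
  keep_values <- match.arg(keep_values)
  stopifnot(inherits(params, "model_params"))
  N <- n_steps(params)
  pre <- .dp_precompute(grids, params, weights, n_quad)
  Vterm <- terminal_value(grids, weights)
  Vn <- array(c(Vterm, Vterm), c(pre$nx, pre$ne, 2L))
  policy <- vector("list", N)
  values <- vector("list", N + 1L)
  values[[N + 1L]] <- Vn
  for (k in N:1) {
    t <- (k - 1L) * params$dt
    r <- .step_reward(t, grids, params, weights, pre$epos)
    bs <- .backup_step(Vn, r, pre)
    Vn <- bs$values
    policy[[k]] <- bs$policy
    if (keep_values == "all" || k == 1L) values[[k]] <- Vn
  }
  structure(
    list(policy = policy, values = values, grids = grids, params = params,
         weights = weights, n_quad = n_quad),
    class = "dp_solution"
  )
}

#' Look up the optimal action for simulated states
#'
#' Nearest-node lookup in the solved policy (cheap and always admissible);
#' offshore positions beyond the grid edge clamp to the edge node.
#'
#' @param solution a [solve_policy()] result.
#' @param t decision time, days (scalar).
#' @param X,Z,E state vectors (one entry per larva).
#' @return Integer depth changes.
#' @export
policy_lookup <- function(solution, t, X, Z, E) {
  stopifnot(inherits(solution, "dp_solution"))
  g <- solution$grids
  k <- as.integer(round(t / solution$params$dt)) + 1L
  if (k < 1L || k > length(solution$policy)) {
    stop("t = ", t, " is outside the decision horizon")
  }
  ix <- pmin(pmax(as.integer(round(X / g$dx)) + 1L, 1L), length(g$x))
  ie <- pmin(pmax(as.integer(round(E / g$de)) + 1L, 1L), length(g$e))
  solution$policy[[k]][cbind(ix, ie, Z + 1L)]
}

#' Use a solved policy as a closed-loop behavior
#'
#' @param solution a [solve_policy()] result.
#' @param label behavior label for summaries.
#' @return An object of class `c("policy_behavior", "behavior")` accepted
#'   by [simulate_ensemble()].
#' @export
as_behavior <- function(solution, label = "optimal") {
  stopifnot(inherits(solution, "dp_solution"))
  structure(list(solution = solution, charge_migration_cost = TRUE,
                 label = label),
            class = c("policy_behavior", "behavior"))
}

#' Interpolated value at arbitrary states
#'
#' Bilinear interpolation of a stored value slice; used by the test
#' oracles and convergence diagnostics.
#'
#' @param solution a [solve_policy()] result (the slice at `t` must have
#'   been kept).
#' @param t time, days.
#' @param X,E state coordinates (vectorized, equal length).
#' @param Z depth layer (scalar 0/1).
#' @return Interpolated values.
#' @export
value_at <- function(solution, t, X, E, Z = 0L) {
  stopifnot(inherits(solution, "dp_solution"))
  g <- solution$grids
  k <- as.integer(round(t / solution$params$dt)) + 1L
  V <- solution$values[[k]]
  if (is.null(V)) stop("value slice at t = ", t, " was not stored")
  x <- pmin(pmax(X, 0), g$x_max)
  e <- pmin(pmax(E, 0), solution$params$E_max)
  ix <- pmin(pmax(findInterval(x, g$x), 1L), length(g$x) - 1L)
  ie <- pmin(pmax(findInterval(e, g$e), 1L), length(g$e) - 1L)
  wx <- (x - g$x[ix]) / g$dx
  we <- (e - g$e[ie]) / g$de
  zi <- Z + 1L
  (1 - wx) * (1 - we) * V[cbind(ix, ie, zi)] +
    wx * (1 - we) * V[cbind(ix + 1L, ie, zi)] +
    (1 - wx) * we * V[cbind(ix, ie + 1L, zi)] +
    wx * we * V[cbind(ix + 1L, ie + 1L, zi)]
}

#' Expected optimal score from the spawning distribution
#'
#' Averages the `t = 0` value over the uniform spawning position
#' `X_0 ~ U[0, 1]` at `Z = 0` and the spawning energy, by exact
#' integration of the piecewise-linear interpolant over `[0, 1]`.
#'
#' @param solution a [solve_policy()] result.
#' @return A scalar expected Trajectory Score.
#' @export
mean_initial_value <- function(solution) {
  stopifnot(inherits(solution, "dp_solution"))
  g <- solution$grids
  e0 <- initial_energy(solution$params)
  nodes <- g$x[g$x <= 1 + 1e-12]
  v <- value_at(solution, 0, nodes, rep(e0, length(nodes)), 0L)
  # trapezoid rule is exact for the linear interpolant on [0, 1]
  sum((v[-1] + v[-length(v)]) / 2 * diff(nodes))
}

#' @export
print.dp_solution <- function(x, ...) {
  cat(sprintf("Optimal-policy solution: %d steps, %d x %d x 2 nodes (%s predation)\n",
              length(x$policy), length(x$grids$x), length(x$grids$e),
              x$params$predation_scheme))
  cat(sprintf("  expected score from spawning distribution: %.4f\n",
              mean_initial_value(x)))
  invisible(x)
}

#' Export a solved policy
#'
#' Writes the nonzero-action entries of the policy as long-format CSV
#' (`t_index,x_index,e_index,z,action`; 0-based time and layer, 1-based
#' grid indices; entries not listed are "stay"), together with a JSON
#' sidecar recording the grids, parameters, weights, solver settings and a
#' simple content checksum, so the policy can be reconstructed exactly.
#'
#' @param solution a [solve_policy()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
export_policy <- function(solution, dir) {
  stopifnot(inherits(solution, "dp_solution"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(solution$policy), function(k) {
    idx <- which(solution$policy[[k]] != 0L, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    data.frame(t_index = k - 1L, x_index = idx[, 1L], e_index = idx[, 2L],
               z = idx[, 3L] - 1L, action = solution$policy[[k]][idx])
  })
  d <- do.call(rbind, rows)
  if (is.null(d)) {
    d <- data.frame(t_index = integer(0), x_index = integer(0),
                    e_index = integer(0), z = integer(0), action = integer(0))
  }
  utils::write.csv(d, file.path(dir, "policy.csv"), row.names = FALSE,
                   quote = FALSE)
  sidecar <- list(
    params = unclass(solution$params),
    weights = unclass(solution$weights),
    grids = list(dx = solution$grids$dx, de = solution$grids$de,
                 x_max = solution$grids$x_max),
    n_quad = solution$n_quad,
    n_nonzero_actions = nrow(d),
    checksum = sum(as.numeric(d$x_index) + 7 * as.numeric(d$e_index) +
                     13 * as.numeric(d$t_index) * d$action) %% 2^31
  )
  jsonlite::write_json(sidecar, file.path(dir, "policy.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
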