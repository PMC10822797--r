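# Micro-instance used by the oracle tests: 4 decision steps, grid-aligned
# dynamics (V = 0, alpha = 1, increments multiples of the spacings) so that
# with K = 0 every reachable state lies exactly on a node.
micro_params <- function(K) {
  model_params(T = 0.5, dt = 0.125, U = 1, K = K, alpha = 1,
               S = 0, G = 0.1, F = 0.2, V = 0, E_max = 5)
}

test_that("Gauss-Hermite rule integrates normal moments", {
  q <- larvadisp:::.gauss_hermite_normal(9L)
  expect_equal(sum(q$weights), 1, tolerance = 1e-12)
  expect_equal(sum(q$weights * q$nodes), 0, tolerance = 1e-10)
  expect_equal(sum(q$weights * q$nodes^2), 1, tolerance = 1e-10)
  expect_equal(sum(q$weights * q$nodes^4), 3, tolerance = 1e-8)
})

test_that("grid construction follows the offshore-extent rule", {
  p <- model_params()
  g <- build_grids(p)
  expect_equal(g$x_max, 40)                       # rule gives ~37.97
  expect_equal(build_grids(model_params(U = 0))$x_max, 20)
  expect_length(build_grids(p, de = 0.05)$e, 101L)
  expect_warning(build_grids(p, x_max = 10), "recommended")
  expect_error(build_grids(p, dx = 0.3, x_max = 40), "divide")
})

test_that("terminal value combines the settling and metamorphosis rewards", {
  g <- build_grids(model_params(), dx = 0.5, de = 0.5)
  w <- score_weights()
  V <- terminal_value(g, w)
  ix <- function(x) which(abs(g$x - x) < 1e-9)
  ie <- function(e) which(abs(g$e - e) < 1e-9)
  expect_equal(V[ix(0.5), ie(1.5)], 0.5)
  expect_equal(V[ix(2.0), ie(0)], 0.125)
  expect_equal(max(V), w$p_settle + w$p_meta)
  expect_true(all(V >= 0 & V <= 1))
})

test_that("one-step Bellman value matches a Monte-Carlo oracle", {
  p <- model_params(T = 0.125, dt = 0.125)   # single decision
  g <- build_grids(p, dx = 0.05, x_max = 2.5)
  w <- score_weights()
  bb <- bellman_backup(terminal_value(g, w), 0, g, p, w)
  term <- function(x, e) {
    w$p_settle * (1 - settling_penalty(x)) +
      w$p_meta * (1 - metamorphosis_penalty(e))
  }
  set.seed(55)
  n <- 2e5
  for (st in list(c(0.5, 2, 0), c(0.9, 2, 1), c(1.5, 2, 0))) {
    x0 <- st[1]; e0 <- st[2]; z <- st[3]
    acts <- if (z == 0) c(0L, 1L) else c(0L, -1L)
    mc <- vapply(acts, function(a) {
      xp <- pmin(abs(x0 + layer_advection(p, z) * p$dt +
                       rnorm(n) * sqrt(2 * layer_diffusivity(p, z) * p$dt)),
                 g$x_max)
      ep <- step_energy(e0, z, a, p)
      mean(term(xp, ep))
    }, numeric(1))
    r <- (p$dt / p$T) * (w$p_pred * (!in_high_predation(0, x0, z, p)) +
                           w$p_starve * (e0 > 0))
    oracle <- r + max(mc)
    se <- 0.25 / sqrt(n)  # generous bound on sd of the bounded terminal draw
    got <- bb$values[which(abs(g$x - x0) < 1e-9),
                     which(abs(g$e - e0) < 1e-9), z + 1]
    # 3 MC standard errors plus a small bilinear-interpolation allowance
    expect_lt(abs(got - oracle), 3 * se + 1e-3)
  }
})

test_that("deterministic micro-instance: DP equals exhaustive schedule enumeration", {
  p <- micro_params(K = 0)
  g <- build_grids(p, dx = 0.125, x_max = 2)
  w <- score_weights()
  sol <- solve_policy(p, w, g, keep_values = "initial")
  x0 <- 0.5
  vals <- vapply(enumerate_action_seqs(4L), open_loop_value_tree,
                 numeric(1), x0 = x0, params = p, weights = w,
                 n_quad = 1L, x_max = g$x_max)
  expect_equal(value_at(sol, 0, x0, initial_energy(p), 0L), max(vals),
               tolerance = 1e-10)
})

test_that("noisy micro-instance: closed-loop value dominates every open-loop schedule", {
  p <- micro_params(K = 0.05)
  g <- build_grids(p, dx = 0.05, x_max = 3)
  w <- score_weights()
  sol <- solve_policy(p, w, g, keep_values = "initial")
  x0 <- 0.5
  vdp <- value_at(sol, 0, x0, initial_energy(p), 0L)
  vals <- vapply(enumerate_action_seqs(4L), open_loop_value_tree,
                 numeric(1), x0 = x0, params = p, weights = w,
                 n_quad = 9L, x_max = g$x_max)
  expect_gte(vdp, max(vals) - 0.01)
  expect_true(all(vdp >= vals - 0.01))
})

test_that("values stay in [0,1] and are monotone non-decreasing in energy", {
  p <- model_params(T = 2)
  sol <- solve_policy(p, grids = build_grids(p, x_max = 10),
                      keep_values = "all")
  for (k in c(1L, 6L, 12L, 17L)) {
    V <- sol$values[[k]]
    expect_true(all(V >= 0 & V <= 1))
    for (z in 1:2) {
      expect_true(all(apply(V[, , z], 1, function(v) all(diff(v) >= -1e-10))))
    }
  }
})

test_that("nonfeeding larvae under diurnal predation and upwelling never ascend", {
  p <- model_params(F = 0, S = 1, predation_scheme = "diurnal")
  sol <- solve_policy(p, grids = build_grids(p, dx = 0.2, de = 0.05),
                      keep_values = "initial")
  ascents <- vapply(sol$policy, function(P) sum(P[, , 1] != 0L), integer(1))
  expect_identical(sum(ascents), 0L)
})

test_that("policy lookup: exact on nodes, clamped beyond the grid, admissible", {
  p <- model_params(T = 2)
  g <- build_grids(p, dx = 0.2, de = 0.05, x_max = 10)
  sol <- solve_policy(p, grids = g, keep_values = "initial")
  P <- sol$policy[[3L]]
  expect_identical(policy_lookup(sol, 2 * p$dt, g$x[7], 0L, g$e[11]),
                   P[7L, 11L, 1L])
  # beyond x_max: the edge node's action at the same (t, E, Z)
  expect_identical(policy_lookup(sol, 2 * p$dt, 99, 1L, g$e[11]),
                   P[length(g$x), 11L, 2L])
  # a looked-up action is always admissible for the queried layer
  set.seed(14)
  x <- runif(50, 0, 12); e <- runif(50, 0, 5); z <- rbinom(50, 1, 0.5)
  a <- policy_lookup(sol, p$dt, x, z, e)
  expect_true(all(a[z == 0] %in% c(0L, 1L)))
  expect_true(all(a[z == 1] %in% c(0L, -1L)))
})

test_that("grid refinement changes the initial value by less than 0.005", {
  p <- model_params()   # nearshore defaults
  v1 <- mean_initial_value(solve_policy(p, keep_values = "initial"))
  v2 <- mean_initial_value(solve_policy(
    p, grids = build_grids(p, dx = 0.05, de = 0.00625), n_quad = 18L,
    keep_values = "initial"))
  expect_lt(abs(v2 - v1), 0.005)
})

test_that("policy export writes sparse actions plus a reconstructing sidecar", {
  p <- model_params(T = 1)
  sol <- solve_policy(p, grids = build_grids(p, dx = 0.5, de = 0.25, x_max = 10),
                      keep_values = "initial")
  d <- withr::local_tempdir()
  export_policy(sol, d)
  pol <- read.csv(file.path(d, "policy.csv"))
  expect_named(pol, c("t_index", "x_index", "e_index", "z", "action"))
  expect_true(all(pol$action %in% c(-1L, 1L)))
  # reconstruct one slice from the CSV and compare
  k <- 1L
  rebuilt <- array(0L, dim(sol$policy[[k]]))
  rows <- pol[pol$t_index == k - 1L, ]
  rebuilt[cbind(rows$x_index, rows$e_index, rows$z + 1L)] <- rows$action
  expect_identical(rebuilt, sol$policy[[k]])
  side <- jsonlite::read_json(file.path(d, "policy.json"))
  expect_equal(side$params$U, p$U)
  expect_equal(side$n_nonzero_actions, nrow(pol))
})
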