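test_that("FVS rates reproduce the hand-evaluated monodisperse case", {
  g <- grid4()
  ps <- build_pair_index_set(g)
  ker <- aggregation_kernel("constant")
  st <- particle_state(N = c(1, 0, 0, 0), m = c(1, 0, 0, 0))
  expect_equal(fvs_tracer_rhs(st, g, ps, ker), c(-1, 1, 0, 0))
  expect_equal(fvs_number_rhs(st, g, ps, ker), c(-1, 0.5, 0, 0))

  zero <- particle_state(numeric(4), numeric(4))
  expect_equal(fvs_tracer_rhs(zero, g, ps, ker), numeric(4))
  expect_equal(fvs_number_rhs(zero, g, ps, ker), numeric(4))

  bad <- particle_state(numeric(3), numeric(3))
  expect_error(fvs_tracer_rhs(bad, g, ps, ker), "cells")
})

test_that("summed FVS number rate equals the analytic total loss", {
  # with all pairs in-domain, d(mu0)/dt = -1/2 sum_jk beta N_j N_k
  g <- build_geometric_grid(1, 14)
  ps <- build_pair_index_set(g)
  for (seed in 1:5) {
    st <- rand_state(14, seed)
    st$N[8:14] <- 0 # keep every active pair inside the domain
    for (fam in c("constant", "additive")) {
      ker <- aggregation_kernel(fam)
      act <- which(st$N > 0)
      loss <- 0
      for (j in act) {
        for (k in act) {
          loss <- loss + 0.5 * kernel_eval(ker, g$reps[j], g$reps[k]) *
            st$N[j] * st$N[k]
        }
      }
      expect_equal(sum(fvs_number_rhs(st, g, ps, ker)), -loss)
      # tracer total telescopes to zero (conservation), relative to the
      # magnitude of the death terms that cancel
      scale <- sum(st$m * (kernel_matrix(ker, g) %*% st$N))
      expect_lt(abs(sum(fvs_tracer_rhs(st, g, ps, ker))) / scale, 1e-13)
    }
  }
})

test_that("euler_step performs the componentwise explicit update", {
  st <- particle_state(N = c(2, 1), m = c(1, 0))
  up <- euler_step(st, list(m = c(-1, 1)), 0.1)
  expect_equal(up$m, c(0.9, 0.1))
  expect_equal(up$N, c(2, 1))
  expect_equal(up$t, 0.1)

  same <- euler_step(st, list(N = c(5, 5), m = c(3, 3)), 0)
  expect_equal(same$N, st$N)
  expect_equal(same$m, st$m)

  # sum-free rates conserve the total
  up2 <- euler_step(st, list(m = c(-0.3, 0.3)), 0.7)
  expect_equal(sum(up2$m), sum(st$m))
  expect_error(euler_step(st, list(m = c(0, 0)), -0.1), "nonnegative")
})

test_that("total_tracer_mass sums the tracer field", {
  expect_equal(total_tracer_mass(particle_state(c(0, 0, 0), c(1, 0, 0))), 1)
  expect_equal(total_tracer_mass(particle_state(numeric(3), numeric(3))), 0)
})

test_that("pbe_integrate handles trivial and cross-method cases", {
  # zero RHS: constant trajectory
  sol <- pbe_integrate(function(t, y) 0 * y, c(1, 2), seq(0, 1, 0.25),
    method = "rosenbrock"
  )
  expect_equal(sol$y, matrix(rep(c(1, 2), each = 5), ncol = 2))

  # one explicit Euler step is exactly euler_step
  rhs <- function(t, y) -y
  sol_e <- pbe_integrate(rhs, 1, c(0, 0.1), method = "euler", dt = 0.1)
  expect_equal(sol_e$y[2, ], 1 - 0.1)

  # adaptive and Euler agree to O(dt) on a monodisperse constant-kernel batch
  g <- grid4()
  op_rhs <- function(t, y) {
    st <- particle_state(y[1:4], y[5:8])
    ps <- build_pair_index_set(g)
    ker <- aggregation_kernel("constant")
    c(fvs_number_rhs(st, g, ps, ker), fvs_tracer_rhs(st, g, ps, ker))
  }
  y0 <- c(1, 0, 0, 0, 1, 0, 0, 0)
  ref <- pbe_integrate(op_rhs, y0, c(0, 0.5), method = "rk45", rtol = 1e-10, atol = 1e-12)
  eul <- pbe_integrate(op_rhs, y0, c(0, 0.5), method = "euler", dt = 0.002)
  ros <- pbe_integrate(op_rhs, y0, c(0, 0.5), method = "rosenbrock")
  expect_lt(max(abs(eul$y[2, ] - ref$y[2, ])), 0.01)
  expect_lt(max(abs(ros$y[2, ] - ref$y[2, ])), 1e-6)
})

test_that("integration failures raise informative errors", {
  blow <- function(t, y) y^2
  expect_error(
    pbe_integrate(blow, 1, c(0, 2), method = "rosenbrock"),
    "integration failure"
  )
  expect_error(pbe_integrate(function(t, y) y, 1, c(0, 1), method = "euler"),
    "dt"
  )
  expect_error(
    pbe_integrate(function(t, y) y, 1, c(0, 1), rtol = -1),
    "positive"
  )
})

test_that("batch FVS conserves total tracer mass along the flow", {
  cfg <- batch_config("additive", p = 2, cells = 30, t_end = 1.2, n_out = 13)
  res <- run_batch(cfg)
  expect_lt(res$diagnostics$max_conservation_drift, 1e-9)
})

test_that("constant-kernel zeroth moment follows 2/(2 + t)", {
  cfg <- batch_config("constant", p = 1, cells = 14, t_end = 2, n_out = 21)
  res <- run_batch(cfg)
  expect_lt(max(abs(res$metrics$mu0 - 2 / (2 + res$metrics$time))), 1e-4)
})
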