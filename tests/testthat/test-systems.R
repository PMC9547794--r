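test_that("monodisperse initial state targets the unit-volume cell", {
  g <- grid4()
  st <- make_monodisperse_state(g, number = 1, tracer = 1)
  expect_equal(st$N, c(1, 0, 0, 0))
  expect_equal(st$m, c(1, 0, 0, 0))
  expect_equal(sum(st$N), 1)
  expect_equal(total_tracer_mass(st), 1)

  # a grid whose domain misses v = 1 is rejected
  tiny <- build_geometric_grid(1, 3, v1 = 0.001)
  expect_error(make_monodisperse_state(tiny), "no grid cell contains")
})

test_that("batch driver honors the stopping contract", {
  # t_end = 0 returns the initial state
  cfg0 <- batch_config("constant", p = 1, cells = 8, t_end = 0)
  res0 <- run_batch(cfg0)
  expect_equal(res0$times, 0)
  expect_equal(res0$N[1, ], make_monodisperse_state(res0$grid)$N)

  # constant kernel: mu0 = 2/(2+t) exactly on any grid, so the I_agg = 0.5
  # stop lands at t = 2 regardless of binning
  cfg <- batch_config("constant", p = 1, cells = 16, target_iagg = 0.5)
  res <- run_batch(cfg)
  expect_equal(res$stop_time, 2, tolerance = 1e-4)
  expect_equal(res$achieved_iagg, 0.5, tolerance = 1e-6)

  # stopping is solver-independent within tolerance (event interpolation)
  cfg_rk <- batch_config("constant",
    p = 1, cells = 16, target_iagg = 0.5,
    solver = solver_config("rk45")
  )
  expect_equal(run_batch(cfg_rk)$stop_time, res$stop_time, tolerance = 1e-3)

  expect_error(batch_config("constant", target_iagg = 1.2), "0, 1")
  expect_error(batch_config("constant"), "target_iagg")
})

test_that("explicit Euler option integrates with the positivity-capped step", {
  # default dt is capped at 0.5 / max death coefficient: positivity only
  cfg <- batch_config("constant",
    p = 1, cells = 10, t_end = 0.5, n_out = 6,
    solver = solver_config("explicit_euler")
  )
  res <- run_batch(cfg)
  expect_true(all(res$N >= 0))
  expect_equal(res$metrics$mu0, 2 / (2 + res$times), tolerance = 0.02)
  # an explicit dt controls the first-order accuracy as usual
  cfg2 <- batch_config("constant",
    p = 1, cells = 10, t_end = 0.5, n_out = 6,
    solver = solver_config("explicit_euler", dt = 0.005)
  )
  res2 <- run_batch(cfg2)
  expect_equal(res2$metrics$mu0, 2 / (2 + res2$times), tolerance = 5e-4)
})

test_that("gel guard stops product-kernel runs on genuine mass outflow", {
  # tiny domain: the gel flux through v_max is reached quickly
  cfg <- batch_config("multiplicative",
    p = 1, cells = 6, target_iagg = 0.999,
    t_end = 12, n_out = 25
  )
  res <- run_batch(cfg)
  expect_true(res$diagnostics$gel_detected)
  expect_lt(res$achieved_iagg, 0.999)
})

test_that("MSMPR steady state without aggregation is the pure nucleation balance", {
  cfg <- msmpr_config(aggregation_kernel("additive", beta0 = 0),
    p = 1, cells = 10
  )
  ss <- compute_steady_state(cfg)
  expect_equal(sum(ss$N), 1, tolerance = 1e-9) # B0 * tau
  expect_equal(ss$N[1], 1, tolerance = 1e-9) # all in the nucleation cell
  expect_lt(attr(ss, "residual"), 1e-9)
  expect_equal(attr(ss, "iagg_ss"), 0, tolerance = 1e-9)
})

test_that("MSMPR tracer pulse decays exactly exponentially in total mass", {
  cfg <- msmpr_config(aggregation_kernel("additive", beta0 = 0.2),
    p = 1, cells = 18, n_out = 31
  )
  ss <- compute_steady_state(cfg)
  expect_lt(attr(ss, "residual"), 1e-9)
  res <- run_msmpr_tracer(cfg, ss)
  met <- res$metrics
  expect_equal(met$m_T[1], 1) # T = 0 pulse mass
  expect_equal(met$lambda_T[1], 1) # pulse sits at v0 = 1
  # aggregation conserves tracer, washout is linear: m_T = m0 exp(-T)
  expect_lt(max(abs(met$m_T - exp(-met$T))), 1e-5)
  # the number field stays at its stationary values
  expect_equal(res$N[nrow(res$N), ], ss$N)
})

test_that("coupled re-integration leaves the steady number field stationary", {
  cfg <- msmpr_config(aggregation_kernel("additive", beta0 = 0.2),
    p = 1, cells = 14, n_out = 7, T_end = 1
  )
  ss <- compute_steady_state(cfg)
  res <- run_msmpr_tracer(cfg, ss, reintegrate_N = TRUE)
  expect_lt(rel_diff(res$N[nrow(res$N), ], ss$N), 1e-6)
  expect_lt(max(abs(res$metrics$m_T - exp(-res$metrics$T))), 1e-4)
})

test_that("invalid MSMPR configurations are rejected", {
  expect_error(msmpr_config("additive", B0 = 0), "positive")
  expect_error(msmpr_config("additive", tau = -1), "positive")
})
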