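#' Batch aggregation run configuration
#'
#' Describes a batch (closed) aggregation experiment: monodisperse unit-volume
#' start \eqn{f_0(v) = \delta(v - 1)} with the tracer marking the initial
#' primaries (\eqn{m_0(v) = \delta(v - 1)}), integrated until either a target
#' degree of aggregation or an end time.
#'
#' @param kernel an [aggregation_kernel()] (or a family name).
#' @param p,cells,v1 geometric grid parameters, see [build_geometric_grid()].
#' @param scheme `"fvs"` (finite-volume scheme) or `"cat"` (cell average
#'   technique).
#' @param target_iagg stopping degree of aggregation in (0, 1), or `NULL` to
#'   run to `t_end`.
#' @param t_end end time (used when `target_iagg` is `NULL`; also the safety
#'   horizon of a target run).
#' @param number0,tracer0 initial particle number and tracer mass.
#' @param solver a [solver_config()].
#' @param n_out number of output times.
#' @return A `pbe_batch_config`.
#' @export
batch_config <- function(kernel, p = 1, cells = 23, v1 = 1,
                         scheme = c("fvs", "cat"),
                         target_iagg = NULL, t_end = NULL,
                         number0 = 1, tracer0 = 1,
                         solver = solver_config(), n_out = 101L) {
  if (is.character(kernel)) kernel <- aggregation_kernel(kernel)
  stopifnot(inherits(kernel, "pbe_kernel"))
  scheme <- match.arg(scheme)
  if (!is.null(target_iagg)) {
    if (!is.numeric(target_iagg) || target_iagg <= 0 || target_iagg >= 1) {
      stop("`target_iagg` must lie in (0, 1)", call. = FALSE)
    }
  } else if (is.null(t_end)) {
    stop("give either `target_iagg` or `t_end`", call. = FALSE)
  }
  structure(
    list(
      system = "batch", kernel = kernel, p = p, cells = cells, v1 = v1,
      scheme = scheme, target_iagg = target_iagg, t_end = t_end,
      number0 = number0, tracer0 = tracer0, solver = solver,
      n_out = as.integer(n_out)
    ),
    class = c("pbe_batch_config", "pbe_config")
  )
}

#' MSMPR run configuration
#'
#' Mixed-suspension mixed-product removal crystallizer: nucleation at rate
#' \eqn{B_0} (nuclei placed at the first representative, carrying no tracer),
#' size-independent washout at residence time \eqn{\tau}, and aggregation. The
#' tracer transient starts from a pulse \eqn{m(0, v) = m_0 \delta(v - v_0)}
#' over the steady-state number density.
#'
#' @inheritParams batch_config
#' @param B0 nucleation rate.
#' @param tau residence time.
#' @param v0 tracer pulse volume.
#' @param m0 tracer pulse mass.
#' @param t_end transient end time, in units of `tau` times `T_end` below.
#' @param T_end dimensionless end time \eqn{T = t/\tau} of the tracer
#'   transient (default 3).
#' @return A `pbe_msmpr_config`.
#' @export
msmpr_config <- function(kernel, p = 1, cells = 23, v1 = 1,
                         scheme = c("fvs", "cat"),
                         B0 = 1, tau = 1, v0 = 1, m0 = 1,
                         T_end = 3, t_end = NULL,
                         solver = solver_config(), n_out = 61L) {
  if (is.character(kernel)) kernel <- aggregation_kernel(kernel)
  stopifnot(inherits(kernel, "pbe_kernel"))
  scheme <- match.arg(scheme)
  if (B0 <= 0 || tau <= 0 || v0 <= 0) {
    stop("`B0`, `tau` and `v0` must be positive", call. = FALSE)
  }
  if (is.null(t_end)) t_end <- T_end * tau
  structure(
    list(
      system = "msmpr", kernel = kernel, p = p, cells = cells, v1 = v1,
      scheme = scheme, B0 = B0, tau = tau, v0 = v0, m0 = m0,
      t_end = t_end, solver = solver, n_out = as.integer(n_out)
    ),
    class = c("pbe_msmpr_config", "pbe_config")
  )
}

#' Solver configuration
#'
#' @param method `"adaptive_stiff"` (Rosenbrock, the default and the mode the
#'   benchmark results were produced with), `"rk45"`, or `"explicit_euler"`.
#' @param rtol,atol local error tolerances of the adaptive methods.
#' @param dt step size for explicit Euler; when `NULL` the drivers cap it at
#'   `0.5 / max(death-rate coefficient)` of the initial state to preserve
#'   positivity.
#' @return A `pbe_solver_config`.
#' @export
solver_config <- function(method = c("adaptive_stiff", "rk45", "explicit_euler"),
                          rtol = 1e-8, atol = 1e-10, dt = NULL) {
  method <- match.arg(method)
  if (rtol <= 0 || atol <= 0) stop("tolerances must be positive", call. = FALSE)
  if (!is.null(dt) && dt <= 0) stop("`dt` must be positive", call. = FALSE)
  structure(list(method = method, rtol = rtol, atol = atol, dt = dt),
    class = "pbe_solver_config"
  )
}

solver_method <- function(solver) {
  switch(solver$method,
    adaptive_stiff = "rosenbrock",
    rk45 = "rk45",
    explicit_euler = "euler"
  )
}

#' Monodisperse initial state
#'
#' Places the whole initial population (and tracer) in the cell whose
#' representative is the unit volume (more generally, the cell containing
#' `v = 1`), the sectional image of \eqn{f_0(v) = \delta(v - 1)}.
#'
#' @param grid a [new_grid()].
#' @param number total particle number (default 1).
#' @param tracer total tracer mass (default equal to `number`).
#' @return A [particle_state()].
#' @export
make_monodisperse_state <- function(grid, number = 1, tracer = number) {
  stopifnot(inherits(grid, "pbe_grid"))
  cell <- locate_cell(grid, 1)
  N <- numeric(grid$I)
  m <- numeric(grid$I)
  N[cell] <- number
  m[cell] <- tracer
  particle_state(N, m, t = 0)
}

# cell containing volume v (preferring an exact representative match)
locate_cell <- function(grid, v) {
  hit <- which(abs(grid$reps - v) <= 1e-12 * max(v, 1))
  if (length(hit)) {
    return(hit[1L])
  }
  cell <- findInterval(v, grid$edges, left.open = TRUE)
  if (cell < 1L || cell > grid$I) {
    stop(sprintf("no grid cell contains v = %g", v), call. = FALSE)
  }
  cell
}

# internal: scheme-dispatching rates over the operator
scheme_rates <- function(scheme, op, N, m = NULL) {
  if (scheme == "fvs") {
    fvs_rates(op, N, m)
  } else {
    if (is.null(m)) m <- numeric(length(N))
    cat_rates(op, N, m)
  }
}

# build rhs/jacobian closures for the coupled (N, m) system with optional
# nucleation source (number only) and washout
make_system_fns <- function(op, scheme, B0 = 0, tau = Inf, nuc_cell = 1L,
                            number_only = FALSE, fixed_N = NULL) {
  I <- op$grid$I
  src <- numeric(I)
  if (B0 > 0) src[nuc_cell] <- B0
  wash <- if (is.finite(tau)) 1 / tau else 0
  if (!is.null(fixed_N)) {
    # tracer-only system over a frozen number density (linear in m)
    death_coef <- scheme_rates(scheme, op, fixed_N, numeric(I))$death_coef
    rhs <- function(t, y) {
      r <- scheme_rates(scheme, op, fixed_N, y)
      r$dm - wash * y
    }
    jac <- if (scheme == "fvs") {
      Jmm <- fvs_jacobian_blocks(op, fixed_N, numeric(I))[I + seq_len(I), I + seq_len(I)] -
        diag(wash, I)
      function(t, y) Jmm
    } else {
      NULL
    }
    return(list(rhs = rhs, jac = jac, linear = TRUE))
  }
  if (number_only) {
    rhs <- function(t, y) {
      scheme_rates(scheme, op, y)$dN + src - wash * y
    }
    jac <- if (scheme == "fvs") {
      function(t, y) fvs_jacobian_blocks(op, y) - diag(wash, I)
    } else {
      NULL
    }
    return(list(rhs = rhs, jac = jac, linear = FALSE))
  }
  rhs <- function(t, y) {
    N <- y[seq_len(I)]
    m <- y[I + seq_len(I)]
    r <- scheme_rates(scheme, op, N, m)
    c(r$dN + src - wash * N, r$dm - wash * m)
  }
  jac <- if (scheme == "fvs") {
    function(t, y) {
      fvs_jacobian_blocks(op, y[seq_len(I)], y[I + seq_len(I)]) - diag(wash, 2L * I)
    }
  } else {
    NULL
  }
  list(rhs = rhs, jac = jac, linear = FALSE)
}

# assemble a pbe_result from integrator output
make_result <- function(sol, grid, config, mu0_ref, tau = NULL, extra = list()) {
  I <- grid$I
  N <- sol$y[, seq_len(I), drop = FALSE]
  m <- sol$y[, I + seq_len(I), drop = FALSE]
  metrics <- moment_series(sol$times, N, m, grid, mu0_ref = mu0_ref, tau = tau)
  cons <- if (metrics$m_T[1L] != 0) metrics$m_T / metrics$m_T[1L] - 1 else rep(0, nrow(metrics))
  structure(
    c(
      list(
        times = sol$times, N = N, m = m, grid = grid, config = config,
        scheme = config$scheme, metrics = metrics,
        stop_time = sol$times[length(sol$times)],
        achieved_iagg = metrics$iagg[nrow(metrics)],
        diagnostics = list(
          nsteps = sol$nsteps, naccept = sol$naccept, nreject = sol$nreject,
          nrhs = sol$nrhs, njac = sol$njac,
          event_triggered = sol$event_triggered,
          event_index = sol$event_index,
          v_max = grid$v_max,
          max_conservation_drift = max(abs(cons))
        )
      ),
      extra
    ),
    class = "pbe_result"
  )
}

#' @export
print.pbe_result <- function(x, ...) {
  cat(sprintf(
    "<pbe_result> %s/%s: %d cells, %d output times, t in [%g, %g]\n",
    x$config$system, x$scheme, x$grid$I, length(x$times), x$times[1L],
    x$stop_time
  ))
  if (!is.null(x$achieved_iagg) && !is.na(x$achieved_iagg)) {
    cat(sprintf("  achieved I_agg = %.6g\n", x$achieved_iagg))
  }
  invisible(x)
}

# analytic guesses of the batch stop time, used to size the output grid
batch_time_guess <- function(kernel, target_iagg) {
  b0 <- kernel$beta0
  switch(kernel$family,
    constant = 2 * target_iagg / (1 - target_iagg) / b0,
    additive = -log(1 - target_iagg) / b0,
    multiplicative = 2 * target_iagg / b0
  )
}

#' Run a batch aggregation experiment
#'
#' Integrates the coupled number/tracer system from the monodisperse start with
#' the configured scheme until the target degree of aggregation (located by
#' interpolation on the zeroth-moment series) or the end time. For gelling
#' (product) kernels the driver refuses to integrate past the detected gel
#' point: it stops as soon as the first volume moment has lost more than 10%
#' of its initial value and flags the result.
#'
#' @param config a [batch_config()].
#' @return A `pbe_result` with fields `times`, `N`, `m`, `metrics` (see
#'   [moment_series()]), `stop_time`, `achieved_iagg` and solver/conservation
#'   `diagnostics`.
#' @export
run_batch <- function(config) {
  stopifnot(inherits(config, "pbe_batch_config"))
  grid <- build_geometric_grid(config$p, config$cells, config$v1)
  op <- pbe_operator(grid, config$kernel)
  state0 <- make_monodisperse_state(grid, config$number0, config$tracer0)
  I <- grid$I
  y0 <- c(state0$N, state0$m)
  mu0_ref <- sum(state0$N)
  mu1_0 <- sum(grid$reps * state0$N)
  fns <- make_system_fns(op, config$scheme)

  gelling <- config$kernel$family == "multiplicative"
  # Gel detection monitors the TOTAL TRACER MASS, which the scheme conserves
  # identically except for genuine outflow through v_max (the gel flux). The
  # number-field first moment is not suitable: sectional binning moves pair
  # sums onto representatives and therefore perturbs sum(v_i N_i) even without
  # gelation, which would falsely trigger the guard on coarse grids.
  m_tot0 <- sum(state0$m)
  gel_monitor <- function(y) {
    if (m_tot0 > 0) {
      sum(y[I + seq_len(I)]) / m_tot0 - 0.9
    } else {
      sum(grid$reps * y[seq_len(I)]) / mu1_0 - 0.9
    }
  }
  event <- NULL
  if (!is.null(config$target_iagg)) {
    t_end <- config$t_end
    if (is.null(t_end)) {
      t_end <- 3 * batch_time_guess(config$kernel, config$target_iagg)
    }
    stop_ratio <- 1 - config$target_iagg
    event <- function(t, y) {
      mu0 <- sum(y[seq_len(I)])
      ev <- c(iagg = mu0 / mu0_ref - stop_ratio)
      if (gelling) {
        ev <- c(ev, gel = gel_monitor(y))
      }
      ev
    }
  } else {
    t_end <- config$t_end
    if (gelling) {
      event <- function(t, y) c(gel = gel_monitor(y))
    }
  }
  if (t_end <= 0) {
    sol <- list(
      times = 0, y = matrix(y0, nrow = 1L), event_triggered = FALSE,
      t_event = NA_real_, event_index = NA_integer_,
      nsteps = 0L, naccept = 0L, nreject = 0L, nrhs = 0L, njac = 0L
    )
    res <- make_result(sol, grid, config, mu0_ref)
    res$diagnostics$gel_detected <- FALSE
    return(res)
  }
  times <- seq(0, t_end, length.out = config$n_out)
  solver <- config$solver
  dt <- solver$dt
  if (solver_method(solver) == "euler" && is.null(dt)) {
    dc0 <- max(scheme_rates(config$scheme, op, state0$N, state0$m)$death_coef)
    dt <- 0.5 / max(dc0, .Machine$double.eps)
  }
  sol <- pbe_integrate(
    fns$rhs, y0, times,
    method = solver_method(solver), jac = fns$jac,
    rtol = solver$rtol, atol = solver$atol, dt = dt,
    jac_refresh = if (config$scheme == "cat") 10L else 1L,
    event = event
  )
  res <- make_result(sol, grid, config, mu0_ref)
  gel_pos <- if (!is.null(config$target_iagg)) 2L else 1L
  res$diagnostics$gel_detected <- gelling && isTRUE(sol$event_triggered) &&
    identical(sol$event_index, gel_pos)
  if (!is.null(config$target_iagg) && !sol$event_triggered) {
    warning(sprintf(
      "target I_agg = %g not reached by t_end = %g (achieved %.4g)",
      config$target_iagg, t_end, res$achieved_iagg
    ), call. = FALSE)
  }
  res
}

#' Compute the MSMPR steady-state number density
#'
#' Marches the number-only system (aggregation + nucleation - washout) from an
#' empty crystallizer until the transient has died out, then polishes the root
#' of the stationary balance with damped Newton iterations so that the returned
#' state satisfies \eqn{\lVert dN/dt \rVert_\infty <} `tol`. The emergent
#' steady-state degree of aggregation \eqn{1 - \mu_0 / (B_0 \tau)} is attached
#' as attribute `iagg_ss` (it is an outcome of the balance, not an input).
#'
#' @param config a [msmpr_config()].
#' @param tol stationarity tolerance on the residual (default `1e-9`).
#' @param march_time marching horizon in units of `tau` before Newton
#'   polishing (default 30).
#' @return A [particle_state()] with attribute `iagg_ss`.
#' @export
compute_steady_state <- function(config, tol = 1e-9, march_time = 30) {
  stopifnot(inherits(config, "pbe_msmpr_config"))
  grid <- build_geometric_grid(config$p, config$cells, config$v1)
  op <- pbe_operator(grid, config$kernel)
  I <- grid$I
  fns <- make_system_fns(op, config$scheme,
    B0 = config$B0, tau = config$tau,
    nuc_cell = 1L, number_only = TRUE
  )
  # marching phase: accuracy is irrelevant, only the approach to stationarity
  sol <- pbe_integrate(
    fns$rhs, numeric(I), c(0, march_time * config$tau),
    method = "rosenbrock", jac = fns$jac,
    rtol = 1e-6, atol = 1e-12, jac_refresh = 25L
  )
  N <- sol$y[nrow(sol$y), ]
  res <- fns$rhs(0, N)
  jfun <- fns$jac
  if (is.null(jfun)) {
    jfun <- function(t, y) numeric_jacobian(fns$rhs, t, y)
  }
  for (it in seq_len(60L)) {
    if (max(abs(res)) < tol) break
    J <- jfun(0, N)
    step <- tryCatch(-solve(J, res), error = function(e) NULL)
    if (is.null(step)) {
      stop("steady-state Newton iteration hit a singular Jacobian", call. = FALSE)
    }
    lambda <- 1
    repeat {
      N_new <- N + lambda * step
      res_new <- fns$rhs(0, N_new)
      if (max(abs(res_new)) < max(abs(res)) || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    N <- N_new
    res <- res_new
  }
  if (max(abs(res)) >= tol) {
    stop(sprintf(
      "MSMPR steady state did not converge: residual %.3g after marching %g tau and Newton polish",
      max(abs(res)), march_time
    ), call. = FALSE)
  }
  state <- particle_state(N, numeric(I), t = 0)
  attr(state, "iagg_ss") <- degree_of_aggregation(sum(N), config$B0 * config$tau)
  attr(state, "residual") <- max(abs(res))
  state
}

#' Run the MSMPR tracer pulse transient
#'
#' Injects the tracer pulse \eqn{m(0, v) = m_0 \delta(v - v_0)} into the cell
#' containing `v0` and integrates the tracer equation over the stationary
#' number density (aggregation transfer + washout; nuclei carry no tracer). The
#' number density is held at the supplied steady state, which makes the tracer
#' system linear with a constant Jacobian; set `reintegrate_N = TRUE` to evolve
#' the full coupled system instead (the number field then simply stays at its
#' stationary values to solver accuracy).
#'
#' @param config a [msmpr_config()].
#' @param steady the converged [compute_steady_state()] state for `config`.
#' @param reintegrate_N logical, see above.
#' @return A `pbe_result`; `metrics` contains the dimensionless-time column
#'   `T`, the tracer decay `m_T(T)` and the mean-volume series `lambda_T`.
#' @export
run_msmpr_tracer <- function(config, steady, reintegrate_N = FALSE) {
  stopifnot(inherits(config, "pbe_msmpr_config"), inherits(steady, "pbe_state"))
  grid <- build_geometric_grid(config$p, config$cells, config$v1)
  check_state_grid(steady, grid)
  op <- pbe_operator(grid, config$kernel)
  I <- grid$I
  m0 <- numeric(I)
  m0[locate_cell(grid, config$v0)] <- config$m0
  times <- seq(0, config$t_end, length.out = config$n_out)
  solver <- config$solver
  if (reintegrate_N) {
    fns <- make_system_fns(op, config$scheme,
      B0 = config$B0, tau = config$tau, nuc_cell = 1L
    )
    sol <- pbe_integrate(
      fns$rhs, c(steady$N, m0), times,
      method = solver_method(solver), jac = fns$jac,
      rtol = solver$rtol, atol = solver$atol, dt = solver$dt,
      jac_refresh = if (config$scheme == "cat") 10L else 1L
    )
  } else {
    fns <- make_system_fns(op, config$scheme,
      tau = config$tau, fixed_N = steady$N
    )
    solm <- pbe_integrate(
      fns$rhs, m0, times,
      method = solver_method(solver), jac = fns$jac,
      rtol = solver$rtol, atol = solver$atol, dt = solver$dt,
      jac_refresh = if (config$scheme == "cat") Inf else 1L
    )
    sol <- solm
    sol$y <- cbind(
      matrix(steady$N, nrow = nrow(solm$y), ncol = I, byrow = TRUE),
      solm$y
    )
  }
  res <- make_result(sol, grid, config,
    mu0_ref = config$B0 * config$tau, tau = config$tau,
    extra = list(iagg_ss = attr(steady, "iagg_ss"))
  )
  res
}
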