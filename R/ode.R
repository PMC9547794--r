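#' Time integration of sectional PBE systems
#'
#' General-purpose integrator used by all run drivers. Three methods:
#'
#' * `"rosenbrock"` (default) — an adaptive, L-stable 2(3)-order Rosenbrock
#'   method (Shampine--Reichelt ode23s coefficients). The sectional aggregation
#'   systems are stiff (death-rate coefficients scale with `v_max`), so a
#'   stiff method mirrors the practice the benchmark results were produced
#'   with. The Jacobian may be supplied analytically; otherwise a central
#'   finite-difference Jacobian is assembled (exact for the quadratic
#'   aggregation terms).
#' * `"rk45"` — adaptive Dormand--Prince 5(4), for non-stiff validation runs.
#' * `"euler"` — fixed-step explicit Euler, the textbook update
#'   \eqn{m^{p+1}_i = m^p_i + \Delta t^p\, \dot m_i}; requires `dt`.
#'
#' An optional `event` function (signature `function(t, y)`, returning one or
#' more values that are positive while integration should continue) stops the
#' run when any component first becomes nonpositive; the crossing is located by
#' linear interpolation within the step and appended as the final output row.
#'
#' @param rhs derivative function `function(t, y)`.
#' @param y0 initial state vector.
#' @param times increasing vector of requested output times (first entry is the
#'   initial time).
#' @param method integration method, see above.
#' @param jac optional Jacobian `function(t, y)` returning the dense matrix
#'   `d rhs / d y` (Rosenbrock only).
#' @param rtol,atol relative/absolute local error tolerances (adaptive methods).
#' @param dt fixed step size (`"euler"` only).
#' @param jac_refresh recompute the Jacobian every this many accepted steps
#'   (Rosenbrock). `Inf` freezes the Jacobian after the first evaluation —
#'   appropriate for linear systems such as the tracer equation over a frozen
#'   number density.
#' @param event optional stopping function, see above.
#' @param max_steps safety cap on accepted steps.
#' @return A list with `times` (output times actually reached), `y` (matrix,
#'   one row per output time), `event_triggered`, `t_event`, `event_index`,
#'   and solver diagnostics `nsteps`, `naccept`, `nreject`, `nrhs`, `njac`.
#' @export
pbe_integrate <- function(rhs, y0, times,
                          method = c("rosenbrock", "rk45", "euler"),
                          jac = NULL, rtol = 1e-8, atol = 1e-10, dt = NULL,
                          jac_refresh = 1L, event = NULL, max_steps = 2e6) {
  method <- match.arg(method)
  y0 <- as.numeric(y0)
  times <- as.numeric(times)
  if (length(times) < 1L || is.unsorted(times, strictly = length(times) > 1L)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(y0))) stop("`y0` must be finite", call. = FALSE)
  if (method == "euler") {
    if (is.null(dt) || !is.finite(dt) || dt <= 0) {
      stop("explicit Euler requires a positive `dt`", call. = FALSE)
    }
  } else {
    if (!is.finite(rtol) || rtol <= 0 || !is.finite(atol) || atol <= 0) {
      stop("tolerances must be positive", call. = FALSE)
    }
  }
  switch(method,
    rosenbrock = ode_rosenbrock(rhs, y0, times, jac, rtol, atol, jac_refresh, event, max_steps),
    rk45 = ode_rk45(rhs, y0, times, rtol, atol, event, max_steps),
    euler = ode_euler(rhs, y0, times, dt, event, max_steps)
  )
}

# central-difference Jacobian; exact for the (dominant) quadratic terms
numeric_jacobian <- function(rhs, t, y) {
  n <- length(y)
  J <- matrix(0, n, n)
  scale <- mean(abs(y))
  for (l in seq_len(n)) {
    d <- 1e-6 * max(abs(y[l]), 1e-2 * scale, 1e-12)
    yp <- y
    ym <- y
    yp[l] <- y[l] + d
    ym[l] <- y[l] - d
    J[, l] <- (rhs(t, yp) - rhs(t, ym)) / (2 * d)
  }
  J
}

ode_fail <- function(t, h, what) {
  stop(sprintf("integration failure at t = %.8g (h = %.3g): %s", t, h, what),
    call. = FALSE
  )
}

# shared scaffolding: output collection and event location
make_collector <- function(times, y0) {
  n_out <- length(times)
  out <- matrix(NA_real_, nrow = n_out, ncol = length(y0))
  out[1L, ] <- y0
  list(out = out, n_out = n_out)
}

finish_result <- function(times, out, last_out, ev_info, diag) {
  keep <- seq_len(last_out)
  res <- list(
    times = times[keep],
    y = out[keep, , drop = FALSE],
    event_triggered = !is.null(ev_info),
    t_event = if (is.null(ev_info)) NA_real_ else ev_info$t,
    event_index = if (is.null(ev_info)) NA_integer_ else ev_info$index
  )
  if (!is.null(ev_info)) {
    res$times <- c(res$times, ev_info$t)
    res$y <- rbind(res$y, ev_info$y)
  }
  c(res, diag)
}

# check event crossing within an accepted step [t0, t1]; returns NULL or info
locate_event <- function(event, t0, y0v, ev0, t1, y1v) {
  ev1 <- event(t1, y1v)
  cross <- which(ev0 > 0 & ev1 <= 0)
  if (!length(cross)) {
    return(list(ev = ev1, hit = NULL))
  }
  theta <- ev0[cross] / (ev0[cross] - ev1[cross])
  i <- which.min(theta)
  th <- unname(theta[i])
  list(ev = ev1, hit = list(
    t = t0 + th * (t1 - t0),
    y = y0v + th * (y1v - y0v),
    index = unname(cross[i])
  ))
}

ode_rosenbrock <- function(rhs, y0, times, jac, rtol, atol, jac_refresh, event, max_steps) {
  d <- 1 / (2 + sqrt(2))
  e32 <- 6 + sqrt(2)
  n <- length(y0)
  col <- make_collector(times, y0)
  out <- col$out
  t <- times[1L]
  y <- y0
  f0 <- rhs(t, y)
  nrhs <- 1L
  njac <- 0L
  naccept <- 0L
  nreject <- 0L
  ev0 <- if (!is.null(event)) event(t, y) else NULL
  ev_info <- NULL
  t_end <- times[length(times)]
  span <- max(t_end - t, .Machine$double.eps)
  h <- span / 100
  Wi <- NULL
  steps_since_jac <- Inf
  next_out <- 2L
  get_jac <- if (is.null(jac)) function(t, y) {
    nrhs <<- nrhs + 2L * n
    numeric_jacobian(rhs, t, y)
  } else jac

  while (next_out <= col$n_out) {
    target <- times[next_out]
    if (t >= target) {
      out[next_out, ] <- y
      next_out <- next_out + 1L
      next
    }
    h <- min(h, target - t)
    hmin <- max(1e-14 * span, abs(t) * .Machine$double.eps * 16)
    if (naccept + nreject > max_steps) ode_fail(t, h, "max step count exceeded")
    if (steps_since_jac >= jac_refresh || is.null(Wi)) {
      J <- get_jac(t, y)
      njac <- njac + 1L
      steps_since_jac <- 0L
      Wi <- NULL
    }
    W <- diag(n) - (h * d) * J
    Wi <- tryCatch(solve(W), error = function(e) NULL)
    if (is.null(Wi)) {
      h <- h / 4
      if (h < hmin) ode_fail(t, h, "singular Rosenbrock matrix")
      nreject <- nreject + 1L
      next
    }
    k1 <- drop(Wi %*% f0)
    f1 <- rhs(t + h / 2, y + (h / 2) * k1)
    k2 <- drop(Wi %*% (f1 - k1)) + k1
    y1 <- y + h * k2
    f2 <- rhs(t + h, y1)
    k3 <- drop(Wi %*% (f2 - e32 * (k2 - f1) - 2 * (k1 - f0)))
    nrhs <- nrhs + 2L
    err <- (h / 6) * (k1 - 2 * k2 + k3)
    bad <- any(!is.finite(y1)) || any(!is.finite(err))
    if (bad) {
      h <- h / 4
      if (h < hmin) ode_fail(t, h, "state became non-finite")
      nreject <- nreject + 1L
      next
    }
    sc <- atol + rtol * pmax(abs(y), abs(y1))
    errnorm <- sqrt(mean((err / sc)^2))
    if (errnorm <= 1 || h <= hmin) {
      # accepted
      t1 <- t + h
      if (!is.null(event)) {
        le <- locate_event(event, t, y, ev0, t1, y1)
        if (!is.null(le$hit)) {
          ev_info <- le$hit
          break
        }
        ev0 <- le$ev
      }
      if (t1 >= target - 1e-12 * span) {
        out[next_out, ] <- y1
        next_out <- next_out + 1L
      }
      t <- t1
      y <- y1
      f0 <- f2
      naccept <- naccept + 1L
      steps_since_jac <- steps_since_jac + 1L
      h <- h * min(5, max(0.2, 0.9 * errnorm^(-1 / 3)))
    } else {
      nreject <- nreject + 1L
      h <- h * max(0.1, 0.9 * errnorm^(-1 / 3))
      if (h < hmin) ode_fail(t, h, "step size underflow")
      steps_since_jac <- Inf # refresh Jacobian after a rejection
    }
  }
  finish_result(times, out, if (is.null(ev_info)) col$n_out else next_out - 1L, ev_info,
    list(nsteps = naccept + nreject, naccept = naccept, nreject = nreject,
         nrhs = nrhs, njac = njac)
  )
}

ode_rk45 <- function(rhs, y0, times, rtol, atol, event, max_steps) {
  # Dormand-Prince 5(4)
  a <- list(
    c(1 / 5),
    c(3 / 40, 9 / 40),
    c(44 / 45, -56 / 15, 32 / 9),
    c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
    c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
    c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
  )
  cc <- c(1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
  b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
  b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200, 187 / 2100, 1 / 40)
  col <- make_collector(times, y0)
  out <- col$out
  t <- times[1L]
  y <- y0
  k1 <- rhs(t, y)
  nrhs <- 1L
  naccept <- 0L
  nreject <- 0L
  ev0 <- if (!is.null(event)) event(t, y) else NULL
  ev_info <- NULL
  t_end <- times[length(times)]
  span <- max(t_end - t, .Machine$double.eps)
  h <- span / 100
  next_out <- 2L
  while (next_out <= col$n_out) {
    target <- times[next_out]
    if (t >= target) {
      out[next_out, ] <- y
      next_out <- next_out + 1L
      next
    }
    h <- min(h, target - t)
    hmin <- max(1e-14 * span, abs(t) * .Machine$double.eps * 16)
    if (naccept + nreject > max_steps) ode_fail(t, h, "max step count exceeded")
    ks <- matrix(0, length(y), 7L)
    ks[, 1L] <- k1
    ok <- TRUE
    for (s in seq_len(6L)) {
      ys <- y + h * drop(ks[, seq_len(s), drop = FALSE] %*% a[[s]])
      if (any(!is.finite(ys))) {
        ok <- FALSE
        break
      }
      ks[, s + 1L] <- rhs(t + cc[s] * h, ys)
      nrhs <- nrhs + 1L
    }
    if (ok) {
      y1 <- y + h * drop(ks %*% b5)
      err <- h * drop(ks %*% (b5 - b4))
      ok <- all(is.finite(y1)) && all(is.finite(err))
    }
    if (!ok) {
      h <- h / 4
      if (h < hmin) ode_fail(t, h, "state became non-finite")
      nreject <- nreject + 1L
      next
    }
    sc <- atol + rtol * pmax(abs(y), abs(y1))
    errnorm <- sqrt(mean((err / sc)^2))
    if (errnorm <= 1 || h <= hmin) {
      t1 <- t + h
      if (!is.null(event)) {
        le <- locate_event(event, t, y, ev0, t1, y1)
        if (!is.null(le$hit)) {
          ev_info <- le$hit
          break
        }
        ev0 <- le$ev
      }
      if (t1 >= target - 1e-12 * span) {
        out[next_out, ] <- y1
        next_out <- next_out + 1L
      }
      t <- t1
      y <- y1
      k1 <- ks[, 7L] # FSAL
      naccept <- naccept + 1L
      h <- h * min(5, max(0.2, 0.9 * errnorm^(-1 / 5)))
    } else {
      nreject <- nreject + 1L
      h <- h * max(0.1, 0.9 * errnorm^(-1 / 5))
      if (h < hmin) ode_fail(t, h, "step size underflow")
    }
  }
  finish_result(times, out, if (is.null(ev_info)) col$n_out else next_out - 1L, ev_info,
    list(nsteps = naccept + nreject, naccept = naccept, nreject = nreject,
         nrhs = nrhs, njac = 0L)
  )
}

ode_euler <- function(rhs, y0, times, dt, event, max_steps) {
  col <- make_collector(times, y0)
  out <- col$out
  t <- times[1L]
  y <- y0
  nrhs <- 0L
  nsteps <- 0L
  ev0 <- if (!is.null(event)) event(t, y) else NULL
  ev_info <- NULL
  next_out <- 2L
  while (next_out <= col$n_out && is.null(ev_info)) {
    target <- times[next_out]
    while (t < target) {
      h <- min(dt, target - t)
      f <- rhs(t, y)
      nrhs <- nrhs + 1L
      y1 <- y + h * f
      if (any(!is.finite(y1))) ode_fail(t, h, "state became non-finite")
      nsteps <- nsteps + 1L
      if (nsteps > max_steps) ode_fail(t, h, "max step count exceeded")
      t1 <- t + h
      if (!is.null(event)) {
        le <- locate_event(event, t, y, ev0, t1, y1)
        if (!is.null(le$hit)) {
          ev_info <- le$hit
          break
        }
        ev0 <- le$ev
      }
      t <- t1
      y <- y1
    }
    if (!is.null(ev_info)) break
    out[next_out, ] <- y
    next_out <- next_out + 1L
  }
  finish_result(times, out, if (is.null(ev_info)) col$n_out else next_out - 1L, ev_info,
    list(nsteps = nsteps, naccept = nsteps, nreject = 0L, nrhs = nrhs, njac = 0L)
  )
}
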