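#' Brute-force tracer right-hand side (validation oracle)
#'
#' Direct triple loop over `(i, j, k)` that re-tests the binning condition
#' `v[i-1/2] < v_j + v_k <= v[i+1/2]` for every ordered pair, with no shared
#' machinery with the production scheme (no pair index sets, no vectorized
#' accumulation). Intended only for validating [fvs_tracer_rhs()] on small
#' grids; quadratic-time code kept deliberately naive.
#'
#' @param state a [particle_state()].
#' @param grid a [new_grid()].
#' @param kernel an [aggregation_kernel()].
#' @return Per-cell tracer-mass rates.
#' @export
brute_force_tracer_rhs <- function(state, grid, kernel) {
  check_state_grid(state, grid)
  I <- grid$I
  v <- grid$reps
  e <- grid$edges
  N <- state$N
  m <- state$m
  out <- numeric(I)
  for (i in seq_len(I)) {
    birth <- 0
    for (j in seq_len(I)) {
      for (k in seq_len(I)) {
        s <- v[j] + v[k]
        if (s > e[i] && s <= e[i + 1L]) {
          birth <- birth + 0.5 * kernel_eval(kernel, v[j], v[k]) *
            (m[j] * N[k] + m[k] * N[j])
        }
      }
    }
    death <- 0
    for (j in seq_len(I)) {
      death <- death + kernel_eval(kernel, v[i], v[j]) * N[j]
    }
    out[i] <- birth - m[i] * death
  }
  out
}

#' Brute-force number right-hand side (validation oracle)
#'
#' Companion of [brute_force_tracer_rhs()] for the number density.
#'
#' @inheritParams brute_force_tracer_rhs
#' @return Per-cell number rates.
#' @export
brute_force_number_rhs <- function(state, grid, kernel) {
  check_state_grid(state, grid)
  I <- grid$I
  v <- grid$reps
  e <- grid$edges
  N <- state$N
  out <- numeric(I)
  for (i in seq_len(I)) {
    birth <- 0
    for (j in seq_len(I)) {
      for (k in seq_len(I)) {
        s <- v[j] + v[k]
        if (s > e[i] && s <= e[i + 1L]) {
          birth <- birth + 0.5 * kernel_eval(kernel, v[j], v[k]) * N[j] * N[k]
        }
      }
    }
    death <- 0
    for (j in seq_len(I)) {
      death <- death + kernel_eval(kernel, v[i], v[j]) * N[j]
    }
    out[i] <- birth - N[i] * death
  }
  out
}

#' Discrete Smoluchowski reference solution on the unit linear grid
#'
#' Solves the classic discrete coagulation equations (and their tracer analog)
#' on the integer volume lattice `v = 1..I` by direct convolution sums,
#' \deqn{\dot N_i = \tfrac12 \sum_{j=1}^{i-1} \beta(v_j, v_{i-j}) N_j N_{i-j}
#'   - N_i \sum_j \beta(v_i, v_j) N_j,}
#' truncated at `I`. On the matching [build_linear_grid()] the finite-volume
#' scheme must agree with this reference to integrator tolerance, because every
#' pair sum coincides exactly with a representative.
#'
#' @param I lattice size.
#' @param kernel an [aggregation_kernel()].
#' @param N0,m0 initial number/tracer vectors of length `I`.
#' @param t_end end time.
#' @param n_out number of output times.
#' @param rtol,atol integration tolerances.
#' @return A list with `times`, `N`, `m` (matrices, rows = times).
#' @export
discrete_smoluchowski_reference <- function(I, kernel, N0, m0, t_end,
                                            n_out = 11L, rtol = 1e-10,
                                            atol = 1e-12) {
  stopifnot(length(N0) == I, length(m0) == I)
  v <- as.numeric(seq_len(I))
  rhs <- function(t, y) {
    N <- y[seq_len(I)]
    m <- y[I + seq_len(I)]
    dN <- numeric(I)
    dm <- numeric(I)
    for (i in seq_len(I)) {
      bn <- 0
      bm <- 0
      if (i >= 2L) {
        for (j in seq_len(i - 1L)) {
          b <- kernel_eval(kernel, v[j], v[i - j])
          bn <- bn + 0.5 * b * N[j] * N[i - j]
          bm <- bm + 0.5 * b * (m[j] * N[i - j] + m[i - j] * N[j])
        }
      }
      dc <- sum(kernel_eval(kernel, rep(v[i], I), v) * N)
      dN[i] <- bn - N[i] * dc
      dm[i] <- bm - m[i] * dc
    }
    c(dN, dm)
  }
  sol <- pbe_integrate(rhs, c(N0, m0), seq(0, t_end, length.out = n_out),
    method = "rk45", rtol = rtol, atol = atol
  )
  list(
    times = sol$times,
    N = sol$y[, seq_len(I), drop = FALSE],
    m = sol$y[, I + seq_len(I), drop = FALSE]
  )
}
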