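#' Finite-volume scheme: tracer-mass right-hand side
#'
#' The semi-discrete finite-volume scheme for the tracer mass distribution of
#' the reduced aggregation model:
#' \deqn{\frac{dm_i}{dt} = \sum_{(j,k)\in\Upsilon^i} \tfrac12 \beta(v_j,v_k)
#'   (m_j N_k + m_k N_j) \;-\; m_i \sum_{j=1}^I \beta(v_i,v_j) N_j.}
#' Birth pairs whose representative sum exceeds `v_max` are dropped (the domain
#' is truncated) while the death term always sums over all cells; the scheme
#' conserves total tracer mass exactly whenever all active pairs stay inside
#' the domain.
#'
#' @param state a [particle_state()] matching the grid.
#' @param grid a [new_grid()].
#' @param pairs the [build_pair_index_set()] of `grid`.
#' @param kernel an [aggregation_kernel()].
#' @return Numeric vector of per-cell tracer-mass rates \eqn{dm_i/dt}.
#' @examples
#' g <- build_geometric_grid(1, 4)
#' ps <- build_pair_index_set(g)
#' ker <- aggregation_kernel("constant")
#' st <- particle_state(N = c(1, 0, 0, 0), m = c(1, 0, 0, 0))
#' fvs_tracer_rhs(st, g, ps, ker)  # -1 1 0 0
#' @export
fvs_tracer_rhs <- function(state, grid, pairs, kernel) {
  check_state_grid(state, grid)
  op <- pbe_operator(grid, kernel, pairs)
  fvs_rates(op, state$N, state$m)$dm
}

#' Finite-volume scheme: number-density right-hand side
#'
#' Companion discretization of the number-density aggregation equation under
#' the same point-mass ansatz and pair index sets:
#' \deqn{\frac{dN_i}{dt} = \sum_{(j,k)\in\Upsilon^i} \tfrac12 \beta(v_j,v_k)
#'   N_j N_k \;-\; N_i \sum_{j=1}^I \beta(v_i,v_j) N_j.}
#'
#' @inheritParams fvs_tracer_rhs
#' @return Numeric vector of per-cell number rates \eqn{dN_i/dt}.
#' @export
fvs_number_rhs <- function(state, grid, pairs, kernel) {
  check_state_grid(state, grid)
  op <- pbe_operator(grid, kernel, pairs)
  fvs_rates(op, state$N)$dN
}

#' One forward-Euler step
#'
#' Componentwise explicit update \eqn{y^{p+1} = y^p + \Delta t^p\, y'} of the
#' number and/or tracer fields; the state time advances by `dt`.
#'
#' @param state a [particle_state()].
#' @param rate a list with components `N` and/or `m` holding the per-cell
#'   rates; a missing (or `NULL`) component leaves that field unchanged. A bare
#'   numeric vector is interpreted as a tracer-mass rate.
#' @param dt nonnegative time step.
#' @return The updated [particle_state()].
#' @export
euler_step <- function(state, rate, dt) {
  stopifnot(inherits(state, "pbe_state"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt < 0) {
    stop("`dt` must be a nonnegative time step", call. = FALSE)
  }
  if (is.numeric(rate)) {
    rate <- list(m = rate)
  }
  N <- state$N
  m <- state$m
  if (!is.null(rate$N)) {
    if (length(rate$N) != length(N)) stop("rate/state dimension mismatch", call. = FALSE)
    N <- N + dt * rate$N
  }
  if (!is.null(rate$m)) {
    if (length(rate$m) != length(m)) stop("rate/state dimension mismatch", call. = FALSE)
    m <- m + dt * rate$m
  }
  particle_state(N, m, t = state$t + dt)
}
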