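#' Per-cell particle state
#'
#' Bundles the sectional unknowns at a time `t`: the particle numbers
#' \eqn{N_i} and the tracer masses \eqn{m_i} per cell. Under the point-mass
#' ansatz the continuous densities are
#' \eqn{f(t,v) \approx \sum_i N_i \delta(v - v_i)} and
#' \eqn{m(t,v) \approx \sum_i m_i \delta(v - v_i)}.
#'
#' @param N numeric vector of particle numbers per cell.
#' @param m numeric vector of tracer masses per cell (defaults to zeros).
#' @param t time stamp (default 0).
#' @return An object of class `pbe_state`.
#' @export
particle_state <- function(N, m = numeric(length(N)), t = 0) {
  N <- as.numeric(N)
  m <- as.numeric(m)
  if (length(N) != length(m)) {
    stop("`N` and `m` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(N)) || any(!is.finite(m))) {
    stop("state values must be finite", call. = FALSE)
  }
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t)) {
    stop("`t` must be a finite scalar time", call. = FALSE)
  }
  structure(list(N = N, m = m, t = t), class = "pbe_state")
}

#' @export
print.pbe_state <- function(x, ...) {
  cat(sprintf(
    "<pbe_state> %d cells at t = %g: mu0 = %.6g, total tracer = %.6g\n",
    length(x$N), x$t, sum(x$N), sum(x$m)
  ))
  invisible(x)
}

#' Total tracer mass of a state
#'
#' \eqn{\sum_i m_i}. In a batch run with all birth pairs inside the truncated
#' domain this is a conserved quantity of the finite-volume scheme (the total
#' birth and death contributions telescope), so it is the package's primary
#' conservation diagnostic.
#'
#' @param state a [particle_state()].
#' @return Scalar tracer mass.
#' @export
total_tracer_mass <- function(state) {
  stopifnot(inherits(state, "pbe_state"))
  sum(state$m)
}

# internal: dimension check against a grid
check_state_grid <- function(state, grid) {
  if (!inherits(state, "pbe_state")) {
    stop("`state` must be a `pbe_state`", call. = FALSE)
  }
  if (!inherits(grid, "pbe_grid")) {
    stop("`grid` must be a `pbe_grid`", call. = FALSE)
  }
  if (length(state$N) != grid$I) {
    stop(sprintf(
      "state has %d cells but grid has %d", length(state$N), grid$I
    ), call. = FALSE)
  }
  invisible(TRUE)
}
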