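#' Degree of aggregation
#'
#' Dimensionless progress variable \eqn{I_{agg} = 1 - \mu_0(t)/\mu_0^{ref}},
#' where the reference zeroth moment is the initial particle number in a batch
#' system or the feed number \eqn{B_0 \tau} in a continuous system.
#'
#' @param mu0_t zeroth moment (total particle number) at time t.
#' @param mu0_ref positive reference zeroth moment.
#' @return The degree of aggregation.
#' @export
degree_of_aggregation <- function(mu0_t, mu0_ref) {
  if (!is.numeric(mu0_ref) || any(!is.finite(mu0_ref)) || any(mu0_ref <= 0)) {
    stop("`mu0_ref` must be positive", call. = FALSE)
  }
  1 - mu0_t / mu0_ref
}

#' Primary-particle numbers per cell
#'
#' A granule of volume \eqn{v_i} built from unit-volume primary particles
#' contains \eqn{\kappa_i = v_i / v_1} of them, so the primary-particle number
#' distribution is \eqn{N_{r,i} = \kappa_i N_i}. With a tracer that initially
#' marks the primary particles, the tracer field `m` carries the same
#' information, which is how the sectional schemes track it.
#'
#' @param state a [particle_state()].
#' @param grid the matching grid (first representative is the primary volume).
#' @return Per-cell primary-particle numbers.
#' @export
primary_particle_distribution <- function(state, grid) {
  check_state_grid(state, grid)
  (grid$reps / grid$reps[1L]) * state$N
}

#' Mean volume of the primary-particle distribution
#'
#' \deqn{\bar\chi_r(t) = \frac{\sum_i v_i N_{r,i}}{\sum_i N_{r,i}}
#'   = \frac{\mu_2}{\mu_1}\quad (\kappa_i = v_i),}
#' the number-weighted mean granule volume per primary particle. Grows like
#' \eqn{e^{2t}} for the additive kernel and \eqn{1/(1-t)} for the product
#' kernel in a batch with monodisperse unit start (see [exact_chi_r()]).
#'
#' @inheritParams primary_particle_distribution
#' @return Scalar mean primary volume.
#' @export
mean_primary_volume <- function(state, grid) {
  check_state_grid(state, grid)
  nr <- primary_particle_distribution(state, grid)
  tot <- sum(nr)
  if (!is.finite(tot) || tot <= 0) {
    stop("mean primary volume undefined for an empty population", call. = FALSE)
  }
  sum(grid$reps * nr) / tot
}

#' Tracer-weighted mean particle volume
#'
#' \deqn{\hat\lambda_T(t) = \frac{\sum_i v_i m_i}{\sum_i m_i},} the discrete
#' counterpart of the first over zeroth moment of the tracer mass density.
#' Invariant under uniform rescaling of the tracer field.
#'
#' @inheritParams primary_particle_distribution
#' @return Scalar mean volume.
#' @export
tracer_weighted_mean_volume <- function(state, grid) {
  check_state_grid(state, grid)
  tot <- sum(state$m)
  if (!is.finite(tot) || tot == 0) {
    stop("tracer-weighted mean volume undefined: zero total tracer", call. = FALSE)
  }
  sum(grid$reps * state$m) / tot
}

#' Exact batch mean primary volume
#'
#' Closed forms for the monodisperse unit batch start: \eqn{e^{2t}} for the
#' additive kernel and \eqn{1/(1-t)} for the product kernel on the pre-gel
#' interval \eqn{0 \le t < 1}.
#'
#' @param family `"additive"` or `"multiplicative"`.
#' @param t time (vectorized).
#' @return Exact \eqn{\bar\chi_r(t)}.
#' @export
exact_chi_r <- function(family = c("additive", "multiplicative"), t) {
  family <- match.arg(family)
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be nonnegative", call. = FALSE)
  }
  if (family == "additive") {
    return(exp(2 * t))
  }
  if (any(t >= 1)) {
    stop("product-kernel mean primary volume is only defined before the gel time t = 1",
      call. = FALSE
    )
  }
  1 / (1 - t)
}

#' Exact MSMPR tracer-weighted mean volume
#'
#' Closed-form tracer-weighted mean particle volume (relative to the pulse
#' volume \eqn{v_0}) for a steady MSMPR at operating point \eqn{I_{agg}}, as a
#' function of dimensionless time \eqn{T = t/\tau}:
#'
#' * additive kernel:
#'   \deqn{\frac{\hat\lambda_T}{v_0} = \frac{1 - I_{agg}}{3 I_{agg} - 1}
#'     + \frac{4 I_{agg} - 2}{3 I_{agg} - 1}
#'       \exp\!\left(T \frac{2 I_{agg}}{1 - I_{agg}}\right),}
#'   singular at \eqn{I_{agg} = 1/3};
#' * multiplicative kernel:
#'   \deqn{\frac{\hat\lambda_T}{v_0} =
#'     \exp\!\left(T \frac{1 - \sqrt{1 - 8 I_{agg}}}{2}\right),}
#'   requiring \eqn{I_{agg} \le 1/8}.
#'
#' Both reduce to 1 at \eqn{T = 0} (the coefficients of the additive case sum
#' to one for every admissible operating point).
#'
#' @param family `"additive"` or `"multiplicative"`.
#' @param iagg steady-state degree of aggregation.
#' @param T dimensionless time \eqn{t/\tau} (vectorized).
#' @return \eqn{\hat\lambda_T / v_0}.
#' @export
exact_lambda_T <- function(family = c("additive", "multiplicative"), iagg, T) {
  family <- match.arg(family)
  if (!is.numeric(iagg) || length(iagg) != 1L || !is.finite(iagg) || iagg < 0 || iagg >= 1) {
    stop("`iagg` must be a fraction in [0, 1)", call. = FALSE)
  }
  if (any(!is.finite(T)) || any(T < 0)) {
    stop("`T` must be nonnegative", call. = FALSE)
  }
  if (family == "additive") {
    if (iagg == 1 / 3) {
      stop("the additive-kernel formula is singular at iagg = 1/3", call. = FALSE)
    }
    a <- (1 - iagg) / (3 * iagg - 1)
    b <- (4 * iagg - 2) / (3 * iagg - 1)
    return(a + b * exp(T * 2 * iagg / (1 - iagg)))
  }
  if (iagg > 1 / 8) {
    stop("the product-kernel formula requires iagg <= 1/8", call. = FALSE)
  }
  exp(T * (1 - sqrt(1 - 8 * iagg)) / 2)
}

#' Exact MSMPR tracer decay
#'
#' With tracer-free nuclei, aggregation conserves tracer and washout removes it
#' at rate \eqn{1/\tau}, so the total tracer mass decays as
#' \eqn{m_T(T) = m_0 e^{-T}} with \eqn{T = t/\tau}, for both kernels.
#'
#' @param m0 initial pulse mass.
#' @param T dimensionless time (vectorized, nonnegative).
#' @return Exact total tracer mass.
#' @export
exact_tracer_decay <- function(m0, T) {
  if (any(!is.finite(T)) || any(T < 0)) {
    stop("`T` must be nonnegative", call. = FALSE)
  }
  m0 * exp(-T)
}

#' Relative error between a numerical and an analytical series
#'
#' Relative discrepancy of a numerical mean-volume (or any positive metric)
#' series against its analytical reference on a common time grid. Two norm
#' conventions are provided because the benchmark statistic does not pin one
#' down:
#'
#' * `"final"` (default): \eqn{|x^{ana}_n - x^{num}_n| / |x^{ana}_n|} at the
#'   final output time;
#' * `"l2"`: normalized discrete L2 over the whole series,
#'   \eqn{\lVert x^{ana} - x^{num}\rVert_2 / \lVert x^{ana}\rVert_2}.
#'
#' Both are nonnegative, zero iff the series coincide on the grid, and equal to
#' `c` for a uniform relative offset `x_num = (1 + c) x_ana`.
#'
#' @param numerical,analytical numeric vectors of equal length.
#' @param norm `"final"` or `"l2"`.
#' @return Scalar relative error.
#' @export
relative_error <- function(numerical, analytical, norm = c("final", "l2")) {
  norm <- match.arg(norm)
  if (length(numerical) != length(analytical) || length(numerical) == 0L) {
    stop("series must be nonempty and on a common time grid", call. = FALSE)
  }
  if (any(!is.finite(analytical)) || any(!is.finite(numerical))) {
    stop("series must be finite", call. = FALSE)
  }
  if (norm == "final") {
    n <- length(analytical)
    return(abs(analytical[n] - numerical[n]) / abs(analytical[n]))
  }
  sqrt(sum((analytical - numerical)^2)) / sqrt(sum(analytical^2))
}

#' Derived moment and metric series of a simulation result
#'
#' Computes, for every stored output time, the volume moments
#' \eqn{\mu_k = \sum_i v_i^k N_i} (k = 0, 1, 2), the total tracer mass
#' \eqn{m_T = \sum_i m_i}, the tracer-weighted mean volume
#' \eqn{\hat\lambda_T}, the mean primary volume \eqn{\bar\chi_r = \mu_2/\mu_1},
#' and the degree of aggregation against `mu0_ref`.
#'
#' @param times output times.
#' @param N,m matrices (rows = times, columns = cells) of the two fields.
#' @param grid the grid.
#' @param mu0_ref reference zeroth moment for the degree of aggregation
#'   (`NULL` omits the column).
#' @param tau residence time; when given, a dimensionless-time column
#'   `T = time / tau` is added.
#' @return A data.frame, one row per output time.
#' @export
moment_series <- function(times, N, m, grid, mu0_ref = NULL, tau = NULL) {
  stopifnot(inherits(grid, "pbe_grid"))
  N <- matrix(N, ncol = grid$I)
  m <- matrix(m, ncol = grid$I)
  v <- grid$reps
  mu0 <- drop(N %*% rep(1, grid$I))
  mu1 <- drop(N %*% v)
  mu2 <- drop(N %*% v^2)
  m_T <- drop(m %*% rep(1, grid$I))
  vm <- drop(m %*% v)
  df <- data.frame(
    time = times,
    mu0 = mu0, mu1 = mu1, mu2 = mu2,
    m_T = m_T,
    lambda_T = ifelse(m_T != 0, vm / m_T, NA_real_),
    chi_r = ifelse(mu1 != 0, mu2 / mu1, NA_real_)
  )
  if (!is.null(tau)) {
    df$T <- df$time / tau
  }
  if (!is.null(mu0_ref)) {
    df$iagg <- degree_of_aggregation(mu0, mu0_ref)
  }
  df
}
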