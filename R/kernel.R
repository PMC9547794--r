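#' Aggregation (coagulation) kernels
#'
#' An aggregation kernel is a symmetric nonnegative rate function
#' \eqn{\beta(v, \eta) = \beta_0 \beta^*(v, \eta)} giving the frequency of
#' successful coalescence between particles of volumes `v` and `eta`. Three
#' time-independent families are supported:
#'
#' * `"constant"`: \eqn{\beta = \beta_0} (size-independent),
#' * `"additive"` (sum kernel): \eqn{\beta = \beta_0 (v + \eta)} — non-gelling
#'   in batch, gelling in continuous systems,
#' * `"multiplicative"` (product kernel): \eqn{\beta = \beta_0 v \eta} —
#'   gelling in both.
#'
#' @param family one of `"constant"`, `"additive"`, `"multiplicative"`.
#' @param beta0 nonnegative rate scale \eqn{\beta_0} (default 1).
#' @return An object of class `pbe_kernel`.
#' @examples
#' ker <- aggregation_kernel("additive")
#' kernel_eval(ker, 1, 2)  # 3
#' @export
aggregation_kernel <- function(family = c("constant", "additive", "multiplicative"),
                               beta0 = 1) {
  family <- match.arg(family)
  if (!is.numeric(beta0) || length(beta0) != 1L || !is.finite(beta0) || beta0 < 0) {
    stop("`beta0` must be a nonnegative finite number", call. = FALSE)
  }
  structure(list(family = family, beta0 = beta0), class = "pbe_kernel")
}

#' Evaluate an aggregation kernel
#'
#' Vectorized over `v` and `eta` (usual recycling rules). Arguments must be
#' strictly positive volumes.
#'
#' @param kernel a [aggregation_kernel()].
#' @param v,eta particle volumes.
#' @return Aggregation rates \eqn{\beta(v, \eta)}.
#' @export
kernel_eval <- function(kernel, v, eta) {
  stopifnot(inherits(kernel, "pbe_kernel"))
  if (length(v) == 0L || length(eta) == 0L) {
    return(numeric(0))
  }
  if (any(!is.finite(v)) || any(!is.finite(eta)) || any(v <= 0) || any(eta <= 0)) {
    stop("kernel arguments must be positive finite volumes", call. = FALSE)
  }
  switch(kernel$family,
    constant = kernel$beta0 * (v * 0 + eta * 0 + 1),
    additive = kernel$beta0 * (v + eta),
    multiplicative = kernel$beta0 * v * eta
  )
}

#' Kernel matrix over grid representatives
#'
#' Dense matrix `K[i, j] = beta(v_i, v_j)` used by the death terms of the
#' sectional schemes.
#'
#' @param kernel a [aggregation_kernel()].
#' @param reps representative volumes (or a `pbe_grid`, whose `reps` are used).
#' @return An `I x I` symmetric matrix.
#' @export
kernel_matrix <- function(kernel, reps) {
  if (inherits(reps, "pbe_grid")) {
    reps <- reps$reps
  }
  I <- length(reps)
  matrix(kernel_eval(kernel, rep(reps, times = I), rep(reps, each = I)), nrow = I)
}

#' @export
print.pbe_kernel <- function(x, ...) {
  cat(sprintf("<pbe_kernel> %s kernel, beta0 = %g\n", x$family, x$beta0))
  invisible(x)
}
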