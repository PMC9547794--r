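# Internal precomputed machinery shared by the FVS and CAT schemes.
#
# Bundles the grid, the pair index sets, the kernel values on all stored pairs
# (wb = mult * beta / 2, the birth weight of each unordered pair) and the dense
# kernel matrix for the death terms. Built once per run; all right-hand sides
# are then cheap vectorized sweeps.

pbe_operator <- function(grid, kernel, pairs = build_pair_index_set(grid)) {
  stopifnot(inherits(grid, "pbe_grid"), inherits(kernel, "pbe_kernel"))
  if (pairs$I != grid$I) {
    stop("`pairs` was built for a different grid", call. = FALSE)
  }
  beta_p <- kernel_eval(kernel, grid$reps[pairs$j], grid$reps[pairs$k])
  list(
    grid = grid,
    kernel = kernel,
    pairs = pairs,
    beta_p = beta_p,
    wb = 0.5 * pairs$mult * beta_p,
    pair_vsum = grid$reps[pairs$j] + grid$reps[pairs$k],
    K = kernel_matrix(kernel, grid$reps)
  )
}

# sum a per-pair quantity into its target cells
cell_sum <- function(op, x) {
  out <- numeric(op$grid$I)
  if (length(x)) {
    rs <- rowsum(x, op$pairs$cell)
    out[as.integer(rownames(rs))] <- rs[, 1L]
  }
  out
}

# FVS birth/death rates; m may be NULL for the number-only system
fvs_rates <- function(op, N, m = NULL) {
  p <- op$pairs
  death_coef <- drop(op$K %*% N)
  bn <- cell_sum(op, op$wb * N[p$j] * N[p$k])
  out <- list(dN = bn - N * death_coef, death_coef = death_coef)
  if (!is.null(m)) {
    bm <- cell_sum(op, op$wb * (m[p$j] * N[p$k] + m[p$k] * N[p$j]))
    out$dm <- bm - m * death_coef
  }
  out
}

# Analytic Jacobian blocks of the FVS rates. Returns the full (2I x 2I)
# Jacobian of c(dN, dm) when m is given, else the (I x I) number block.
fvs_jacobian_blocks <- function(op, N, m = NULL) {
  I <- op$grid$I
  p <- op$pairs
  w <- op$wb
  Kn <- drop(op$K %*% N)
  rows <- c(p$cell, p$cell)
  J_birth_N <- as.matrix(Matrix::sparseMatrix(
    i = rows, j = c(p$j, p$k), x = c(w * N[p$k], w * N[p$j]), dims = c(I, I)
  ))
  J_NN <- J_birth_N - diag(Kn, I) - N * op$K
  if (is.null(m)) {
    return(J_NN)
  }
  J_mN <- as.matrix(Matrix::sparseMatrix(
    i = rows, j = c(p$j, p$k), x = c(w * m[p$k], w * m[p$j]), dims = c(I, I)
  )) - m * op$K
  J_mm <- J_birth_N - diag(Kn, I)
  rbind(
    cbind(J_NN, matrix(0, I, I)),
    cbind(J_mN, J_mm)
  )
}
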