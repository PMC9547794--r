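# shared fixtures built in code

# the worked 4-cell doubling grid: reps (1,2,4,8), edges (0,1.5,3,6,12)
grid4 <- function() build_geometric_grid(p = 1, I = 4)

# random positive state on a grid, reproducible
rand_state <- function(I, seed) {
  set.seed(seed)
  particle_state(N = stats::runif(I), m = stats::runif(I))
}

# small collection of (grid, kernel) cases for oracle sweeps
oracle_cases <- function() {
  grids <- list(
    build_geometric_grid(1, 6),
    build_geometric_grid(2, 9),
    build_geometric_grid(3, 12),
    build_linear_grid(8)
  )
  kernels <- list(
    aggregation_kernel("constant"),
    aggregation_kernel("additive"),
    aggregation_kernel("multiplicative", beta0 = 0.5)
  )
  list(grids = grids, kernels = kernels)
}

rel_diff <- function(a, b) {
  scale <- max(abs(a), abs(b), 1e-300)
  max(abs(a - b)) / scale
}
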