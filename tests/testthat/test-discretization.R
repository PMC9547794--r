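test_that("geometric grid construction follows the representative rule", {
  g <- grid4()
  expect_equal(g$reps, c(1, 2, 4, 8))
  expect_equal(g$edges, c(0, 1.5, 3, 6, 12))
  expect_equal(g$widths, diff(g$edges))
  expect_equal(g$v_max, 12)

  g3 <- build_geometric_grid(p = 3, I = 4)
  expect_equal(g3$reps, 2^((0:3) / 3))

  # doubling ratio is exact for p = 1 at any size
  g1 <- build_geometric_grid(1, 30)
  expect_equal(g1$reps[-1] / g1$reps[-30], rep(2, 29))

  # invariants: edges increasing, reps strictly inside cells
  for (p in c(1, 2, 5)) {
    g <- build_geometric_grid(p, 17)
    expect_true(all(diff(g$edges) > 0))
    expect_true(all(g$edges[1:17] < g$reps & g$reps <= g$edges[2:18]))
  }
})

test_that("grid construction is scale-covariant and validates input", {
  for (case in list(c(1, 8, 3), c(3, 11, 0.25), c(5, 23, 10))) {
    p <- case[1]
    I <- case[2]
    c0 <- case[3]
    g1 <- build_geometric_grid(p, I, v1 = 1)
    gc <- build_geometric_grid(p, I, v1 = c0)
    expect_equal(gc$reps, c0 * g1$reps)
    expect_equal(gc$edges, c0 * g1$edges)
  }
  expect_error(build_geometric_grid(0, 10), "positive integer")
  expect_error(build_geometric_grid(1, 1), ">= 2")
  expect_error(build_geometric_grid(1, 10, v1 = -1), "positive")
  expect_error(new_grid(c(0, 2, 1), c(1, 1.5)), "increasing")
  expect_error(new_grid(c(0.5, 1, 2), c(0.8, 1.5)), "first edge")
  expect_error(new_grid(c(0, 1, 2), c(1.5, 1.8)), "inside its cell")
})

test_that("pair index sets implement half-open upper-inclusive binning", {
  g <- grid4()
  ps <- build_pair_index_set(g)
  lookup <- function(j, k) ps$cell[ps$j == min(j, k) & ps$k == max(j, k)]
  expect_identical(lookup(1, 1), 2L) # sum 2 in (1.5, 3]
  expect_identical(lookup(1, 2), 2L) # sum 3 exactly on the edge: lower cell
  expect_identical(lookup(2, 2), 3L) # sum 4 in (3, 6]
  expect_length(lookup(4, 4), 0L) # sum 16 > v_max = 12: in no set
  expect_equal(ps$mult, ifelse(ps$j == ps$k, 1, 2))
})

test_that("pair index sets partition all admissible pairs (exhaustive, I <= 12)", {
  for (p in 1:3) {
    g <- build_geometric_grid(p, 12)
    ps <- build_pair_index_set(g)
    key <- paste(ps$j, ps$k)
    for (j in 1:12) {
      for (k in j:12) {
        s <- g$reps[j] + g$reps[k]
        in_cell <- which(g$edges[1:12] < s & s <= g$edges[2:13])
        hit <- ps$cell[key == paste(j, k)]
        if (s > g$v_max) {
          expect_length(in_cell, 0L)
          expect_length(hit, 0L)
        } else {
          expect_length(in_cell, 1L)
          expect_identical(hit, in_cell)
        }
      }
    }
    # p = 1: a self-pair doubles the volume, landing exactly one cell up
    if (p == 1) {
      self <- ps$j == ps$k
      expect_equal(ps$cell[self], ps$j[self] + 1L)
    }
  }
})

test_that("kernels evaluate their closed forms, are symmetric, reject bad input", {
  add <- aggregation_kernel("additive")
  mul <- aggregation_kernel("multiplicative")
  con <- aggregation_kernel("constant", beta0 = 2.5)
  expect_equal(kernel_eval(add, 1, 2), 3)
  expect_equal(kernel_eval(mul, 2, 4), 8)
  expect_equal(kernel_eval(con, 7, 0.1), 2.5)
  set.seed(11)
  v <- stats::runif(50, 0.01, 100)
  e <- stats::runif(50, 0.01, 100)
  for (ker in list(add, mul, con)) {
    expect_equal(kernel_eval(ker, v, e), kernel_eval(ker, e, v))
    expect_true(all(kernel_eval(ker, v, e) >= 0))
    expect_error(kernel_eval(ker, -1, 2), "positive")
    expect_error(kernel_eval(ker, 1, 0), "positive")
  }
  expect_error(aggregation_kernel("brownian"), "arg")
  K <- kernel_matrix(add, grid4())
  expect_equal(K, t(K))
  expect_equal(K[1, 3], 5)
})

test_that("grids and pair sets serialize to JSON and back", {
  g <- build_geometric_grid(3, 9, v1 = 0.5)
  ps <- build_pair_index_set(g)
  js <- grid_to_json(g, ps)
  g2 <- grid_from_json(js)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$reps, g$reps)
  expect_equal(g2$p, g$p)
  parsed <- jsonlite::fromJSON(js)
  expect_length(parsed$pairs, g$I)
})
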