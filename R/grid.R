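#' Construct a sectional volume grid from edges and representatives
#'
#' Low-level constructor for the truncated one-dimensional volume domain used by
#' all sectional schemes in the package. The domain `(0, v_max]` is split into
#' `I` cells; cell `i` spans `(edges[i], edges[i+1]]` and carries a single
#' representative volume `reps[i]` on which all particles of the cell are
#' assumed to be concentrated.
#'
#' Invariants enforced: edges are strictly increasing with `edges[1] == 0` and
#' `edges[I+1] == v_max`; every representative lies strictly inside its cell
#' (`edges[i] < reps[i] <= edges[i+1]`); widths are the successive edge
#' differences.
#'
#' @param edges numeric vector of length `I + 1`, cell boundaries, starting at 0.
#' @param reps numeric vector of length `I`, representative volumes.
#' @param p ratio exponent of a geometric grid (`v[i+1] = 2^(1/p) v[i]`), or
#'   `NA` for grids that are not geometric.
#' @return An object of class `pbe_grid`: a list with fields `edges`, `reps`,
#'   `widths`, `I`, `v_max`, `p`.
#' @seealso [build_geometric_grid()], [build_linear_grid()]
#' @export
new_grid <- function(edges, reps, p = NA_integer_) {
  edges <- as.numeric(edges)
  reps <- as.numeric(reps)
  I <- length(reps)
  if (I < 2L) {
    stop("a grid needs at least 2 cells", call. = FALSE)
  }
  if (length(edges) != I + 1L) {
    stop("`edges` must have length `length(reps) + 1`", call. = FALSE)
  }
  if (any(!is.finite(edges)) || any(!is.finite(reps))) {
    stop("grid edges and representatives must be finite", call. = FALSE)
  }
  if (edges[1L] != 0) {
    stop("the first edge must be 0 (v_{1/2} = 0)", call. = FALSE)
  }
  if (any(diff(edges) <= 0)) {
    stop("grid edges must be strictly increasing", call. = FALSE)
  }
  inside <- edges[seq_len(I)] < reps & reps <= edges[seq_len(I) + 1L]
  if (!all(inside)) {
    stop("every representative must lie inside its cell", call. = FALSE)
  }
  structure(
    list(
      edges = edges,
      reps = reps,
      widths = diff(edges),
      I = I,
      v_max = edges[I + 1L],
      p = p
    ),
    class = "pbe_grid"
  )
}

#' Build the geometric volume grid v_{i+1} = 2^(1/p) v_i
#'
#' Representative volumes follow the geometric rule
#' `reps[i] = v1 * 2^((i-1)/p)`. Interior edges are the arithmetic midpoints of
#' adjacent representatives, the lower boundary is 0, and the upper boundary
#' `v_max` extrapolates the last midpoint by the grid ratio `2^(1/p)`. The
#' representative rule is honored exactly because it determines where pair sums
#' `v_j + v_k` land, which is what the sectional schemes depend on.
#'
#' @param p positive integer ratio exponent; `p = 1` doubles the volume from
#'   cell to cell, larger `p` refines the grid.
#' @param I number of cells (at least 2).
#' @param v1 representative volume of the first cell (default 1, the volume of
#'   a primary particle).
#' @return A [new_grid()] object.
#' @examples
#' g <- build_geometric_grid(p = 1, I = 4)
#' g$reps   # 1 2 4 8
#' g$edges  # 0 1.5 3 6 12
#' @export
build_geometric_grid <- function(p, I, v1 = 1) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 1 || p != round(p)) {
    stop("`p` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(I) || length(I) != 1L || !is.finite(I) || I < 2 || I != round(I)) {
    stop("`I` must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(v1) || length(v1) != 1L || !is.finite(v1) || v1 <= 0) {
    stop("`v1` must be a positive volume", call. = FALSE)
  }
  I <- as.integer(I)
  p <- as.integer(p)
  reps <- v1 * 2^((seq_len(I) - 1) / p)
  mids <- (reps[-I] + reps[-1L]) / 2
  edges <- c(0, mids, mids[I - 1L] * 2^(1 / p))
  new_grid(edges, reps, p = p)
}

#' Build a unit-spaced linear grid
#'
#' Representatives sit at the integers `1..I` with edges at the half-integers
#' (and 0 at the bottom). On this grid every pair sum `v_j + v_k` coincides
#' exactly with a representative, so the finite-volume scheme reduces to the
#' classic discrete Smoluchowski equations; used mainly for validation.
#'
#' @param I number of cells (at least 2).
#' @return A [new_grid()] object.
#' @export
build_linear_grid <- function(I) {
  if (!is.numeric(I) || length(I) != 1L || !is.finite(I) || I < 2 || I != round(I)) {
    stop("`I` must be an integer >= 2", call. = FALSE)
  }
  I <- as.integer(I)
  reps <- as.numeric(seq_len(I))
  edges <- c(0, seq_len(I - 1L) + 0.5, I + 0.5)
  new_grid(edges, reps, p = NA_integer_)
}

#' @export
print.pbe_grid <- function(x, ...) {
  kind <- if (is.na(x$p)) "sectional" else sprintf("geometric (ratio 2^(1/%d))", x$p)
  cat(sprintf(
    "<pbe_grid> %s grid: %d cells, v in (0, %.6g], reps %.6g .. %.6g\n",
    kind, x$I, x$v_max, x$reps[1L], x$reps[x$I]
  ))
  invisible(x)
}

#' Precompute the aggregation pair index sets
#'
#' For every cell `i` collects the pairs of representatives whose sum lands in
#' that cell, i.e. the index set
#' \deqn{\Upsilon^i = \{(j,k): v_{i-1/2} < v_j + v_k \le v_{i+1/2}\}.}
#' Binning is half-open and upper-inclusive, so a sum lying exactly on an edge
#' belongs to the lower cell. Pairs whose sum exceeds `v_max` are outside the
#' truncated domain and belong to no set. Every admissible pair belongs to
#' exactly one cell (the sets partition the admissible pairs).
#'
#' Pairs are stored once per unordered pair (`j <= k`) with multiplicity 2 for
#' `j < k` and 1 for `j = k`; the symmetric ordered set is recovered by the
#' schemes through the multiplicity, which halves the precompute cost without
#' changing the birth terms.
#'
#' @param grid a [new_grid()] object.
#' @return An object of class `pbe_pairs`: list with integer vectors `j`, `k`,
#'   `cell`, numeric `mult`, the cell count `I`, and `by_cell`, a list mapping
#'   each cell to the rows of its pairs (deterministic ordering: by `j`, then
#'   `k`).
#' @examples
#' g <- build_geometric_grid(1, 4)
#' ps <- build_pair_index_set(g)
#' ps$cell[ps$j == 1 & ps$k == 1]  # sum 2 lands in cell 2
#' @export
build_pair_index_set <- function(grid) {
  stopifnot(inherits(grid, "pbe_grid"))
  I <- grid$I
  pj <- rep.int(seq_len(I), times = I - seq_len(I) + 1L)
  pk <- unlist(lapply(seq_len(I), function(j) j:I), use.names = FALSE)
  s <- grid$reps[pj] + grid$reps[pk]
  cell <- findInterval(s, grid$edges, left.open = TRUE)
  keep <- cell >= 1L & cell <= I
  pj <- pj[keep]
  pk <- pk[keep]
  cell <- as.integer(cell[keep])
  mult <- ifelse(pj == pk, 1, 2)
  by_cell <- split(seq_along(cell), factor(cell, levels = seq_len(I)))
  structure(
    list(j = pj, k = pk, cell = cell, mult = mult, I = I, by_cell = by_cell),
    class = "pbe_pairs"
  )
}

#' @export
print.pbe_pairs <- function(x, ...) {
  cat(sprintf(
    "<pbe_pairs> %d unordered pairs over %d cells (%d ordered contributions)\n",
    length(x$j), x$I, sum(x$mult)
  ))
  invisible(x)
}

#' Serialize a grid or pair index set to JSON
#'
#' @param grid a `pbe_grid`.
#' @param pairs optionally, a matching `pbe_pairs`; if supplied the per-cell
#'   pair lists are embedded alongside the grid geometry.
#' @return A JSON string.
#' @export
grid_to_json <- function(grid, pairs = NULL) {
  stopifnot(inherits(grid, "pbe_grid"))
  out <- list(
    I = grid$I,
    p = grid$p,
    v_max = grid$v_max,
    edges = grid$edges,
    reps = grid$reps,
    widths = grid$widths
  )
  if (!is.null(pairs)) {
    stopifnot(inherits(pairs, "pbe_pairs"), pairs$I == grid$I)
    out$pairs <- lapply(pairs$by_cell, function(ix) {
      cbind(j = pairs$j[ix], k = pairs$k[ix], mult = pairs$mult[ix])
    })
  }
  jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA)
}

#' Deserialize a grid from JSON produced by [grid_to_json()]
#'
#' @param json JSON string or path to a JSON file.
#' @return A `pbe_grid`.
#' @export
grid_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  new_grid(x$edges, x$reps, p = if (is.null(x$p) || is.na(x$p)) NA_integer_ else as.integer(x$p))
}
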