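#' Grid dimensions for a node count
#'
#' Chooses a square grid whose cell count is at least `n / occupancy`:
#' side `ceiling(sqrt(n / occupancy))`. The default occupancy of 25% leaves
#' enough vacant cells for nodes to move past each other during
#' optimization while keeping the drawing reasonably compact.
#'
#' @param n number of nodes (>= 1).
#' @param occupancy target fraction of occupied cells, in (0, 1].
#' @return integer vector `c(width, height)`.
#' @export
#' @examples
#' make_grid(290)  # 35 x 35
make_grid <- function(n, occupancy = 0.25) {
  if (n < 1L) stop("'n' must be at least 1")
  if (occupancy <= 0 || occupancy > 1) stop("'occupancy' must be in (0, 1]")
  side <- as.integer(ceiling(sqrt(n / occupancy)))
  c(width = side, height = side)
}

#' Construct a grid layout object
#'
#' A grid layout assigns every node an integer cell `(x, y)` with
#' `0 <= x < width`, `0 <= y < height`, one node per cell.
#'
#' @param coords integer matrix with two columns (x, y), one row per node;
#'   row names, if present, are node ids.
#' @param width,height grid dimensions.
#' @return an object of class `"grid_layout"` with fields `coords`,
#'   `width`, `height`.
#' @export
grid_layout <- function(coords, width, height) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  if (ncol(coords) != 2L) stop("'coords' must have two columns")
  if (anyNA(coords)) stop("missing coordinates")
  width <- as.integer(width); height <- as.integer(height)
  if (any(coords[, 1L] < 0L | coords[, 1L] >= width |
          coords[, 2L] < 0L | coords[, 2L] >= height)) {
    stop("coordinates fall outside the grid")
  }
  cell <- coords[, 2L] * width + coords[, 1L]
  if (anyDuplicated(cell)) {
    stop("two nodes share grid cell(s): ",
         paste(unique(cell[duplicated(cell)]), collapse = ", "))
  }
  colnames(coords) <- c("x", "y")
  structure(list(coords = coords, width = width, height = height),
            class = "grid_layout")
}

#' @export
print.grid_layout <- function(x, ...) {
  cat(sprintf("grid layout: %d nodes on a %d x %d grid\n",
              nrow(x$coords), x$width, x$height))
  invisible(x)
}

#' Random initial layout
#'
#' Places `n` nodes on `n` distinct cells chosen uniformly without
#' replacement. Uses R's RNG stream, so results are reproducible under
#' [set.seed()]; alternatively pass `seed` to set it here.
#'
#' @param n number of nodes.
#' @param grid integer `c(width, height)`, e.g. from [make_grid()].
#' @param seed optional integer seed.
#' @param nodes optional node ids to use as row names.
#' @return a [grid_layout()] object.
#' @export
init_random <- function(n, grid, seed = NULL, nodes = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ncell <- as.integer(grid[1L]) * as.integer(grid[2L])
  if (ncell < n) stop("grid has fewer cells than nodes")
  cells <- sample.int(ncell, n) - 1L
  coords <- cbind(x = cells %% grid[1L], y = cells %/% grid[1L])
  if (!is.null(nodes)) rownames(coords) <- nodes
  grid_layout(coords, grid[1L], grid[2L])
}

check_engine_args <- function(layout, W) {
  stopifnot(inherits(layout, "grid_layout"))
  if (nrow(W) != nrow(layout$coords)) {
    stop("weight matrix and layout cover different node counts")
  }
  ids <- rownames(layout$coords)
  if (!is.null(ids) && !is.null(rownames(W)) && !identical(ids, rownames(W))) {
    stop("weight matrix and layout node ids disagree")
  }
  storage.mode(W) <- "integer"
  W
}

#' Layout cost
#'
#' The total interaction energy of the placement: the sum over unordered
#' node pairs of `W[i, j] * d[i, j]`, where `d` is the Manhattan distance
#' between the occupied cells. Lower is better: positive weights pull pairs
#' together, negative weights push them apart.
#'
#' @param layout a [grid_layout()] object.
#' @param W integer weight matrix (see [build_weights()]).
#' @return the cost, an exact integer-valued number.
#' @export
grid_cost <- function(layout, W) {
  W <- check_engine_args(layout, W)
  cpp_cost(layout$coords, W)
}

#' Cost change of a single-node move
#'
#' Computes `cost(after) - cost(before)` for moving one node to a vacant
#' cell in O(n), by summing the weight-times-distance change over the other
#' nodes only.
#'
#' @inheritParams grid_cost
#' @param node node index (or id if the layout carries row names).
#' @param new_cell integer `c(x, y)` target cell; must be on-grid and vacant.
#' @return the exact integer cost difference.
#' @export
delta_cost <- function(layout, W, node, new_cell) {
  W <- check_engine_args(layout, W)
  if (is.character(node)) node <- match(node, rownames(layout$coords))
  node <- as.integer(node)
  if (is.na(node) || node < 1L || node > nrow(layout$coords)) {
    stop("unknown node")
  }
  nx <- as.integer(new_cell[1L]); ny <- as.integer(new_cell[2L])
  if (nx < 0L || nx >= layout$width || ny < 0L || ny >= layout$height) {
    stop("target cell is off the grid")
  }
  hit <- layout$coords[, 1L] == nx & layout$coords[, 2L] == ny
  if (any(hit) && which(hit)[1L] != node) stop("target cell is occupied")
  cpp_delta_cost(layout$coords, W, node - 1L, nx, ny)
}

#' Neighborhood-test local search
#'
#' Repeatedly sweeps the nodes in index order; each node is offered every
#' vacant cell of its neighborhood and takes the best strictly-improving
#' move (ties broken by the fixed order N, NE, E, SE, S, SW, W, NW). The
#' search stops when a full sweep moves nothing, so the result is a local
#' minimum that no single-node move to an adjacent vacant cell can improve.
#'
#' @inheritParams grid_cost
#' @param neighborhood `"moore"` (8 cells, the default) or `"vonneumann"`
#'   (4 cells).
#' @return the optimized [grid_layout()], with attributes `evaluations`
#'   (number of delta-cost evaluations) and `sweeps`.
#' @export
neighborhood_test <- function(layout, W,
                              neighborhood = c("moore", "vonneumann")) {
  W <- check_engine_args(layout, W)
  moore <- match.arg(neighborhood) == "moore"
  res <- cpp_neighborhood_test(layout$coords, W, layout$width, layout$height,
                               moore)
  out <- grid_layout(`rownames<-`(res$coords, rownames(layout$coords)),
                     layout$width, layout$height)
  attr(out, "evaluations") <- res$evaluations
  attr(out, "sweeps") <- res$sweeps
  out
}

#' Random perturbation of a layout
#'
#' Visits the nodes in index order and moves each, with probability `p`, to
#' a uniformly chosen vacant cell of its neighborhood (vacancy is evaluated
#' at move time). Nodes without a vacant neighbor stay put. With `p = 0`
#' the layout is returned unchanged; with `p = 1` every node that has a
#' vacant neighbor moves. Uses R's RNG stream.
#'
#' @inheritParams neighborhood_test
#' @param p perturbation probability in [0, 1].
#' @return the perturbed [grid_layout()].
#' @export
perturb <- function(layout, p, neighborhood = c("moore", "vonneumann")) {
  stopifnot(inherits(layout, "grid_layout"))
  if (p < 0 || p > 1) stop("'p' must be in [0, 1]")
  moore <- match.arg(neighborhood) == "moore"
  res <- cpp_perturb(layout$coords, layout$width, layout$height, p, moore)
  grid_layout(`rownames<-`(res, rownames(layout$coords)),
              layout$width, layout$height)
}
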