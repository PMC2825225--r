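#' Fit a grid layout to a network
#'
#' The main entry point. Derives pairwise interaction weights from the
#' network's graph distances through a layout style (optionally boosted for
#' same-module pairs), places the nodes randomly on an integer grid, and
#' minimizes the Manhattan-distance interaction cost
#' \deqn{cost(R) = \sum_{i<j} w_{ij} \, d_{ij}(R)}
#' by a neighborhood-test local search with
#' re-optimization-after-perturbation restarts: `niter` times, every node is
#' displaced with probability `p` to a random adjacent vacant cell, the
#' perturbed layout is locally re-optimized, and the candidate is accepted
#' only if it strictly lowers the cost.
#'
#' Moderate perturbation probabilities work well in practice; the default is
#' `p = 0.7` with `niter = 60` iterations.
#'
#' @param net a [netgrid_network()] object.
#' @param style a style name (`"common"`, `"compact"`, `"stretched"`) or a
#'   [layout_style()] object.
#' @param p perturbation probability in [0, 1].
#' @param niter number of perturbation-restart iterations.
#' @param occupancy target fraction of occupied grid cells (ignored when
#'   `grid` is given).
#' @param grid optional explicit `c(width, height)` overriding [make_grid()].
#' @param seed optional integer seed; with a fixed seed the fit is exactly
#'   reproducible.
#' @param boost optional list with elements `delta` (positive integer) and
#'   optionally `distances` (integer set, e.g. `c(2, 3)`) and `modules`
#'   (labels to restrict to); passed to [apply_module_boost()] using the
#'   network's module labels.
#' @param weights optional pre-built weight matrix overriding the
#'   style/boost pipeline (node order must match `net$nodes`).
#' @param neighborhood `"moore"` (8-cell, default) or `"vonneumann"`
#'   (4-cell) adjacency for both local search and perturbation.
#' @return an object of class `"netgrid"`: a list with components
#'   \item{network}{the input network}
#'   \item{layout}{the fitted [grid_layout()]}
#'   \item{weights}{the weight matrix used}
#'   \item{cost}{final cost value}
#'   \item{trace}{accepted-cost trace, initial value plus one entry per
#'     iteration; non-increasing by construction}
#'   \item{evaluations}{total number of delta-cost evaluations}
#'   \item{params}{the fitting parameters, including the seed}
#' @seealso [neighborhood_test()], [perturb()], [render_svg()],
#'   [write_layout()]
#' @export
#' @examples
#' net <- synth_network(c(8, 8), p_in = 0.6, p_out = 0.05, seed = 1)
#' fit <- netgrid(net, niter = 10, seed = 1)
#' fit
#' head(coef(fit))
netgrid <- function(net, style = "common", p = 0.7, niter = 60,
                    occupancy = 0.25, grid = NULL, seed = NULL, boost = NULL,
                    weights = NULL,
                    neighborhood = c("moore", "vonneumann")) {
  stopifnot(inherits(net, "netgrid_network"))
  neighborhood <- match.arg(neighborhood)
  if (p < 0 || p > 1) stop("'p' must be in [0, 1]")
  niter <- as.integer(niter)
  if (niter < 0L) stop("'niter' must be non-negative")
  style <- layout_style(style)
  n <- length(net$nodes)

  if (is.null(weights)) {
    L <- all_pairs_distances(net)
    W <- build_weights(L, style)
    if (!is.null(boost)) {
      if (is.null(boost$delta)) stop("'boost' needs an element 'delta'")
      W <- apply_module_boost(W, node_modules(net), delta = boost$delta,
                              dist = L, distance_filter = boost$distances,
                              target_modules = boost$modules)
    }
  } else {
    W <- weights
    if (nrow(W) != n) stop("'weights' does not match the node count")
    storage.mode(W) <- "integer"
  }

  if (is.null(grid)) grid <- make_grid(n, occupancy)
  if (!is.null(seed)) set.seed(seed)
  init <- init_random(n, grid, nodes = net$nodes)
  res <- cpp_optimize(init$coords, W, init$width, init$height, p, niter,
                      neighborhood == "moore")
  layout <- grid_layout(`rownames<-`(res$coords, net$nodes),
                        init$width, init$height)
  structure(
    list(network = net, layout = layout, weights = W,
         cost = res$cost, trace = as.numeric(res$trace),
         evaluations = res$evaluations,
         params = list(style = style$name, p = p, niter = niter,
                       occupancy = occupancy,
                       grid = c(width = init$width, height = init$height),
                       seed = seed, boost = boost,
                       neighborhood = neighborhood)),
    class = "netgrid")
}

#' @export
print.netgrid <- function(x, ...) {
  cat(sprintf("netgrid layout fit: %d nodes on a %d x %d grid\n",
              length(x$network$nodes), x$layout$width, x$layout$height))
  cat(sprintf("  style = %s, p = %g, niter = %d; final cost = %s\n",
              x$params$style, x$params$p, x$params$niter,
              format(x$cost, big.mark = ",")))
  cat(sprintf("  accepted %d of %d perturbation restarts\n",
              sum(diff(x$trace) < 0), x$params$niter))
  invisible(x)
}

#' @export
coef.netgrid <- function(object, ...) object$layout$coords

#' @export
as.data.frame.netgrid <- function(x, ...) {
  co <- x$layout$coords
  data.frame(node = x$network$nodes, x = co[, 1L], y = co[, 2L],
             class = unname(node_classes(x$network)),
             module = unname(node_modules(x$network)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize a fitted grid layout
#'
#' Reports the final cost, cost improvement over the initial local minimum,
#' occupied bounding box, and (when modules are present) the mean
#' intra-module Manhattan distance per module — the quantity that
#' module-boosted weights are designed to shrink.
#'
#' @param object a fitted [netgrid()] object.
#' @param ... unused.
#' @return an object of class `"summary.netgrid"`.
#' @export
summary.netgrid <- function(object, ...) {
  co <- object$layout$coords
  bbox <- c(width = diff(range(co[, 1L])) + 1L,
            height = diff(range(co[, 2L])) + 1L)
  mods <- node_modules(object$network)
  cohesion <- NULL
  if (length(unique(mods[mods != "unassigned"])) >= 1L &&
      any(mods != "unassigned")) {
    labs <- sort(unique(mods[mods != "unassigned"]))
    cohesion <- vapply(labs, function(m) {
      mean_intra_distance(object$layout, names(mods)[mods == m])
    }, numeric(1L))
  }
  structure(list(n = nrow(co), grid = object$params$grid, bbox = bbox,
                 bbox_area = prod(bbox), cost = object$cost,
                 initial_cost = object$trace[1L],
                 accepted = sum(diff(object$trace) < 0),
                 niter = object$params$niter,
                 evaluations = object$evaluations,
                 style = object$params$style, cohesion = cohesion),
            class = "summary.netgrid")
}

#' @export
print.summary.netgrid <- function(x, ...) {
  cat(sprintf("netgrid fit: %d nodes, %d x %d grid, style = %s\n",
              x$n, x$grid[1L], x$grid[2L], x$style))
  cat(sprintf("  cost: %s (from initial local minimum %s; %d/%d restarts accepted)\n",
              format(x$cost, big.mark = ","),
              format(x$initial_cost, big.mark = ","), x$accepted, x$niter))
  cat(sprintf("  occupied bounding box: %d x %d (area %d)\n",
              x$bbox[1L], x$bbox[2L], x$bbox_area))
  if (!is.null(x$cohesion)) {
    cat("  mean intra-module Manhattan distance:\n")
    for (m in names(x$cohesion)) {
      cat(sprintf("    %-28s %.2f\n", m, x$cohesion[[m]]))
    }
  }
  invisible(x)
}

#' Mean intra-group Manhattan distance
#'
#' The average Manhattan distance over all unordered pairs of the given
#' nodes in a layout; the module-cohesion measure used to assess
#' module-boosted layouts.
#'
#' @param layout a [grid_layout()] object with node row names.
#' @param nodes character vector of node ids (>= 2).
#' @return mean pairwise Manhattan distance.
#' @export
mean_intra_distance <- function(layout, nodes) {
  co <- layout$coords[rownames(layout$coords) %in% nodes, , drop = FALSE]
  if (nrow(co) < 2L) return(NA_real_)
  dx <- abs(outer(co[, 1L], co[, 1L], `-`))
  dy <- abs(outer(co[, 2L], co[, 2L], `-`))
  d <- dx + dy
  mean(d[upper.tri(d)])
}

#' Plot a fitted grid layout
#'
#' Draws edges as straight segments and nodes as points, colored by module
#' (falling back to class, then to a single color), in grid-native
#' coordinates using base graphics. For publication-quality vector output
#' use [render_svg()].
#'
#' @param x a fitted [netgrid()] object.
#' @param cex node symbol expansion.
#' @param ... further arguments passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.netgrid <- function(x, cex = 1, ...) {
  co <- x$layout$coords
  mods <- node_modules(x$network)
  labs <- sort(unique(mods))
  cols <- stats::setNames(grDevices::hcl.colors(max(length(labs), 2L), "Dark 3"),
                          labs)[mods]
  plot(NA, xlim = c(-0.5, x$layout$width - 0.5),
       ylim = c(-0.5, x$layout$height - 0.5), asp = 1,
       xlab = "x", ylab = "y", ...)
  e <- x$network$edges
  if (nrow(e)) {
    i <- match(e[, 1L], x$network$nodes)
    j <- match(e[, 2L], x$network$nodes)
    graphics::segments(co[i, 1L], co[i, 2L], co[j, 1L], co[j, 2L],
                       col = "grey70")
  }
  graphics::points(co[, 1L], co[, 2L], pch = 19, col = cols, cex = cex)
  invisible(x)
}
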