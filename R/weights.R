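#' All-pairs graph distances
#'
#' Unweighted shortest-path (breadth-first) distances between every pair of
#' nodes. Pairs in different connected components are marked with `NA`, the
#' unreachable sentinel understood by [build_weights()].
#'
#' @param net a [netgrid_network()] object.
#' @return symmetric integer matrix with zero diagonal, `NA` for
#'   unreachable pairs, and node ids as dimnames.
#' @export
all_pairs_distances <- function(net) {
  g <- as_igraph(net)
  L <- igraph::distances(g, algorithm = "unweighted")
  L <- L[net$nodes, net$nodes, drop = FALSE]
  L[is.infinite(L)] <- NA
  storage.mode(L) <- "integer"
  L
}

#' Layout styles: weight as a function of graph distance
#'
#' A layout style is an integer step function chi mapping graph distance to
#' interaction weight: positive weights attract (the optimizer shortens the
#' Manhattan distance of the pair), negative weights repel. Distances beyond
#' the table's largest key take its terminal value; unreachable pairs take
#' `chi_unreachable`.
#'
#' Three built-in styles trade off attraction against repulsion:
#' \describe{
#'   \item{common}{chi(1)=9, chi(2)=4, chi(3)=1, chi(>=4)=-1, unreachable
#'     -1. Attraction and repulsion roughly balance, nodes spread evenly
#'     and modules separate clearly.}
#'   \item{compact}{chi(1)=9, chi(2)=4, chi(3)=2, chi(4)=1, chi(>=5)=0,
#'     unreachable 0. Attraction dominates; the drawing is tight, modules
#'     may touch.}
#'   \item{stretched}{chi(1)=6, chi(2)=1, chi(>=3)=-2, unreachable -2.
#'     Attraction is weak, so modules drift far apart.}
#' }
#'
#' @param style style name, or an already-built style object (returned
#'   unchanged).
#' @param chi integer vector of weights for distances `1, 2, ..., length(chi)`
#'   when building a custom style; must be non-increasing with `chi[1] > 0`.
#' @param chi_unreachable integer weight for unreachable pairs.
#' @param name name to attach to a custom style.
#' @return an object of class `"netgrid_style"` with fields `name`, `chi`,
#'   `chi_unreachable`.
#' @export
#' @examples
#' layout_style("compact")
#' layout_style(chi = c(5L, 1L, -1L), chi_unreachable = -1L, name = "mine")
layout_style <- function(style = c("common", "compact", "stretched"),
                         chi = NULL, chi_unreachable = NULL, name = "custom") {
  if (inherits(style, "netgrid_style")) return(style)
  if (!is.null(chi)) {
    chi <- as.integer(chi)
    if (length(chi) < 1L || chi[1L] <= 0L) stop("chi(1) must be positive")
    if (is.unsorted(rev(chi))) stop("chi must be non-increasing in distance")
    if (is.null(chi_unreachable)) chi_unreachable <- chi[length(chi)]
    return(structure(list(name = name, chi = chi,
                          chi_unreachable = as.integer(chi_unreachable)),
                     class = "netgrid_style"))
  }
  style <- match.arg(style)
  tabs <- list(
    common    = list(chi = c(9L, 4L, 1L, -1L), unreachable = -1L),
    compact   = list(chi = c(9L, 4L, 2L, 1L, 0L), unreachable = 0L),
    stretched = list(chi = c(6L, 1L, -2L), unreachable = -2L))
  structure(list(name = style, chi = tabs[[style]]$chi,
                 chi_unreachable = tabs[[style]]$unreachable),
            class = "netgrid_style")
}

#' @export
print.netgrid_style <- function(x, ...) {
  cat(sprintf("layout style '%s': chi(%s) = %s; chi(>=%d) = %d; unreachable = %d\n",
              x$name,
              paste(seq_along(x$chi), collapse = ","),
              paste(x$chi, collapse = ","),
              length(x$chi), x$chi[length(x$chi)], x$chi_unreachable))
  invisible(x)
}

#' Read a layout style from a config file
#'
#' Loads a chi table from a YAML or JSON file mapping distances to integer
#' weights, e.g. `{"1": 9, "2": 4, "3": 1, "inf": -1}`. Keys must be the
#' consecutive integers starting at 1 plus an optional `"inf"` entry for
#' unreachable pairs (defaulting to the terminal value).
#'
#' @param source path to a `.yaml`/`.yml` or `.json` file.
#' @param name style name to attach (defaults to the file name).
#' @return a `"netgrid_style"` object.
#' @export
read_style <- function(source, name = NULL) {
  tab <- if (grepl("\\.ya?ml$", source, ignore.case = TRUE)) {
    yaml::read_yaml(source)
  } else {
    jsonlite::read_json(source, simplifyVector = TRUE)
  }
  tab <- as.list(tab)
  unreach <- tab[["inf"]]
  tab[["inf"]] <- NULL
  keys <- suppressWarnings(as.integer(names(tab)))
  if (anyNA(keys)) stop("style keys must be integers or 'inf'")
  if (!setequal(keys, seq_len(max(keys)))) {
    stop("style keys must be consecutive integers starting at 1")
  }
  chi <- as.integer(unlist(tab))[order(keys)]
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(source))
  layout_style(chi = chi, chi_unreachable = unreach, name = name)
}

chi_of <- function(style, L) {
  k <- length(style$chi)
  idx <- pmin(L, k)
  idx[is.na(idx) | idx < 1L] <- 1L   # placeholders, overwritten below
  W <- style$chi[idx]
  W[!is.na(L) & L == 0L] <- 0L
  W[is.na(L)] <- style$chi_unreachable
  W
}

#' Build the interaction weight matrix from graph distances
#'
#' Applies a layout style elementwise: `W[i, j] = chi(L[i, j])`, with the
#' style's unreachable weight for `NA` distances and zero on the diagonal.
#'
#' @param dist distance matrix from [all_pairs_distances()].
#' @param style a style name or `"netgrid_style"` object (see
#'   [layout_style()]).
#' @return symmetric integer weight matrix with the same dimnames as `dist`.
#' @export
build_weights <- function(dist, style = "common") {
  style <- layout_style(style)
  W <- matrix(chi_of(style, as.vector(dist)), nrow = nrow(dist),
              dimnames = dimnames(dist))
  diag(W) <- 0L
  storage.mode(W) <- "integer"
  stopifnot(!anyNA(W))
  W
}

#' Boost weights of same-module node pairs
#'
#' Adds a positive constant to `W[i, j]` for node pairs in the same
#' functional module, so that module members aggregate in the layout. Two
#' variants are supported: restricting the boost to pairs at selected graph
#' distances (e.g. `distance_filter = c(2, 3)` with `delta = 10`), and
#' boosting all pairs within selected modules (e.g.
#' `target_modules = "virulence_factor_synthesis"` with `delta = 15`).
#' Pairs labeled `"unassigned"` are never boosted.
#'
#' @param W integer weight matrix from [build_weights()].
#' @param modules named character vector node -> module label (see
#'   [node_modules()]); only nodes named in `rownames(W)` are used.
#' @param delta positive integer added to each qualifying pair.
#' @param dist distance matrix, required when `distance_filter` is given.
#' @param distance_filter optional integer set: only pairs whose graph
#'   distance lies in the set are boosted.
#' @param target_modules optional character set of module labels: only pairs
#'   within those modules are boosted.
#' @return the boosted weight matrix (symmetric, integer).
#' @export
apply_module_boost <- function(W, modules, delta, dist = NULL,
                               distance_filter = NULL, target_modules = NULL) {
  delta <- as.integer(delta)
  if (length(delta) != 1L || is.na(delta) || delta <= 0L) {
    stop("'delta' must be a positive integer")
  }
  ids <- rownames(W)
  if (is.null(ids)) stop("'W' must carry node ids as dimnames")
  lab <- stats::setNames(rep(NA_character_, length(ids)), ids)
  common <- intersect(ids, names(modules))
  lab[common] <- modules[common]
  lab[lab == "unassigned"] <- NA_character_
  if (!is.null(target_modules)) lab[!(lab %in% target_modules)] <- NA_character_
  same <- outer(lab, lab, `==`)
  same[is.na(same)] <- FALSE
  if (!is.null(distance_filter)) {
    if (is.null(dist)) stop("'dist' is required with a distance filter")
    same <- same & matrix(dist %in% as.integer(distance_filter), nrow = nrow(W))
  }
  diag(same) <- FALSE
  W[same] <- W[same] + delta
  storage.mode(W) <- "integer"
  W
}
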