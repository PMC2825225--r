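#' Construct a network object
#'
#' The basic container used throughout the package: an undirected, simple
#' graph with optional node classes (`"metabolite"` / `"reaction"`, set by
#' [build_bipartite()]) and optional functional-module labels (used by
#' [apply_module_boost()] and for rendering).
#'
#' Edges are stored as unordered pairs: duplicates (in either orientation)
#' are collapsed and self-loops are dropped with a warning, since the layout
#' cost is defined on pairs of distinct nodes. Isolated nodes are legal and
#' are placed by the layout engine like any other node.
#'
#' @param edges two-column character matrix or data frame of edge endpoints;
#'   may have zero rows.
#' @param nodes character vector of node ids. Defaults to the ids appearing
#'   in `edges`; must be a superset of them, so isolated nodes can be listed
#'   explicitly.
#' @param node_class optional named character vector mapping node ids to
#'   `"metabolite"` or `"reaction"`.
#' @param node_module optional named character vector mapping node ids to
#'   module labels; nodes without a label are reported as `"unassigned"`.
#' @return an object of class `"netgrid_network"` with fields `nodes`,
#'   `edges` (two-column character matrix), `node_class`, `node_module`.
#' @export
#' @examples
#' net <- netgrid_network(rbind(c("A", "B"), c("B", "C")))
#' net
netgrid_network <- function(edges, nodes = NULL, node_class = NULL,
                            node_module = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (ncol(edges) < 2L) stop("'edges' must have two columns")
  edges <- matrix(as.character(edges[, 1:2]), ncol = 2L)
  seen <- unique(as.vector(t(edges)))   # before loop-dropping, so a node
  loops <- edges[, 1L] == edges[, 2L]   # named only in a self-loop survives
  if (any(loops)) {
    warning(sprintf("dropping %d self-loop edge(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  # canonical unordered-pair form, first-seen order
  canon <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  canon <- canon[!duplicated(paste(canon[, 1L], canon[, 2L], sep = "\r")), ,
                 drop = FALSE]
  if (is.null(nodes)) {
    nodes <- seen
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicate node ids")
    missing <- setdiff(unique(as.vector(canon)), nodes)
    if (length(missing)) {
      stop("edge endpoint(s) not in node list: ", paste(missing, collapse = ", "))
    }
  }
  if (length(nodes) < 1L) stop("network must have at least one node")
  check_label_map <- function(map, what) {
    if (is.null(map)) return(NULL)
    if (is.null(names(map))) stop(sprintf("'%s' must be a named vector", what))
    unknown <- setdiff(names(map), nodes)
    if (length(unknown)) {
      stop(sprintf("%s refers to unknown node(s): %s", what,
                   paste(unknown, collapse = ", ")))
    }
    stats::setNames(as.character(map), names(map))
  }
  structure(
    list(nodes = nodes, edges = canon,
         node_class = check_label_map(node_class, "node_class"),
         node_module = check_label_map(node_module, "node_module")),
    class = "netgrid_network")
}

#' @export
print.netgrid_network <- function(x, ...) {
  cat(sprintf("netgrid network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (!is.null(x$node_class)) {
    tab <- table(node_classes(x))
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  if (!is.null(x$node_module)) {
    tab <- table(node_modules(x))
    cat("  modules:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Node class and module labels
#'
#' Return the per-node class (`"metabolite"` / `"reaction"`) or module label
#' for every node of the network, filling unlabeled nodes with
#' `"unassigned"`.
#'
#' @param net a [netgrid_network()] object.
#' @return named character vector over all nodes of `net`.
#' @export
node_modules <- function(net) {
  out <- stats::setNames(rep("unassigned", length(net$nodes)), net$nodes)
  if (!is.null(net$node_module)) out[names(net$node_module)] <- net$node_module
  out
}

#' @rdname node_modules
#' @export
node_classes <- function(net) {
  out <- stats::setNames(rep("unassigned", length(net$nodes)), net$nodes)
  if (!is.null(net$node_class)) out[names(net$node_class)] <- net$node_class
  out
}

strip_comments <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines[nzchar(trimws(lines))]
}

#' Read a network from an edge-list file
#'
#' Parses a plain-text edge list (one edge per line, the first two
#' whitespace- or tab-separated fields are the endpoints; `#` starts a
#' comment), the same two-column dialect as SIF files without the
#' interaction type. An optional companion file assigns module labels,
#' one `node<TAB>label` pair per line; nodes it does not mention are
#' labeled `"unassigned"`.
#'
#' @param source path to the edge-list file (or a connection readable by
#'   [readLines()]).
#' @param class_source optional path to the node label file.
#' @return a [netgrid_network()] object.
#' @export
read_edge_list <- function(source, class_source = NULL) {
  raw <- readLines(source, warn = FALSE)
  # "#node<TAB>id" comment records carry isolated nodes (see write_edge_list)
  iso <- sub("^#node[ \t]+", "", grep("^#node[ \t]+\\S", raw, value = TRUE))
  lines <- strip_comments(raw)
  if (length(lines) == 0L) stop("no edges in ", paste(source, collapse = ""))
  fields <- strsplit(lines, "[ \t]+")
  short <- vapply(fields, length, 1L) < 2L
  if (any(short)) {
    stop(sprintf("malformed edge line (need 2 fields): '%s'",
                 lines[which(short)[1L]]))
  }
  edges <- t(vapply(fields, function(f) f[1:2], character(2L)))
  modules <- NULL
  if (!is.null(class_source)) {
    cl <- strip_comments(readLines(class_source, warn = FALSE))
    cf <- strsplit(cl, "\t")
    bad <- vapply(cf, length, 1L) < 2L
    if (any(bad)) {
      stop(sprintf("malformed class line (need node<TAB>label): '%s'",
                   cl[which(bad)[1L]]))
    }
    modules <- stats::setNames(vapply(cf, `[`, "", 2L),
                               vapply(cf, `[`, "", 1L))
    known <- unique(c(as.vector(edges), iso))
    unknown <- setdiff(names(modules), known)
    if (length(unknown)) {
      stop("class file names unknown node(s): ", paste(unknown, collapse = ", "))
    }
  }
  netgrid_network(edges, nodes = unique(c(as.vector(t(edges)), iso)),
                  node_module = modules)
}

#' Write a network to edge-list (and optional label) files
#'
#' Inverse of [read_edge_list()]: writes one `a<TAB>b` line per edge, and,
#' when `class_sink` is given, one `node<TAB>label` line per node carrying a
#' module label. Reading the files back reproduces the node set, edge set
#' and labels.
#'
#' @param net a [netgrid_network()] object.
#' @param sink path of the edge-list file to write.
#' @param class_sink optional path of the label file to write.
#' @return `net`, invisibly.
#' @export
write_edge_list <- function(net, sink, class_sink = NULL) {
  iso <- setdiff(net$nodes, as.vector(net$edges))
  lines <- sprintf("%s\t%s", net$edges[, 1L], net$edges[, 2L])
  if (length(iso)) {
    # isolated nodes are kept as comment records so the node set round-trips
    lines <- c(lines, sprintf("#node\t%s", iso))
  }
  writeLines(lines, sink)
  if (!is.null(class_sink)) {
    mods <- net$node_module
    if (is.null(mods)) mods <- character()
    writeLines(sprintf("%s\t%s", names(mods), mods), class_sink)
  }
  invisible(net)
}

#' Build a bipartite metabolite-reaction network from a reaction table
#'
#' Converts a set of reactions into the bipartite graph used for metabolic
#' network drawing: one node per metabolite and one per reaction, with an
#' undirected edge for every (substrate or product, reaction) incidence.
#' Reaction directionality is discarded; duplicate incidences collapse to a
#' single edge. Node classes are set to `"metabolite"` / `"reaction"`.
#'
#' @param reactions a data frame with columns `reaction_id`, `substrates`,
#'   `products` (the latter two `";"`-separated id strings), as produced by
#'   [read_reaction_table()], or a list of records with those fields given
#'   as character vectors.
#' @return a bipartite [netgrid_network()] object.
#' @export
#' @examples
#' rxn <- data.frame(reaction_id = "R1", substrates = "A;B", products = "C")
#' build_bipartite(rxn)
build_bipartite <- function(reactions) {
  if (is.data.frame(reactions)) {
    split_ids <- function(x) {
      lapply(strsplit(as.character(x), ";", fixed = TRUE),
             function(v) trimws(v[nzchar(trimws(v))]))
    }
    reactions <- Map(function(id, s, p) list(reaction_id = id, substrates = s,
                                             products = p),
                     as.character(reactions$reaction_id),
                     split_ids(reactions$substrates),
                     split_ids(reactions$products))
  }
  rids <- vapply(reactions, function(r) r$reaction_id, "")
  if (any(!nzchar(rids))) stop("empty reaction id")
  if (anyDuplicated(rids)) stop("duplicate reaction ids")
  edges <- do.call(rbind, lapply(reactions, function(r) {
    mets <- unique(c(r$substrates, r$products))
    if (length(mets) == 0L) stop("reaction ", r$reaction_id,
                                 " has no substrates or products")
    cbind(mets, r$reaction_id)
  }))
  mets <- unique(edges[, 1L])
  clash <- intersect(mets, rids)
  if (length(clash)) {
    stop("id used for both a reaction and a metabolite: ",
         paste(clash, collapse = ", "))
  }
  netgrid_network(
    edges, nodes = c(mets, rids),
    node_class = stats::setNames(
      c(rep("metabolite", length(mets)), rep("reaction", length(rids))),
      c(mets, rids)))
}

#' Read a reaction table from a TSV file
#'
#' Expects a tab-separated file with a header row naming the columns
#' `reaction_id`, `substrates` and `products`; the id columns are
#' `";"`-separated lists.
#'
#' @param source path of the TSV file.
#' @return a data frame suitable for [build_bipartite()].
#' @export
read_reaction_table <- function(source) {
  tab <- utils::read.table(source, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "")
  need <- c("reaction_id", "substrates", "products")
  if (!all(need %in% names(tab))) {
    stop("reaction table needs columns: ", paste(need, collapse = ", "))
  }
  tab
}

#' Default currency-metabolite stoplist
#'
#' Ubiquitous small molecules (water, CO2, the ATP/ADP and NAD(P)H pools,
#' phosphate, protons) that act as spurious hubs in metabolite-reaction
#' graphs and are conventionally excluded before layout. Shipped as an
#' editable text file in `inst/extdata/currency_metabolites.txt`.
#'
#' @return character vector of lower-case metabolite ids.
#' @export
default_currency_stoplist <- function() {
  path <- system.file("extdata", "currency_metabolites.txt", package = "netgrid")
  strip_comments(readLines(path, warn = FALSE))
}

#' Remove currency metabolites from a network
#'
#' Drops the stoplisted nodes and their incident edges. Matching is
#' case-insensitive. Surviving nodes keep their ids, classes and module
#' labels; nodes left isolated by the removal are retained (the layout still
#' places them). Stoplist entries absent from the network are ignored.
#'
#' @param net a [netgrid_network()] object.
#' @param stoplist character vector of node ids to remove; defaults to
#'   [default_currency_stoplist()].
#' @return the filtered [netgrid_network()] object.
#' @export
remove_currency <- function(net, stoplist = default_currency_stoplist()) {
  drop <- net$nodes[tolower(net$nodes) %in% tolower(stoplist)]
  keep <- setdiff(net$nodes, drop)
  if (length(keep) == 0L) stop("stoplist removes every node")
  edges <- net$edges[!(net$edges[, 1L] %in% drop | net$edges[, 2L] %in% drop), ,
                     drop = FALSE]
  sub_map <- function(map) {
    if (is.null(map)) return(NULL)
    map[names(map) %in% keep]
  }
  netgrid_network(edges, nodes = keep, node_class = sub_map(net$node_class),
                  node_module = sub_map(net$node_module))
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    as.data.frame(net$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
}
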