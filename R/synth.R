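#' Generate a synthetic modular network
#'
#' Planted-partition generator used as the test bed for the layout engine:
#' nodes are split into modules of the given sizes, each within-module pair
#' is connected independently with probability `p_in` and each cross-module
#' pair with probability `p_out <= p_in`, so the ground-truth module labels
#' are known exactly. With `bipartite = TRUE` each module is generated as
#' reactions wired to metabolites (nodes alternate classes and only
#' metabolite-reaction pairs may be connected), mimicking the structure of
#' currency-filtered metabolic graphs.
#'
#' @param module_sizes vector of positive integer module sizes.
#' @param p_in within-module edge probability.
#' @param p_out between-module edge probability (`p_out <= p_in`).
#' @param bipartite generate metabolite/reaction classes and restrict edges
#'   to cross-class pairs.
#' @param seed optional integer seed (uses R's RNG stream).
#' @param module_labels optional character labels, one per module; default
#'   `"M1"`, `"M2"`, ...
#' @return a [netgrid_network()] with ground-truth `node_module` labels
#'   (and `node_class` when `bipartite`).
#' @export
#' @examples
#' synth_network(c(3, 3), p_in = 1, p_out = 0, seed = 1)
synth_network <- function(module_sizes, p_in, p_out, bipartite = FALSE,
                          seed = NULL, module_labels = NULL) {
  module_sizes <- as.integer(module_sizes)
  if (any(module_sizes < 1L)) stop("module sizes must be positive")
  if (p_out > p_in || p_in > 1 || p_out < 0) {
    stop("need 0 <= p_out <= p_in <= 1")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(module_labels)) {
    module_labels <- paste0("M", seq_along(module_sizes))
  }
  if (length(module_labels) != length(module_sizes)) {
    stop("one label per module required")
  }
  n <- sum(module_sizes)
  mod <- rep(module_labels, module_sizes)
  cls <- if (bipartite) {
    unlist(lapply(module_sizes, function(m) {
      rep_len(c("metabolite", "reaction"), m)
    }))
  } else NULL
  ids <- sprintf("n%0*d", nchar(n), seq_len(n))

  pair <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  prob <- ifelse(mod[pair[, 1L]] == mod[pair[, 2L]], p_in, p_out)
  if (bipartite) prob[cls[pair[, 1L]] == cls[pair[, 2L]]] <- 0
  keep <- stats::runif(nrow(pair)) < prob
  edges <- cbind(ids[pair[keep, 1L]], ids[pair[keep, 2L]])
  netgrid_network(
    edges, nodes = ids,
    node_class = if (bipartite) stats::setNames(cls, ids),
    node_module = stats::setNames(mod, ids))
}

with_preserved_rng <- function(expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE)) {
            rm(".Random.seed", envir = globalenv())
          })
  expr
}

#' Deterministic demonstration fixtures
#'
#' Two fixed synthetic metabolite-reaction networks used throughout the
#' test suite in place of real genome-scale data: a 290-node network with 3
#' functional modules (central metabolism, lipid synthesis, nucleotide
#' synthesis) and a 677-node network with 7 functional subsystems plus a
#' small set of unassigned reactions. Both are planted-partition bipartite
#' graphs with mean degree around 3-4, the sparsity typical of
#' currency-filtered metabolic graphs, built under internal fixed seeds so
#' repeated calls return identical networks without touching the caller's
#' RNG state.
#'
#' @param n which fixture: 290 or 677 (node count).
#' @return a [netgrid_network()] with module (and class) labels.
#' @export
fixture_network <- function(n = c(290, 677)) {
  n <- match.arg(as.character(n[1L]), c("290", "677"))
  with_preserved_rng({
    if (n == "290") {
      synth_network(
        c(100L, 95L, 95L), p_in = 0.07, p_out = 0.002, bipartite = TRUE,
        seed = 290L,
        module_labels = c("central_metabolism", "lipid_synthesis",
                          "nucleotide_synthesis"))
    } else {
      net <- synth_network(
        c(120L, 110L, 100L, 95L, 90L, 80L, 60L), p_in = 0.06,
        p_out = 0.0015, bipartite = TRUE, seed = 677L,
        module_labels = c("central_metabolism", "lipid_synthesis",
                          "cell_wall_lps_synthesis",
                          "virulence_factor_synthesis", "trna_synthetases",
                          "ethanol_pyruvate_metabolism", "sulfur_metabolism"))
      # 22 unassigned reactions, each wired to three random metabolites
      mets <- names(node_classes(net))[node_classes(net) == "metabolite"]
      extra <- sprintf("u%02d", 1:22)
      new_edges <- do.call(rbind, lapply(extra, function(id) {
        cbind(id, sample(mets, 3L))
      }))
      netgrid_network(
        rbind(net$edges, new_edges),
        nodes = c(net$nodes, extra),
        node_class = c(net$node_class,
                       stats::setNames(rep("reaction", length(extra)), extra)),
        node_module = c(net$node_module,
                        stats::setNames(rep("unassigned", length(extra)),
                                        extra)))
    }
  })
}
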