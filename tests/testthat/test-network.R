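test_that("edge lists parse, deduplicate and drop self-loops", {
  f <- withr::local_tempfile(lines = c("# comment", "A B", "B\tC", ""))
  net <- read_edge_list(f)
  expect_setequal(net$nodes, c("A", "B", "C"))
  expect_equal(nrow(net$edges), 2L)

  f2 <- withr::local_tempfile(lines = c("A B", "B A"))
  expect_equal(nrow(read_edge_list(f2)$edges), 1L)

  f3 <- withr::local_tempfile(lines = "A A")
  expect_warning(net3 <- read_edge_list(f3), "self-loop")
  expect_equal(nrow(net3$edges), 0L)
  expect_equal(net3$nodes, "A")

  f4 <- withr::local_tempfile(lines = "# nothing here")
  expect_error(read_edge_list(f4), "no edges")
})

test_that("class files attach module labels and reject unknown nodes", {
  f <- withr::local_tempfile(lines = c("A B", "B C"))
  cf <- withr::local_tempfile(lines = c("A\tm1", "B\tm1"))
  net <- read_edge_list(f, cf)
  expect_equal(unname(node_modules(net)[c("A", "B", "C")]),
               c("m1", "m1", "unassigned"))

  cf_bad <- withr::local_tempfile(lines = "Z\tm1")
  expect_error(read_edge_list(f, cf_bad), "Z")
})

test_that("edge-list write/read round-trips nodes, edges and labels", {
  net <- synth_network(c(4, 4), p_in = 0.8, p_out = 0.1, seed = 7)
  # add an isolated node to exercise the comment-record path
  net <- netgrid_network(net$edges, nodes = c(net$nodes, "iso"),
                         node_module = c(node_modules(net), iso = "m9"))
  f <- withr::local_tempfile()
  cf <- withr::local_tempfile()
  write_edge_list(net, f, cf)
  back <- read_edge_list(f, cf)
  expect_setequal(back$nodes, net$nodes)
  canon <- function(e) sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  expect_equal(canon(back$edges), canon(net$edges))
  expect_equal(node_modules(back)[sort(net$nodes)],
               node_modules(net)[sort(net$nodes)])
})

test_that("bipartite construction follows reaction incidences", {
  net <- build_bipartite(data.frame(reaction_id = "R1", substrates = "A;B",
                                    products = "C"))
  expect_setequal(net$nodes, c("A", "B", "C", "R1"))
  expect_equal(nrow(net$edges), 3L)
  expect_equal(unname(node_classes(net)["R1"]), "reaction")

  # shared metabolite gets one edge per reaction; hand-enumerated oracle:
  # R1: A->B gives A-R1, B-R1; R2: B->A gives B-R2, A-R2 => 4 edges
  rxn <- data.frame(reaction_id = c("R1", "R2"),
                    substrates = c("A", "B"), products = c("B", "A"))
  net2 <- build_bipartite(rxn)
  expect_equal(length(net2$nodes), 4L)
  expect_equal(nrow(net2$edges), 4L)
  deg <- table(as.vector(net2$edges))
  expect_equal(unname(deg[["A"]]), 2L)

  expect_error(build_bipartite(
    data.frame(reaction_id = "A", substrates = "A;B", products = "C")),
    "both a reaction and a metabolite")
})

test_that("bipartite networks are 2-colored by the class labels", {
  for (s in 1:5) {
    net <- synth_network(c(10, 10), p_in = 0.4, p_out = 0.1,
                         bipartite = TRUE, seed = s)
    cls <- node_classes(net)
    expect_true(all(cls[net$edges[, 1L]] != cls[net$edges[, 2L]]))
  }
  rxn <- data.frame(reaction_id = c("R1", "R2"),
                    substrates = c("g6p;atp", "f6p"),
                    products = c("f6p;adp", "fdp"))
  net <- build_bipartite(rxn)
  cls <- node_classes(net)
  expect_true(all(cls[net$edges[, 1L]] != cls[net$edges[, 2L]]))
})

test_that("currency removal drops listed nodes and keeps the rest intact", {
  net <- netgrid_network(rbind(c("A", "R1"), c("h2o", "R1")),
                         node_module = c(A = "m1"))
  out <- remove_currency(net, "h2o")
  expect_setequal(out$nodes, c("A", "R1"))
  expect_equal(nrow(out$edges), 1L)
  expect_equal(unname(node_modules(out)["A"]), "m1")

  # empty stoplist is the identity
  same <- remove_currency(net, character())
  expect_setequal(same$nodes, net$nodes)
  expect_equal(nrow(same$edges), nrow(net$edges))

  # absent stoplist entries are ignored; isolated survivors are retained
  iso <- remove_currency(netgrid_network(rbind(c("A", "h2o"))), c("h2o", "xyz"))
  expect_equal(iso$nodes, "A")
  expect_equal(nrow(iso$edges), 0L)
})

test_that("removing a cut node splits components as hand-counted", {
  # path A - h2o - B: removing h2o must leave 2 components (A and B alone)
  net <- netgrid_network(rbind(c("A", "h2o"), c("h2o", "B")))
  out <- remove_currency(net, "h2o")
  L <- all_pairs_distances(out)
  n_comp <- igraph::count_components(
    igraph::graph_from_data_frame(as.data.frame(out$edges), directed = FALSE,
                                  vertices = out$nodes))
  expect_equal(n_comp, 2L)
  expect_true(is.na(L["A", "B"]))

  # never adds edges
  for (s in 1:3) {
    set.seed(s)
    net <- random_network(12, 0.25)
    drop <- sample(net$nodes, 3)
    out <- remove_currency(net, drop)
    expect_lte(nrow(out$edges), nrow(net$edges))
    expect_true(all(!(as.vector(out$edges) %in% drop)))
  }
})

test_that("network invariants are enforced", {
  expect_error(netgrid_network(rbind(c("A", "B")), nodes = c("A", "A", "B")),
               "duplicate")
  expect_error(netgrid_network(rbind(c("A", "B")), nodes = "A"), "endpoint")
  expect_error(netgrid_network(rbind(c("A", "B")),
                               node_module = c(Q = "m1")), "unknown")
  expect_error(netgrid_network(matrix(character(), ncol = 2)), "at least one")
})
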