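test_that("grid sizing follows the occupancy formula", {
  expect_equal(unname(make_grid(4, 0.25)), c(4L, 4L))
  expect_equal(unname(make_grid(1, 1)), c(1L, 1L))
  expect_equal(unname(make_grid(290, 0.25)), c(35L, 35L))
  expect_gte(prod(make_grid(17, 0.33)), 17)
  expect_error(make_grid(0), "at least 1")
  expect_error(make_grid(5, 0), "occupancy")
})

test_that("random initialization is seeded, collision-free and uniform", {
  a <- init_random(10, c(7, 7), seed = 5)
  b <- init_random(10, c(7, 7), seed = 5)
  expect_identical(a$coords, b$coords)
  expect_true(layout_invariants_hold(a))

  full <- init_random(9, c(3, 3), seed = 1)
  expect_equal(sort(full$coords[, 2L] * 3L + full$coords[, 1L]), 0:8)

  expect_error(init_random(5, c(2, 2)), "fewer cells")

  # one node on a 2x2 grid: each cell frequency within 3 sigma of 1/4
  set.seed(99)
  cells <- replicate(10000, {
    co <- init_random(1, c(2, 2))$coords
    co[1L, 2L] * 2L + co[1L, 1L]
  })
  counts <- tabulate(cells + 1L, nbins = 4L)
  sigma <- sqrt(10000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 2500) < 3 * sigma))
})

test_that("cost is the weighted sum of Manhattan distances", {
  W <- matrix(c(0L, 3L, 3L, 0L), 2)
  lay <- grid_layout(rbind(c(0, 0), c(2, 1)), 4, 4)
  expect_equal(grid_cost(lay, W), 9)

  one <- grid_layout(rbind(c(0, 0)), 1, 1)
  expect_equal(grid_cost(one, matrix(0L, 1, 1)), 0)

  # translation invariance
  lay2 <- grid_layout(rbind(c(1, 1), c(3, 2)), 4, 4)
  expect_equal(grid_cost(lay2, W), grid_cost(lay, W))

  # negative weights repel: larger distance lowers cost
  Wn <- matrix(c(0L, -2L, -2L, 0L), 2)
  far <- grid_layout(rbind(c(0, 0), c(3, 3)), 4, 4)
  expect_lt(grid_cost(far, Wn), grid_cost(lay, Wn))
})

test_that("delta-cost equals the full-recompute difference", {
  set.seed(11)
  for (rep in 1:200) {
    n <- sample(3:12, 1)
    side <- sample((ceiling(sqrt(n)) + 1):8, 1)
    W <- matrix(sample(-3:9, n * n, replace = TRUE), n)
    W <- W + t(W)
    diag(W) <- 0L
    storage.mode(W) <- "integer"
    lay <- init_random(n, c(side, side))
    occ <- paste(lay$coords[, 1L], lay$coords[, 2L])
    vac <- setdiff(paste(rep(0:(side - 1), side),
                         rep(0:(side - 1), each = side)), occ)
    target <- as.integer(strsplit(sample(vac, 1), " ")[[1]])
    node <- sample(n, 1)
    d <- delta_cost(lay, W, node, target)
    after <- lay$coords
    after[node, ] <- target
    expect_identical(d, full_cost_r(after, W) - full_cost_r(lay$coords, W))
  }
})

test_that("delta-cost edge cases: zero-weight nodes, antisymmetry, errors", {
  W <- matrix(0L, 3, 3)
  lay <- grid_layout(rbind(c(0, 0), c(2, 0), c(0, 2)), 4, 4)
  expect_equal(delta_cost(lay, W, 1, c(1, 1)), 0)

  W2 <- matrix(5L, 3, 3)
  diag(W2) <- 0L
  d_fwd <- delta_cost(lay, W2, 1, c(1, 1))
  moved <- grid_layout(rbind(c(1, 1), c(2, 0), c(0, 2)), 4, 4)
  expect_equal(delta_cost(moved, W2, 1, c(0, 0)), -d_fwd)

  expect_error(delta_cost(lay, W2, 1, c(2, 0)), "occupied")
  expect_error(delta_cost(lay, W2, 1, c(4, 0)), "off the grid")
  expect_error(delta_cost(lay, W2, 9, c(1, 1)), "unknown node")
})

test_that("neighborhood test reaches a certified local minimum", {
  # two attracting nodes at opposite corners end up at Manhattan distance 1:
  # exhaustively, d = 1 minimizes 5 * d over achievable distances
  W <- matrix(c(0L, 5L, 5L, 0L), 2)
  lay <- grid_layout(rbind(c(0, 0), c(3, 3)), 4, 4)
  out <- neighborhood_test(lay, W)
  d <- sum(abs(out$coords[1, ] - out$coords[2, ]))
  expect_equal(d, 1L)
  expect_true(is_single_move_local_min(out, W))

  # a local minimum is a fixed point
  again <- neighborhood_test(out, W)
  expect_identical(again$coords, out$coords)
  expect_equal(attr(again, "sweeps"), 1L)
})

test_that("neighborhood test never increases cost and certifies on random instances", {
  set.seed(21)
  for (rep in 1:15) {
    n <- sample(5:40, 1)
    side <- ceiling(sqrt(n / 0.4))
    W <- matrix(sample(c(-2L, -1L, 0L, 1L, 4L, 9L), n * n, replace = TRUE), n)
    W <- W + t(W)
    diag(W) <- 0L
    storage.mode(W) <- "integer"
    lay <- init_random(n, c(side, side))
    out <- neighborhood_test(lay, W)
    expect_lte(grid_cost(out, W), grid_cost(lay, W))
    expect_true(layout_invariants_hold(out))
    expect_true(is_single_move_local_min(out, W))
  }
})

test_that("perturbation honors p = 0, p = 1 and the layout invariants", {
  set.seed(31)
  lay <- init_random(12, c(8, 8))
  expect_identical(perturb(lay, 0)$coords, lay$coords)

  moved <- perturb(lay, 1)
  expect_true(layout_invariants_hold(moved))
  # sparse grid: every node has a vacant Moore neighbor at move time
  expect_true(all(rowSums(moved$coords != lay$coords) > 0))

  # fully packed grid: nobody can move even at p = 1
  packed <- init_random(9, c(3, 3))
  expect_identical(perturb(packed, 1)$coords, packed$coords)

  expect_error(perturb(lay, 1.5), "in \\[0, 1\\]")
})

test_that("invariants hold across randomized operation sequences", {
  set.seed(41)
  n <- 20
  W <- build_weights(all_pairs_distances(random_network(n, 0.2)), "common")
  lay <- init_random(n, make_grid(n))
  for (step in 1:30) {
    lay <- if (runif(1) < 0.5) {
      perturb(lay, runif(1))
    } else {
      neighborhood_test(lay, W)
    }
    expect_true(layout_invariants_hold(lay))
  }
})
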