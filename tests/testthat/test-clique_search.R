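make_weight_data <- function(w) {
  # wrap a weight matrix as a pairwise_matrix for clique_scan
  structure(w, metric = "custom", entropies = rep(1, nrow(w)),
            class = c("pairwise_matrix", "matrix", "array"))
}

test_that("triangle formation order matches hand enumeration on 4 nodes", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.9
  w[1, 3] <- w[3, 1] <- 0.8
  w[2, 3] <- w[3, 2] <- 0.7
  w[1, 4] <- w[4, 1] <- 0.6
  w[2, 4] <- w[4, 2] <- 0.5
  w[3, 4] <- w[4, 3] <- 0.4
  d <- discrete_dataset(matrix(0:1, 2, 4))
  cl <- clique_scan(d, make_weight_data(w), max_cliques = 10)
  # edges inserted: (1,2),(1,3),(2,3),(1,4),(2,4),(3,4)
  # triangles: {1,2,3} at edge 3, {1,2,4} at 5, then {1,3,4},{2,3,4} at 6
  expect_identical(cl$indices,
                   c("1;2;3", "1;2;4", "1;3;4", "2;3;4"))
  expect_identical(cl$edge_index, c(3L, 5L, 6L, 6L))
  expect_identical(nrow(cl), 4L)
})

test_that("tied weights insert in lexicographic order", {
  w <- matrix(0, 4, 4)
  d <- discrete_dataset(matrix(0:1, 2, 4))
  cl <- clique_scan(d, make_weight_data(w), max_cliques = 5)
  # lexicographic edge order: (1,2),(1,3),(1,4),(2,3),...
  # the first triangle {1,2,3} completes at the 4th insertion, which is the
  # 3rd mutually incident edge among {1,2,3}
  expect_identical(cl$indices[1], "1;2;3")
  expect_identical(cl$edge_index[1], 4L)
})

test_that("the clique budget truncates the harvest", {
  w <- matrix(0, 5, 5)
  d <- discrete_dataset(matrix(0:1, 2, 5))
  cl <- clique_scan(d, make_weight_data(w), max_cliques = 1)
  expect_identical(nrow(cl), 1L)
})

test_that("an unbounded harvest equals brute-force triangle enumeration", {
  for (seed in 1:5) {
    set.seed(seed)
    k <- 20
    w <- matrix(0, k, k)
    w[upper.tri(w)] <- stats::runif(k * (k - 1) / 2)
    w <- w + t(w)
    d <- discrete_dataset(matrix(0:1, 2, k))
    cl <- clique_scan(d, make_weight_data(w), max_cliques = 10000)
    adj <- matrix(TRUE, k, k)  # all edges eventually inserted
    expect_identical(sort(cl$indices), oracle_triangles(adj))
    # formation order respects descending edge-weight insertion: the
    # creating edge index equals the max insertion index over the
    # triangle's three edges
    pairs <- which(upper.tri(w), arr.ind = TRUE)
    ord <- order(-w[pairs], pairs[, 1], pairs[, 2])
    ins <- matrix(0L, k, k)
    for (e in seq_len(nrow(pairs))) {
      u <- pairs[ord[e], 1]; v <- pairs[ord[e], 2]
      ins[u, v] <- ins[v, u] <- e
    }
    for (r in seq_len(nrow(cl))) {
      s <- cl$set[[r]]
      expect_identical(cl$edge_index[r],
                       max(ins[s[1], s[2]], ins[s[1], s[3]],
                           ins[s[2], s[3]]))
    }
    expect_true(!is.unsorted(cl$edge_index))
  }
})

test_that("harvest agrees with igraph triangles on a thresholded graph", {
  set.seed(99)
  k <- 15
  w <- matrix(0, k, k)
  w[upper.tri(w)] <- stats::runif(k * (k - 1) / 2)
  w <- w + t(w)
  d <- discrete_dataset(matrix(0:1, 2, k))
  cl <- clique_scan(d, make_weight_data(w), max_cliques = 10000)
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
  tri <- matrix(igraph::triangles(g), nrow = 3)
  expected <- sort(apply(apply(tri, 2, sort), 2, paste, collapse = ";"))
  expect_identical(sort(cl$indices), expected)
})

test_that("scored cliques match direct O-information calls", {
  gen <- planted_fixture(n = 1500, flip = 0.1, n_background = 5, seed = 43)
  cl <- clique_scan(gen$data, "mi", max_cliques = 30)
  sc <- score_cliques(gen$data, cl)
  for (r in seq_len(nrow(sc$formation))) {
    expect_equal(sc$formation$raw_value[r],
                 o_information(gen$data, sc$formation$set[[r]]),
                 tolerance = 1e-12)
  }
  expect_identical(sort(sc$ranked$indices), sort(sc$formation$indices))
  expect_true(!is.unsorted(-sc$ranked$canonical_score))
})

test_that("noisy parity triplets are harvestable, pure parity forms late (mi metric)", {
  # with sampling noise every edge carries a little empirical MI, so the
  # planted triplet appears in a full harvest
  gen <- planted_fixture(n = 4000, flip = 0.1, n_background = 3, seed = 47)
  cl <- clique_scan(gen$data, "mi", max_cliques = choose(6, 3))
  expect_true("1;2;3" %in% cl$indices)
  # exact parity design: the three intra-triplet MI values are exactly 0,
  # while a correlated background triple has strictly positive MI, so the
  # parity triangle cannot be among the first harvested cliques
  x <- rep(c(0L, 1L, 0L, 1L), each = 64L)
  y <- rep(c(0L, 0L, 1L, 1L), each = 64L)
  z <- (x + y) %% 2L
  b1 <- rep(0:1, 128L)                # balanced within every (x,y) block
  b2 <- b1; b2[c(1L, 2L)] <- 1L - b2[c(1L, 2L)]
  b2[c(65L, 66L)] <- 1L - b2[c(65L, 66L)]
  b3 <- b1; b3[c(3L, 4L)] <- 1L - b3[c(3L, 4L)]
  b3[c(67L, 68L)] <- 1L - b3[c(67L, 68L)]
  pure <- discrete_dataset(cbind(x = x, y = y, z = z,
                                 b1 = b1, b2 = b2, b3 = b3))
  expect_equal(mutual_information(pure, 1, 3), 0, tolerance = 1e-12)
  clp <- clique_scan(pure, "mi", max_cliques = choose(6, 3))
  expect_identical(clp$indices[1], "4;5;6")
  expect_gt(which(clp$indices == "1;2;3"), 3L)
})

test_that("empty clique lists score to empty records", {
  d <- discrete_dataset(matrix(0:1, 2, 4))
  w <- matrix(0, 4, 4)
  cl <- clique_scan(d, make_weight_data(w), max_cliques = 5)
  cl0 <- cl[0, , drop = FALSE]
  class(cl0) <- class(cl)
  sc <- score_cliques(d, cl0)
  expect_identical(nrow(sc$ranked), 0L)
})
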