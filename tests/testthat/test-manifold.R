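test_that("neighbourhood size rule is max(floor(M/10), 2)", {
  expect_equal(choose_k(20), 2)
  expect_equal(choose_k(35), 3)
  expect_equal(choose_k(9), 2)
  expect_equal(choose_k(100), 10)
  expect_error(choose_k(2), "at least 3")
})

three_point_D <- function() {
  D <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.1,
                0.9, 0.1, 0), 3, 3)
  D
}

test_that("k-NN retention keeps row-wise nearest neighbours, union-symmetrized", {
  e <- knn_retention(three_point_D(), k = 1)
  expect_equal(matrix(unclass(e), ncol = 2),
               cbind(c(1L, 2L), c(2L, 3L)), ignore_attr = TRUE)

  # complete tie matrix: every vertex picks the k lowest-indexed others
  Dt <- matrix(0.5, 4, 4); diag(Dt) <- 0
  e2 <- knn_retention(Dt, k = 2)
  # rows 1..4 pick {2,3},{1,3},{1,2},{1,2}; union has 5 edges
  expect_equal(matrix(unclass(e2), ncol = 2),
               cbind(c(1L, 1L, 1L, 2L, 2L), c(2L, 3L, 4L, 3L, 4L)),
               ignore_attr = TRUE)

  # k = M - 1 retains the complete graph
  set.seed(8)
  D <- distance_matrix(matrix(rnorm(40 * 6), 40, 6))$D
  e3 <- knn_retention(D, k = 5)
  expect_equal(nrow(e3), choose(6, 2))
  expect_error(knn_retention(D, k = 6), "invalid k")
})

test_that("every vertex keeps at least k incident edges under the union rule", {
  set.seed(12)
  for (case in 1:10) {
    M <- sample(6:15, 1)
    D <- distance_matrix(matrix(rnorm(50 * M), 50, M))$D
    k <- sample(2:4, 1)
    e <- knn_retention(D, k)
    deg <- tabulate(c(e[, 1], e[, 2]), nbins = M)
    expect_true(all(deg >= k))
  }
})

test_that("geodesic distances route through intermediaries and match Floyd-Warshall", {
  D <- three_point_D()
  e <- knn_retention(D, k = 1)
  G <- geodesic_distances(D, e)
  expect_equal(G[1, 3], 0.2)    # via vertex 2, not the 0.9 direct path

  set.seed(19)
  for (case in 1:15) {
    M <- sample(5:12, 1)
    D <- distance_matrix(matrix(rnorm(40 * M), 40, M))$D
    e <- knn_retention(D, k = sample(2:3, 1))
    expect_equal(geodesic_distances(D, e), floyd_warshall(D, e))
  }
})

test_that("geodesics never exceed retained direct distances and detect fragmentation", {
  set.seed(23)
  D <- distance_matrix(matrix(rnorm(40 * 8), 40, 8))$D
  e_full <- knn_retention(D, k = 7)
  G <- geodesic_distances(D, e_full)
  expect_true(all(G <= D + 1e-12))

  # two cliques with no bridging edge
  edges <- rbind(cbind(1L, 2L), cbind(1L, 3L), cbind(2L, 3L),
                 cbind(4L, 5L), cbind(4L, 6L), cbind(5L, 6L))
  D2 <- matrix(1, 6, 6); diag(D2) <- 0
  G2 <- geodesic_distances(D2, edges)
  expect_true(all(is.infinite(G2[1:3, 4:6])))
})

test_that("enlarging k never increases a geodesic distance", {
  set.seed(31)
  D <- distance_matrix(matrix(rnorm(50 * 10), 50, 10))$D
  prev <- geodesic_distances(D, knn_retention(D, 2))
  for (k in 3:6) {
    cur <- geodesic_distances(D, knn_retention(D, k))
    expect_true(all(cur <= prev + 1e-12))
    prev <- cur
  }
})

test_that("pruning + geodesic stage agrees with vegan's isomap distances", {
  skip_if_not_installed("vegan")
  set.seed(42)
  D <- distance_matrix(matrix(rnorm(60 * 9), 60, 9))$D
  for (k in 2:4) {
    G <- geodesic_distances(D, knn_retention(D, k))
    vd <- as.matrix(vegan::isomapdist(as.dist(D), k = k,
                                      fragmentedOK = TRUE))
    dimnames(vd) <- NULL
    expect_equal(G, vd, tolerance = 1e-12)
  }
})

test_that("classical MDS exactly recovers Euclidean configurations", {
  # 3 points on a line, 0.2 apart
  G <- matrix(c(0, 0.2, 0.4,
                0.2, 0, 0.2,
                0.4, 0.2, 0), 3, 3)
  P <- classical_mds(G, q = 1)
  got <- as.matrix(dist(P))
  dimnames(got) <- NULL
  expect_equal(got, G, tolerance = 1e-9)
  expect_true(all(abs(colMeans(P)) < 1e-10))

  # planar configuration, q = 2
  set.seed(5)
  pts <- matrix(rnorm(14), 7, 2)
  G2 <- as.matrix(dist(pts))
  P2 <- classical_mds(G2, q = 2)
  got2 <- as.matrix(dist(P2))
  dimnames(got2) <- NULL
  dimnames(G2) <- NULL
  expect_equal(got2, G2, tolerance = 1e-9)
  expect_true(all(abs(colMeans(P2)) < 1e-10))

  # cross-check against stats::cmdscale
  ref <- stats::cmdscale(G2, k = 2)
  expect_equal(as.matrix(dist(P2)), as.matrix(dist(ref)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("fragmented inputs follow the largest-component policy", {
  G <- matrix(Inf, 5, 5)
  line <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  G[1:3, 1:3] <- line
  G[4:5, 4:5] <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(classical_mds(G, fragmented_ok = FALSE), "fragmented")
  P <- classical_mds(G, q = 2)
  expect_true(attr(P, "fragmented"))
  expect_equal(attr(P, "embedded"), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_true(all(is.na(P[4:5, ])))
  expect_equal(abs(P[3, 1] - P[1, 1]), 2, tolerance = 1e-9)
})

test_that("edge weights are reciprocals of embedded distances on the edge support", {
  # two connected points 0.5 apart
  pts <- structure(matrix(c(-0.25, 0.25, 0, 0), 2, 2),
                   embedded = c(TRUE, TRUE), fragmented = FALSE)
  e <- cbind(i = 1L, j = 2L)
  g <- build_weighted_graph(pts, e)
  expect_equal(g$W[1, 2], 2.0)
  expect_equal(g$A[1, 2], 1)

  # end-to-end on the 3-point line: retained edges get weight 1/0.1
  D <- three_point_D()
  g3 <- prune_graph(D, k = 1, ndim = 1)
  expect_equal(g3$W[1, 2], 10, tolerance = 1e-8)
  expect_equal(g3$W[2, 3], 10, tolerance = 1e-8)
  expect_equal(g3$W[1, 3], 0)   # non-edge stays 0 despite finite distance

  # coincident embedded points trigger the capped-weight warning
  pts0 <- structure(matrix(0, 2, 2), embedded = c(TRUE, TRUE))
  expect_warning(g0 <- build_weighted_graph(pts0, e), "coincident")
  expect_equal(g0$W[1, 2], 1e8)
})

test_that("pruned graphs expose symmetric nonnegative weights with empty diagonal", {
  set.seed(77)
  for (case in 1:5) {
    M <- sample(8:20, 1)
    D <- distance_matrix(matrix(rnorm(60 * M), 60, M))$D
    g <- prune_graph(D)
    expect_identical(g$W, t(g$W))
    expect_true(all(g$W >= 0))
    expect_equal(unname(diag(g$W)), rep(0, M))
    expect_identical((g$W > 0) * 1, g$A)
  }
})
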