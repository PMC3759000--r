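K4 <- function() graph_from_adjacency(matrix(1, 4, 4) - diag(4))
path3 <- function() graph_from_adjacency(
  adjacency_from_edges(3, rbind(c(1, 2), c(2, 3))))

test_that("transitivity matches hand-enumerated triples", {
  expect_equal(graph_transitivity(graph_from_adjacency(
    adjacency_from_edges(3, rbind(c(1, 2), c(2, 3), c(1, 3))))), 1.0)
  star <- adjacency_from_edges(4, rbind(c(1, 2), c(1, 3), c(1, 4)))
  expect_equal(graph_transitivity(graph_from_adjacency(star)), 0.0)
  # square 1-2-3-4 with chord 1-3: two triangles (123, 134), degrees
  # (3, 2, 3, 2) give 8 connected triples -> 6/8
  sq <- adjacency_from_edges(4, rbind(c(1, 2), c(2, 3), c(3, 4),
                                      c(4, 1), c(1, 3)))
  expect_equal(graph_transitivity(graph_from_adjacency(sq)), 0.75)
  expect_equal(brute_transitivity(sq), 0.75)
  # no connected triple -> undefined
  lone <- adjacency_from_edges(4, rbind(c(1, 2), c(3, 4)))
  expect_true(is.na(graph_transitivity(graph_from_adjacency(lone))))
})

test_that("average path length counts connected pairs only", {
  expect_equal(average_path_length(path3()), 4 / 3)
  expect_equal(average_path_length(K4()), 1.0)
  two_edges <- graph_from_adjacency(
    adjacency_from_edges(4, rbind(c(1, 2), c(3, 4))))
  expect_equal(average_path_length(two_edges), 1.0)
  single <- graph_from_adjacency(matrix(0, 1, 1))
  expect_true(is.na(average_path_length(single)))
})

test_that("graph metrics agree with exhaustive enumeration oracles", {
  set.seed(55)
  for (case in 1:20) {
    M <- sample(4:8, 1)
    A <- random_adjacency(M, p = runif(1, 0.25, 0.8))
    g <- graph_from_adjacency(A)
    expect_equal(graph_transitivity(g), brute_transitivity(A))
    expect_equal(average_path_length(g), brute_average_path_length(A))
    ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(igraph::clique_num(ig), brute_clique_number(A))
    n_comp <- igraph::components(ig)$no
    ec <- if (n_comp > 1) 0L else igraph::edge_connectivity(ig)
    expect_equal(ec, brute_edge_connectivity(A))
  }
})

test_that("complete and path graphs hit their closed-form feature values", {
  fv <- feature_vector(K4(), weighted = FALSE, sw_reps = 1, sw_seed = 1)
  expect_equal(unname(fv[fnc_feature_names[1:13] != "Small Worldness"]),
               c(1, 4, 1, 3, 1 / 3, 3, 3, 3, 3, 4, 6, 1))
  # G(4, 6) is forced to be K4 itself, so sigma is exactly 1
  expect_equal(unname(fv["Small Worldness"]), 1.0)

  fp <- feature_vector(path3(), weighted = FALSE, sw_reps = 5, sw_seed = 1)
  expect_equal(unname(fp["Graph Density"]), 2 / 3)
  expect_equal(unname(fp["Clique Number"]), 2)
  expect_equal(unname(fp["Edge Connectivity"]), 1)
  expect_equal(unname(fp[c("Max Degree", "Median Degree", "Min Degree")]),
               c(2, 1, 1))
  expect_equal(unname(fp["Average Path Length"]), 4 / 3)
  expect_equal(unname(fp["Transitivity"]), 0)   # one open triple, no triangle
})

test_that("fragmented graphs report zero edge connectivity", {
  frag <- graph_from_adjacency(
    adjacency_from_edges(5, rbind(c(1, 2), c(2, 3), c(4, 5))))
  fv <- feature_vector(frag, weighted = FALSE, sw_reps = 2, sw_seed = 1)
  expect_equal(unname(fv["Edge Connectivity"]), 0)
})

test_that("degree summaries are ordered and features survive relabeling", {
  set.seed(66)
  for (case in 1:8) {
    M <- sample(6:10, 1)
    A <- random_adjacency(M, 0.5)
    if (sum(A) == 0) next
    g <- feature_vector(graph_from_adjacency(A), weighted = FALSE,
                        sw_reps = 10, sw_seed = 99)
    expect_lte(g["Min Degree"], g["Median Degree"])
    expect_lte(g["Median Degree"], g["Max Degree"])
    perm <- sample(M)
    Ap <- A[perm, perm]
    gp <- feature_vector(graph_from_adjacency(Ap), weighted = FALSE,
                         sw_reps = 10, sw_seed = 99)
    expect_equal(unname(g), unname(gp), tolerance = 1e-12)
  }
})

test_that("weighted path metrics use inverse-weight edge lengths", {
  # triangle with weights 1, 2, 4 -> lengths 1, 0.5, 0.25
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 2
  W[1, 3] <- W[3, 1] <- 4
  g <- graph_from_adjacency((W > 0) * 1, W = W)
  # shortest lengths: 1-2: min(1, 0.25+0.5)=0.75; 2-3: 0.5; 1-3: 0.25
  expect_equal(average_path_length(g, weighted = TRUE),
               (0.75 + 0.5 + 0.25) / 3)
  expect_equal(average_path_length(g, weighted = FALSE), 1.0)
  fv <- feature_vector(g, weighted = TRUE, sw_reps = 1, sw_seed = 1)
  # closeness per vertex: 1/(0.75+0.25), 1/(0.75+0.5), 1/(0.25+0.5)
  # = (1, 0.8, 4/3); the median is 1
  expect_equal(unname(fv["Median Closeness"]), 1.0)
})

test_that("the G(n,m) reference ensemble is exact when forced and unbiased at scale", {
  ref <- erdos_renyi_reference(4, 6, reps = 3, seed = 1)
  expect_equal(ref$C_rand, 1.0)
  expect_equal(ref$L_rand, 1.0)

  a <- erdos_renyi_reference(10, 20, reps = 1, seed = 42)
  b <- erdos_renyi_reference(10, 20, reps = 1, seed = 42)
  expect_identical(a, b)

  expect_error(erdos_renyi_reference(4, 7), "invalid edge count")

  # E[transitivity] ~ p = m / C(n,2) for G(n,m); the extra 0.01 covers
  # the exact conditional edge probability (m-2)/(N-2) being slightly
  # below p at this size
  ref2 <- erdos_renyi_reference(20, 40, reps = 2000, seed = 7)
  p <- 40 / choose(20, 2)
  expect_lt(abs(ref2$C_rand - p), 3 * 0.1 / sqrt(2000) + 0.01)
})

test_that("sigma is the gamma/lambda ratio and detects small-world structure", {
  set.seed(13)
  A <- random_adjacency(12, 0.5)
  sw <- small_worldness(graph_from_adjacency(A), reps = 200, seed = 3)
  expect_equal(sw$sigma, sw$gamma / sw$lambda, tolerance = 1e-12)

  # ring lattice n = 30, 4 neighbours, 5% rewired: gamma >> 1, lambda ~ 1
  set.seed(17)
  ws <- igraph::sample_smallworld(1, 30, 2, 0.05)
  Aw <- as.matrix(igraph::as_adjacency_matrix(ws))
  Aw[Aw > 1] <- 1; diag(Aw) <- 0
  sw2 <- small_worldness(graph_from_adjacency(Aw), reps = 500, seed = 21)
  expect_gt(sw2$sigma, 1)

  expect_error(small_worldness(graph_from_adjacency(matrix(0, 3, 3))),
               "no edges")
})
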