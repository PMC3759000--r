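#' The 13 connectivity feature names, in canonical column order
#' @export
fnc_feature_names <- c("Average Path Length", "Clique Number",
                       "Graph Density", "Edge Connectivity",
                       "Median Closeness", "Median Graph Coreness",
                       "Max Degree", "Median Degree", "Min Degree",
                       "Vertex Count", "Edge Count", "Transitivity",
                       "Small Worldness")

as_igraph <- function(g, weighted = FALSE) {
  if (inherits(g, "fnc_graph")) {
    if (weighted)
      igraph::graph_from_adjacency_matrix(g$W, mode = "undirected",
                                          weighted = TRUE)
    else
      igraph::graph_from_adjacency_matrix(g$A, mode = "undirected")
  } else if (igraph::is_igraph(g)) g
  else igraph::graph_from_adjacency_matrix((as.matrix(g) != 0) * 1,
                                           mode = "undirected")
}

#' Global transitivity (clustering coefficient)
#'
#' 3 x (number of triangles) divided by the number of connected vertex
#' triples, on the binarized adjacency.  `NA` when no connected triples
#' exist.
#'
#' @param g an `fnc_graph`, igraph object, or adjacency matrix.
#' @return A number in `[0, 1]`, or `NA` if undefined.
#' @export
graph_transitivity <- function(g) {
  val <- igraph::transitivity(as_igraph(g), type = "global")
  if (is.nan(val)) undefined_value() else val
}

#' Average shortest-path length
#'
#' Mean shortest-path distance over all pairs of distinct vertices with a
#' finite distance (unreachable pairs are excluded, so a fragmented graph
#' averages within components).  Unweighted distances are hop counts;
#' weighted distances use edge length `1 / weight`.
#'
#' @param g an `fnc_graph`, igraph object, or adjacency matrix.
#' @param weighted use inverse-weight edge lengths (only meaningful for
#'   `fnc_graph` input); default FALSE (hop counts).
#' @return Mean path length, or `NA` for a graph with no connected pair.
#' @export
average_path_length <- function(g, weighted = FALSE) {
  d <- shortest_path_matrix(g, weighted)
  vals <- d[upper.tri(d)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) return(undefined_value())
  mean(vals)
}

# Pairwise shortest-path matrix; weighted => edge length = 1/weight.
shortest_path_matrix <- function(g, weighted = FALSE) {
  if (weighted && inherits(g, "fnc_graph")) {
    ig <- as_igraph(g, weighted = TRUE)
    w <- igraph::E(ig)$weight
    igraph::distances(ig, weights = 1 / w)
  } else {
    igraph::distances(as_igraph(g), weights = NA)
  }
}

# Closeness per vertex: 1 / sum of shortest-path distances to the other
# vertices of its own component; NA for isolated vertices.
closeness_values <- function(g, weighted = FALSE) {
  d <- shortest_path_matrix(g, weighted)
  diag(d) <- NA
  apply(d, 1, function(row) {
    s <- sum(row[is.finite(row)], na.rm = TRUE)
    n_reach <- sum(is.finite(row), na.rm = TRUE)
    if (n_reach == 0 || s == 0) NA_real_ else 1 / s
  })
}

#' Erdos-Renyi G(n,m) reference ensemble
#'
#' Draws `reps` graphs uniformly from G(n, m) (exactly `me` edges) and
#' returns the ensemble means of global transitivity and average path
#' length, the null reference for the small-world coefficient.
#' Replicates with undefined transitivity (no connected triple) are
#' skipped from that mean; the skip count is reported.
#'
#' @param Mv vertex count.
#' @param me edge count, `0 < me <= Mv (Mv - 1) / 2`.
#' @param reps ensemble size, at least 1.
#' @param seed optional integer seed for reproducibility; `NULL` uses the
#'   current RNG stream.
#' @return List with `C_rand`, `L_rand`, `reps`, `skipped_C`,
#'   `skipped_L`.
#' @export
erdos_renyi_reference <- function(Mv, me, reps = 5000L, seed = NULL) {
  Mv <- as.integer(Mv); me <- as.integer(me); reps <- as.integer(reps)
  if (me < 1L || me > Mv * (Mv - 1) / 2)
    stop("invalid edge count for G(n,m)", call. = FALSE)
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  draw <- function() {
    cs <- numeric(reps); ls <- numeric(reps)
    for (r in seq_len(reps)) {
      g <- igraph::sample_gnm(Mv, me)
      cs[r] <- igraph::transitivity(g, type = "global")
      ls[r] <- igraph::mean_distance(g, directed = FALSE,
                                     unconnected = TRUE)
    }
    list(C_rand = mean(cs[!is.nan(cs)]), L_rand = mean(ls[!is.nan(ls)]),
         reps = reps, skipped_C = sum(is.nan(cs)),
         skipped_L = sum(is.nan(ls)))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Small-world coefficient sigma
#'
#' \eqn{\sigma = \gamma / \lambda} with
#' \eqn{\gamma = C / \bar C_{rand}} and
#' \eqn{\lambda = L / \bar L_{rand}}, where \eqn{C} and \eqn{L} are the
#' graph's global transitivity and average path length (binarized
#' adjacency) and the reference means come from an
#' [erdos_renyi_reference()] ensemble with matching vertex and edge
#' counts.  \eqn{\sigma \gg 1} indicates small-world organization:
#' clustering well above, and path length comparable to, an equally dense
#' random graph.
#'
#' @param g an `fnc_graph`, igraph object, or adjacency matrix, with at
#'   least one edge.
#' @param reps ensemble size; default 5000.
#' @param seed optional seed passed to [erdos_renyi_reference()].
#' @return An object of class `fnc_smallworld`: list with `sigma`,
#'   `gamma`, `lambda`, `C_rand`, `L_rand`, `reps`, and `reason` when
#'   sigma is undefined.
#' @export
small_worldness <- function(g, reps = 5000L, seed = NULL) {
  ig <- as_igraph(g)
  m <- igraph::ecount(ig)
  if (m < 1L) stop("graph has no edges", call. = FALSE)
  ref <- erdos_renyi_reference(igraph::vcount(ig), m, reps, seed)
  C <- graph_transitivity(ig)
  L <- average_path_length(ig)
  out <- list(sigma = undefined_value(), gamma = undefined_value(),
              lambda = undefined_value(),
              C_rand = ref$C_rand, L_rand = ref$L_rand, reps = ref$reps,
              reason = NULL)
  if (is.na(C) || is.na(ref$C_rand) || ref$C_rand == 0) {
    out$reason <- "transitivity undefined or zero reference clustering"
  } else if (is.na(L) || is.na(ref$L_rand) || ref$L_rand == 0) {
    out$reason <- "path length undefined in graph or reference"
  } else {
    out$gamma <- C / ref$C_rand
    out$lambda <- L / ref$L_rand
    out$sigma <- out$gamma / out$lambda
  }
  class(out) <- "fnc_smallworld"
  out
}

#' @export
print.fnc_smallworld <- function(x, ...) {
  if (is.na(x$sigma))
    cat(sprintf("Small-worldness undefined (%s)\n", x$reason))
  else
    cat(sprintf("sigma = %.4g (gamma = %.4g, lambda = %.4g; %d-rep G(n,m) ensemble)\n",
                x$sigma, x$gamma, x$lambda, x$reps))
  invisible(x)
}

#' The 13-feature connectivity fingerprint of one pruned graph
#'
#' Computes, in order: average path length, clique number, graph density
#' `2m / (M (M - 1))`, edge connectivity (global minimum edge cut; 0 for
#' a fragmented graph), median closeness, median coreness (k-core index),
#' max / median / min degree, vertex count, edge count, global
#' transitivity, and small-worldness.  With `weighted = TRUE` (the
#' default) the path-based features — average path length and closeness —
#' use edge lengths `1 / weight` from the inverse-distance weights;
#' triangle, degree, clique, core and count features are always computed
#' on the binarized adjacency, as is small-worldness.
#'
#' Undefined values (e.g. transitivity of a triangle-free graph with no
#' connected triple) propagate as `NA` rather than errors.
#'
#' @param g an `fnc_graph`.
#' @param weighted use weighted path metrics; default TRUE.
#' @param sw_reps ensemble size for the small-world null; default 5000.
#' @param sw_seed optional seed for the small-world ensemble.
#' @return Named numeric vector of length 13 (names =
#'   [fnc_feature_names]) with attribute `subject_id`.
#' @export
feature_vector <- function(g, weighted = TRUE, sw_reps = 5000L,
                           sw_seed = NULL) {
  stopifnot(inherits(g, "fnc_graph"))
  ig <- as_igraph(g)
  m <- igraph::ecount(ig)
  M <- igraph::vcount(ig)
  deg <- igraph::degree(ig)
  n_comp <- igraph::components(ig)$no
  clos <- closeness_values(g, weighted = weighted)
  sw <- if (m >= 1L) small_worldness(g, reps = sw_reps, seed = sw_seed)$sigma
        else undefined_value()
  out <- c(
    average_path_length(g, weighted = weighted),
    igraph::clique_num(ig),
    2 * m / (M * (M - 1)),
    if (n_comp > 1L) 0 else igraph::edge_connectivity(ig),
    if (all(is.na(clos))) undefined_value()
      else median(clos, na.rm = TRUE),
    median(igraph::coreness(ig)),
    max(deg), median(deg), min(deg),
    M, m,
    graph_transitivity(ig),
    sw)
  names(out) <- fnc_feature_names
  attr(out, "subject_id") <- g$subject_id
  out
}
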