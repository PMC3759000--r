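#' Neighbourhood size rule
#'
#' The number of nearest neighbours retained per vertex: 10% of the
#' subject's component count, or 2, whichever is greater —
#' `max(floor(M / 10), 2)`.
#'
#' @param M component (vertex) count, at least 3.
#' @return Integer k.
#' @export
#' @examples
#' choose_k(20)  # 2
#' choose_k(35)  # 3
choose_k <- function(M) {
  if (M < 3L) stop("need at least 3 components", call. = FALSE)
  max(floor(M / 10), 2L)
}

#' k-nearest-neighbour edge retention
#'
#' Retains the unordered edge \{i, j\} iff `j` is among the `k` smallest
#' off-diagonal entries of row `i` of the distance matrix, or `i` is
#' among the `k` smallest of row `j` (union symmetrization).  Ties at the
#' k-th distance are broken deterministically towards the lower column
#' index.
#'
#' @param D an `fnc_dist` object or a symmetric distance matrix.
#' @param k neighbours per vertex, `k < M`; default [choose_k()].
#' @return An object of class `fnc_edges`: a 2-column integer matrix of
#'   retained edges (i < j) with attribute `k` and `M`.
#' @export
knn_retention <- function(D, k = NULL) {
  D <- as_dist_matrix(D)
  M <- nrow(D)
  if (is.null(k)) k <- choose_k(M)
  k <- as.integer(k)
  if (k < 1L || k >= M)
    stop("invalid k: need 1 <= k < M", call. = FALSE)
  pairs <- matrix(FALSE, M, M)
  for (i in seq_len(M)) {
    d <- D[i, ]
    ord <- order(d, seq_len(M))        # ties -> lower column index
    ord <- ord[ord != i]
    nn <- ord[seq_len(k)]
    pairs[i, nn] <- TRUE
  }
  pairs <- pairs | t(pairs)            # union rule
  idx <- which(pairs & upper.tri(pairs), arr.ind = TRUE)
  edges <- cbind(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  structure(edges, k = k, M = M, class = c("fnc_edges", class(edges)))
}

as_dist_matrix <- function(D) {
  if (inherits(D, "fnc_dist")) D$D else as.matrix(D)
}

#' Geodesic (shortest-path) distances over retained edges
#'
#' All-pairs shortest paths where each retained edge keeps its original
#' pseudo-distance as length; the distance between pruned pairs becomes
#' the shortest path through intermediary nodes, and unreachable pairs
#' are `Inf`.
#'
#' @param D an `fnc_dist` object or symmetric distance matrix.
#' @param edges an `fnc_edges` object from [knn_retention()].
#' @return Symmetric M x M matrix of geodesic distances (class matrix;
#'   `Inf` marks fragmentation).
#' @export
geodesic_distances <- function(D, edges) {
  D <- as_dist_matrix(D)
  M <- nrow(D)
  g <- igraph::make_empty_graph(n = M, directed = FALSE)
  if (nrow(edges) > 0) {
    w <- D[cbind(edges[, 1], edges[, 2])]
    g <- igraph::add_edges(g, t(edges[, 1:2, drop = FALSE]))
    igraph::E(g)$weight <- w
  }
  G <- igraph::distances(g, weights = igraph::E(g)$weight)
  dimnames(G) <- NULL
  G
}

#' Classical multidimensional scaling of a geodesic matrix
#'
#' Double-centers \eqn{-\tfrac12 J G^{(2)} J} (entrywise squared
#' distances, J the centering projector), takes the top eigenpairs with
#' positive eigenvalues and scales eigenvectors by the square roots of
#' their eigenvalues.  If fewer than `q` positive eigenvalues exist the
#' embedding has that smaller dimension.
#'
#' Fragmented inputs (entries of `Inf`) are handled, when
#' `fragmented_ok = TRUE`, by embedding the largest connected component
#' and leaving the remaining vertices' coordinates `NA`; the result then
#' carries `fragmented = TRUE`.
#'
#' @param G symmetric matrix of geodesic distances from
#'   [geodesic_distances()].
#' @param q requested embedding dimension, at most `M - 1`; default
#'   `min(15, M - 1)`.
#' @param fragmented_ok proceed on the largest component when `G` has
#'   infinite entries (default TRUE); otherwise a fragmentation error.
#' @return M x q' coordinate matrix (q' <= q), mean-centered over embedded
#'   vertices, with attributes `fragmented`, `embedded` (logical vector)
#'   and `eigenvalues`.
#' @export
classical_mds <- function(G, q = NULL, fragmented_ok = TRUE) {
  M <- nrow(G)
  if (is.null(q)) q <- min(15L, M - 1L)
  if (q < 1L || q > M - 1L)
    stop("invalid embedding dimension: need 1 <= q <= M - 1", call. = FALSE)
  fragmented <- any(!is.finite(G))
  embedded <- rep(TRUE, M)
  if (fragmented) {
    if (!fragmented_ok)
      stop("fragmented geodesic matrix: graph is disconnected", call. = FALSE)
    # vertices of the largest component = largest block of mutually
    # finite distances
    comp <- integer(M); cid <- 0L
    for (v in seq_len(M)) {
      if (comp[v] == 0L) {
        cid <- cid + 1L
        comp[is.finite(G[v, ])] <- cid
      }
    }
    keep <- comp == which.max(tabulate(comp))
    embedded <- keep
    G <- G[keep, keep, drop = FALSE]
  }
  n <- nrow(G)
  B <- -0.5 * scale(t(scale(t(G^2), scale = FALSE)), scale = FALSE)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  q_eff <- min(q, length(pos), n - 1L)
  pts <- matrix(NA_real_, M, max(q_eff, 1L))
  if (q_eff >= 1L) {
    coords <- e$vectors[, pos[seq_len(q_eff)], drop = FALSE] %*%
      diag(sqrt(e$values[pos[seq_len(q_eff)]]), q_eff)
    pts[embedded, ] <- coords
  } else {
    pts[embedded, 1] <- 0      # degenerate: all points coincide
  }
  structure(pts, fragmented = fragmented, embedded = embedded,
            eigenvalues = e$values)
}

#' Inverse-distance weighted graph from an embedding
#'
#' For each retained edge the weight is the reciprocal of the Euclidean
#' distance between the two endpoints in the embedded coordinate system
#' (floored at `eps` to avoid infinite weights for coincident points);
#' non-edges have weight 0.  Edges with an unembedded endpoint (vertices
#' outside the largest component of a fragmented graph) are dropped, so
#' such vertices appear as weight-0 rows.
#'
#' @param points embedding from [classical_mds()].
#' @param edges an `fnc_edges` object.
#' @param eps floor for embedded distances; default `1e-8`.
#' @return An object of class `fnc_graph`: list with `W` (weighted
#'   adjacency), `A` (binarized adjacency), `M`, `fragmented`,
#'   `embedded`.
#' @export
build_weighted_graph <- function(points, edges, eps = 1e-8) {
  M <- nrow(points)
  embedded <- attr(points, "embedded") %||% rep(TRUE, M)
  W <- matrix(0, M, M)
  capped <- 0L
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    if (!embedded[i] || !embedded[j]) next
    d <- sqrt(sum((points[i, ] - points[j, ])^2))
    if (d < eps) capped <- capped + 1L
    W[i, j] <- W[j, i] <- 1 / max(d, eps)
  }
  if (capped > 0L)
    warning(sprintf("%d edge(s) between (near-)coincident embedded points; weight capped at 1/eps",
                    capped), call. = FALSE)
  A <- (W > 0) * 1
  structure(list(W = W, A = A, M = M,
                 fragmented = isTRUE(attr(points, "fragmented")),
                 embedded = embedded),
            class = "fnc_graph")
}

#' Full pruning stage: distance matrix to weighted graph
#'
#' Composes [knn_retention()], [geodesic_distances()], [classical_mds()]
#' and [build_weighted_graph()] — the graph-creation stage of the
#' pipeline.
#'
#' @inheritParams knn_retention
#' @param ndim requested embedding dimension (default `min(15, M - 1)`).
#' @param fragmented_ok see [classical_mds()].
#' @return An `fnc_graph` (see [build_weighted_graph()]), additionally
#'   carrying `subject_id` and `k`.
#' @export
prune_graph <- function(D, k = NULL, ndim = NULL, fragmented_ok = TRUE) {
  id <- if (inherits(D, "fnc_dist")) D$subject_id else NULL
  edges <- knn_retention(D, k)
  G <- geodesic_distances(D, edges)
  pts <- classical_mds(G, q = ndim, fragmented_ok = fragmented_ok)
  g <- build_weighted_graph(pts, edges)
  g$subject_id <- id
  g$k <- attr(edges, "k")
  g
}

#' @export
print.fnc_graph <- function(x, ...) {
  m <- sum(x$A[upper.tri(x$A)])
  cat(sprintf("FNC pruned graph%s: %d vertices, %d edges%s\n",
              if (!is.null(x$subject_id)) paste0(" for ", x$subject_id) else "",
              x$M, m, if (x$fragmented) " (fragmented)" else ""))
  invisible(x)
}
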