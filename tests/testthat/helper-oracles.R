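# Independent brute-force oracles used to check the package's
# implementations.  These deliberately avoid the code paths (and, for the
# graph oracles, the igraph routines) they are used to verify.

# Direct evaluation of the lagged cross-correlation formula: full-series
# means and divisor-T standard deviations, explicit sum over t per lag.
ccf_oracle <- function(x, y, L) {
  T_len <- length(x)
  mx <- sum(x) / T_len; my <- sum(y) / T_len
  sx <- sqrt(sum((x - mx)^2) / T_len)
  sy <- sqrt(sum((y - my)^2) / T_len)
  out <- numeric(2 * L + 1)
  for (l in -L:L) {
    acc <- 0
    if (l >= 0) {
      for (t in 1:(T_len - l)) acc <- acc + (x[t + l] - mx) * (y[t] - my)
    } else {
      for (t in 1:(T_len + l)) acc <- acc + (x[t] - mx) * (y[t - l] - my)
    }
    out[l + L + 1] <- acc / (T_len * sx * sy)
  }
  names(out) <- -L:L
  out
}

distance_oracle <- function(X, L) {
  M <- ncol(X)
  D <- matrix(0, M, M)
  for (i in seq_len(M)) for (j in seq_len(M)) {
    if (i == j) next
    d <- 1 - max(abs(ccf_oracle(X[, i], X[, j], L)))
    D[i, j] <- min(max(d, 0), 1)
  }
  D
}

# All-pairs shortest paths by Floyd-Warshall over a retained edge list
# with pseudo-distance edge lengths.
floyd_warshall <- function(D, edges) {
  M <- nrow(D)
  G <- matrix(Inf, M, M)
  diag(G) <- 0
  if (nrow(edges) > 0) for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    G[i, j] <- G[j, i] <- D[i, j]
  }
  for (k in seq_len(M)) for (i in seq_len(M)) for (j in seq_len(M))
    if (G[i, k] + G[k, j] < G[i, j]) G[i, j] <- G[i, k] + G[k, j]
  G
}

# Exhaustive clique number: test every vertex subset.
brute_clique_number <- function(A) {
  M <- nrow(A)
  best <- 1L
  for (code in seq_len(2^M - 1)) {
    S <- which(bitwAnd(code, 2^(seq_len(M) - 1)) > 0)
    if (length(S) <= best) next
    ok <- TRUE
    for (a in seq_along(S)) for (b in seq_along(S)) {
      if (a < b && A[S[a], S[b]] == 0) { ok <- FALSE; break }
    }
    if (ok) best <- length(S)
  }
  best
}

# Transitivity by triple enumeration: 3*triangles / connected triples.
brute_transitivity <- function(A) {
  M <- nrow(A)
  triangles <- 0L; triples <- 0L
  for (i in seq_len(M)) for (j in seq_len(M)) for (k in seq_len(M)) {
    if (i >= j || j >= k) next
    e <- A[i, j] + A[i, k] + A[j, k]
    if (e == 3) triangles <- triangles + 1L
    # each pair of incident edges at a centre vertex is one triple
  }
  for (centre in seq_len(M)) {
    nb <- sum(A[centre, ] > 0)
    triples <- triples + choose(nb, 2)
  }
  if (triples == 0) return(NA_real_)
  3 * triangles / triples
}

# Global minimum edge cut: minimise crossing edges over all vertex
# bipartitions (0 when the graph is already disconnected).
brute_edge_connectivity <- function(A) {
  M <- nrow(A)
  best <- Inf
  for (code in seq_len(2^(M - 1) - 1)) {   # fix vertex M on one side
    S <- which(bitwAnd(code, 2^(seq_len(M - 1) - 1)) > 0)
    Tset <- setdiff(seq_len(M), S)
    best <- min(best, sum(A[S, Tset, drop = FALSE] > 0))
  }
  as.integer(best)
}

# Mean hop-count shortest path over connected pairs, via Floyd-Warshall
# on unit lengths.
brute_average_path_length <- function(A) {
  M <- nrow(A)
  edges <- which(A > 0 & upper.tri(A), arr.ind = TRUE)
  G <- floyd_warshall((A > 0) * 1, edges)
  vals <- G[upper.tri(G)]
  vals <- vals[is.finite(vals) & vals > 0]
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

# Small helpers for building test graphs ----------------------------------

adjacency_from_edges <- function(M, edges) {
  A <- matrix(0, M, M)
  for (r in seq_len(nrow(edges))) {
    A[edges[r, 1], edges[r, 2]] <- 1
    A[edges[r, 2], edges[r, 1]] <- 1
  }
  A
}

# Wrap a plain adjacency matrix as an fnc_graph (unit weights).
graph_from_adjacency <- function(A, W = A) {
  structure(list(W = W, A = (A > 0) * 1, M = nrow(A),
                 fragmented = FALSE, embedded = rep(TRUE, nrow(A)),
                 subject_id = "test"),
            class = "fnc_graph")
}

random_adjacency <- function(M, p = 0.4) {
  A <- matrix(0, M, M)
  up <- which(upper.tri(A))
  A[up] <- as.numeric(runif(length(up)) < p)
  A + t(A)
}
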