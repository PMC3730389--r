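# Independent oracles and small generators used across the suite.

# random labeled symmetric 0/1 adjacency matrix, at least one edge
random_adjacency <- function(n, density = 0.4) {
  repeat {
    A <- matrix(0L, n, n)
    idx <- which(upper.tri(A))
    k <- max(1L, round(length(idx) * density))
    A[sample(idx, k)] <- 1L
    A <- A + t(A)
    if (sum(A) > 0) break
  }
  dimnames(A) <- list(paste0("N", seq_len(n)), paste0("N", seq_len(n)))
  A
}

# all-pairs shortest-path distances by matrix powering (walk counts of
# length d first become nonzero at d = distance)
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  Ak <- diag(n)
  for (d in seq_len(n)) {
    Ak <- Ak %*% A
    D[D == Inf & Ak > 0] <- d
  }
  D
}

# geodesic counts sigma[s, t] from walk counts: number of walks of length
# dist(s, t) equals the number of shortest paths
oracle_path_counts <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  pow <- vector("list", n)
  pow[[1]] <- A
  for (d in 2:max(2, n)) pow[[d]] <- pow[[d - 1]] %*% A
  S <- matrix(0, n, n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s != t && is.finite(D[s, t])) S[s, t] <- pow[[D[s, t]]][s, t]
  }
  S
}

# exhaustive betweenness: for every pair (s, t) and interior node v, the
# shortest paths through v are sigma[s,v] * sigma[v,t] when distances add up
oracle_betweenness <- function(A, normalized = TRUE) {
  n <- nrow(A)
  D <- oracle_distances(A)
  S <- oracle_path_counts(A)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t]) || S[s, t] == 0) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        bc[v] <- bc[v] + S[s, v] * S[v, t] / S[s, t]
      }
    }
  }
  if (normalized) bc <- bc / ((n - 1) * (n - 2) / 2)
  names(bc) <- rownames(A)
  bc
}

# reachability by boolean matrix powering
oracle_connected <- function(A) {
  n <- nrow(A)
  R <- diag(n) + A
  for (i in seq_len(n)) R <- (R %*% R > 0) * 1
  all(R > 0)
}

# tiny labeled adjacency from an edge list
adjacency_from_edges <- function(labels, edges) {
  A <- matrix(0L, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (e in edges) {
    A[e[1], e[2]] <- 1L
    A[e[2], e[1]] <- 1L
  }
  A
}

two_triangles <- function() {
  adjacency_from_edges(paste0("N", 1:6),
                       list(c(1, 2), c(2, 3), c(1, 3),
                            c(4, 5), c(5, 6), c(4, 6)))
}
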