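#' Degree centrality
#'
#' The number of edges incident to each node of a binary network.
#'
#' @param adj an adjacency matrix (binary, symmetric, zero diagonal).
#' @return A named integer vector of degrees.
#' @export
degree_centrality <- function(adj) {
  stopifnot(is.matrix(adj))
  deg <- as.integer(rowSums(adj))
  names(deg) <- rownames(adj)
  deg
}

#' Betweenness centrality (Brandes' algorithm)
#'
#' For each node, the fraction of shortest paths between the other node pairs
#' that pass through it, computed by Brandes' dependency accumulation over
#' unweighted (BFS) shortest paths. Raw scores count each unordered pair
#' once; normalized scores divide by `(p-1)(p-2)/2`, the number of pairs
#' excluding the focal node, so the middle node of a 3-node path scores
#' exactly 1.
#'
#' @param adj an adjacency matrix with at least 3 nodes.
#' @param normalized return the `[0, 1]` fraction (default) or raw pair
#'   counts.
#' @return A named numeric vector.
#' @examples
#' pathg <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
#' pathg[1, 2] <- pathg[2, 1] <- pathg[2, 3] <- pathg[3, 2] <- 1
#' betweenness_centrality(pathg)  # B scores 1, A and C score 0
#' @export
betweenness_centrality <- function(adj, normalized = TRUE) {
  stopifnot(is.matrix(adj))
  p <- nrow(adj)
  if (p < 3L) stop("betweenness normalization needs at least 3 nodes")
  nbrs <- apply(adj > 0, 1L, which, simplify = FALSE)
  bc <- numeric(p)
  for (s in seq_len(p)) {
    sigma <- numeric(p); sigma[s] <- 1
    dist <- rep(-1L, p); dist[s] <- 0L
    preds <- vector("list", p)
    order_visited <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      order_visited <- c(order_visited, v)
      for (w in nbrs[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(p)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / 2                      # each unordered pair visited from both ends
  if (normalized) bc <- bc / ((p - 1) * (p - 2) / 2)
  names(bc) <- rownames(adj)
  bc
}

#' Centrality table of a binary network
#'
#' @param adj an adjacency matrix with at least 3 nodes.
#' @return A data frame with columns `acupoint`, `degree`, `betweenness_raw`,
#'   `betweenness_norm`.
#' @export
centrality_table <- function(adj) {
  data.frame(acupoint = rownames(adj),
             degree = degree_centrality(adj),
             betweenness_raw = betweenness_centrality(adj, normalized = FALSE),
             betweenness_norm = betweenness_centrality(adj, normalized = TRUE),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Modularity of a module assignment
#'
#' Newman-Girvan modularity
#' \deqn{Q = \frac{1}{2l} \sum_{ij} \left(a_{ij} - \frac{k_i k_j}{2l}\right)\delta_{ij}}{Q = (1/2l) * sum_ij (a_ij - k_i k_j / 2l) delta_ij}
#' where `l` is the edge count, `k_i` node degrees, and `delta_ij = 1` when
#' `i` and `j` share a module. With this (standard) prefactor the one-module
#' partition of any graph scores exactly 0 and component-split disjoint
#' cliques score their textbook closed forms. `prefactor = "quarter"`
#' recomputes with a `1/(4l)` prefactor (exactly half the standard value), a
#' convention that rescales Q without changing which partition maximizes it.
#'
#' @param adj an adjacency matrix with at least one edge.
#' @param assignment integer/character module id per node.
#' @param prefactor `"standard"` (`1/2l`) or `"quarter"` (`1/4l`).
#' @return The modularity value.
#' @export
modularity_q <- function(adj, assignment, prefactor = c("standard", "quarter")) {
  prefactor <- match.arg(prefactor)
  p <- nrow(adj)
  if (length(assignment) != p) stop("assignment must cover every node")
  l <- sum(adj) / 2
  if (l < 1) stop("modularity is undefined for a graph with no edges")
  ids <- as.integer(factor(assignment))
  deg <- rowSums(adj)
  q <- 0
  for (c in unique(ids)) {
    members <- ids == c
    e_c <- sum(adj[members, members, drop = FALSE]) / 2
    d_c <- sum(deg[members])
    q <- q + e_c / l - (d_c / (2 * l))^2
  }
  if (prefactor == "quarter") q / 2 else q
}

# canonical relabeling: module ids numbered by first appearance in node order
canonical_assignment <- function(assignment) {
  ids <- match(assignment, unique(assignment))
  names(ids) <- names(assignment)
  ids
}

new_partition <- function(adj, assignment, method) {
  assignment <- canonical_assignment(assignment)
  names(assignment) <- rownames(adj)
  structure(list(assignment = assignment,
                 q = modularity_q(adj, assignment),
                 module_count = length(unique(assignment)),
                 method = method),
            class = "acupoint_partition")
}

#' @export
print.acupoint_partition <- function(x, ...) {
  cat(sprintf("Partition into %d modules (Q = %.4f, %s)\n",
              x$module_count, x$q, x$method))
  for (c in sort(unique(x$assignment))) {
    mem <- names(x$assignment)[x$assignment == c]
    if (is.null(mem)) mem <- which(x$assignment == c)
    cat(sprintf("  Module %s (%d): %s\n", LETTERS[min(c, 26L)], length(mem),
                paste(mem, collapse = ", ")))
  }
  invisible(x)
}

# Delta-Q of moving node v (degree kv) with e_va edges into its current
# module (excluding itself) and e_vb into a candidate module, standard form.
move_gain <- function(e_vb, e_va, kv, d_b, d_a, l) {
  (e_vb - e_va) / l - kv * (d_b - d_a + kv) / (2 * l^2)
}

#' Detect modules by greedy modularity maximization
#'
#' Greedy agglomeration (repeatedly merging the connected module pair with
#' the largest positive modularity gain) followed by Kernighan-Lin-style
#' single-node refinement sweeps, restarted `restarts` times from seeded
#' random sweep orders; the best-Q partition over restarts is returned. The
#' result is deterministic for a fixed `(seed, restarts)` pair; ties are
#' broken by input node order, then module id order.
#'
#' @param adj an adjacency matrix with at least one edge; a warning is issued
#'   for disconnected graphs (detection still runs; disconnected components
#'   can never be merged profitably).
#' @param seed integer seed for restart sweep orders.
#' @param restarts number of seeded restarts, `>= 1`.
#' @return An object of class `"acupoint_partition"`: list with `assignment`
#'   (named module ids, canonically numbered by first appearance), `q`,
#'   `module_count`, `method`.
#' @export
detect_modules <- function(adj, seed = 1L, restarts = 10L) {
  stopifnot(is.matrix(adj), restarts >= 1L)
  p <- nrow(adj)
  l <- sum(adj) / 2
  if (l < 1) stop("module detection is undefined for a graph with no edges")
  if (!is_fully_connected(adj)) {
    warning("graph is not fully connected; modules will align with components")
  }
  deg <- rowSums(adj)
  best <- NULL
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  for (run in seq_len(restarts)) {
    set.seed(as.integer(seed) + run - 1L)
    # first run starts from singletons (pure agglomeration); later runs
    # start from random coarse partitions for basin diversity
    asgn <- if (run == 1L) {
      seq_len(p)
    } else {
      sample.int(sample(2:p, 1L), p, replace = TRUE)
    }
    q <- -Inf
    repeat {                         # alternate merging and node sweeps
      asgn <- greedy_agglomerate(adj, deg, l, asgn)
      asgn <- kl_refine(adj, deg, l, asgn, order = sample.int(p))
      q_new <- modularity_q(adj, asgn)
      if (q_new <= q + 1e-12) break
      q <- q_new
    }
    if (is.null(best) || q > best$q + 1e-12) {
      best <- list(assignment = asgn, q = q)
    }
  }
  new_partition(adj, best$assignment, method = sprintf(
    "greedy agglomeration + KL refinement, %d restart%s, seed %d",
    restarts, if (restarts > 1L) "s" else "", as.integer(seed)))
}

# merge modules while any merge improves Q; deterministic given initial state
greedy_agglomerate <- function(adj, deg, l, asgn = seq_len(nrow(adj))) {
  repeat {
    mods <- unique(asgn)
    d_c <- vapply(mods, function(c) sum(deg[asgn == c]), numeric(1))
    # inter-module edge counts
    best_gain <- 1e-12; best_pair <- NULL
    for (i in seq_along(mods)) {
      for (j in seq_along(mods)) {
        if (j <= i) next
        a <- mods[i]; b <- mods[j]
        e_ab <- sum(adj[asgn == a, asgn == b, drop = FALSE])
        if (e_ab == 0) next
        gain <- e_ab / l - d_c[i] * d_c[j] / (2 * l^2)
        if (gain > best_gain) { best_gain <- gain; best_pair <- c(a, b) }
      }
    }
    if (is.null(best_pair)) break
    asgn[asgn == best_pair[2L]] <- best_pair[1L]
  }
  asgn
}

# Kernighan-Lin refinement: rounds of tentative single-node moves. Within a
# round each node moves at most once; at every step the globally best move
# (over all unmoved nodes and all target modules, including a fresh
# singleton) is applied even when its gain is negative, and at the end the
# round is rolled back to its best prefix. Rounds repeat while they improve
# Q. Ties break by node position in `order`, then module id.
kl_refine <- function(adj, deg, l, asgn, order = seq_len(nrow(adj)),
                      max_rounds = 30L) {
  p <- nrow(adj)
  best_move_for <- function(v, asgn) {
    a <- asgn[v]
    members_a <- asgn == a
    e_va <- sum(adj[v, members_a])  # v's self column is 0
    d_a <- sum(deg[members_a])
    cand <- setdiff(sort(unique(asgn)), a)
    if (sum(members_a) > 1L) cand <- c(cand, max(asgn) + 1L)
    if (!length(cand)) return(NULL)
    gains <- vapply(cand, function(b) {
      members_b <- asgn == b
      move_gain(sum(adj[v, members_b]), e_va, deg[v],
                sum(deg[members_b]), d_a, l)
    }, numeric(1))
    k <- which.max(gains)
    list(gain = gains[k], to = cand[k])
  }
  for (round in seq_len(max_rounds)) {
    base <- asgn
    moved <- logical(p)
    trail <- vector("list", p)
    cum <- 0
    best_cum <- 0
    best_step <- 0L
    for (step in seq_len(p)) {
      pick <- NULL
      for (v in order) {
        if (moved[v]) next
        mv <- best_move_for(v, asgn)
        if (!is.null(mv) && (is.null(pick) || mv$gain > pick$gain + 1e-12)) {
          pick <- list(v = v, to = mv$to, gain = mv$gain)
        }
      }
      if (is.null(pick)) break
      asgn[pick$v] <- pick$to
      moved[pick$v] <- TRUE
      trail[[step]] <- pick
      cum <- cum + pick$gain
      if (cum > best_cum + 1e-12) {
        best_cum <- cum
        best_step <- step
      }
    }
    if (best_cum > 1e-12) {
      # roll back to the best prefix of the round
      asgn <- base
      for (step in seq_len(best_step)) asgn[trail[[step]]$v] <- trail[[step]]$to
    } else {
      asgn <- base
      break
    }
  }
  asgn
}

#' Exhaustive modularity-optimal partition
#'
#' Enumerates every set partition of the nodes (in restricted-growth-string
#' order) and returns the modularity-maximal one; ties go to the
#' lexicographically smallest assignment. Serves as the exact oracle for
#' [detect_modules()] on small graphs; refuses graphs with more than 12
#' nodes (Bell(12) is about 4.2 million partitions).
#'
#' @param adj an adjacency matrix, at most 12 nodes, at least one edge.
#' @return An `"acupoint_partition"` object.
#' @export
exact_best_partition <- function(adj) {
  stopifnot(is.matrix(adj))
  p <- nrow(adj)
  if (p > 12L) stop("exhaustive search is limited to 12 nodes")
  l <- sum(adj) / 2
  if (l < 1) stop("modularity is undefined for a graph with no edges")
  deg <- rowSums(adj)
  best_q <- -Inf
  best_asgn <- NULL
  asgn <- integer(p)
  ec <- numeric(p)
  dc <- numeric(p)
  rec <- function(v, nmod) {
    if (v > p) {
      keep <- seq_len(nmod)
      q <- sum(ec[keep] / l - (dc[keep] / (2 * l))^2)
      if (q > best_q + 1e-12) {
        best_q <<- q
        best_asgn <<- asgn[]
      }
      return(invisible())
    }
    nbr <- adj[seq_len(v - 1L), v]
    prev <- asgn[seq_len(v - 1L)]
    for (c in seq_len(nmod + 1L)) {
      inc <- sum(nbr[prev == c])
      asgn[v] <<- c
      ec[c] <<- ec[c] + inc
      dc[c] <<- dc[c] + deg[v]
      rec(v + 1L, max(nmod, c))
      ec[c] <<- ec[c] - inc
      dc[c] <<- dc[c] - deg[v]
    }
  }
  asgn[1L] <- 1L
  dc[1L] <- deg[1L]
  if (p == 1L) best_asgn <- 1L else rec(2L, 1L)
  new_partition(adj, best_asgn, method = "exhaustive search")
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same nodes; 1 for
#' identical partitions (up to relabeling), about 0 for independent ones.
#'
#' @param a,b equal-length label vectors.
#' @return The ARI value.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(tab)
  exp_idx <- sum_comb(rowSums(tab)) * sum_comb(colSums(tab)) / choose(n, 2)
  max_idx <- (sum_comb(rowSums(tab)) + sum_comb(colSums(tab))) / 2
  if (max_idx == exp_idx) return(1)
  (idx - exp_idx) / (max_idx - exp_idx)
}

#' Serialize centralities and module assignment
#'
#' Writes a CSV with columns `acupoint`, `degree`, `betweenness_raw`,
#' `betweenness_norm`, `module`.
#'
#' @param adj an adjacency matrix.
#' @param partition an `"acupoint_partition"` for the same nodes.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_centrality <- function(adj, partition, path) {
  tab <- centrality_table(adj)
  tab$module <- partition$assignment[match(tab$acupoint, names(partition$assignment))]
  utils::write.table(tab, path, sep = ",", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
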