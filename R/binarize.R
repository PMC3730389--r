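#' Binarize an MI matrix at a threshold
#'
#' An edge is drawn between two acupoints iff their MI value strictly exceeds
#' the threshold `r` ("exceeding" semantics). The result is a binary,
#' symmetric, zero-diagonal adjacency matrix.
#'
#' @param mi an [mi_matrix()] (any symmetric numeric matrix with labels works).
#' @param r finite threshold.
#' @return An integer matrix of class `"adjacency_matrix"`.
#' @export
binarize <- function(mi, r) {
  stopifnot(is.matrix(mi), is.finite(r), length(r) == 1L)
  adj <- (unclass(mi) > r) * 1L
  diag(adj) <- 0L
  storage.mode(adj) <- "integer"
  class(adj) <- c("adjacency_matrix", class(adj))
  adj
}

#' Edge density of a binary network
#'
#' The number of realized undirected edges divided by the number of possible
#' pairs `p(p-1)/2`.
#'
#' @param adj an adjacency matrix (binary, symmetric, zero diagonal).
#' @return A fraction in `[0, 1]`.
#' @export
edge_density <- function(adj) {
  p <- nrow(adj)
  if (p < 2L) stop("edge density needs at least 2 nodes")
  sum(adj) / (p * (p - 1))
}

#' Is a binary network fully connected?
#'
#' "Fully connected" means a single connected component (every node reachable
#' from every other), not a complete graph. Checked by breadth-first search
#' from the first node.
#'
#' @param adj an adjacency matrix.
#' @return `TRUE` iff the graph has one connected component.
#' @export
is_fully_connected <- function(adj) {
  p <- nrow(adj)
  if (p == 1L) return(TRUE)
  seen <- logical(p)
  seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE] > 0) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Default binarization threshold grid
#'
#' Thresholds from 0.001 to 0.999 in 0.001 increments, carried exactly at
#' 3-decimal precision (built from scaled integers to avoid floating-point
#' drift).
#'
#' @return A numeric vector of length 999.
#' @export
default_grid <- function() seq_len(999L) / 1000

#' Scan binarization thresholds
#'
#' Evaluates [binarize()] at every grid threshold, recording edge count, edge
#' density, and full connectivity, and reports the largest grid threshold
#' whose network is still fully connected. Connectivity is monotone: raising
#' the threshold only removes edges, so once the network fragments it stays
#' fragmented; the scan exploits this but the per-threshold records are
#' identical to evaluating each threshold directly.
#'
#' @param mi an [mi_matrix()].
#' @param grid strictly increasing, non-empty threshold vector; defaults to
#'   [default_grid()].
#' @return An object of class `"threshold_scan"`: list with `table` (data
#'   frame of `r`, `edge_count`, `edge_density`, `fully_connected`) and
#'   `r_max_connected` (`NA` if no grid threshold keeps the network in one
#'   component).
#' @export
scan_thresholds <- function(mi, grid = default_grid()) {
  stopifnot(is.matrix(mi))
  if (length(grid) == 0L) stop("grid must be non-empty")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  p <- nrow(mi)
  vals <- sort(unclass(mi)[upper.tri(mi)])
  n_pairs <- length(vals)
  # edges at threshold r = number of off-diagonal values strictly above r
  edge_count <- n_pairs - findInterval(grid, vals)
  density <- edge_count / n_pairs
  connected_at <- function(i) is_fully_connected(binarize(mi, grid[i]))
  # binary search for the largest connected grid index
  if (!connected_at(1L)) {
    k <- 0L
  } else if (connected_at(length(grid))) {
    k <- length(grid)
  } else {
    lo <- 1L; hi <- length(grid)      # connected at lo, not at hi
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (connected_at(mid)) lo <- mid else hi <- mid
    }
    k <- lo
  }
  tab <- data.frame(r = grid,
                    edge_count = edge_count,
                    edge_density = density,
                    fully_connected = seq_along(grid) <= k)
  structure(list(table = tab,
                 r_max_connected = if (k > 0L) grid[k] else NA_real_,
                 n_nodes = p),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("Threshold scan over %d thresholds (%d nodes)\n",
              nrow(x$table), x$n_nodes))
  if (is.na(x$r_max_connected)) {
    cat("No threshold keeps the network fully connected.\n")
  } else {
    at <- x$table[match(x$r_max_connected, x$table$r), ]
    cat(sprintf("Max fully connected threshold: R = %.3f (%d edges, density %.3f)\n",
                at$r, at$edge_count, at$edge_density))
  }
  invisible(x)
}

#' Select binarized networks by edge density
#'
#' Returns the fully connected grid networks whose edge density falls within
#' `[density_lo, density_hi]`, ordered by decreasing threshold, so the first
#' element is the sparsest admissible network.
#'
#' @param mi an [mi_matrix()].
#' @param density_lo,density_hi density band bounds, `0 < lo <= hi <= 1`.
#' @param grid threshold grid; defaults to [default_grid()].
#' @return A named list of [binarize()] results (names are the thresholds).
#' @export
select_by_density <- function(mi, density_lo = 0.39, density_hi = 0.50,
                              grid = default_grid()) {
  if (!(density_lo > 0 && density_lo <= density_hi && density_hi <= 1)) {
    stop("need 0 < density_lo <= density_hi <= 1")
  }
  scan <- scan_thresholds(mi, grid)
  tab <- scan$table
  ok <- tab$fully_connected & tab$edge_density >= density_lo &
    tab$edge_density <= density_hi
  if (!any(ok)) {
    stop(sprintf("no fully connected network has edge density in [%.3g, %.3g]; try a wider band",
                 density_lo, density_hi))
  }
  rs <- rev(tab$r[ok])
  out <- lapply(rs, function(r) binarize(mi, r))
  names(out) <- formatC(rs, format = "fg")
  out
}

# pick the analysis network: density nearest target within the band,
# ties broken toward the larger threshold. connectivity = "require" keeps the
# spec'd connected-only selection; "prefer" falls back to the in-band network
# ignoring connectivity when no connected one exists (planted data with
# negative between-module MI never yields a connected thresholded graph).
select_analysis_network <- function(mi, density_band = c(0.39, 0.50),
                                    target_density = 0.40,
                                    grid = default_grid(),
                                    connectivity = c("require", "prefer")) {
  connectivity <- match.arg(connectivity)
  scan <- scan_thresholds(mi, grid)
  tab <- scan$table
  in_band <- tab$edge_density >= density_band[1L] &
    tab$edge_density <= density_band[2L]
  ok <- in_band & tab$fully_connected
  if (!any(ok)) {
    if (connectivity == "require" || !any(in_band)) {
      stop(sprintf("no %snetwork has edge density in [%.3g, %.3g]; try a wider band",
                   if (connectivity == "require") "fully connected " else "",
                   density_band[1L], density_band[2L]))
    }
    warning("no fully connected network in the density band; using the nearest in-band network regardless of connectivity")
    ok <- in_band
  }
  cand <- tab[ok, , drop = FALSE]
  dist <- abs(cand$edge_density - target_density)
  pick <- cand[order(dist, -cand$r), , drop = FALSE][1L, ]
  list(adjacency = binarize(mi, pick$r),
       r = pick$r,
       edge_count = pick$edge_count,
       edge_density = pick$edge_density,
       fully_connected = pick$fully_connected,
       scan = scan)
}

#' Serialize a binary network
#'
#' `write_adjacency()` writes the labeled 0/1 matrix as CSV;
#' `write_edge_list()` writes one undirected edge per line as 2-column TSV;
#' `write_scan_log()` writes a threshold-scan table as CSV.
#'
#' @param adj an adjacency matrix.
#' @param scan a [scan_thresholds()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(adj, path) {
  df <- data.frame(acupoint = rownames(adj), unclass(adj), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' @rdname write_adjacency
#' @export
write_edge_list <- function(adj, path) {
  idx <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  df <- data.frame(acupoint_a = rownames(adj)[idx[, 1L]],
                   acupoint_b = colnames(adj)[idx[, 2L]])
  df <- df[order(df$acupoint_a, df$acupoint_b), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' @rdname write_adjacency
#' @export
write_scan_log <- function(scan, path) {
  stopifnot(inherits(scan, "threshold_scan"))
  utils::write.table(scan$table, path, sep = ",", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
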