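#' Fit an acupoint co-occurrence network model
#'
#' Runs the full analysis on a study-by-acupoint incidence dataset:
#' frequency filtering, pairwise pointwise-MI scoring ([mi_matrix()]),
#' threshold-scan binarization under connectivity and edge-density
#' constraints ([scan_thresholds()]), centrality analysis
#' ([centrality_table()]), and modularity-based module detection
#' ([detect_modules()]).
#'
#' The analysis network is the grid threshold whose edge density is nearest
#' `target_density` among fully connected networks inside `density_band`
#' (ties toward the larger threshold). With `connectivity = "prefer"` the
#' connectivity requirement is waived (with a warning) when no connected
#' in-band network exists — the appropriate setting for planted synthetic
#' data, where between-module pairs co-occur below independence and so never
#' form edges at any positive threshold.
#'
#' @param data a [prescription_dataset()], or a path to an incidence CSV.
#' @param min_freq usage-frequency filter; acupoints used in at most this
#'   fraction of studies are dropped (strict `>` retention). Default 0.05.
#' @param grid binarization threshold grid; defaults to [default_grid()].
#' @param density_band admissible edge-density interval for the analysis
#'   network; default `c(0.39, 0.50)`.
#' @param target_density preferred edge density within the band; default 0.40.
#' @param connectivity `"require"` (default) or `"prefer"`; see Details.
#' @param seed,restarts passed to [detect_modules()].
#' @param mi_cut MI threshold for the reported high-MI pair table; default 0.17.
#' @param local_set acupoint labels regarded as local to the symptomatic
#'   region, used to tag high-MI pairs L/D; defaults to
#'   [lbp_local_acupoints()].
#' @return An object of class `"acunet"`; see [summary.acunet()],
#'   [plot.acunet()], [simulate.acunet()], [report_bundle()].
#' @examples
#' fit <- acunet(lbp_fixture(), seed = 1)
#' fit
#' head(fit$pair_table)
#' @export
acunet <- function(data, min_freq = 0.05, grid = default_grid(),
                   density_band = c(0.39, 0.50), target_density = 0.40,
                   connectivity = c("require", "prefer"),
                   seed = 1L, restarts = 10L, mi_cut = 0.17,
                   local_set = lbp_local_acupoints()) {
  connectivity <- match.arg(connectivity)
  if (is.character(data)) data <- read_incidence(data)
  stopifnot(inherits(data, "prescription_dataset"))
  ds <- filter_by_frequency(data, min_freq)
  usage <- usage_stats(ds)
  mi <- mi_matrix(ds)
  sel <- select_analysis_network(mi, density_band, target_density, grid,
                                 connectivity)
  adj <- sel$adjacency
  cent <- centrality_table(adj)
  part <- if (sel$fully_connected) {
    detect_modules(adj, seed = seed, restarts = restarts)
  } else {
    suppressWarnings(detect_modules(adj, seed = seed, restarts = restarts))
  }
  pair_table <- mi_pair_table(mi)
  pair_table <- pair_table[pair_table$mi > mi_cut, , drop = FALSE]
  pair_table <- tag_pairs(pair_table, local_set)
  structure(list(data = ds,
                 usage = usage,
                 mi = mi,
                 scan = sel$scan,
                 network = adj,
                 r = sel$r,
                 edge_density = sel$edge_density,
                 fully_connected = sel$fully_connected,
                 centrality = cent,
                 partition = part,
                 pair_table = pair_table,
                 call = match.call(),
                 config = list(min_freq = min_freq,
                               density_band = density_band,
                               target_density = target_density,
                               connectivity = connectivity,
                               seed = as.integer(seed),
                               restarts = as.integer(restarts),
                               mi_cut = mi_cut,
                               local_set = local_set)),
            class = "acunet")
}

#' Tag high-MI pairs as local or distant
#'
#' A pair is tagged `"L"` iff both members belong to `local_set` (acupoints
#' near the symptomatic region); otherwise `"D"` (at least one distant
#' acupoint).
#'
#' @param pairs data frame with columns `acupoint_a`, `acupoint_b`.
#' @param local_set character vector of local acupoint labels.
#' @return `pairs` with a `tag` column.
#' @export
tag_pairs <- function(pairs, local_set = lbp_local_acupoints()) {
  stopifnot(is.data.frame(pairs),
            all(c("acupoint_a", "acupoint_b") %in% names(pairs)))
  pairs$tag <- ifelse(pairs$acupoint_a %in% local_set &
                        pairs$acupoint_b %in% local_set, "L", "D")
  pairs
}

#' @export
print.acunet <- function(x, ...) {
  cat("Acupoint co-occurrence network\n")
  cat(sprintf("  %d studies, %d acupoints retained (min_freq = %g)\n",
              nrow(x$data$incidence), ncol(x$data$incidence),
              x$config$min_freq))
  cat(sprintf("  analysis network: R = %.3f, %d edges, density %.3f%s\n",
              x$r, sum(x$network) / 2, x$edge_density,
              if (x$fully_connected) ", fully connected" else " (not connected)"))
  cat(sprintf("  modules: %d (Q = %.4f)\n",
              x$partition$module_count, x$partition$q))
  invisible(x)
}

#' Summarize a fitted acupoint network
#'
#' @param object an [acunet()] fit.
#' @param ... unused.
#' @return An object of class `"summary.acunet"` holding the usage/centrality
#'   table (ranked by usage frequency), the tagged high-MI pair table, the
#'   module assignment, and the selected-network facts.
#' @export
summary.acunet <- function(object, ...) {
  tab <- merge(object$usage, object$centrality, by = "acupoint", sort = FALSE)
  tab$module <- object$partition$assignment[
    match(tab$acupoint, names(object$partition$assignment))]
  tab <- tab[order(-tab$frequency, tab$acupoint), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(usage_table = tab[, c("rank", "acupoint", "percent", "degree",
                                       "betweenness_norm", "module")],
                 pair_table = object$pair_table,
                 partition = object$partition,
                 r = object$r,
                 edge_density = object$edge_density,
                 r_max_connected = object$scan$r_max_connected,
                 fully_connected = object$fully_connected),
            class = "summary.acunet")
}

#' @export
print.summary.acunet <- function(x, ...) {
  cat(sprintf("Analysis network: R = %.3f (max connected R = %s), edge density %.3f\n",
              x$r,
              if (is.na(x$r_max_connected)) "none"
              else sprintf("%.3f", x$r_max_connected),
              x$edge_density))
  print(x$partition)
  cat(sprintf("\nHigh-MI pairs (%d):\n", nrow(x$pair_table)))
  pt <- x$pair_table
  pt$mi <- formatC(pt$mi, digits = 4, format = "f")
  print(pt, row.names = FALSE)
  cat("\nUsage, degree and betweenness by acupoint:\n")
  ut <- x$usage_table
  ut$betweenness_norm <- formatC(ut$betweenness_norm, digits = 5, format = "f")
  print(ut, row.names = FALSE)
  invisible(x)
}

#' Plot a fitted acupoint network
#'
#' Draws the analysis network with nodes colored by detected module and
#' sized by degree (`which = "network"`), or an image of the MI matrix
#' (`which = "mi"`).
#'
#' @param x an [acunet()] fit.
#' @param which `"network"` or `"mi"`.
#' @param ... passed on to [igraph::plot.igraph()] or [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.acunet <- function(x, which = c("network", "mi"), ...) {
  which <- match.arg(which)
  if (which == "mi") {
    graphics::image(unclass(x$mi), axes = FALSE, main = "MI matrix", ...)
    return(invisible(x))
  }
  g <- igraph::graph_from_adjacency_matrix(unclass(x$network),
                                           mode = "undirected")
  igraph::V(g)$color <- x$partition$assignment
  igraph::plot.igraph(g, vertex.size = 5 + degree_centrality(x$network),
                      vertex.label.cex = 0.7, ...)
  invisible(x)
}

#' Simulate incidence datasets from a fitted network model
#'
#' Parameterizes a planted prescription-module model from the fit — groups
#' are the detected modules, `p_within` is the mean within-module usage rate
#' among studies assigned to that module's dominant prescriptions, and
#' `p_background` the mean off-module rate — and draws `nsim` new incidence
#' datasets of the same size.
#'
#' @param object an [acunet()] fit.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of [prescription_dataset()] objects.
#' @export
simulate.acunet <- function(object, nsim = 1, seed = 1L, ...) {
  asgn <- object$partition$assignment
  groups <- split(names(asgn), asgn)
  names(groups) <- LETTERS[seq_along(groups)]
  inc <- object$data$incidence
  # dominant module per study: the module with the highest usage rate
  rates <- sapply(groups, function(g) {
    rowSums(inc[, g, drop = FALSE]) / length(g)
  })
  study_mod <- max.col(rates, ties.method = "first")
  within <- mean(vapply(seq_len(nrow(inc)), function(i) {
    rates[i, study_mod[i]]
  }, numeric(1)))
  background <- mean(vapply(seq_len(nrow(inc)), function(i) {
    mean(rates[i, -study_mod[i]])
  }, numeric(1)))
  mixing <- as.numeric(table(factor(study_mod, levels = seq_along(groups))))
  lapply(seq_len(nsim), function(k) {
    generate_planted(planted_model(nrow(inc), groups,
                                   p_within = within,
                                   p_background = min(background, within),
                                   mixing = mixing,
                                   seed = as.integer(seed) + k - 1L))
  })
}

#' Export a binary network as GraphML
#'
#' Writes well-formed GraphML (via igraph) with undirected edges and node
#' attributes `degree`, `betweenness`, and `module`, readable by Cytoscape
#' and similar tools.
#'
#' @param adj an adjacency matrix.
#' @param node_attrs optional data frame with column `acupoint` plus
#'   attribute columns (e.g. from [centrality_table()]); a `module` column or
#'   an `"acupoint_partition"` may be supplied via `partition`.
#' @param partition optional `"acupoint_partition"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(adj, path, node_attrs = NULL, partition = NULL) {
  g <- igraph::graph_from_adjacency_matrix(unclass(adj), mode = "undirected")
  if (!is.null(node_attrs)) {
    stopifnot("acupoint" %in% names(node_attrs))
    idx <- match(igraph::V(g)$name, node_attrs$acupoint)
    for (col in setdiff(names(node_attrs), "acupoint")) {
      g <- igraph::set_vertex_attr(g, col, value = node_attrs[[col]][idx])
    }
  }
  if (!is.null(partition)) {
    idx <- match(igraph::V(g)$name, names(partition$assignment))
    g <- igraph::set_vertex_attr(g, "module",
                                 value = as.integer(partition$assignment[idx]))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write the full report bundle of a fitted network
#'
#' Writes, under `dir`: the ranked usage/centrality table
#' (`usage_table.csv`), the tagged high-MI pair table (`pair_table.csv`),
#' the threshold-scan log (`scan_log.csv`), the MI matrix and its long form,
#' the analysis network (matrix, edge list, GraphML), the module assignment
#' with centralities (`partition.csv`), and a JSON run manifest recording
#' seed, selected threshold, density, package version, and file checksums.
#' Byte-identical across runs for a fixed fit.
#'
#' @param fit an [acunet()] fit.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
report_bundle <- function(fit, dir) {
  stopifnot(inherits(fit, "acunet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(dir, f)
  s <- summary(fit)

  ut <- s$usage_table
  ut$percent <- formatC(ut$percent, digits = 1L, format = "f")
  ut$betweenness_norm <- formatC(ut$betweenness_norm, digits = 5L, format = "f")
  utils::write.table(ut, pth("usage_table.csv"), sep = ",", quote = FALSE,
                     row.names = FALSE, eol = "\n")

  pt <- s$pair_table
  pt$mi <- formatC(pt$mi, digits = 4L, format = "f")
  utils::write.table(pt, pth("pair_table.csv"), sep = ",", quote = FALSE,
                     row.names = FALSE, eol = "\n")

  write_scan_log(fit$scan, pth("scan_log.csv"))
  write_mi_matrix(fit$mi, pth("mi_matrix.csv"))
  write_mi_pairs(fit$mi, pth("mi_pairs.tsv"))
  write_adjacency(fit$network, pth("adjacency.csv"))
  write_edge_list(fit$network, pth("edge_list.tsv"))
  write_centrality(fit$network, fit$partition, pth("partition.csv"))
  export_graphml(fit$network, pth("network.graphml"),
                 node_attrs = fit$centrality, partition = fit$partition)

  files <- c("usage_table.csv", "pair_table.csv", "scan_log.csv",
             "mi_matrix.csv", "mi_pairs.tsv", "adjacency.csv",
             "edge_list.tsv", "partition.csv", "network.graphml")
  manifest <- list(
    package = "acunet",
    version = as.character(utils::packageVersion("acunet")),
    seed = fit$config$seed,
    restarts = fit$config$restarts,
    min_freq = fit$config$min_freq,
    density_band = fit$config$density_band,
    target_density = fit$config$target_density,
    r_selected = fit$r,
    edge_density = fit$edge_density,
    fully_connected = fit$fully_connected,
    modularity_q = fit$partition$q,
    module_count = fit$partition$module_count,
    checksums = as.list(tools::md5sum(vapply(files, pth, character(1))) |>
                          stats::setNames(files)))
  writeLines(to_json(manifest), pth("manifest.json"))
  invisible(manifest)
}

# minimal JSON writer for the manifest (scalars, vectors, named lists)
to_json <- function(x) {
  if (is.list(x)) {
    if (is.null(names(x))) {
      paste0("[", paste(vapply(x, to_json, character(1)), collapse = ","), "]")
    } else {
      paste0("{", paste(sprintf('"%s":%s', names(x),
                                vapply(x, to_json, character(1))),
                        collapse = ","), "}")
    }
  } else if (length(x) != 1L) {
    paste0("[", paste(vapply(x, to_json, character(1)), collapse = ","), "]")
  } else if (is.character(x)) {
    sprintf('"%s"', gsub('"', '\\\\"', x))
  } else if (is.logical(x)) {
    if (x) "true" else "false"
  } else {
    format(x, digits = 15, scientific = FALSE, trim = TRUE)
  }
}
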