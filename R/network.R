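#' Build a significance-filtered co-expression network
#'
#' Creates an undirected simple graph over the genes of a correlation matrix:
#' a pair becomes an edge iff its q-value is below `fdr_max` and its
#' correlation passes `rho_min` — by default on the absolute value
#' (`|rho| >= rho_min`); with `use_abs = FALSE` only positive correlations
#' `rho >= rho_min` qualify. Genes without qualifying partners are retained as
#' isolated nodes. Edges carry `rho`, `p`, `q` attributes; the thresholds are
#' recorded as graph attributes.
#'
#' @param corr a `corr_matrix` from [correlation_matrix()].
#' @param fdr_max FDR cutoff (strict `<`).
#' @param rho_min correlation magnitude cutoff (`>=`).
#' @param use_abs threshold on `|rho|` (default) or on signed `rho`.
#' @return An `igraph` graph.
#' @export
build_network <- function(corr, fdr_max = 0.001, rho_min = 0.8, use_abs = TRUE) {
  stopifnot(inherits(corr, "corr_matrix"))
  if (fdr_max <= 0 || rho_min <= 0) stop("thresholds must be positive")
  ut <- which(upper.tri(corr$rho), arr.ind = TRUE)
  rho <- corr$rho[ut]
  mag <- if (use_abs) abs(rho) else rho
  keep <- corr$q[ut] < fdr_max & mag >= rho_min
  edges <- data.frame(
    from = corr$genes[ut[keep, 1]],
    to = corr$genes[ut[keep, 2]],
    rho = rho[keep],
    p = corr$p[ut][keep],
    q = corr$q[ut][keep],
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = corr$genes, stringsAsFactors = FALSE)
  )
  g <- igraph::set_graph_attr(g, "fdr_max", fdr_max)
  g <- igraph::set_graph_attr(g, "rho_min", rho_min)
  g <- igraph::set_graph_attr(g, "use_abs", use_abs)
  g
}

# Tolerant topology summary used by both network_summary() and
# removal_report(); copes with n < 2 and edgeless graphs.
cohesion_stats <- function(net) {
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  comp <- if (n > 0) igraph::components(net) else list(no = 0L, csize = integer(0))
  largest <- if (n > 0) max(comp$csize) else 0L
  if (m > 0) {
    diam <- igraph::diameter(net, weights = NA, unconnected = TRUE)
    meang <- igraph::mean_distance(net, weights = NA, unconnected = TRUE)
  } else {
    diam <- 0; meang <- 0  # geodesics undefined without edges: reported as 0
  }
  reachable <- sum(choose(comp$csize, 2))
  total <- choose(n, 2)
  list(
    n_nodes = n, n_edges = m,
    density = if (n >= 2) density_from_counts(n, m) else NA_real_,
    n_components = comp$no,
    largest_component = largest,
    diameter = diam,
    mean_geodesic = if (is.finite(meang)) meang else 0,
    unreachable_fraction = if (total > 0) 1 - reachable / total else 0
  )
}

#' Topology summary of a gene network
#'
#' Node/edge counts, edge density `2m/(n(n-1))`, a degree histogram with
#' explicit integer bin edges, connected components, the diameter of the
#' graph's components (unweighted geodesics), and the mean geodesic over
#' reachable pairs (0 when no edges exist); unreachable pairs are reported as
#' a separate fraction rather than folded into the mean.
#'
#' @param net an `igraph` network with at least 2 nodes.
#' @return A list of class `network_summary`.
#' @export
network_summary <- function(net) {
  if (igraph::vcount(net) < 2) stop("summary needs at least 2 nodes")
  s <- cohesion_stats(net)
  deg <- igraph::degree(net)
  maxd <- max(deg)
  s$degree_histogram <- list(
    breaks = 0:(maxd + 1),                       # bin i counts degree i-1
    counts = tabulate(deg + 1, nbins = maxd + 1)
  )
  stopifnot(sum(s$degree_histogram$counts) == s$n_nodes)
  structure(s, class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(paste0("<network_summary: %d nodes, %d edges, density %.4g, ",
                     "%d component(s), diameter %g, mean geodesic %.4g>\n"),
              x$n_nodes, x$n_edges, x$density, x$n_components,
              x$diameter, x$mean_geodesic))
  invisible(x)
}

#' Write a network as an edge-list TSV
#'
#' Columns `gene_a`, `gene_b`, `rho`, `p`, `q`.
#' @param net an `igraph` network with `rho`, `p`, `q` edge attributes.
#' @param path output file.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  df <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                   rho = igraph::E(net)$rho, p = igraph::E(net)$p,
                   q = igraph::E(net)$q, stringsAsFactors = FALSE)
  write_atomic(path, function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

#' Write a network as GraphML
#'
#' @param net an `igraph` network.
#' @param path output file.
#' @export
write_graphml <- function(net, path) {
  write_atomic(path, function(tmp) {
    igraph::write_graph(net, tmp, format = "graphml")
  })
}
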