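#' Build control and stimulus networks on a matched gene set
#'
#' Constructs two co-expression networks over the *same* node set — one from
#' control samples, one from treated samples — with identical thresholds, so
#' their topologies are directly comparable. Genes whose expression is
#' constant in one condition (and therefore dropped from that correlation
#' matrix) are retained as isolated nodes to keep the node sets identical.
#'
#' @param genes gene set (or character vector) present in both matrices.
#' @param expr_control,expr_treat expression matrices (genes x samples).
#' @param fdr_max,rho_min,use_abs thresholds passed to [build_network()].
#' @return List with `control` and `treat` `igraph` networks on the same nodes.
#' @export
matched_networks <- function(genes, expr_control, expr_treat,
                             fdr_max = 0.001, rho_min = 0.8, use_abs = TRUE) {
  ids <- as_gene_ids(genes)
  for (nm in c("control", "treat")) {
    mat <- if (nm == "control") expr_control else expr_treat
    missing <- setdiff(ids, rownames(mat))
    if (length(missing) > 0) {
      stop(sprintf("genes absent from the %s matrix: %s", nm,
                   paste(utils::head(missing, 5), collapse = ", ")))
    }
  }
  one <- function(expr) {
    corr <- withCallingHandlers(
      correlation_matrix(expr, genes = ids),
      warning = function(w) {
        # constant genes are re-added as isolated nodes below
        invokeRestart("muffleWarning")
      })
    g <- build_network(corr, fdr_max = fdr_max, rho_min = rho_min,
                       use_abs = use_abs)
    absent <- setdiff(ids, igraph::V(g)$name)
    if (length(absent) > 0) g <- igraph::add_vertices(g, length(absent), name = absent)
    igraph::permute(g, match(igraph::V(g)$name, ids))
  }
  list(control = one(expr_control), treat = one(expr_treat))
}

#' Compare the topology of two networks on the same node set
#'
#' Side-by-side summaries for a differential network analysis: node/edge
#' counts and densities, the edge-set Jaccard index, degree histograms on
#' shared bins (computed from the pooled degree range), the empirical CDF of
#' edge weights `|rho|` sampled on a fixed 0.01-step grid, a two-sample
#' Kolmogorov-Smirnov distance between the edge-weight distributions, and the
#' minimum retained `|rho|` per network.
#'
#' @param a,b `igraph` networks over identical node sets.
#' @param labels length-2 character vector naming the two networks.
#' @return A list of class `network_comparison`.
#' @export
compare_networks <- function(a, b, labels = c("a", "b")) {
  na <- igraph::V(a)$name; nb <- igraph::V(b)$name
  if (!setequal(na, nb)) stop("networks must share the same node set")

  edge_keys <- function(g) {
    el <- igraph::as_edgelist(g)
    if (nrow(el) == 0) return(character(0))
    apply(cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])), 1,
          paste, collapse = "|")
  }
  ka <- edge_keys(a); kb <- edge_keys(b)
  uni <- union(ka, kb)
  jaccard <- if (length(uni) == 0) 1 else length(intersect(ka, kb)) / length(uni)

  deg_a <- igraph::degree(a); deg_b <- igraph::degree(b)
  maxd <- max(deg_a, deg_b)
  breaks <- 0:(maxd + 1)
  hist_a <- tabulate(deg_a + 1, nbins = maxd + 1)
  hist_b <- tabulate(deg_b + 1, nbins = maxd + 1)

  wa <- abs(igraph::E(a)$rho); wb <- abs(igraph::E(b)$rho)
  lo <- min(c(igraph::graph_attr(a, "rho_min"), igraph::graph_attr(b, "rho_min"),
              wa, wb, 0.8))
  grid <- seq(floor(lo * 100) / 100, 1, by = 0.01)
  cdf_at <- function(w) {
    if (length(w) == 0) return(rep(NA_real_, length(grid)))
    vapply(grid, function(g) mean(w <= g), numeric(1))
  }
  ks <- if (length(wa) > 0 && length(wb) > 0) {
    pooled <- sort(unique(c(wa, wb)))
    max(abs(vapply(pooled, function(v) mean(wa <= v) - mean(wb <= v), numeric(1))))
  } else NA_real_

  per_net <- function(g, w, lab) {
    list(label = lab, n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
         density = density_from_counts(igraph::vcount(g), igraph::ecount(g)),
         min_abs_rho = if (length(w) > 0) min(w) else NA_real_)
  }
  structure(list(
    networks = list(per_net(a, wa, labels[1]), per_net(b, wb, labels[2])),
    shared_nodes = length(intersect(na, nb)),
    edge_jaccard = jaccard,
    degree_breaks = breaks,
    degree_counts = list(hist_a, hist_b),
    weight_grid = grid,
    weight_cdf = list(cdf_at(wa), cdf_at(wb)),
    ks_statistic = ks
  ), class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  a <- x$networks[[1]]; b <- x$networks[[2]]
  cat(sprintf(paste0("<network_comparison: %s (%d edges, density %.4g) vs ",
                     "%s (%d edges, density %.4g); Jaccard %.3f, KS %.3f>\n"),
              a$label, a$n_edges, a$density, b$label, b$n_edges, b$density,
              x$edge_jaccard, x$ks_statistic))
  invisible(x)
}
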