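#' Node centralities: degree, closeness, authority
#'
#' The three metrics entering the composite hub score:
#'
#' * **degree** — raw edge count (unnormalized; normalization cancels in
#'   within-network ranking);
#' * **closeness** — `(|C_v| - 1) / sum_{u in C_v} d(v, u)` computed within
#'   the node's connected component (0 for isolated nodes), so disconnected
#'   graphs stay well defined;
#' * **authority** — the HITS authority score, which on an undirected graph is
#'   the principal (Perron) eigenvector of the adjacency matrix, computed by
#'   power iteration from a uniform positive start on `A + 0.5 I` (the shift
#'   guards against oscillation on bipartite components), L2-normalized each
#'   step, stopping when the sup-norm change is below 1e-10. The iteration is
#'   run within each connected component — on a disconnected graph the global
#'   power iteration need not converge when two components have near-equal
#'   spectral radii — and each component's eigenvector is scaled by its
#'   spectral radius relative to the largest, so the result coincides with
#'   the global principal eigenvector on connected graphs while remaining
#'   informative on every component. Reported with maximum 1; isolated nodes
#'   score 0.
#'
#' @param net an `igraph` network (non-empty).
#' @param tol,max_iter power-iteration stopping controls.
#' @return A data.frame `gene_id`, `degree`, `closeness`, `authority`.
#' @export
centralities <- function(net, tol = 1e-10, max_iter = 10000) {
  n <- igraph::vcount(net)
  if (n == 0) stop("empty graph")
  nodes <- igraph::V(net)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  deg <- unname(igraph::degree(net))

  closeness <- numeric(n)
  authority <- numeric(n)
  lambda <- numeric(0)
  comp <- igraph::components(net)
  vecs <- vector("list", comp$no)
  for (c_id in seq_len(comp$no)) {
    members <- which(comp$membership == c_id)
    nc <- length(members)
    if (nc < 2) { lambda[c_id] <- 0; vecs[[c_id]] <- 0; next }
    d <- igraph::distances(net, v = members, to = members, weights = NA)
    closeness[members] <- (nc - 1) / rowSums(d)

    A <- igraph::as_adjacency_matrix(
      igraph::induced_subgraph(net, members), sparse = FALSE)
    x <- rep(1 / sqrt(nc), nc)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      x_new <- as.vector(A %*% x) + 0.5 * x
      x_new <- x_new / sqrt(sum(x_new^2))
      if (max(abs(x_new - x)) < tol) { x <- x_new; converged <- TRUE; break }
      x <- x_new
    }
    if (!converged) {
      stop(sprintf("authority power iteration did not converge in %d iterations",
                   max_iter))
    }
    # Rayleigh quotient gives the component's spectral radius
    lambda[c_id] <- sum(x * as.vector(A %*% x))
    vecs[[c_id]] <- abs(x) / max(abs(x))
  }
  lam_max <- max(lambda)
  if (lam_max > 0) {
    for (c_id in seq_len(comp$no)) {
      members <- which(comp$membership == c_id)
      if (length(members) >= 2) {
        authority[members] <- vecs[[c_id]] * lambda[c_id] / lam_max
      }
    }
  }

  data.frame(gene_id = nodes, degree = deg, closeness = closeness,
             authority = authority, stringsAsFactors = FALSE)
}

#' Composite hub scores
#'
#' Score = degree x closeness x authority per node; a node scores 0 iff any
#' factor is 0 (e.g. isolated nodes). Ranks are 1..n in decreasing score
#' order; exact score ties are broken by lexicographic gene ID so the ranking
#' is deterministic.
#'
#' @param cent a centrality table from [centralities()].
#' @return The table with `score` and `rank` columns added, sorted by rank;
#'   class `hub_scores`.
#' @export
hub_scores <- function(cent) {
  stopifnot(all(c("gene_id", "degree", "closeness", "authority") %in% names(cent)))
  cent$score <- cent$degree * cent$closeness * cent$authority
  o <- order(-cent$score, cent$gene_id)
  cent <- cent[o, , drop = FALSE]
  cent$rank <- seq_len(nrow(cent))
  rownames(cent) <- NULL
  class(cent) <- c("hub_scores", "data.frame")
  cent
}

#' Select top-k hub genes per community
#'
#' For each named community, the `k` best-ranked nodes by composite score
#' (all members when the community is smaller than `k`).
#'
#' @param partition a `community_partition`.
#' @param scores a `hub_scores` table.
#' @param k hubs per community (>= 1).
#' @param communities community labels to draw from; either integer labels of
#'   the partition or a list from [large_communities()] (default: all
#'   communities).
#' @return A [gene_set()] of the selected hubs (union over communities) with
#'   attribute `provenance`: data.frame `gene_id`, `community`, `rank`.
#' @export
select_hubs <- function(partition, scores, k = 50, communities = NULL) {
  stopifnot(inherits(partition, "community_partition"))
  if (k < 1) stop("k must be >= 1")
  labels <- if (is.null(communities)) {
    sort(unique(partition$membership))
  } else if (is.list(communities)) {
    vapply(communities, function(gs) attr(gs, "community"), integer(1))
  } else {
    as.integer(communities)
  }
  unknown <- setdiff(labels, partition$membership)
  if (length(unknown) > 0) {
    stop("unknown community label(s): ", paste(unknown, collapse = ", "))
  }
  rank_of <- stats::setNames(scores$rank, scores$gene_id)
  prov <- do.call(rbind, lapply(labels, function(lab) {
    members <- names(partition$membership)[partition$membership == lab]
    members <- members[members %in% names(rank_of)]
    members <- members[order(rank_of[members])]
    top <- utils::head(members, k)
    data.frame(gene_id = top, community = lab, rank = unname(rank_of[top]),
               stringsAsFactors = FALSE)
  }))
  out <- gene_set(prov$gene_id, label = sprintf("top-%d hubs", k))
  attr(out, "provenance") <- prov
  out
}

#' Cohesion report for targeted node removal
#'
#' Quantifies how removing a node set (e.g. the selected hubs) changes
#' network cohesion: node/edge counts, density, components, diameter, and
#' mean geodesic over reachable pairs are reported before and after removal.
#' Optionally, the same number of *random* non-selected nodes is removed
#' `baseline_repeats` times to give a paired-by-count null distribution for
#' the change.
#'
#' @param net an `igraph` network.
#' @param remove gene set (or character vector) of nodes to remove; must be a
#'   subset of the network's nodes, and not all of them.
#' @param baseline_repeats number of random-removal repeats (0 = none).
#' @param seed RNG seed for the random baselines.
#' @return A list of class `cohesion_report`: `before`, `after` (see
#'   [network_summary()] fields), `removed`, and — when requested —
#'   `baseline` (data.frame of per-repeat statistics) with
#'   `baseline_mean_geodesic` (mean, sd).
#' @export
removal_report <- function(net, remove, baseline_repeats = 0, seed = NULL) {
  ids <- as_gene_ids(remove)
  nodes <- igraph::V(net)$name
  if (!all(ids %in% nodes)) {
    stop("removal set contains nodes absent from the network: ",
         paste(utils::head(setdiff(ids, nodes), 5), collapse = ", "))
  }
  if (length(ids) >= length(nodes)) stop("cannot remove all nodes")
  before <- cohesion_stats(net)
  after <- cohesion_stats(igraph::delete_vertices(net, ids))

  out <- list(before = before, after = after, removed = ids)
  if (baseline_repeats > 0) {
    pool <- setdiff(nodes, ids)
    if (length(pool) <= length(ids)) stop("not enough non-selected nodes for baselines")
    draw <- function() {
      drop <- sample(pool, length(ids))
      s <- cohesion_stats(igraph::delete_vertices(net, drop))
      data.frame(n_edges = s$n_edges, density = s$density,
                 n_components = s$n_components, diameter = s$diameter,
                 mean_geodesic = s$mean_geodesic)
    }
    base <- if (is.null(seed)) {
      do.call(rbind, replicate(baseline_repeats, draw(), simplify = FALSE))
    } else {
      with_seed(seed, do.call(rbind, replicate(baseline_repeats, draw(),
                                               simplify = FALSE)))
    }
    out$baseline <- base
    out$baseline_mean_geodesic <- c(mean = mean(base$mean_geodesic),
                                    sd = stats::sd(base$mean_geodesic))
  }
  class(out) <- "cohesion_report"
  out
}

#' @export
print.cohesion_report <- function(x, ...) {
  cat(sprintf(paste0("<cohesion_report: removed %d node(s); mean geodesic ",
                     "%.3f -> %.3f, diameter %g -> %g, components %d -> %d>\n"),
              length(x$removed), x$before$mean_geodesic, x$after$mean_geodesic,
              x$before$diameter, x$after$diameter,
              x$before$n_components, x$after$n_components))
  invisible(x)
}
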