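#' Random-walk (walktrap) agglomerative community dendrogram
#'
#' From-scratch implementation of the Pons-Latapy short-random-walk
#' agglomerative scheme. With transition matrix `P = D^-1 A`, two communities
#' are close when their `t`-step walk distributions look alike:
#' `r^2(C1, C2) = sum_k (P^t_{C1 k} - P^t_{C2 k})^2 / d(k)`. Starting from
#' singletons, the pair of *adjacent* communities whose merge minimizes the
#' Ward-style cost `delta_sigma = (1/n) |C1||C2|/(|C1|+|C2|) r^2(C1, C2)` is
#' merged repeatedly; community walk distributions are updated as
#' size-weighted averages. Disconnected components never merge (only adjacent
#' communities may), and nodes of degree 0 — for which the walk is undefined —
#' are returned as permanent singleton communities.
#'
#' The walk is unweighted by default, matching inference on a thresholded
#' graph whose retained correlations are near-uniform in magnitude;
#' `weighted = TRUE` uses `|rho|` edge weights instead.
#'
#' @param net an `igraph` network (vertex names required).
#' @param steps walk length `t` >= 1 (default 4).
#' @param weighted use `|rho|` edge weights in the walk.
#' @return A list of class `walktrap_tree`: `merges` (data.frame `step`, `a`,
#'   `b`, `new`, `dsigma`, `q` — modularity of the partition after the merge),
#'   `n_nodes`, `node_names`, `q_singletons`, `n_components`.
#' @export
walktrap_dendrogram <- function(net, steps = 4, weighted = FALSE) {
  if (steps < 1) stop("steps must be >= 1")
  n <- igraph::vcount(net)
  if (n == 0) stop("empty graph")
  nodes <- igraph::V(net)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  m_edges <- igraph::ecount(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  deg0 <- igraph::degree(net)

  if (m_edges == 0) {
    return(structure(list(
      merges = data.frame(step = integer(0), a = integer(0), b = integer(0),
                          new = integer(0), dsigma = numeric(0), q = numeric(0)),
      n_nodes = n, node_names = nodes, q_singletons = NA_real_,
      n_components = igraph::components(net)$no
    ), class = "walktrap_tree"))
  }

  A <- igraph::as_adjacency_matrix(net, sparse = FALSE,
                                   attr = if (weighted) "rho" else NULL)
  if (weighted) A <- abs(A)
  deg <- rowSums(A)
  walk <- which(deg > 0)
  nw <- length(walk)
  P <- A[walk, walk, drop = FALSE] / deg[walk]
  Pt <- P
  if (steps > 1) for (i in seq_len(steps - 1)) Pt <- Pt %*% P
  dk <- deg[walk]

  # community state indexed by community id: 1..n for singletons, n+step for
  # merge products; only communities of walk nodes carry walk distributions
  max_id <- n + nw
  prob <- matrix(NA_real_, max_id, nw)
  prob[walk, ] <- Pt
  size <- integer(max_id); size[seq_len(n)] <- 1L
  nbr <- vector("list", max_id)
  for (v in walk) nbr[[v]] <- setdiff(which(A[v, ] > 0), v)

  pkey <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
  dsig_many <- function(i, ks) {
    # delta sigma between community i and each community in ks
    d2 <- sweep(prob[ks, , drop = FALSE], 2, prob[i, ])^2
    r2 <- as.vector(d2 %*% (1 / dk))
    (size[i] * size[ks]) / (size[i] + size[ks]) * r2 / nw
  }
  init_i <- pmin(el[, 1], el[, 2]); init_j <- pmax(el[, 1], el[, 2])
  dup <- duplicated(paste0(init_i, "_", init_j))
  init_i <- init_i[!dup]; init_j <- init_j[!dup]
  ds <- numeric(0)
  # group by first endpoint so each batch is one vectorized evaluation
  for (i in unique(init_i)) {
    ks <- init_j[init_i == i]
    v <- dsig_many(i, ks)
    names(v) <- paste0(i, "_", ks)
    ds <- c(ds, v)
  }

  n_merges <- nw - igraph::components(
    igraph::delete_vertices(net, which(deg0 == 0)))$no
  membership <- seq_len(n)
  merges <- data.frame(step = seq_len(n_merges), a = NA_integer_,
                       b = NA_integer_, new = NA_integer_,
                       dsigma = NA_real_, q = NA_real_)
  q_single <- .modularity_ids(el, deg0, membership, m_edges)

  for (step in seq_len(n_merges)) {
    best <- min(ds)
    cand <- names(ds)[ds <= best + 1e-12]
    ij <- matrix(as.integer(unlist(strsplit(cand, "_", fixed = TRUE))),
                 ncol = 2, byrow = TRUE)
    o <- order(ij[, 1], ij[, 2])[1]   # deterministic tie-break
    i <- ij[o, 1]; j <- ij[o, 2]
    new_id <- n + step

    prob[new_id, ] <- (size[i] * prob[i, ] + size[j] * prob[j, ]) /
      (size[i] + size[j])
    size[new_id] <- size[i] + size[j]
    neighbors <- setdiff(unique(c(nbr[[i]], nbr[[j]])), c(i, j))
    nbr[[new_id]] <- neighbors
    drop_keys <- c(pkey(i, j), pkey(i, neighbors), pkey(j, neighbors))
    ds <- ds[!names(ds) %in% drop_keys]
    for (k in neighbors) nbr[[k]] <- c(setdiff(nbr[[k]], c(i, j)), new_id)
    if (length(neighbors) > 0) {
      v <- dsig_many(new_id, neighbors)
      names(v) <- pkey(new_id, neighbors)
      ds <- c(ds, v)
    }
    membership[membership %in% c(i, j)] <- new_id
    merges$a[step] <- i; merges$b[step] <- j; merges$new[step] <- new_id
    merges$dsigma[step] <- max(0, best)
    merges$q[step] <- .modularity_ids(el, deg0, membership, m_edges)
  }

  structure(list(merges = merges, n_nodes = n, node_names = nodes,
                 q_singletons = q_single,
                 n_components = igraph::components(net)$no),
            class = "walktrap_tree")
}

#' @export
print.walktrap_tree <- function(x, ...) {
  cat(sprintf("<walktrap_tree: %d nodes, %d merges, max Q = %.4f>\n",
              x$n_nodes, nrow(x$merges),
              max(c(x$q_singletons, x$merges$q), na.rm = TRUE)))
  invisible(x)
}

# modularity from integer community ids over an edge list (node-index pairs)
.modularity_ids <- function(el, deg, membership, m) {
  intra <- membership[el[, 1]] == membership[el[, 2]]
  e_c <- table(membership[el[, 1]][intra])
  d_c <- tapply(deg, membership, sum)
  q_c <- -(d_c / (2 * m))^2
  q_c[names(e_c)] <- q_c[names(e_c)] + as.numeric(e_c) / m
  sum(q_c)
}

#' Newman-Girvan modularity of a partition
#'
#' `Q = sum_c (e_c / m - (d_c / 2m)^2)` with `e_c` the intra-community edge
#' count, `d_c` the total degree of community `c`, and `m` the edge count.
#'
#' @param net an `igraph` network with at least one edge.
#' @param partition a `community_partition`, or a membership vector named by
#'   (or aligned to) the vertex names.
#' @return Modularity Q in `[-0.5, 1]`.
#' @export
modularity_q <- function(net, partition) {
  m <- igraph::ecount(net)
  if (m == 0) stop("modularity undefined for a graph without edges")
  memb <- if (inherits(partition, "community_partition")) partition$membership else partition
  nodes <- igraph::V(net)$name
  if (!is.null(names(memb))) {
    if (!all(nodes %in% names(memb))) stop("partition does not cover all nodes")
    memb <- memb[nodes]
  } else if (length(memb) != length(nodes)) {
    stop("partition does not cover all nodes")
  }
  el <- igraph::as_edgelist(net, names = FALSE)
  .modularity_ids(el, igraph::degree(net), as.integer(factor(memb)), m)
}

#' Modularity-optimal cut of a walktrap dendrogram
#'
#' Scans every partition along the merge sequence (including the initial
#' all-singletons state) and returns the one with maximal modularity; ties are
#' broken toward fewer communities (the later merge step).
#'
#' @param tree a `walktrap_tree`.
#' @return A list of class `community_partition`: `membership` (named integer
#'   vector, labels 1..k in order of first appearance), `q`, `sizes`,
#'   `n_communities`.
#' @export
best_partition <- function(tree) {
  stopifnot(inherits(tree, "walktrap_tree"))
  n <- tree$n_nodes
  qs <- c(tree$q_singletons, tree$merges$q)
  best_step <- if (all(is.na(qs))) nrow(tree$merges) else {
    cand <- which(qs >= max(qs, na.rm = TRUE) - 1e-12)
    max(cand) - 1L  # position 1 = singleton partition (step 0)
  }
  membership <- seq_len(n)
  if (best_step > 0) {
    for (s in seq_len(best_step)) {
      pair <- c(tree$merges$a[s], tree$merges$b[s])
      membership[membership %in% pair] <- tree$merges$new[s]
    }
  }
  labels <- as.integer(factor(membership, levels = unique(membership)))
  names(labels) <- tree$node_names
  structure(list(
    membership = labels,
    q = if (best_step == 0) tree$q_singletons else tree$merges$q[best_step],
    sizes = table(labels),
    n_communities = length(unique(labels))
  ), class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition: %d communities over %d nodes, Q = %s>\n",
              x$n_communities, length(x$membership),
              if (is.na(x$q)) "NA" else sprintf("%.4f", x$q)))
  invisible(x)
}

#' Communities of at least a minimum size
#'
#' The community filter applied before enrichment and hub selection: only
#' communities with `min_size` or more member genes are kept, ordered by size
#' descending (ties by original label) and relabelled `C1..Ck`.
#'
#' @param partition a `community_partition`.
#' @param min_size minimum community size (>= 1).
#' @return Named list of [gene_set()]s (`C1`, `C2`, ...); each carries the
#'   original community label as attribute `community`.
#' @export
large_communities <- function(partition, min_size = 100) {
  stopifnot(inherits(partition, "community_partition"))
  if (min_size < 1) stop("min_size must be >= 1")
  sizes <- partition$sizes
  keep <- sizes[sizes >= min_size]
  if (length(keep) == 0) return(structure(list(), names = character(0)))
  ord <- order(-as.integer(keep), as.integer(names(keep)))
  keep <- keep[ord]
  out <- lapply(seq_along(keep), function(i) {
    lab <- names(keep)[i]
    gs <- gene_set(names(partition$membership)[partition$membership == as.integer(lab)],
                   label = sprintf("C%d", i))
    attr(gs, "community") <- as.integer(lab)
    gs
  })
  names(out) <- sprintf("C%d", seq_along(out))
  out
}
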