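# Independent oracles used across the suite. Each is a direct transcription
# of a definition, kept free of the package's own code paths.

# Benjamini-Hochberg from the step-up definition: q_i = min_{j: p_(j) >= p_i}
# of the running minimum of p_(j) * n / j, with monotonicity enforced.
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  # enforce monotonicity from the largest p downward
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}

# Floyd-Warshall all-pairs shortest paths on an unweighted igraph graph
floyd_warshall <- function(g) {
  n <- igraph::vcount(g)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  el <- igraph::as_edgelist(g, names = FALSE)
  for (r in seq_len(nrow(el))) {
    d[el[r, 1], el[r, 2]] <- 1
    d[el[r, 2], el[r, 1]] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      nd <- d[i, k] + d[k, ]
      d[i, ] <- pmin(d[i, ], nd)
    }
  }
  d
}

# closeness from a Floyd-Warshall distance matrix, within components
closeness_from_dist <- function(d) {
  n <- nrow(d)
  vapply(seq_len(n), function(v) {
    reach <- which(is.finite(d[v, ]) & seq_len(n) != v)
    if (length(reach) == 0) return(0)
    length(reach) / sum(d[v, reach])
  }, numeric(1))
}

# authority oracle: dense eigendecomposition per connected component, each
# component's Perron vector max-normed and scaled by its spectral radius
# relative to the global largest
authority_eigen_oracle <- function(g) {
  n <- igraph::vcount(g)
  comp <- igraph::components(g)
  out <- numeric(n)
  lambda <- numeric(comp$no)
  vecs <- vector("list", comp$no)
  for (c_id in seq_len(comp$no)) {
    members <- which(comp$membership == c_id)
    if (length(members) < 2) { lambda[c_id] <- 0; next }
    A <- igraph::as_adjacency_matrix(igraph::induced_subgraph(g, members),
                                     sparse = FALSE)
    es <- eigen(A, symmetric = TRUE)
    lambda[c_id] <- es$values[1]
    v <- abs(es$vectors[, 1])
    vecs[[c_id]] <- v / max(v)
  }
  if (max(lambda) > 0) {
    for (c_id in seq_len(comp$no)) {
      members <- which(comp$membership == c_id)
      if (length(members) >= 2) {
        out[members] <- vecs[[c_id]] * lambda[c_id] / max(lambda)
      }
    }
  }
  out
}

# hypergeometric upper tail P[X >= k] by direct enumeration with choose()
hyper_tail_brute <- function(k, K, N, n) {
  js <- max(0, k):min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# modularity of every partition along a merge sequence, reconstructed
# independently of best_partition(); returns the vector of Q values
# (singletons first) computed with igraph::modularity
q_profile_oracle <- function(g, tree) {
  n <- tree$n_nodes
  memb <- seq_len(n)
  qs <- igraph::modularity(g, memb)
  for (s in seq_len(nrow(tree$merges))) {
    memb[memb %in% c(tree$merges$a[s], tree$merges$b[s])] <- tree$merges$new[s]
    qs <- c(qs, igraph::modularity(g, as.integer(factor(memb))))
  }
  qs
}

# named graph constructors used in several files
named_graph <- function(g, prefix = "v") {
  igraph::V(g)$name <- paste0(prefix, seq_len(igraph::vcount(g)))
  g
}

# small two-arm design (n samples split over control/treatA at one timepoint)
two_arm_design <- function(n_per_arm, timepoint = 48) {
  make_design(n_reps = n_per_arm, timepoints = timepoint,
              conditions = c("control", "treatA"))
}
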