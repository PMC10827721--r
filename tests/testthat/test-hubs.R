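test_that("centralities match hand values on stars, paths, and cycles", {
  # star with 4 leaves: center degree 4, closeness 1; leaf closeness 4/7;
  # authority center/leaf ratio = sqrt(4) = 2
  s <- named_graph(igraph::make_star(5, mode = "undirected"), prefix = "s")
  cent <- centralities(s)
  center <- cent[cent$degree == 4, ]
  leaves <- cent[cent$degree == 1, ]
  expect_equal(center$closeness, 1)
  expect_equal(leaves$closeness, rep(4 / 7, 4))
  expect_equal(center$authority, 1)
  expect_equal(leaves$authority, rep(0.5, 4), tolerance = 1e-8)

  # vertex-transitive cycle: all three centralities identical across nodes
  c6 <- named_graph(igraph::make_ring(6))
  cc <- centralities(c6)
  expect_equal(length(unique(cc$degree)), 1)
  expect_equal(length(unique(round(cc$closeness, 12))), 1)
  expect_equal(cc$authority, rep(1, 6), tolerance = 1e-8)

  # isolated node: closeness 0
  g <- igraph::add_vertices(s, 1, name = "iso")
  expect_equal(centralities(g)$closeness[5 + 1], 0)
})

test_that("authority matches dense eigendecomposition on random graphs", {
  set.seed(41)
  for (n in c(15, 30, 50)) {
    g <- named_graph(igraph::sample_gnp(n, 0.15))
    if (igraph::ecount(g) == 0) next
    cent <- centralities(g)
    expect_equal(cent$authority, authority_eigen_oracle(g), tolerance = 1e-8)
  }
})

test_that("closeness and diameter match Floyd-Warshall on random graphs", {
  set.seed(42)
  for (n in c(12, 25, 50)) {
    g <- named_graph(igraph::sample_gnp(n, 0.12))
    if (igraph::ecount(g) == 0) next
    cent <- centralities(g)
    d <- floyd_warshall(g)
    expect_equal(cent$closeness, closeness_from_dist(d), tolerance = 1e-12)
    finite <- d[is.finite(d)]
    s <- cohesion_stats(g)
    expect_equal(s$diameter, max(finite))
  }
})

test_that("hub scores multiply factors with deterministic ranking", {
  p4 <- named_graph(igraph::make_ring(4, circular = FALSE), prefix = "n")
  sc <- hub_scores(centralities(p4))
  # hand factors: ends deg 1, closeness 3/6, authority sin(pi/5)/sin(2pi/5);
  # middles deg 2, closeness 3/4, authority 1
  ends <- sc[sc$degree == 1, ]; mids <- sc[sc$degree == 2, ]
  expect_equal(mids$score, rep(2 * 0.75 * 1, 2), tolerance = 1e-6)
  expect_equal(ends$score,
               rep(1 * 0.5 * sin(pi / 5) / sin(2 * pi / 5), 2), tolerance = 1e-6)
  expect_true(all(mids$rank < ends$rank))
  # exact ties broken lexicographically
  expect_equal(sc$gene_id[sc$rank], sc$gene_id)  # rank is the row order
  expect_true(sc$gene_id[1] < sc$gene_id[2])

  # isolated node scores 0; maximal node ranks first
  s <- named_graph(igraph::make_star(6, mode = "undirected"), prefix = "s")
  s <- igraph::add_vertices(s, 1, name = "iso")
  sc2 <- hub_scores(centralities(s))
  expect_equal(sc2$score[sc2$gene_id == "iso"], 0)
  expect_equal(sc2$rank[which.max(sc2$degree)], 1)
})

test_that("hub selection takes top-k per community with clamping", {
  set.seed(43)
  memb <- setNames(rep(1:3, c(60, 60, 30)), sprintf("g%03d", 1:150))
  part <- structure(list(membership = memb, q = 0.5, sizes = table(memb),
                         n_communities = 3), class = "community_partition")
  scores <- data.frame(gene_id = names(memb), degree = 1, closeness = 1,
                       authority = 1)
  scores$score <- runif(150)
  scores <- scores[order(-scores$score, scores$gene_id), ]
  scores$rank <- seq_len(150)

  hubs <- select_hubs(part, scores, k = 50, communities = 1:3)
  expect_length(hubs, 50 + 50 + 30)   # third community clamped
  prov <- attr(hubs, "provenance")
  expect_equal(unname(table(prov$community)), c(50L, 50L, 30L), ignore_attr = TRUE)
  # k = 1: the per-community argmax
  top1 <- select_hubs(part, scores, k = 1, communities = 1:3)
  expect_length(top1, 3)
  best_c1 <- scores$gene_id[scores$gene_id %in% names(memb)[memb == 1]][1]
  expect_true(best_c1 %in% top1)
  expect_error(select_hubs(part, scores, k = 50, communities = c(1, 9)),
               "unknown")
})

test_that("removal reports match hand geodesics on stars", {
  s <- named_graph(igraph::make_star(6, mode = "undirected"), prefix = "s")
  # s1 is the center; removing a leaf keeps diameter 2, one component
  rep_leaf <- removal_report(s, "s2")
  expect_equal(rep_leaf$after$diameter, 2)
  expect_equal(rep_leaf$after$n_components, 1)
  expect_equal(rep_leaf$after$n_nodes, 5)
  # removing the center isolates all 5 leaves
  rep_center <- removal_report(s, "s1")
  expect_equal(rep_center$after$n_components, 5)
  expect_equal(rep_center$after$mean_geodesic, 0)
  expect_equal(rep_center$after$n_edges, 0)
  # removing nothing changes nothing
  rep_none <- removal_report(s, character(0))
  expect_equal(rep_none$before, rep_none$after)
  expect_error(removal_report(s, paste0("s", 1:6)), "all nodes")
  expect_error(removal_report(s, "zz"), "absent")
})

test_that("hub removal damages cohesion more than random removal", {
  skip_if_not_installed("mclust")  # co-located with the stochastic suite
  set.seed(3)
  pa <- named_graph(igraph::sample_pa(300, m = 2, directed = FALSE))
  sc <- hub_scores(centralities(pa))
  top10 <- sc$gene_id[1:10]
  rep <- removal_report(pa, top10, baseline_repeats = 20, seed = 4)
  expect_gt(rep$after$mean_geodesic, rep$baseline_mean_geodesic[["mean"]])
  # baselines are reproducible under the same seed
  rep2 <- removal_report(pa, top10, baseline_repeats = 20, seed = 4)
  expect_equal(rep$baseline, rep2$baseline)
})

test_that("planted hubs surface in the per-module score ranking", {
  d <- make_design(n_reps = 20, timepoints = 48,
                   conditions = c("control", "treatA"))
  p <- generator_params(n_genes = 400, module_sizes = c(60, 60, 60),
                        module_loading = 0.6, hub_per_module = 5,
                        hub_loading = 0.95, de_fraction = 0,
                        dispersion = 0.1, seed = 2)
  sim <- simulate_experiment(d, p)
  net <- build_network(suppressWarnings(correlation_matrix(log_cpm(sim$counts))))
  sc <- hub_scores(centralities(net))
  rank_of <- setNames(sc$rank, sc$gene_id)
  recovery <- vapply(1:3, function(m) {
    members <- names(sim$truth$module_of)[which(sim$truth$module_of == m)]
    top <- members[order(rank_of[members])][1:10]   # k = 2 x planted count
    mean(sim$truth$hub_genes[[m]] %in% top)
  }, numeric(1))
  expect_gte(mean(recovery), 0.7)
})
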