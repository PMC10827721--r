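test_that("full-factorial design has the expected layout and IDs", {
  d <- make_design(3, c(48, 72, 96), c("control", "treatA", "treatB"))
  expect_equal(nrow(d), 27)
  expect_equal(anyDuplicated(d$sample_id), 0)
  expect_true("treatA_72_r2" %in% d$sample_id)
  expect_equal(as.vector(table(d$condition, d$timepoint)), rep(3, 9))

  expect_equal(nrow(make_design(2, 48, c("control", "treatA"))), 4)
  expect_error(make_design(1), "n_reps")
  expect_error(make_design(3, numeric(0)), "non-empty")
})

test_that("generator parameters are validated", {
  expect_error(generator_params(module_sizes = c(1, 30)), "at least 2")
  expect_error(generator_params(n_genes = 50, module_sizes = c(30, 30)), "exceeds")
  expect_error(generator_params(module_loading = 0.9, hub_loading = 0.5), "hub_loading")
  expect_error(generator_params(dispersion = 0), "positive")
  expect_error(generator_params(libsize_range = c(2, 1)), "libsize_range")
})

test_that("simulation is bit-identical under a fixed seed and leaves RNG alone", {
  d <- make_design(2, 48, c("control", "treatA"))
  p <- generator_params(n_genes = 100, module_sizes = c(20, 20), seed = 42)
  set.seed(123); before <- runif(1)
  set.seed(123)
  s1 <- simulate_experiment(d, p)
  expect_identical(runif(1), before)  # caller RNG state untouched
  s2 <- simulate_experiment(d, p)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_experiment(d, generator_params(n_genes = 100,
                                                module_sizes = c(20, 20),
                                                seed = 43))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("ground truth is internally consistent", {
  d <- make_design()
  p <- generator_params(n_genes = 400, module_sizes = c(50, 40),
                        hub_per_module = 3, de_fraction = 0.1, seed = 7)
  sim <- simulate_experiment(d, p)
  expect_equal(dim(sim$counts), c(400, 27))
  expect_true(all(sim$counts >= 0))
  # hubs lie inside their module
  for (m in 1:2) {
    members <- names(sim$truth$module_of)[which(sim$truth$module_of == m)]
    expect_true(all(sim$truth$hub_genes[[m]] %in% members))
    expect_length(sim$truth$hub_genes[[m]], 3)
  }
  # |de_genes| = round(de_fraction * n_genes)
  expect_equal(length(unique(sim$truth$de$gene_id)), round(0.1 * 400))
  expect_true(all(abs(sim$truth$de$logfc) == p$de_logfc))
})

test_that("background genes are uncorrelated: mean |rho| matches the independence value", {
  d <- make_design()  # 27 samples
  p <- generator_params(n_genes = 300, module_sizes = integer(0),
                        de_fraction = 0, seed = 5)
  e <- log_cpm(simulate_experiment(d, p)$counts)
  set.seed(6)
  pairs <- cbind(sample.int(300, 1200, replace = TRUE),
                 sample.int(300, 1200, replace = TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], ][1:1000, ]
  rho <- vapply(seq_len(1000), function(i) {
    spearman_rho(e[pairs[i, 1], ], e[pairs[i, 2], ])
  }, numeric(1))
  # under independence E|rho| = sqrt(2/pi)/sqrt(n-1); check to 3 SE
  expected <- sqrt(2 / pi) / sqrt(26)
  expect_lt(abs(mean(abs(rho)) - expected), 3 * sd(abs(rho)) / sqrt(1000))
  expect_lt(abs(mean(rho)), 3 * sd(rho) / sqrt(1000))
  expect_lt(mean(abs(rho)), 0.25)
})

test_that("tiny dispersion with fixed depth approaches the Poisson limit", {
  d <- two_arm_design(10)
  p <- generator_params(n_genes = 200, module_sizes = integer(0),
                        de_fraction = 0, dispersion = 1e-8,
                        baseline_logmean_mean = 4, baseline_logmean_sd = 0.5,
                        libsize_range = c(1, 1), seed = 8)
  sim <- simulate_experiment(d, p)
  ratio <- apply(sim$counts, 1, var) / rowMeans(sim$counts)
  expect_gt(median(ratio), 0.8)
  expect_lt(median(ratio), 1.25)
})

test_that("within-module correlation increases with the factor loading", {
  d <- make_design(n_reps = 20, timepoints = 48,
                   conditions = c("control", "treatA"))  # 40 samples
  mean_within <- vapply(c(0.2, 0.5, 0.9), function(lam) {
    p <- generator_params(n_genes = 300, module_sizes = c(30, 30, 30),
                          module_loading = lam, hub_per_module = 0,
                          hub_loading = lam, de_fraction = 0, seed = 9)
    sim <- simulate_experiment(d, p)
    e <- log_cpm(sim$counts)
    rho <- suppressWarnings(correlation_matrix(e))$rho
    vals <- c()
    for (m in 1:3) {
      idx <- which(sim$truth$module_of == m)
      sub <- rho[idx, idx]
      vals <- c(vals, abs(sub[upper.tri(sub)]))
    }
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_within) > 0))
  expect_gt(mean_within[3], 0.5)
})

test_that("planted DE genes are recovered by the DE stage", {
  # de_logfc = 2, phi = 0.1, 5 replicates; recovery at FDR < 0.05 must reach
  # 90%; the plug-in-dispersion LRT is anti-conservative in the far tail, so
  # the empirical FDR is bounded at 20% rather than the nominal 5%
  d <- make_design(n_reps = 5)
  p <- generator_params(n_genes = 1000, module_sizes = integer(0),
                        de_fraction = 0.05, de_logfc = 2, dispersion = 0.1,
                        seed = 1)
  sim <- simulate_experiment(d, p)
  truth <- sim$truth$de
  calls <- character(0); truth_pairs <- character(0); false_calls <- 0
  recovery <- c()
  for (tr in c("treatA", "treatB")) {
    tg <- truth$gene_id[truth$condition == tr]
    for (tp in c(48, 72, 96)) {
      tab <- de_test(sim$counts, sim$design,
                     list(treat = tr, control = "control", timepoint = tp))
      hit <- tab$gene_id[tab$fdr < 0.05]
      calls <- c(calls, paste(tr, hit))
      false_calls <- false_calls + sum(!hit %in% tg)
      recovery <- c(recovery, mean(tg %in% hit))
    }
  }
  expect_gt(mean(recovery), 0.9)
  expect_lt(false_calls / length(calls), 0.2)
})
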