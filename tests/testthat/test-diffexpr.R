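test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # oracle equivalence on a grid of vectors up to length 6
  grid <- c(0.001, 0.04, 0.2, 0.5, 1)
  for (len in 1:6) {
    vecs <- as.matrix(expand.grid(rep(list(grid), len)))
    for (r in seq_len(nrow(vecs))) {
      p <- unname(vecs[r, ])
      expect_equal(bh_adjust(p), bh_brute(p))
    }
  }
  # q >= p and order preservation on random vectors
  set.seed(1)
  for (i in 1:20) {
    p <- runif(30)
    q <- bh_adjust(p)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= 0))  # order-preserving
    expect_equal(q, bh_brute(p))
  }
})

test_that("identical group means give logFC 0 and p near 1", {
  d <- two_arm_design(3)
  base <- c(20L, 100L, 500L, 7L, 60L)
  y <- matrix(rep(base, 6), 5, 6,
              dimnames = list(paste0("g", 1:5), d$sample_id))
  tab <- de_test(y, d, list(treat = "treatA", control = "control", timepoint = 48))
  expect_equal(tab$logFC, rep(0, 5), tolerance = 1e-8)
  expect_true(all(tab$pvalue > 0.99))
})

test_that("type-I error is calibrated on a null simulation", {
  set.seed(42)
  n <- 2000
  mu <- exp(rnorm(n, 4, 1.5))
  d <- two_arm_design(5)
  y <- matrix(rnbinom(n * 10, mu = rep(mu, 10), size = 10), n, 10,
              dimnames = list(sprintf("g%04d", 1:n), d$sample_id))
  tab <- de_test(y, d, list(treat = "treatA", control = "control", timepoint = 48))
  typeI <- mean(tab$pvalue < 0.05)
  expect_gte(typeI, 0.025)
  expect_lte(typeI, 0.08)
  # p-values approximately uniform under the null
  expect_gt(ks.test(tab$pvalue, "punif")$p.value, 0.01)
})

test_that("planted log-fold changes are recovered in sign and magnitude", {
  d <- two_arm_design(8)
  p <- generator_params(n_genes = 500, module_sizes = integer(0),
                        de_fraction = 0.1, de_logfc = 2, dispersion = 0.1,
                        seed = 21)
  sim <- simulate_experiment(d, p)
  tab <- de_test(sim$counts, sim$design,
                 list(treat = "treatA", control = "control", timepoint = 48))
  truth <- sim$truth$de[sim$truth$de$condition == "treatA", ]
  est <- tab$logFC[match(truth$gene_id, tab$gene_id)]
  ok <- abs(est - truth$logfc) < 0.5
  expect_gte(mean(ok), 0.9)
})

test_that("DE filtering applies strict FDR and logFC cutoffs", {
  tab <- data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    logFC = c(1.6, 1.5, -2.0, 3.0, -1.6),
    pvalue = c(1e-5, 1e-10, 1e-5, 0.5, 1e-5),
    fdr = c(5e-4, 1e-9, 5e-4, 0.6, 2e-3),
    contrast = "x"
  )
  sets <- filter_de(tab, fdr_max = 0.001, lfc_min = 1.5)
  expect_equal(as.character(sets$up), "a")      # b excluded: logFC not > 1.5
  expect_equal(as.character(sets$down), "c")    # e excluded: fdr not < 0.001
  expect_error(filter_de(tab, fdr_max = 0), "positive")

  # monotone in the thresholds
  set.seed(2)
  tab2 <- data.frame(gene_id = sprintf("g%03d", 1:200),
                     logFC = rnorm(200, 0, 2), pvalue = runif(200)^2)
  tab2$fdr <- bh_adjust(tab2$pvalue); tab2$contrast <- "x"
  n_up <- function(fdr_max, lfc_min) {
    length(filter_de(tab2, fdr_max, lfc_min)$up)
  }
  for (lfc in c(0.5, 1, 1.5, 2)) {
    counts <- vapply(c(0.001, 0.01, 0.1, 0.5), n_up, numeric(1), lfc_min = lfc)
    expect_true(all(diff(counts) >= 0))   # non-decreasing in fdr_max
  }
  for (fdr in c(0.01, 0.1, 0.5)) {
    counts <- vapply(c(0.5, 1, 1.5, 2), n_up, numeric(1), fdr_max = fdr)
    expect_true(all(diff(counts) <= 0))   # non-increasing in lfc_min
  }
})

test_that("Venn partition is disjoint and additive", {
  v <- venn_partition(gene_set(c("g1", "g2", "g3"), direction = "up"),
                      gene_set(c("g2", "g3", "g4"), direction = "up"))
  expect_equal(unname(v$sizes), c(1, 2, 1))
  expect_equal(sort(v$shared), c("g2", "g3"))

  v2 <- venn_partition(c("a", "b"), c("c", "d"))
  expect_length(v2$shared, 0)
  v3 <- venn_partition(c("a", "b"), c("a", "b", "c"))
  expect_length(v3$only_a, 0)
  # additive identity on random sets
  set.seed(3)
  for (i in 1:10) {
    a <- sample(letters, sample(5:15, 1))
    b <- sample(letters, sample(5:15, 1))
    v <- venn_partition(a, b)
    expect_equal(length(v$only_a) + length(v$shared), length(unique(a)))
    expect_equal(length(v$only_b) + length(v$shared), length(unique(b)))
  }
  expect_error(venn_partition(gene_set("a", direction = "up"),
                              gene_set("b", direction = "down")),
               "direction")
})

test_that("logFC comparisons handle degenerate and exact cases", {
  x <- c(1.2, 0.5, 2.0, 1.1, 0.8)
  # x vs itself, paired t: statistic 0, p = 1
  r <- compare_logfc(x, x, method = "t", paired = TRUE)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  # constant nonzero shift with zero-variance differences
  r2 <- compare_logfc(x + 5, x, method = "t", paired = TRUE)
  expect_equal(r2$p.value, 0)
  # shift with tiny noise: overwhelming evidence at n = 10
  set.seed(4)
  y <- rnorm(10)
  r3 <- compare_logfc(y + 5 + rnorm(10, 0, 1e-3), y, method = "t", paired = TRUE)
  expect_lt(r3$p.value, 1e-6)
  # exact rank-sum: {1,2,3} vs {4,5,6} -> 2/20 arrangements as extreme
  r4 <- compare_logfc(c(1, 2, 3), c(4, 5, 6), method = "wilcoxon")
  expect_equal(r4$p.value, 0.1)
  # all-zero paired differences: signed-rank undefined
  expect_error(compare_logfc(x, x, method = "wilcoxon", paired = TRUE),
               "undefined")
  expect_error(compare_logfc(1:2, 1:2), "n >= 3")
  expect_error(compare_logfc(1:4, 1:5, paired = TRUE), "length")
})
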