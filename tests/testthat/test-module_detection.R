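test_that("average-linkage clustering matches a naive UPGMA oracle", {
  # two points merge at their dissimilarity
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  hc2 <- hierarchical_cluster(d2)
  expect_equal(hc2$height, 0.4)
  # well-separated groups: the final merge towers over within-group merges
  dd <- matrix(0.9, 10, 10)
  dd[1:5, 1:5] <- 0.1
  dd[6:10, 6:10] <- 0.1
  diag(dd) <- 0
  dimnames(dd) <- list(letters[1:10], letters[1:10])
  hcg <- hierarchical_cluster(dd)
  expect_equal(max(hcg$height), 0.9)
  expect_lt(sort(hcg$height, decreasing = TRUE)[2], 0.2)
  # random instance: cophenetic distances match the naive O(n^3) oracle
  n <- 25
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- withr::with_seed(71, runif(n * (n - 1) / 2))
  d <- d + t(d)
  dimnames(d) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  hc <- hierarchical_cluster(d)
  expect_equal(unname(as.matrix(stats::cophenetic(hc))),
               oracle_upgma_cophenetic(d), tolerance = 1e-12)
  # invalid input
  d[1, 2] <- NA
  d[2, 1] <- NA
  expect_error(hierarchical_cluster(d), "finite")
})

test_that("branch cut leaves unstructured data entirely grey", {
  n <- 100
  d <- matrix(1, n, n)
  noise <- withr::with_seed(72, runif(n * (n - 1) / 2) * 0.02)
  d[upper.tri(d)] <- 1 - noise
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  diag(d) <- 0
  dimnames(d) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  hc <- hierarchical_cluster(d)
  for (ds in 0:3) {
    lab <- cut_tree_dynamic(hc, min_cluster_size = 50, deep_split = ds)
    expect_equal(sum(lab > 0), 0)
  }
})

test_that("branch cut recovers planted blocks exactly", {
  n <- 240
  bl <- rep(1:4, each = 60)
  d <- matrix(0.9, n, n) + withr::with_seed(73, matrix(runif(n * n) * 0.05, n))
  d <- (d + t(d)) / 2
  for (k in 1:4) {
    blk <- withr::with_seed(73 + k, matrix(runif(3600) * 0.05, 60))
    d[bl == k, bl == k] <- 0.2 + (blk + t(blk)) / 2
  }
  diag(d) <- 0
  dimnames(d) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  lab <- cut_tree_dynamic(hierarchical_cluster(d), 50, 2)
  expect_equal(sort(unique(lab[lab > 0])), 1:4)
  expect_equal(unname(table(lab)), rep(60L, 4L), ignore_attr = TRUE)
  expect_equal(external_metrics(lab, bl)$ari, 1)
})

test_that("deeper split never yields fewer modules on the same dendrogram", {
  hc <- scenario_fit()$dendrogram
  counts <- vapply(0:3, function(ds) {
    lab <- cut_tree_dynamic(hc, 50, ds)
    length(unique(lab[lab > 0]))
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("eigengenes summarize rank-1 modules and planted factors", {
  # module of duplicated genes: eigengene correlates 1 with each member
  base <- withr::with_seed(74, rnorm(20))
  x <- rbind(g1 = base, g2 = 2 * base + 1, g3 = -0.5 * base)
  colnames(x) <- sprintf("s%02d", 1:20)
  me <- module_eigengenes(x, c(g1 = 1L, g2 = 1L, g3 = 1L))
  expect_equal(dim(me), c(20L, 1L))
  for (g in rownames(x)) {
    expect_equal(abs(cor(me[, 1], x[g, ])), 1, tolerance = 1e-10)
  }
  # orientation: positively correlated with the module mean profile
  zm <- standardize_genes(x)
  expect_gte(cor(me[, 1], colMeans(zm)), 0)
  # planted one-factor module recovers the factor
  ds <- scenario_data()
  lab1 <- ifelse(ds$truth == 1, 1L, 0L)
  names(lab1) <- names(ds$truth)
  me1 <- module_eigengenes(ds$expression, lab1)
  expect_gte(abs(cor(me1[, "ME1"], ds$factors[, 1])), 0.95)
  # single-gene module: the standardized profile itself
  lab_single <- c(g1 = 1L)
  me_s <- module_eigengenes(x["g1", , drop = FALSE], lab_single)
  expect_equal(unname(me_s[, 1]), unname(standardize_genes(x["g1", , drop = FALSE])[1, ]))
})

test_that("eigengene orientation is invariant to gene order", {
  ds <- scenario_data()
  lab <- ds$truth
  me <- module_eigengenes(ds$expression, lab)
  perm <- withr::with_seed(75, sample(names(lab)))
  me_p <- module_eigengenes(ds$expression[perm, ], lab[perm])
  expect_equal(me_p, me, tolerance = 1e-9)
})

test_that("merging restores an artificially split module and respects orthogonality", {
  ds <- scenario_data()
  truth <- ds$truth
  # split planted module 1 into two labels
  split_lab <- truth
  m1 <- names(truth)[truth == 1]
  split_lab[m1[seq_len(30)]] <- 5L
  merged <- merge_similar_modules(ds$expression, split_lab, 0.8)
  expect_equal(length(unique(merged[merged > 0])), 4)
  expect_equal(external_metrics(merged, truth)$ari, 1)
  # orthogonal planted factors are never merged
  keep <- merge_similar_modules(ds$expression, truth, 0.8)
  expect_equal(length(unique(keep[keep > 0])), 4)
  expect_equal(external_metrics(keep, truth)$ari, 1)
  # threshold 1.0 is strict: nothing merges
  expect_equal(external_metrics(merge_similar_modules(ds$expression, split_lab, 1.0),
                                split_lab)$ari, 1)
})

test_that("kME refinement expels background genes and readopts strays", {
  ds <- scenario_data()
  noisy <- ds$truth
  # corrupt: grey out 10 genes of module 2, put 10 background genes in it
  m2 <- names(ds$truth)[ds$truth == 2]
  bg <- names(ds$truth)[ds$truth == 0]
  noisy[m2[1:10]] <- 0L
  noisy[bg[1:10]] <- 2L
  refined <- refine_modules(ds$expression, noisy, min_kme = 0.5,
                            min_cluster_size = 50)
  expect_equal(external_metrics(refined, ds$truth)$ari, 1)
})

test_that("module detection is deterministic end to end", {
  ds <- scenario_data()
  f1 <- suppressWarnings(suppressMessages(wgchna(ds$expression, ds$traits)))
  f2 <- scenario_fit()
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$eigengenes, f2$eigengenes)
})

test_that("gene-order permutation leaves the module partition unchanged", {
  ds <- scenario_data()
  perm <- withr::with_seed(76, sample(rownames(ds$expression)))
  fit_p <- suppressWarnings(suppressMessages(
    wgchna(ds$expression[perm, ], ds$traits)))
  f <- scenario_fit()
  common <- rownames(ds$expression)
  expect_equal(external_metrics(fit_p$labels[common], f$labels[common])$ari, 1)
})

test_that("module colors are deterministic with grey for unassigned", {
  lab <- c(a = 0L, b = 1L, c = 2L, d = 1L)
  col <- module_colors(lab)
  expect_identical(unname(col), c("grey", "turquoise", "blue", "turquoise"))
})
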