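test_that("the worked-example hypergraph matches its printed structure", {
  hg <- toy_hypergraph()
  expect_length(hg$node_ids, 7)
  expect_length(hg$edge_ids, 4)
  expect_equal(unname(edge_degrees(hg)), c(3, 2, 2, 2))
  expect_equal(sum(hg$edge_weights), 9)
  e4 <- hg$incidence[, "e4"]
  expect_equal(names(e4)[e4 == 1], c("v4", "v7"))
  d <- node_hyperdegrees(hg)
  expect_equal(unname(d["v3"]), 3 + 2)  # member of e1 and e2
  expect_equal(unname(d["v4"]), 2)      # member of e4 only
})

test_that("incidence membership follows the |z| >= tau rule", {
  x <- rand_expr(30, 10, seed = 21)
  z <- standardize_genes(x)
  # tau = 0: every gene joins every hyperedge
  hg0 <- build_incidence(z, tau = 0)
  expect_true(all(hg0$incidence == 1))
  expect_equal(unname(edge_degrees(hg0)), rep(30, 10))
  # threshold definition on a known row
  zrow <- z["g001", ]
  hg1 <- suppressWarnings(build_incidence(z, tau = 1))
  kept_edges <- colnames(hg1$incidence)
  expect_equal(unname(hg1$incidence["g001", ]),
               unname(as.numeric(abs(zrow[kept_edges]) >= 1)))
  # non-standardized input is rejected
  expect_error(build_incidence(x, 1), "standardized")
})

test_that("membership fraction at tau = 1 matches the normal tail", {
  z <- standardize_genes(rand_expr(50, 10, seed = 22))
  hg <- suppressWarnings(build_incidence(z, tau = 1))
  frac <- mean(hg$incidence)
  expected <- 2 * (1 - pnorm(1))  # ~0.317
  expect_lt(abs(frac - expected), 3 * sqrt(expected * (1 - expected) / 500))
})

test_that("degenerate hyperedges and isolated genes are dropped with warnings", {
  z <- standardize_genes(rand_expr(40, 10, seed = 23))
  w <- capture_warnings(hg <- build_incidence(z, tau = 1.6))
  expect_gte(length(w), 1)
  expect_match(paste(w, collapse = " "), "dropped")
  expect_true(all(edge_degrees(hg) >= 2))
  expect_true(all(rowSums(hg$incidence) >= 1))
  expect_error(suppressWarnings(build_incidence(z, tau = 10)), "smaller tau")
})

test_that("correlation weights equal the mean powered |cor| over edge pairs", {
  # single perfect pair: a duplicated gene gives weight exactly 1
  x <- rand_expr(2, 6, seed = 24)
  x[2, ] <- 2 * x[1, ] + 3
  rownames(x) <- c("a", "b")
  h <- matrix(1, 2, 1, dimnames = list(c("a", "b"), "e1"))
  hg <- weighted_hypergraph(h)
  for (beta in c(1, 4)) {
    expect_equal(unname(hyperedge_weights_corr(x, hg, beta)$edge_weights), 1)
  }
  # brute-force oracle on a random instance
  inst <- rand_hypergraph(30, 12, seed = 25, tau = 1, beta = 6)
  w <- inst$hg$edge_weights
  w_oracle <- oracle_edge_weights_corr(inst$x[inst$hg$node_ids, ],
                                       inst$hg$incidence, 6)
  expect_lt(max(abs(w - w_oracle)), 1e-10)
  expect_true(all(w >= 0 & w <= 1))
})

test_that("raising beta never increases a hyperedge weight", {
  inst <- rand_hypergraph(25, 10, seed = 26, tau = 0.8, beta = 1)
  x <- inst$x
  hg <- inst$hg
  prev <- hyperedge_weights_corr(x, hg, 1)$edge_weights
  for (beta in 2:8) {
    cur <- hyperedge_weights_corr(x, hg, beta)$edge_weights
    expect_true(all(cur <= prev + 1e-12))
    prev <- cur
  }
})

test_that("hypergraph handshake identity holds on random instances", {
  for (seed in 31:35) {
    inst <- rand_hypergraph(20, 9, seed = seed, tau = 0.7, beta = 2)
    d <- node_hyperdegrees(inst$hg)
    expect_equal(sum(d),
                 sum(inst$hg$edge_weights * edge_degrees(inst$hg)),
                 tolerance = 1e-10)
  }
})

test_that("all-ones weights reduce hyperdegrees to edge counts", {
  z <- standardize_genes(rand_expr(15, 6, seed = 27))
  hg <- suppressWarnings(build_incidence(z, 0.5))
  expect_equal(unname(node_hyperdegrees(hg)),
               unname(rowSums(hg$incidence)))
})

test_that("mutual-information weights match the contingency-table oracle", {
  # independence by construction: balanced orthogonal patterns
  x <- rbind(a = rep(c(1, 1, 2, 2), 3), b = rep(c(1, 2), 6))
  colnames(x) <- sprintf("s%02d", 1:12)
  h <- matrix(1, 2, 1, dimnames = list(c("a", "b"), "e1"))
  hg <- weighted_hypergraph(h)
  expect_equal(unname(hyperedge_weights_mi(x, hg, bins = 2)), 0, tolerance = 1e-12)
  # duplicated gene with balanced values: MI = log 2 exactly
  y <- rbind(a = rep(c(0, 1), 6), b = rep(c(0, 1), 6))
  colnames(y) <- colnames(x)
  expect_equal(unname(hyperedge_weights_mi(y, hg, bins = 2)), log(2),
               tolerance = 1e-10)
  # random instance against the naive oracle
  inst <- rand_hypergraph(12, 10, seed = 28, tau = 0.8)
  w <- hyperedge_weights_mi(inst$x, inst$hg, bins = 4)
  w_oracle <- oracle_edge_weights_mi(inst$x[inst$hg$node_ids, ],
                                     inst$hg$incidence, 4)
  expect_lt(max(abs(w - w_oracle)), 1e-10)
  # constant genes make binning undefined
  bad <- inst$x
  bad[inst$hg$node_ids[1], ] <- 3
  expect_error(hyperedge_weights_mi(bad, inst$hg, 4), "constant")
})

test_that("rank correlation helper handles identity, reversal, degeneracy", {
  sp <- wgchna:::spearman_safe
  a <- c(0.1, 0.4, 0.2, 0.9, 0.6)
  expect_equal(sp(a, a * 3 + 1)$rho, 1)
  expect_equal(sp(a, -a)$rho, -1)
  expect_true(is.na(sp(rep(1, 5), a)$rho))
})

test_that("weight schemes require at least five hyperedges", {
  inst <- rand_hypergraph(10, 4, seed = 29, tau = 0.3)
  expect_error(compare_weight_schemes(inst$x, inst$hg), ">= 5")
})

test_that("hypergraph serialization round-trips", {
  inst <- rand_hypergraph(15, 8, seed = 30, tau = 0.8, beta = 2)
  ep <- withr::local_tempfile(fileext = ".tsv")
  wp <- withr::local_tempfile(fileext = ".tsv")
  write_hypergraph(inst$hg, ep, wp)
  back <- read_hypergraph(ep, wp)
  expect_equal(sort(back$node_ids), sort(inst$hg$node_ids))
  expect_identical(back$edge_ids, inst$hg$edge_ids)
  ord <- match(inst$hg$node_ids, back$node_ids)
  expect_equal(unname(back$incidence[ord, ]), unname(inst$hg$incidence))
  expect_equal(unname(back$edge_weights), unname(inst$hg$edge_weights))
})
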