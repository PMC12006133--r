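# Shared fixtures, all generated in code under fixed seeds.

rand_expr <- function(n_genes, n_samples, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  })
  dimnames(x) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%03d", seq_len(n_samples)))
  x
}

# A small random hypergraph instance with correlation weights already set.
# tau is kept modest so edges rarely drop below two members.
rand_hypergraph <- function(n_genes, n_samples, seed = 1, tau = 0.8, beta = 3) {
  x <- rand_expr(n_genes, n_samples, seed)
  hg <- suppressWarnings(build_incidence(standardize_genes(x), tau))
  list(x = x, hg = hyperedge_weights_corr(x, hg, beta))
}

# The canonical planted-module dataset, cached per test run.
scenario_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_synthetic(default_scenario())
    cache
  }
})

# Full pipeline fit on the canonical scenario, cached (used by several
# acceptance checks).
scenario_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- scenario_data()
      cache <<- suppressWarnings(suppressMessages(wgchna(ds$expression, ds$traits)))
    }
    cache
  }
})

# Two well-separated Gaussian blobs in `dim` dimensions.
blob_features <- function(n_per = 30, dim = 5, separation = 10, seed = 5) {
  withr::with_seed(seed, {
    a <- matrix(rnorm(n_per * dim), n_per, dim)
    b <- matrix(rnorm(n_per * dim), n_per, dim)
  })
  b[, 1] <- b[, 1] + separation
  list(features = rbind(a, b), labels = rep(1:2, each = n_per))
}

expect_labels_equivalent <- function(a, b) {
  expect_equal(external_metrics(a, b)$ari, 1)
}
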