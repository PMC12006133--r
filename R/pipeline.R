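#' Pipeline configuration
#'
#' All tunable stage parameters in one resolvable record. Defaults follow
#' standard co-expression practice: minimum module size 50, split depth 2,
#' modules merged above 80\% eigengene similarity.
#'
#' @param tau Hypergraph membership threshold on |z| (default 1).
#' @param beta Soft-threshold exponent; `NULL` (default) selects it by
#'   scale-free scan over `betas`.
#' @param betas Candidate exponents for the scan (default 1:12).
#' @param n_bins Bins for the scale-free fit (default 10).
#' @param r2_cut Signed R^2 acceptance level for [pick_beta()] (default 0.8).
#' @param corr_method `"pearson"` (default) or `"spearman"`.
#' @param max_missing_frac,min_variance Gene filters (see [filter_genes()]).
#' @param min_cluster_size Minimum module size (default 50).
#' @param deep_split Branch-cut sensitivity 0..3 (default 2).
#' @param merge_similarity Eigengene correlation above which modules merge
#'   (default 0.8).
#' @param min_kme Membership threshold for [refine_modules()] (default 0.5).
#' @param mi_bins Bins for mutual-information weights (default 8).
#' @param top_k Hub genes reported per module (default 10).
#' @return List of class `wgchna_config`.
#' @export
wgchna_config <- function(tau = 1, beta = NULL, betas = 1:12, n_bins = 10,
                          r2_cut = 0.8, corr_method = "pearson",
                          max_missing_frac = 0.2, min_variance = 0,
                          min_cluster_size = 50, deep_split = 2,
                          merge_similarity = 0.8, min_kme = 0.5,
                          mi_bins = 8, top_k = 10) {
  structure(list(tau = tau, beta = beta, betas = betas, n_bins = n_bins,
                 r2_cut = r2_cut, corr_method = corr_method,
                 max_missing_frac = max_missing_frac,
                 min_variance = min_variance,
                 min_cluster_size = min_cluster_size,
                 deep_split = deep_split,
                 merge_similarity = merge_similarity, min_kme = min_kme,
                 mi_bins = mi_bins, top_k = top_k),
            class = "wgchna_config")
}

#' Run the full co-expression hypernetwork pipeline
#'
#' Preprocess (filter, impute, standardize), build the sample hypergraph,
#' select the soft threshold by scale-free scan (unless `config$beta` is
#' fixed), weight hyperedges by aggregated pairwise correlation, compute
#' the hypergraph Laplacian, TOM and dissTOM, cluster, cut branches
#' dynamically, merge similar modules, refine membership by kME, and run
#' the downstream eigengene/trait/hub analyses.
#'
#' @param x Genes x samples expression matrix (may contain missing values).
#' @param traits Optional samples x traits numeric matrix (see
#'   [read_traits()]).
#' @param config A [wgchna_config()].
#' @return Object of class `wgchna_fit`: list with the imputed expression,
#'   hypergraph, scan, chosen `beta`, Laplacians, TOM (`tom_matrix`),
#'   dissimilarity, dendrogram, `labels` (named; every gene that survived
#'   filtering appears exactly once, 0 = grey), `eigengenes`, `hubs`,
#'   `module_trait` (when traits given) and a `log` of stage dimensions.
#' @export
wgchna <- function(x, traits = NULL, config = wgchna_config()) {
  stopifnot(inherits(config, "wgchna_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  x <- filter_genes(x, config$max_missing_frac, config$min_variance)
  x <- impute_missing(x)
  note("genes after filtering: ", nrow(x), "; samples: ", ncol(x))
  z <- standardize_genes(x)
  hg <- build_incidence(z, config$tau)
  note("hypergraph: ", length(hg$node_ids), " nodes, ",
       length(hg$edge_ids), " hyperedges (tau = ", config$tau, ")")

  scan <- NULL
  beta <- config$beta
  if (is.null(beta)) {
    scan <- scan_beta(x, config$tau, config$betas, config$n_bins,
                      config$corr_method)
    choice <- pick_beta(scan, config$r2_cut)
    beta <- choice$beta
    note("soft threshold beta = ", beta,
         if (choice$below_cut) " (below scale-free cut; best available)" else "")
  }
  hg <- hyperedge_weights_corr(x, hg, beta, config$corr_method)
  lap <- hypergraph_laplacians(hg)
  tm <- tom_matrix(lap)
  note("TOM computed; ", tm$n_clamped, " entr(ies) clamped")
  diss <- diss_tom(tm)
  dend <- hierarchical_cluster(diss)

  labels0 <- cut_tree_dynamic(dend, config$min_cluster_size, config$deep_split)
  note("branch cut: ", length(unique(labels0[labels0 > 0])), " module(s)")
  labels <- merge_similar_modules(x[hg$node_ids, , drop = FALSE], labels0,
                                  config$merge_similarity)
  labels <- refine_modules(x, labels, config$min_kme,
                           config$min_cluster_size)
  labels <- merge_similar_modules(x, labels, config$merge_similarity)

  # residual sweep: genes still grey are re-clustered on their dissTOM
  # submatrix, where a module masked by the already-assigned branches can
  # surface; repeated until no further module emerges
  for (sweep in 1:5) {
    grey <- intersect(names(labels)[labels == 0L], hg$node_ids)
    if (length(grey) < 2L * config$min_cluster_size) break
    sub_dend <- hierarchical_cluster(diss[grey, grey])
    # the sweep digs for structure the main cut left behind, so it always
    # uses the most sensitive split level; kME refinement and the size
    # floor dissolve anything spurious it surfaces
    sub <- cut_tree_dynamic(sub_dend, config$min_cluster_size,
                            deep_split = 3)
    if (!any(sub > 0L)) break
    cand <- labels
    cand[names(sub)[sub > 0L]] <- max(labels) + sub[sub > 0L]
    cand <- refine_modules(x, cand, config$min_kme, config$min_cluster_size)
    cand <- merge_similar_modules(x, cand, config$merge_similarity)
    if (length(unique(cand[cand > 0L])) <= length(unique(labels[labels > 0L]))) break
    note("residual sweep ", sweep, ": modules ",
         length(unique(labels[labels > 0L])), " -> ",
         length(unique(cand[cand > 0L])))
    labels <- cand
  }
  # every filtered gene appears exactly once; genes dropped from the
  # hypergraph but adopted by refinement keep their refined label
  full <- stats::setNames(rep(0L, nrow(x)), rownames(x))
  full[names(labels)] <- labels
  labels <- full
  note("final modules: ", length(unique(labels[labels > 0])),
       "; grey genes: ", sum(labels == 0))

  eigengenes <- NULL
  hubs <- NULL
  module_trait <- NULL
  if (any(labels > 0)) {
    eigengenes <- module_eigengenes(x, labels)
    hubs <- hub_genes(x, labels, eigengenes, config$top_k)
    if (!is.null(traits)) {
      module_trait <- module_trait_correlation(eigengenes, traits)
    }
  }

  structure(list(expression = x, hypergraph = hg, scan = scan, beta = beta,
                 laplacians = lap, tom = tm, diss = diss, dendrogram = dend,
                 labels = labels, eigengenes = eigengenes, hubs = hubs,
                 module_trait = module_trait, config = config, log = log),
            class = "wgchna_fit")
}

#' @export
print.wgchna_fit <- function(x, ...) {
  cat("Weighted gene co-expression hypernetwork fit\n")
  for (line in x$log) cat(" -", line, "\n")
  invisible(x)
}
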