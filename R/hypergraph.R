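#' Construct a weighted hypergraph object
#'
#' Low-level constructor; validates the incidence structure. Every hyperedge
#' must contain at least two nodes, every node must belong to at least one
#' hyperedge, and weights must be finite and nonnegative.
#'
#' @param incidence Binary genes x hyperedges matrix.
#' @param edge_weights Nonnegative weight per hyperedge.
#' @param node_ids,edge_ids Identifiers (default taken from dimnames).
#' @return Object of class `weighted_hypergraph` with fields `incidence`,
#'   `edge_weights`, `node_ids`, `edge_ids`.
#' @export
weighted_hypergraph <- function(incidence, edge_weights = rep(1, ncol(incidence)),
                                node_ids = rownames(incidence),
                                edge_ids = colnames(incidence)) {
  incidence <- as.matrix(incidence)
  storage.mode(incidence) <- "double"
  if (!all(incidence %in% c(0, 1))) stop("incidence must be binary")
  if (is.null(node_ids)) node_ids <- paste0("v", seq_len(nrow(incidence)))
  if (is.null(edge_ids)) edge_ids <- paste0("e", seq_len(ncol(incidence)))
  check_duplicates(node_ids, "node identifier")
  check_duplicates(edge_ids, "edge identifier")
  if (length(edge_weights) != ncol(incidence)) stop("one weight per hyperedge required")
  if (any(!is.finite(edge_weights)) || any(edge_weights < 0)) {
    stop("edge weights must be finite and nonnegative")
  }
  if (any(colSums(incidence) < 2)) stop("every hyperedge must contain >= 2 nodes")
  if (any(rowSums(incidence) == 0)) stop("isolated node(s) present")
  dimnames(incidence) <- list(node_ids, edge_ids)
  structure(list(incidence = incidence,
                 edge_weights = stats::setNames(as.numeric(edge_weights), edge_ids),
                 node_ids = node_ids, edge_ids = edge_ids),
            class = "weighted_hypergraph")
}

#' @export
print.weighted_hypergraph <- function(x, ...) {
  cat("Weighted hypergraph:", length(x$node_ids), "nodes,",
      length(x$edge_ids), "hyperedges\n")
  cat("  edge degrees:", paste(range(edge_degrees(x)), collapse = "-"),
      " total edge weight:", sum(x$edge_weights), "\n")
  invisible(x)
}

#' Build hypergraph incidence from standardized expression
#'
#' One hyperedge per sample. Gene v belongs to the hyperedge of sample s iff
#' `|z_vs| >= tau`, i.e. the gene is expressed at least `tau` standard
#' deviations away from its own mean in that sample. With `tau = 0` every
#' gene joins every hyperedge (the degenerate all-ones incidence).
#' Hyperedges with fewer than two member genes are dropped with a warning,
#' as are genes left in no surviving hyperedge.
#'
#' @param z Standardized genes x samples matrix (see [standardize_genes()]).
#' @param tau Membership threshold on `|z|`, `>= 0`. Default 1.
#' @return A [weighted_hypergraph()] with all edge weights initialized to 1.
#' @export
build_incidence <- function(z, tau = 1) {
  check_expression(z)
  stopifnot(tau >= 0)
  m <- rowMeans(z)
  s <- rowMeans(z^2) - m^2
  if (max(abs(m)) > 1e-6 || max(abs(s - 1)) > 1e-4) {
    stop("input to build_incidence must be standardized per gene")
  }
  h <- (abs(z) >= tau) * 1
  de <- colSums(h)
  drop_e <- de < 2
  if (all(drop_e)) stop("all hyperedges have < 2 members; use a smaller tau")
  if (any(drop_e)) {
    warning(sum(drop_e), " hyperedge(s) with < 2 member genes dropped")
    h <- h[, !drop_e, drop = FALSE]
  }
  drop_v <- rowSums(h) == 0
  if (any(drop_v)) {
    warning(sum(drop_v), " gene(s) in no surviving hyperedge dropped")
    h <- h[!drop_v, , drop = FALSE]
  }
  weighted_hypergraph(h)
}

#' Correlation-based hyperedge weights
#'
#' For each hyperedge e, the weight is the mean over unordered gene pairs
#' within e of `|corr(g_i, g_j)|^beta`, with the correlation computed across
#' all samples. The genes x genes correlation matrix is computed once and
#' reused for every hyperedge, so weights lie in `[0, 1]`.
#'
#' @param x Complete genes x samples expression matrix covering the
#'   hypergraph's nodes (extra genes/samples are ignored).
#' @param hg A [weighted_hypergraph()] built from `x`.
#' @param beta Soft-threshold exponent on the absolute correlation, `>= 1`.
#' @param method Correlation flavour, `"pearson"` (default) or `"spearman"`.
#' @return `hg` with `edge_weights` replaced by the correlation weights.
#' @export
hyperedge_weights_corr <- function(x, hg, beta = 6, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(hg, "weighted_hypergraph"), beta >= 1)
  x <- align_to_nodes(x, hg)
  cmat <- abs(stats::cor(t(x), method = method))^beta
  w <- edge_pair_means(hg$incidence, cmat)
  hg$edge_weights <- stats::setNames(w, hg$edge_ids)
  hg
}

#' Mutual-information-based hyperedge weights
#'
#' For each hyperedge, the mean over member gene pairs of the plug-in mutual
#' information (in nats) between the two genes' expression, estimated by
#' equal-width binning of each gene's values across all samples.
#'
#' @inheritParams hyperedge_weights_corr
#' @param bins Number of equal-width bins per gene, `>= 2`.
#' @return Numeric vector of weights, one per hyperedge (named by edge id).
#' @export
hyperedge_weights_mi <- function(x, hg, bins = 8) {
  stopifnot(inherits(hg, "weighted_hypergraph"), bins >= 2)
  x <- align_to_nodes(x, hg)
  mi <- pairwise_mi(x, bins)
  stats::setNames(edge_pair_means(hg$incidence, mi), hg$edge_ids)
}

#' Compare correlation- and mutual-information-based hyperedge weights
#'
#' Computes both weight vectors on the same hypergraph and their Spearman
#' rank correlation with a two-sided (asymptotic) p-value. A constant weight
#' vector makes the rank correlation undefined; `NA` is reported rather
#' than 0.
#'
#' @inheritParams hyperedge_weights_corr
#' @param bins Bins for the mutual-information estimate.
#' @return Object of class `hyperedge_weight_report`: list with
#'   `corr_weights`, `mi_weights`, `spearman_rho`, `spearman_p`.
#' @export
compare_weight_schemes <- function(x, hg, beta = 6, bins = 8) {
  stopifnot(inherits(hg, "weighted_hypergraph"))
  if (length(hg$edge_ids) < 5) stop("need >= 5 hyperedges to compare weight schemes")
  cw <- hyperedge_weights_corr(x, hg, beta)$edge_weights
  mw <- hyperedge_weights_mi(x, hg, bins)
  sp <- spearman_safe(cw, mw)
  structure(list(corr_weights = cw, mi_weights = mw,
                 spearman_rho = sp$rho, spearman_p = sp$p),
            class = "hyperedge_weight_report")
}

#' @export
print.hyperedge_weight_report <- function(x, ...) {
  cat("Hyperedge weight comparison over", length(x$corr_weights), "hyperedges\n")
  cat(sprintf("  Spearman rho = %.3f (p = %.3g)\n", x$spearman_rho, x$spearman_p))
  invisible(x)
}

#' Weighted node hyperdegrees
#'
#' `d(v) = sum_e W_e h(v, e)`; the diagonal of the node-degree matrix of the
#' hypergraph Laplacian.
#'
#' @param hg A [weighted_hypergraph()].
#' @return Named numeric vector over nodes.
#' @export
node_hyperdegrees <- function(hg) {
  stopifnot(inherits(hg, "weighted_hypergraph"))
  stats::setNames(as.vector(hg$incidence %*% hg$edge_weights), hg$node_ids)
}

#' Hyperedge degrees
#'
#' `delta(e)`: the number of member genes of each hyperedge.
#'
#' @param hg A [weighted_hypergraph()].
#' @return Named numeric vector over hyperedges.
#' @export
edge_degrees <- function(hg) {
  stopifnot(inherits(hg, "weighted_hypergraph"))
  colSums(hg$incidence)
}

#' A small worked example hypergraph
#'
#' Seven gene nodes and four sample hyperedges:
#' e1 = \{v1, v2, v3\}, e2 = \{v3, v5\}, e3 = \{v5, v6\}, e4 = \{v4, v7\},
#' with weights W = (3, 2, 2, 2). Useful as a fixture: it has two connected
#' components (\{v1, v2, v3, v5, v6\} and \{v4, v7\}).
#'
#' @return A [weighted_hypergraph()].
#' @export
toy_hypergraph <- function() {
  nodes <- paste0("v", 1:7)
  edges <- list(e1 = c("v1", "v2", "v3"), e2 = c("v3", "v5"),
                e3 = c("v5", "v6"), e4 = c("v4", "v7"))
  h <- sapply(edges, function(e) as.numeric(nodes %in% e))
  rownames(h) <- nodes
  weighted_hypergraph(h, edge_weights = c(3, 2, 2, 2))
}

#' Serialize a hypergraph as TSV edge list plus weight table
#'
#' @param hg A [weighted_hypergraph()].
#' @param edges_path Path for the (edge_id, node_id) membership TSV.
#' @param weights_path Path for the (edge_id, weight) TSV.
#' @export
write_hypergraph <- function(hg, edges_path, weights_path) {
  stopifnot(inherits(hg, "weighted_hypergraph"))
  pairs <- which(hg$incidence == 1, arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 2L], pairs[, 1L]), , drop = FALSE]
  writeLines(c("edge_id\tnode_id",
               paste(hg$edge_ids[pairs[, 2L]], hg$node_ids[pairs[, 1L]], sep = "\t")),
             edges_path)
  writeLines(c("edge_id\tweight",
               paste(hg$edge_ids, sprintf("%.17g", hg$edge_weights), sep = "\t")),
             weights_path)
  invisible(c(edges_path, weights_path))
}

#' Read a hypergraph written by [write_hypergraph()]
#'
#' Node order follows first appearance in the edge list; edge order follows
#' the weight table.
#'
#' @param edges_path,weights_path Paths written by [write_hypergraph()].
#' @return A [weighted_hypergraph()].
#' @export
read_hypergraph <- function(edges_path, weights_path) {
  el <- utils::read.table(edges_path, header = TRUE, sep = "\t",
                          colClasses = "character")
  wt <- utils::read.table(weights_path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric"))
  nodes <- unique(el$node_id)
  edges <- wt$edge_id
  h <- matrix(0, length(nodes), length(edges), dimnames = list(nodes, edges))
  h[cbind(match(el$node_id, nodes), match(el$edge_id, edges))] <- 1
  weighted_hypergraph(h, edge_weights = wt$weight)
}

# ---- internal helpers -------------------------------------------------------

align_to_nodes <- function(x, hg) {
  check_expression(x)
  if (anyNA(x)) stop("expression matrix must be complete; impute first")
  missing_nodes <- setdiff(hg$node_ids, rownames(x))
  if (length(missing_nodes)) {
    stop("expression matrix lacks hypergraph node(s): ",
         paste(utils::head(missing_nodes, 5), collapse = ", "))
  }
  x[hg$node_ids, , drop = FALSE]
}

# Mean over unordered within-edge gene pairs of a symmetric gene x gene
# score matrix. Uses diag(H' S H) = sum_{i,j in e} S_ij; the diagonal of S
# is excluded by zeroing it first.
edge_pair_means <- function(h, smat) {
  de <- colSums(h)
  if (any(de < 2)) stop("hyperedge with no gene pair")
  diag_backup <- diag(smat)
  diag(smat) <- 0
  tot <- colSums(h * (smat %*% h))
  diag(smat) <- diag_backup
  tot / (de * (de - 1))
}

# Plug-in pairwise mutual information (nats) on equal-width bins.
pairwise_mi <- function(x, bins = 8) {
  rng <- apply(x, 1L, range)
  if (any(rng[1L, ] == rng[2L, ])) {
    stop("constant gene(s), binning undefined: ",
         paste(rownames(x)[rng[1L, ] == rng[2L, ]], collapse = ", "))
  }
  n <- nrow(x)
  s <- ncol(x)
  b <- matrix(0L, n, s, dimnames = dimnames(x))
  for (i in seq_len(n)) {
    br <- seq(rng[1L, i], rng[2L, i], length.out = bins + 1L)
    b[i, ] <- pmin(pmax(findInterval(x[i, ], br, rightmost.closed = TRUE), 1L), bins)
  }
  mi <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1L)) {
    off_i <- (b[i, ] - 1L) * bins
    for (j in (i + 1L):n) {
      joint <- tabulate(off_i + b[j, ], nbins = bins * bins) / s
      pm <- matrix(joint, bins, bins)
      pi_ <- rowSums(pm)
      pj_ <- colSums(pm)
      nz <- pm > 0
      mi[i, j] <- mi[j, i] <- sum(pm[nz] * log(pm[nz] / outer(pi_, pj_)[nz]))
    }
  }
  # self-information (gene entropy) on the diagonal, handy for diagnostics
  for (i in seq_len(n)) {
    p <- tabulate(b[i, ], nbins = bins) / s
    p <- p[p > 0]
    mi[i, i] <- -sum(p * log(p))
  }
  mi
}

spearman_safe <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
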