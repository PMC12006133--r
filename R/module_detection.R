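#' Average-linkage hierarchical clustering of a TOM dissimilarity
#'
#' Thin, validated wrapper around [stats::hclust()]: checks that the input
#' is a finite, symmetric dissimilarity with a zero diagonal before
#' clustering.
#'
#' @param diss Symmetric genes x genes dissimilarity (e.g. [diss_tom()]).
#' @param linkage Agglomeration method (default `"average"`, the UPGMA
#'   linkage conventional for TOM-based module detection).
#' @return An [stats::hclust] dendrogram; leaf labels are the gene ids.
#' @export
hierarchical_cluster <- function(diss, linkage = "average") {
  if (!is.matrix(diss) || !is.numeric(diss)) stop("diss must be a numeric matrix")
  if (any(!is.finite(diss))) stop("non-finite dissimilarities")
  if (nrow(diss) != ncol(diss) || max(abs(diss - t(diss))) > 1e-12) {
    stop("diss must be symmetric")
  }
  if (any(diag(diss) != 0)) stop("diss must have a zero diagonal")
  stats::hclust(stats::as.dist(diss), method = linkage)
}

#' Dynamic branch cut of a dendrogram
#'
#' Identifies co-expression modules as dendrogram branches that are both
#' large enough and clearly separated from their surroundings. An internal
#' node is a candidate module when
#' \itemize{
#'   \item its leaf count is at least `min_cluster_size`,
#'   \item it spans at most 90\% of all leaves (a "module" containing
#'     essentially every gene carries no partition information), and
#'   \item its join gap — the height at which the branch merges into its
#'     parent minus the branch's own top merge height — is at least
#'     `gap_frac` times the total spread of merge heights, where `gap_frac`
#'     is mapped from `deep_split` 0..3 as 0.100, 0.075, 0.050, 0.025.
#' }
#' Candidates are accepted greedily in order of decreasing join gap,
#' skipping any candidate that overlaps an accepted one, so nested branches
#' resolve to the most clearly separated representative. Leaves in no
#' accepted branch get the unassigned label 0 ("grey"). Larger `deep_split`
#' relaxes the gap requirement and therefore never yields fewer modules.
#'
#' @param dend An [stats::hclust] dendrogram (see [hierarchical_cluster()]).
#' @param min_cluster_size Minimum module size (default 50).
#' @param deep_split Split sensitivity, integer 0..3 (default 2).
#' @return Named integer vector of labels (0 = unassigned); modules are
#'   numbered 1, 2, ... by decreasing size.
#' @export
cut_tree_dynamic <- function(dend, min_cluster_size = 50, deep_split = 2) {
  stopifnot(inherits(dend, "hclust"), min_cluster_size >= 1,
            deep_split %in% 0:3)
  n <- length(dend$order)
  if (n < min_cluster_size) stop("dendrogram has fewer leaves than min_cluster_size")
  gap_frac <- c(0.100, 0.075, 0.050, 0.025)[deep_split + 1L]
  nm <- nrow(dend$merge)

  members <- vector("list", nm)
  for (i in seq_len(nm)) {
    a <- dend$merge[i, 1L]
    b <- dend$merge[i, 2L]
    members[[i]] <- c(if (a < 0) -a else members[[a]],
                      if (b < 0) -b else members[[b]])
  }
  parent <- rep(NA_integer_, nm)
  for (i in seq_len(nm)) {
    for (j in dend$merge[i, ]) if (j > 0) parent[j] <- i
  }
  gap <- ifelse(is.na(parent), NA_real_, dend$height[parent] - dend$height)
  spread <- max(dend$height) - min(dend$height)
  sizes <- lengths(members)

  lab <- rep(0L, n)
  if (spread > 0) {
    cand <- which(sizes >= min_cluster_size & sizes <= 0.9 * n &
                    !is.na(gap) & gap >= gap_frac * spread)
    cand <- cand[order(-gap[cand], -sizes[cand], cand)]
    nxt <- 1L
    for (i in cand) {
      m <- members[[i]]
      if (any(lab[m] != 0L)) next  # overlaps an accepted branch
      lab[m] <- nxt
      nxt <- nxt + 1L
    }
  }
  names(lab) <- dend$labels %||% as.character(seq_len(n))
  renumber_modules(lab)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first right singular vector of its
#' standardized genes x samples submatrix: one representative expression
#' score per sample. The sign is oriented so the eigengene correlates
#' nonnegatively with the module's mean standardized profile, removing the
#' SVD sign ambiguity. A single-gene module's eigengene is that gene's
#' standardized profile.
#'
#' @param x Complete genes x samples expression matrix.
#' @param labels Named integer labels over the genes of `x` (0 = grey).
#' @return Samples x modules matrix; columns named `ME<label>` in
#'   increasing label order. Grey is excluded.
#' @export
module_eigengenes <- function(x, labels) {
  check_expression(x)
  labels <- align_labels(labels, x)
  mods <- sort(unique(labels[labels > 0L]))
  if (!length(mods)) stop("no non-grey module to summarize")
  me <- vapply(mods, function(m) {
    z <- standardize_genes(x[names(labels)[labels == m], , drop = FALSE])
    if (nrow(z) == 1L) return(as.vector(z))
    v <- svd(z, nu = 0L, nv = 1L)$v[, 1L]
    orient_eigengene(v, colMeans(z))
  }, numeric(ncol(x)))
  dimnames(me) <- list(colnames(x), paste0("ME", mods))
  me
}

#' Merge modules with correlated eigengenes
#'
#' Iteratively merges the pair of modules whose eigengenes have the highest
#' Pearson correlation, as long as that correlation strictly exceeds
#' `merge_similarity`; eigengenes are recomputed after every merge. The
#' merged pair keeps the label of the larger module (smaller label on size
#' ties). Terminates because each merge reduces the module count.
#'
#' @param x Complete genes x samples expression matrix.
#' @param labels Named integer labels (0 = grey).
#' @param merge_similarity Eigengene correlation above which modules merge
#'   (default 0.8, i.e. "more than 80\% similar").
#' @return Updated labels, renumbered by decreasing module size.
#' @export
merge_similar_modules <- function(x, labels, merge_similarity = 0.8) {
  check_expression(x)
  labels <- align_labels(labels, x)
  stopifnot(merge_similarity >= 0, merge_similarity <= 1)
  repeat {
    mods <- sort(unique(labels[labels > 0L]))
    if (length(mods) < 2L) break
    me <- module_eigengenes(x, labels)
    cc <- stats::cor(me)
    cc[!upper.tri(cc)] <- -Inf
    best <- max(cc)
    if (!(best > merge_similarity)) break
    idx <- which(cc == best, arr.ind = TRUE)[1L, ]  # first pair, deterministic
    pair <- mods[c(idx[["row"]], idx[["col"]])]
    sz <- c(sum(labels == pair[1L]), sum(labels == pair[2L]))
    winner <- if (sz[1L] > sz[2L]) pair[1L] else if (sz[2L] > sz[1L]) pair[2L]
              else min(pair)
    loser <- setdiff(pair, winner)
    labels[labels == loser] <- winner
  }
  renumber_modules(labels)
}

#' Refine module membership by eigengene correlation
#'
#' Recomputes module eigengenes and reassigns every gene to the module whose
#' eigengene it correlates with most strongly (its kME), provided
#' `|kME| >= min_kme`; genes below the threshold become grey, and modules
#' that fall below `min_cluster_size` dissolve. Iterates to a fixed point
#' (at most `max_iter` rounds). This sharpens branch-cut clusters: loosely
#' attached background genes fall out, and stray members of a module are
#' pulled back in.
#'
#' @param x Complete genes x samples expression matrix.
#' @param labels Named integer labels (0 = grey).
#' @param min_kme Minimum absolute eigengene correlation for membership
#'   (default 0.5).
#' @param min_cluster_size Modules smaller than this dissolve (default 50).
#' @param max_iter Iteration cap (default 10).
#' @return Updated labels, renumbered by decreasing module size.
#' @export
refine_modules <- function(x, labels, min_kme = 0.5, min_cluster_size = 50,
                           max_iter = 10) {
  check_expression(x)
  labels <- align_labels(labels, x)
  for (it in seq_len(max_iter)) {
    mods <- sort(unique(labels[labels > 0L]))
    if (!length(mods)) break
    me <- module_eigengenes(x, labels)
    kme <- stats::cor(t(x), me)
    new <- apply(kme, 1L, function(r) {
      j <- which.max(abs(r))
      if (abs(r[j]) >= min_kme) mods[j] else 0L
    })
    new <- as.integer(new)
    names(new) <- rownames(x)
    sz <- table(new[new > 0L])
    dissolve <- as.integer(names(sz)[sz < min_cluster_size])
    new[new %in% dissolve] <- 0L
    if (identical(new, labels)) break
    labels <- new
  }
  renumber_modules(labels)
}

#' Deterministic module colors
#'
#' Maps module labels to the conventional co-expression palette: 0 is
#' "grey", positive labels walk a fixed ordered color list (falling back to
#' `module<k>` beyond it).
#'
#' @param labels Integer module labels.
#' @return Character vector of colors, same length/names as `labels`.
#' @export
module_colors <- function(labels) {
  palette <- c("turquoise", "blue", "brown", "yellow", "green", "red",
               "black", "pink", "magenta", "purple", "greenyellow", "tan",
               "salmon", "cyan", "midnightblue", "lightcyan", "grey60",
               "lightgreen", "lightyellow", "royalblue", "darkred",
               "darkgreen", "darkturquoise", "darkgrey", "orange")
  out <- ifelse(labels == 0L, "grey",
                ifelse(labels <= length(palette), palette[pmax(labels, 1L)],
                       paste0("module", labels)))
  names(out) <- names(labels)
  out
}

# ---- internal helpers -------------------------------------------------------

# Renumber non-grey modules 1..k by decreasing size; ties keep the smaller
# original label first.
renumber_modules <- function(labels) {
  mods <- sort(unique(labels[labels > 0L]))
  if (!length(mods)) return(labels)
  sz <- vapply(mods, function(m) sum(labels == m), integer(1))
  ord <- mods[order(-sz, mods)]
  out <- labels
  for (r in seq_along(ord)) out[labels == ord[r]] <- r
  out
}

align_labels <- function(labels, x) {
  nm <- names(labels)
  if (is.null(nm)) {
    if (length(labels) != nrow(x)) stop("labels do not match the gene set")
    nm <- rownames(x)
  } else if (!all(nm %in% rownames(x))) {
    stop("labels name genes absent from the expression matrix")
  }
  out <- as.integer(labels)
  names(out) <- nm
  out
}

# Fix SVD sign: align with the module mean profile; fall back to making the
# first nonzero coordinate positive when the correlation is degenerate.
orient_eigengene <- function(v, mean_profile) {
  s <- stats::sd(mean_profile)
  if (s > 0 && stats::sd(v) > 0) {
    r <- stats::cor(v, mean_profile)
    if (!is.na(r) && r < 0) return(-v)
    if (!is.na(r) && r > 0) return(v)
  }
  nz <- which(v != 0)
  if (length(nz) && v[nz[1L]] < 0) -v else v
}
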