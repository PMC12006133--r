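#' Internal clustering quality metrics (SI, CHI, DBI)
#'
#' Standard internal cluster-validity indices on a feature matrix
#' (typically each gene's row of the TOM matrix, so that the metrics judge
#' the structure the clustering was computed on; expression rows work too):
#' \itemize{
#'   \item silhouette index: mean silhouette width with Euclidean distance
#'     (singleton clusters contribute 0),
#'   \item Calinski-Harabasz index: between/within variance ratio
#'     `(B/(k-1)) / (W/(n-k))`,
#'   \item Davies-Bouldin index: average over clusters of the worst pair
#'     ratio `(s_i + s_j) / d(c_i, c_j)` (lower is better).
#' }
#' Genes labelled 0 (grey) are excluded.
#'
#' @param features Genes x feature numeric matrix.
#' @param labels Integer labels aligned with the rows of `features`.
#' @return List with `si`, `chi`, `dbi`, `n_clusters`, `n_used`. All three
#'   indices are `NA` when fewer than 2 non-grey clusters exist.
#' @export
internal_metrics <- function(features, labels) {
  if (!is.matrix(features)) stop("features must be a matrix")
  if (length(labels) != nrow(features)) stop("labels do not match features")
  keep <- labels > 0L
  f <- features[keep, , drop = FALSE]
  l <- as.integer(labels[keep])
  k <- length(unique(l))
  if (k < 2L) {
    return(list(si = NA_real_, chi = NA_real_, dbi = NA_real_,
                n_clusters = k, n_used = nrow(f)))
  }
  n <- nrow(f)
  d <- as.matrix(stats::dist(f))
  # silhouette
  sil <- vapply(seq_len(n), function(i) {
    own <- l == l[i]
    if (sum(own) == 1L) return(0)
    a <- sum(d[i, own]) / (sum(own) - 1L)
    b <- min(vapply(setdiff(unique(l), l[i]),
                    function(cl) mean(d[i, l == cl]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  # centroid-based indices
  cls <- sort(unique(l))
  cen <- t(vapply(cls, function(cl) colMeans(f[l == cl, , drop = FALSE]),
                  numeric(ncol(f))))
  gmean <- colMeans(f)
  nc <- vapply(cls, function(cl) sum(l == cl), integer(1))
  bss <- sum(nc * rowSums((cen - matrix(gmean, k, ncol(f), byrow = TRUE))^2))
  wss <- sum(vapply(seq_along(cls), function(j) {
    sum(sweep(f[l == cls[j], , drop = FALSE], 2L, cen[j, ])^2)
  }, numeric(1)))
  chi <- if (wss > 0) (bss / (k - 1)) / (wss / (n - k)) else Inf
  scat <- vapply(seq_along(cls), function(j) {
    mean(sqrt(rowSums(sweep(f[l == cls[j], , drop = FALSE], 2L, cen[j, ])^2)))
  }, numeric(1))
  cd <- as.matrix(stats::dist(cen))
  rmat <- outer(scat, scat, `+`) / cd
  diag(rmat) <- -Inf
  dbi <- mean(apply(rmat, 1L, max))
  list(si = mean(sil), chi = chi, dbi = dbi, n_clusters = k, n_used = n)
}

#' External clustering agreement metrics (ARI, AMI)
#'
#' Chance-adjusted agreement between two labelings of the same genes:
#' adjusted Rand index via the permutation-model contingency formula, and
#' adjusted mutual information with the expected mutual information under
#' the hypergeometric model and max-entropy normalization,
#' `AMI = (MI - E[MI]) / (max(H_a, H_b) - E[MI])`.
#'
#' When both labelings consist of a single cluster each they are identical
#' partitions and both indices are 1 by convention; a single-cluster
#' labeling against a multi-cluster one yields `NA` (undefined).
#'
#' @param labels_a,labels_b Integer label vectors of equal length.
#' @return List with `ari`, `ami`.
#' @export
external_metrics <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("labelings differ in length")
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  a <- rowSums(tab)
  b <- colSums(tab)
  if (length(a) == 1L && length(b) == 1L) return(list(ari = 1, ami = 1))

  # --- adjusted Rand ---
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(a, 2))
  sum_b <- sum(choose(b, 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  ari <- if (max_index == expected) {
    if (sum_ij == max_index) 1 else NA_real_
  } else {
    (sum_ij - expected) / (max_index - expected)
  }

  # --- adjusted mutual information ---
  p <- tab / n
  pa <- a / n
  pb <- b / n
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  emi <- expected_mi(a, b, n)
  denom <- max(ha, hb) - emi
  ami <- if (abs(denom) < 1e-12) {
    if (abs(mi - emi) < 1e-12) 1 else NA_real_
  } else {
    (mi - emi) / denom
  }
  list(ari = ari, ami = ami)
}

# Expected mutual information of two labelings under the hypergeometric
# (fixed-margins permutation) model.
expected_mi <- function(a, b, n) {
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1L, ai + bj - n)
      hi <- min(ai, bj)
      if (lo > hi) next
      nij <- lo:hi
      lp <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(n - ai + 1) +
        lgamma(n - bj + 1) - lgamma(n + 1) - lgamma(nij + 1) -
        lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
        lgamma(n - ai - bj + nij + 1)
      emi <- emi + sum((nij / n) * log(n * nij / (ai * bj)) * exp(lp))
    }
  }
  emi
}
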