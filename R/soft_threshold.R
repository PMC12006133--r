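#' Signed scale-free fit index of a degree distribution
#'
#' Bins the degrees into `n_bins` equal-count (quantile) bins, estimates the
#' empirical density of each bin as `count / (n * bin width)`, and fits a
#' least-squares line of log10 density on log10 mean bin degree. Returns the
#' regression R^2 signed by `-sign(slope)`, so the index is positive exactly
#' when frequency decreases with degree (the scale-free direction).
#'
#' Quantile bins keep roughly equal occupancy, which is robust to the heavy
#' tails typical of scale-free degree distributions; the density (rather
#' than raw bin frequency) is what carries the power-law shape under this
#' binning, since raw equal-count frequencies are flat by construction.
#'
#' @param degrees Positive degree values (>= 10 of them).
#' @param n_bins Number of quantile bins, >= 3 (default 10).
#' @return Signed R^2 in `[-1, 1]`, or `NA` when fewer than 3 distinct
#'   nonempty bins exist (e.g. constant degrees).
#' @export
scale_free_fit <- function(degrees, n_bins = 10) {
  stopifnot(length(degrees) >= 10, n_bins >= 3, all(degrees > 0))
  br <- unique(stats::quantile(degrees, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 4L) return(NA_real_)
  bin <- cut(degrees, breaks = br, include.lowest = TRUE)
  kbar <- tapply(degrees, bin, mean)
  cnt <- tapply(degrees, bin, length)
  width <- diff(br)
  dens <- as.numeric(cnt) / (length(degrees) * width)
  ok <- !is.na(kbar) & !is.na(dens) & dens > 0 & kbar > 0
  if (sum(ok) < 3L || length(unique(kbar[ok])) < 3L) return(NA_real_)
  fit <- stats::lm(log10(dens[ok]) ~ log10(kbar[ok]))
  slope <- unname(stats::coef(fit)[2L])
  if (is.na(slope)) return(NA_real_)
  unname(-sign(slope) * summary(fit)$r.squared)
}

#' Scan soft-threshold exponents for scale-free topology
#'
#' For each candidate exponent beta, builds the sample hypergraph once
#' (membership threshold `tau` fixed), computes correlation-based hyperedge
#' weights with exponent beta, derives the weighted node hyperdegrees, and
#' records their signed scale-free fit index and mean.
#'
#' @param x Complete genes x samples expression matrix.
#' @param tau Hypergraph membership threshold (see [build_incidence()]).
#' @param betas Ordered candidate exponents (default 1:12).
#' @param n_bins Bins for [scale_free_fit()].
#' @param method Correlation flavour passed to [hyperedge_weights_corr()].
#' @return Data frame of class `soft_threshold_scan` with columns `beta`,
#'   `r_squared`, `mean_degree`.
#' @export
scan_beta <- function(x, tau = 1, betas = 1:12, n_bins = 10,
                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(betas) >= 1)
  check_expression(x)
  if (anyNA(x)) stop("expression matrix must be complete; impute first")
  z <- standardize_genes(x)
  hg <- build_incidence(z, tau)
  xs <- x[hg$node_ids, , drop = FALSE]
  cmat <- abs(stats::cor(t(xs), method = method))
  h <- hg$incidence
  res <- vapply(betas, function(beta) {
    w <- edge_pair_means(h, cmat^beta)
    d <- as.vector(h %*% w)
    c(scale_free_fit(d, n_bins), mean(d))
  }, numeric(2))
  out <- data.frame(beta = betas, r_squared = res[1L, ], mean_degree = res[2L, ])
  class(out) <- c("soft_threshold_scan", "data.frame")
  out
}

#' Select the soft threshold from a scan
#'
#' Returns the smallest beta whose signed scale-free R^2 reaches `r2_cut`
#' (inclusive). When no beta qualifies but the scan is still informative
#' (best signed R^2 at least `r2_floor`), the beta maximizing the signed
#' R^2 is returned with `below_cut = TRUE`. When even the best R^2 falls
#' below `r2_floor` the fit index carries no signal and its argmax is
#' noise; the conventional unsigned-network default exponent
#' (`fallback_beta`, nearest available candidate) is returned instead,
#' also flagged `below_cut`.
#'
#' @param scan A [scan_beta()] result.
#' @param r2_cut Signed R^2 required for acceptance (default 0.8).
#' @param r2_floor Minimum best R^2 for the argmax fallback to be
#'   meaningful (default 0.3).
#' @param fallback_beta Exponent used when the scan is uninformative
#'   (default 6, the customary unsigned co-expression default).
#' @return List with `beta`, `r_squared`, `below_cut`.
#' @export
pick_beta <- function(scan, r2_cut = 0.8, r2_floor = 0.3, fallback_beta = 6) {
  stopifnot(inherits(scan, "soft_threshold_scan") || is.data.frame(scan))
  r2 <- scan$r_squared
  if (all(is.na(r2))) stop("scale-free fit undefined for every candidate beta")
  hit <- which(!is.na(r2) & r2 >= r2_cut)
  if (length(hit)) {
    i <- hit[1L]
    below <- FALSE
  } else {
    below <- TRUE
    i <- if (max(r2, na.rm = TRUE) >= r2_floor) {
      which.max(r2)
    } else {
      which.min(abs(scan$beta - fallback_beta))
    }
  }
  list(beta = scan$beta[i], r_squared = r2[i], below_cut = below)
}
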