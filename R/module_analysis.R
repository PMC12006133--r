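#' Module-trait correlation with p-values
#'
#' Pearson correlation between each module eigengene and each (encoded,
#' numeric) trait column, with two-sided p-values from the Student-t
#' transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom. A Benjamini-Hochberg adjusted p-value matrix is also returned;
#' no correction is applied to the primary p-values.
#'
#' @param me Samples x modules eigengene matrix (see [module_eigengenes()]).
#' @param traits Samples x traits numeric matrix (see [read_traits()]),
#'   sample-aligned with `me` (matched by rownames when present).
#' @return Object of class `module_trait_result`: list of matrices `r`,
#'   `p`, `p_adj` (modules x traits). Zero-variance trait columns yield
#'   `NA` columns with a warning.
#' @export
module_trait_correlation <- function(me, traits) {
  if (!is.matrix(me) || !is.matrix(traits)) stop("me and traits must be matrices")
  if (!is.null(rownames(me)) && !is.null(rownames(traits))) {
    if (!setequal(rownames(me), rownames(traits))) {
      stop("sample sets of eigengenes and traits differ")
    }
    traits <- traits[rownames(me), , drop = FALSE]
  } else if (nrow(me) != nrow(traits)) {
    stop("eigengenes and traits have different sample counts")
  }
  n <- nrow(me)
  if (n < 3L) stop("need >= 3 samples for module-trait correlation")
  const <- apply(traits, 2L, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("zero-variance trait column(s): ",
            paste(colnames(traits)[const], collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(me, traits))
  r[, const] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[!is.na(r) & abs(r) >= 1] <- 0  # |r| = 1 -> infinite t
  p_adj <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p),
                  dimnames = dimnames(p))
  structure(list(r = r, p = p, p_adj = p_adj), class = "module_trait_result")
}

#' @export
print.module_trait_result <- function(x, ...) {
  cat("Module-trait correlations (", nrow(x$r), " modules x ",
      ncol(x$r), " traits)\n", sep = "")
  print(round(x$r, 3))
  invisible(x)
}

#' Hub genes by module membership (kME)
#'
#' kME of a gene is the Pearson correlation of its expression profile with
#' its own module's eigengene. Within each module, genes are ranked by
#' decreasing |kME| (ties broken by gene order) and the top `top_k` are
#' returned.
#'
#' @param x Complete genes x samples expression matrix.
#' @param labels Named integer module labels (0 = grey, excluded).
#' @param me Samples x modules eigengene matrix matching `labels`.
#' @param top_k Genes reported per module (all genes if the module is
#'   smaller).
#' @return Data frame with columns `module`, `gene`, `kme`, `rank`.
#' @export
hub_genes <- function(x, labels, me, top_k = 10) {
  check_expression(x)
  labels <- align_labels(labels, x)
  mods <- sort(unique(labels[labels > 0L]))
  cols <- paste0("ME", mods)
  if (!all(cols %in% colnames(me))) stop("eigengene matrix does not match labels")
  out <- lapply(mods, function(m) {
    genes <- names(labels)[labels == m]
    kme <- as.vector(stats::cor(t(x[genes, , drop = FALSE]), me[, paste0("ME", m)]))
    ord <- order(-abs(kme), seq_along(kme))
    take <- utils::head(ord, top_k)
    data.frame(module = m, gene = genes[take], kme = kme[take],
               rank = seq_along(take))
  })
  do.call(rbind, out)
}

#' Export module gene lists (GMT plus per-module text files)
#'
#' Writes one GMT file with a line per non-grey module
#' (`module_<label><TAB>description<TAB>gene...`) and one plain-text gene
#' list per module. Grey genes are excluded.
#'
#' @param labels Named integer module labels.
#' @param dir Output directory (created if absent).
#' @param gmt_name Filename for the GMT (default `"modules.gmt"`).
#' @return Invisibly, the paths written.
#' @export
export_module_gene_lists <- function(labels, dir, gmt_name = "modules.gmt") {
  if (is.null(names(labels))) stop("labels must be named by gene id")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mods <- sort(unique(labels[labels > 0L]))
  if (!length(mods)) stop("no non-grey module to export")
  gmt_path <- file.path(dir, gmt_name)
  lines <- vapply(mods, function(m) {
    genes <- names(labels)[labels == m]
    paste(c(paste0("module_", m), paste0("co-expression module ", m), genes),
          collapse = "\t")
  }, character(1))
  writeLines(lines, gmt_path)
  list_paths <- vapply(mods, function(m) {
    p <- file.path(dir, paste0("module_", m, "_genes.txt"))
    writeLines(names(labels)[labels == m], p)
    p
  }, character(1))
  invisible(c(gmt_path, list_paths))
}

#' Read a GMT gene-set file
#'
#' @param path Path to a GMT file (set name, description, then gene ids,
#'   tab-separated).
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[`, character(1), 1L))
}
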