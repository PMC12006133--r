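#' Hypergraph Laplacians and the derived gene-gene affinity
#'
#' Computes, for a weighted hypergraph with incidence H, edge weights W,
#' edge degrees De and weighted node hyperdegrees Dv:
#' \itemize{
#'   \item the unnormalized Laplacian `Dv - H W De^-1 H'` (rows sum to zero),
#'   \item the normalized Laplacian
#'     `I - Dv^-1/2 H W De^-1 H' Dv^-1/2` (symmetric, eigenvalues in `[0, 1]`),
#'   \item the affinity `A = Dv^-1/2 H W De^-1 H' Dv^-1/2` with its diagonal
#'     zeroed; `A` equals `I -` normalized Laplacian off the diagonal and its
#'     entries lie in `[0, 1]`.
#' }
#' Using the weighted hyperdegree `d(v) = sum_e W_e h(v,e)` as the diagonal
#' of Dv is what makes the unnormalized rows sum to zero exactly.
#'
#' @param hg A [weighted_hypergraph()] with weights set.
#' @return Object of class `laplacian_set`: list with `unnormalized`,
#'   `normalized`, `affinity`, `hyperdegrees`, `node_ids`.
#' @export
hypergraph_laplacians <- function(hg) {
  stopifnot(inherits(hg, "weighted_hypergraph"))
  h <- hg$incidence
  w <- hg$edge_weights
  de <- colSums(h)
  dv <- as.vector(h %*% w)
  if (any(dv <= 0)) {
    stop("zero weighted hyperdegree for node(s): ",
         paste(hg$node_ids[dv <= 0], collapse = ", "))
  }
  hw <- sweep(h, 2L, w / de, `*`)
  m <- hw %*% t(h)
  m <- (m + t(m)) / 2  # symmetrize against rounding
  lu <- -m
  diag(lu) <- diag(lu) + dv
  s <- 1 / sqrt(dv)
  an <- m * outer(s, s)
  ln <- -an
  diag(ln) <- diag(ln) + 1
  a <- an
  diag(a) <- 0
  dn <- list(hg$node_ids, hg$node_ids)
  dimnames(lu) <- dimnames(ln) <- dimnames(a) <- dn
  structure(list(unnormalized = lu, normalized = ln, affinity = a,
                 hyperdegrees = stats::setNames(dv, hg$node_ids),
                 node_ids = hg$node_ids),
            class = "laplacian_set")
}

#' Topological overlap matrix from the hypergraph affinity
#'
#' For genes i != j,
#' `TOM_ij = (A_ij + sum_{k != i,j} A_ik A_kj) / (min(d_i, d_j) + 1 - A_ij)`
#' with `d_i = sum_{j != i} A_ij`, and `TOM_ii = 1`. The affinity A (the
#' nonnegative off-diagonal part of `I -` normalized Laplacian) plays the
#' role of the network adjacency: normalized-Laplacian off-diagonals
#' themselves are nonpositive, so they cannot serve directly as a
#' similarity. Entries are clamped to `[0, 1]`; the number of clamped
#' entries is recorded.
#'
#' @param lap A [hypergraph_laplacians()] result.
#' @return Object of class `tom_matrix`: list with `tom` (symmetric, unit
#'   diagonal), `degrees` (the affinity row sums) and `n_clamped`.
#' @export
tom_matrix <- function(lap) {
  stopifnot(inherits(lap, "laplacian_set"))
  a <- lap$affinity
  d <- rowSums(a)
  num <- a + a %*% a      # diag(a) = 0, so the k = i, j terms vanish
  den <- outer(d, d, pmin) + 1 - a
  if (any(den <= 0)) stop("nonpositive TOM denominator; invalid affinity")
  tom <- num / den
  diag(tom) <- 1
  n_clamped <- sum(tom < 0) + sum(tom > 1)
  if (n_clamped > 0) {
    message(n_clamped, " TOM entr(ies) clamped to [0, 1]")
    tom[tom < 0] <- 0
    tom[tom > 1] <- 1
  }
  tom <- (tom + t(tom)) / 2
  diag(tom) <- 1
  structure(list(tom = tom, degrees = d, n_clamped = n_clamped),
            class = "tom_matrix")
}

#' Topological overlap dissimilarity
#'
#' Elementwise `1 - TOM`: the dissimilarity that drives hierarchical
#' clustering. Diagonal is exactly zero.
#'
#' @param tm A [tom_matrix()] result.
#' @return Symmetric genes x genes dissimilarity matrix.
#' @export
diss_tom <- function(tm) {
  stopifnot(inherits(tm, "tom_matrix"))
  1 - tm$tom
}

#' Write a gene x gene matrix (TOM, dissTOM) as TSV
#'
#' Gene identifiers appear as both the header row and the first column.
#'
#' @param m Symmetric numeric matrix with gene dimnames.
#' @param path Output path.
#' @export
write_gene_matrix <- function(m, path) {
  write_id_table(m, path, id_col = "gene_id")
}

#' Read a gene x gene matrix written by [write_gene_matrix()]
#' @param path Input path.
#' @return Numeric matrix with gene dimnames.
#' @export
read_gene_matrix <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character")
  ids <- raw[[1L]]
  m <- apply(as.matrix(raw[, -1L, drop = FALSE]), c(1, 2), as.numeric)
  dimnames(m) <- list(ids, colnames(raw)[-1L])
  m
}
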