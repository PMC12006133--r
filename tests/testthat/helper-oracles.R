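# Naive, loop-based reference implementations. These deliberately share no
# code with the package internals: explicit nested loops over the defining
# sums, used to pin down the vectorized production paths.

oracle_edge_weights_corr <- function(x, h, beta) {
  cmat <- abs(stats::cor(t(x)))
  w <- numeric(ncol(h))
  for (e in seq_len(ncol(h))) {
    members <- which(h[, e] == 1)
    tot <- 0
    np <- 0
    for (i in members) {
      for (j in members) {
        if (j > i) {
          tot <- tot + cmat[i, j]^beta
          np <- np + 1
        }
      }
    }
    w[e] <- tot / np
  }
  w
}

oracle_mi_pair <- function(x, y, bins) {
  cut_bins <- function(v) {
    br <- seq(min(v), max(v), length.out = bins + 1)
    pmin(pmax(findInterval(v, br, rightmost.closed = TRUE), 1), bins)
  }
  bx <- cut_bins(x)
  by <- cut_bins(y)
  n <- length(x)
  mi <- 0
  for (i in seq_len(bins)) {
    for (j in seq_len(bins)) {
      pij <- sum(bx == i & by == j) / n
      if (pij > 0) {
        mi <- mi + pij * log(pij / ((sum(bx == i) / n) * (sum(by == j) / n)))
      }
    }
  }
  mi
}

oracle_edge_weights_mi <- function(x, h, bins) {
  w <- numeric(ncol(h))
  for (e in seq_len(ncol(h))) {
    members <- which(h[, e] == 1)
    tot <- 0
    np <- 0
    for (i in members) {
      for (j in members) {
        if (j > i) {
          tot <- tot + oracle_mi_pair(x[i, ], x[j, ], bins)
          np <- np + 1
        }
      }
    }
    w[e] <- tot / np
  }
  w
}

oracle_laplacians <- function(h, w) {
  n <- nrow(h)
  ne <- ncol(h)
  de <- colSums(h)
  dv <- numeric(n)
  for (v in seq_len(n)) {
    for (e in seq_len(ne)) dv[v] <- dv[v] + w[e] * h[v, e]
  }
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (e in seq_len(ne)) {
        m[i, j] <- m[i, j] + h[i, e] * w[e] * h[j, e] / de[e]
      }
    }
  }
  lu <- diag(dv) - m
  an <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) an[i, j] <- m[i, j] / sqrt(dv[i] * dv[j])
  }
  ln <- diag(n) - an
  a <- an
  diag(a) <- 0
  list(unnormalized = lu, normalized = ln, affinity = a, hyperdegrees = dv)
}

oracle_tom <- function(a) {
  n <- nrow(a)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- sum(a[i, -i])
  tom <- matrix(1, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      shared <- 0
      for (k in seq_len(n)) {
        if (k != i && k != j) shared <- shared + a[i, k] * a[k, j]
      }
      tom[i, j] <- (a[i, j] + shared) / (min(d[i], d[j]) + 1 - a[i, j])
    }
  }
  pmin(pmax(tom, 0), 1)
}

# O(n^2) pair-counting adjusted Rand index.
oracle_ari_pairs <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (sa) n10 <- n10 + 1
      else if (sb) n01 <- n01 + 1
      else n00 <- n00 + 1
    }
  }
  tot <- n11 + n10 + n01 + n00
  expected <- (n11 + n10) * (n11 + n01) / tot
  maxi <- ((n11 + n10) + (n11 + n01)) / 2
  (n11 - expected) / (maxi - expected)
}

oracle_chi <- function(f, l) {
  cls <- sort(unique(l))
  k <- length(cls)
  n <- nrow(f)
  g <- colMeans(f)
  bss <- 0
  wss <- 0
  for (cl in cls) {
    rows <- f[l == cl, , drop = FALSE]
    cen <- colMeans(rows)
    bss <- bss + nrow(rows) * sum((cen - g)^2)
    for (r in seq_len(nrow(rows))) wss <- wss + sum((rows[r, ] - cen)^2)
  }
  (bss / (k - 1)) / (wss / (n - k))
}

oracle_dbi <- function(f, l) {
  cls <- sort(unique(l))
  k <- length(cls)
  cen <- lapply(cls, function(cl) colMeans(f[l == cl, , drop = FALSE]))
  scat <- vapply(seq_len(k), function(i) {
    rows <- f[l == cls[i], , drop = FALSE]
    mean(vapply(seq_len(nrow(rows)),
                function(r) sqrt(sum((rows[r, ] - cen[[i]])^2)), numeric(1)))
  }, numeric(1))
  tot <- 0
  for (i in seq_len(k)) {
    worst <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      r <- (scat[i] + scat[j]) / sqrt(sum((cen[[i]] - cen[[j]])^2))
      if (r > worst) worst <- r
    }
    tot <- tot + worst
  }
  tot / k
}

# Naive O(n^3) UPGMA: average linkage over the original dissimilarity,
# returning the cophenetic matrix.
oracle_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    a <- clusters[[best[1]]]
    b <- clusters[[best[2]]]
    coph[a, b] <- best_d
    coph[b, a] <- best_d
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}
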