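# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: explicit loops, naive formulas, full eigendecompositions.

# patristic distance by explicit root-to-tip path traversal
bf_patristic <- function(phy) {
  n <- length(phy$tip.label)
  edge_len <- phy$edge.length
  parent_of <- integer(max(phy$edge))
  len_to_parent <- numeric(max(phy$edge))
  for (e in seq_len(nrow(phy$edge))) {
    parent_of[phy$edge[e, 2]] <- phy$edge[e, 1]
    len_to_parent[phy$edge[e, 2]] <- edge_len[e]
  }
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  path_to_root <- function(node) {
    nodes <- node
    while (node != root) {
      node <- parent_of[node]
      nodes <- c(nodes, node)
    }
    nodes
  }
  d <- matrix(0, n, n, dimnames = list(phy$tip.label, phy$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      pi <- path_to_root(i)
      pj <- path_to_root(j)
      mrca <- intersect(pi, pj)[1]
      seg <- function(p) {
        tot <- 0
        for (nd in p) {
          if (nd == mrca) break
          tot <- tot + len_to_parent[nd]
        }
        tot
      }
      d[i, j] <- seg(pi) + seg(pj)
    }
  }
  d
}

bf_mpd_within <- function(otus, d) {
  s <- 0; k <- 0
  for (i in seq_along(otus)) for (j in seq_along(otus)) if (i < j) {
    s <- s + d[otus[i], otus[j]]; k <- k + 1
  }
  s / k
}

bf_mpd_between <- function(a, b, d) {
  s <- 0
  for (i in a) for (j in b) s <- s + d[i, j]
  s / (length(a) * length(b))
}

bf_bc_incidence <- function(a, b) {
  1 - 2 * length(intersect(a, b)) / (length(a) + length(b))
}

bf_c_score <- function(X, normalise) {
  X <- (X > 0) + 0
  X <- X[, colSums(X) > 0, drop = FALSE]
  p <- ncol(X)
  vals <- c()
  for (i in seq_len(p)) for (j in seq_len(p)) if (i < j) {
    Ri <- sum(X[, i]); Rj <- sum(X[, j])
    S <- sum(X[, i] * X[, j])
    cu <- (Ri - S) * (Rj - S)
    vals <- c(vals, if (normalise) cu / (Ri * Rj) else cu)
  }
  mean(vals)
}

bf_annotate <- function(m, fmap) {
  fns <- sort(unique(unlist(fmap$assignments)))
  out <- matrix(0, nrow(m), length(fns), dimnames = list(rownames(m), fns))
  for (s in rownames(m)) for (f in fns) {
    tot <- 0
    for (otu in colnames(m)) {
      if (otu %in% names(fmap$assignments) &&
          f %in% fmap$assignments[[otu]]) {
        tot <- tot + m[s, otu]
      }
    }
    out[s, f] <- tot
  }
  out[, colSums(out) > 0, drop = FALSE]
}

bf_vif <- function(X) {
  sapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm(X[, j] ~ X[, -j, drop = FALSE])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  })
}

# explicit double-centring + full eigendecomposition PCoA of a truncated
# distance matrix
bf_pcnm <- function(d, truncation) {
  dt <- as.matrix(d)
  dt[dt > truncation] <- 4 * truncation
  diag(dt) <- 0
  n <- nrow(dt)
  A <- -0.5 * dt^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- e$values > max(abs(e$values)) * 1e-8
  list(values = e$values[keep], vectors = e$vectors[, keep, drop = FALSE])
}
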