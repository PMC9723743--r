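#' Principal Coordinates of Neighbour Matrices (PCNM)
#'
#' Spectral decomposition of a truncated distance matrix into orthogonal
#' eigenvector variables representing structure at different scales, usable
#' directly as constraints in a CCA. Distances above the truncation
#' threshold are replaced by four times the threshold; the truncated matrix
#' is double-centred (Gower) and eigendecomposed; eigenvectors with
#' positive eigenvalues are returned in decreasing eigenvalue order. The
#' same construction serves geographic distances and host genetic
#' p-distances alike.
#'
#' @param dist symmetric non-negative distance matrix (>= 3 points).
#' @param truncation distance threshold; default the longest edge of the
#'   minimum spanning tree of `dist` (the smallest truncation keeping all
#'   points connected).
#' @return list of class `pcnm` with `vectors` (n x k orthonormal matrix,
#'   columns named `PCNM1..k`), `values` (positive eigenvalues) and
#'   `truncation`.
#' @export
pcnm <- function(dist, truncation = NULL) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 3) stop("PCNM needs at least 3 points")
  if (any(d < 0)) stop("negative distances")
  if (is.null(truncation)) truncation <- mst_max_edge(d)
  dt <- d
  dt[dt > truncation] <- 4 * truncation
  diag(dt) <- 0
  A <- -0.5 * dt^2
  G <- A - matrix(rowMeans(A), n, n) - matrix(colMeans(A), n, n, byrow = TRUE) + mean(A)
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-8
  keep <- e$values > tol
  vec <- e$vectors[, keep, drop = FALSE]
  colnames(vec) <- paste0("PCNM", seq_len(ncol(vec)))
  rownames(vec) <- rownames(d)
  structure(list(vectors = vec, values = e$values[keep], truncation = truncation),
            class = "pcnm")
}

# longest edge of the minimum spanning tree (Prim)
mst_max_edge <- function(d) {
  n <- nrow(d)
  in_tree <- rep(FALSE, n)
  in_tree[1] <- TRUE
  best <- d[1, ]
  max_edge <- 0
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    max_edge <- max(max_edge, best[j])
    in_tree[j] <- TRUE
    best <- pmin(best, d[j, ])
  }
  max_edge
}

# ---- CCA internals ---------------------------------------------------------

# chi-square standardised residual matrix of a count/incidence table
ca_transform <- function(Y) {
  Y <- as.matrix(unclass(Y))
  if (any(rowSums(Y) <= 0)) stop("CCA requires positive row totals")
  Y <- Y[, colSums(Y) > 0, drop = FALSE]
  gt <- sum(Y)
  P <- Y / gt
  r <- rowSums(P)
  cc <- colSums(P)
  E <- r %o% cc
  list(Q = (P - E) / sqrt(E), r = r)
}

# weighted centring then sqrt-weight scaling of a raw design matrix
weight_design <- function(X, r) {
  X <- as.matrix(X)
  if (ncol(X) == 0) return(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  mu <- colSums(X * r) / sum(r)
  sweep(X, 2, mu) * sqrt(r)
}

# core partial-CCA decomposition on a prepared transform. Constant
# constraint columns vanish under weighted centring and are silently
# dropped (a centred constant has no effect); collinearity among the
# informative columns is an error unless on_rank_deficient = "keep".
cca_decompose <- function(Q, r, X, Z = NULL, on_rank_deficient = "error") {
  total <- sum(Q^2)
  conditioned <- 0
  Qr <- Q
  Xw <- weight_design(X, r)
  Xw <- Xw[, sqrt(colSums(Xw^2)) > 1e-12, drop = FALSE]
  rank_z <- 0
  if (!is.null(Z) && ncol(as.matrix(Z)) > 0) {
    Zw <- weight_design(Z, r)
    qz <- qr(Zw)
    rank_z <- qz$rank
    fit_z <- qr.fitted(qz, Q)
    conditioned <- sum(fit_z^2)
    Qr <- Q - fit_z
    if (ncol(Xw) > 0) Xw <- Xw - qr.fitted(qz, Xw)
  }
  if (ncol(Xw) == 0) {
    return(list(total = total, conditioned = conditioned, constrained = 0,
                residual = sum(Qr^2), rank_x = 0L, rank_z = rank_z,
                fitted = Qr * 0))
  }
  qx <- qr(Xw)
  if (qx$rank < ncol(Xw) && on_rank_deficient == "error") {
    bad <- colnames(Xw)[qx$pivot[seq(qx$rank + 1, ncol(Xw))]]
    stop("collinear constraint column(s): ", paste(bad, collapse = ", "))
  }
  fitted <- qr.fitted(qx, Qr)
  constrained <- sum(fitted^2)
  residual <- sum((Qr - fitted)^2)
  list(total = total, conditioned = conditioned, constrained = constrained,
       residual = residual, rank_x = qx$rank, rank_z = rank_z, fitted = fitted)
}

#' Constrained correspondence analysis
#'
#' Chi-square standardises the community table (the correspondence-analysis
#' transform), optionally partials out the conditioning variables `Z` by
#' weighted regression, then decomposes the inertia explained by the
#' constraints `X` via weighted least squares and SVD. The inertia
#' decomposition `constrained + conditioned + residual = total` is asserted
#' on every fit.
#'
#' @param Y community table ([count_table], `function_table` or matrix)
#'   with positive row totals; all-zero columns are dropped.
#' @param X numeric constraint matrix (rows aligned with `Y`). Factors
#'   must be coded upstream, e.g. with [dummy_matrix()].
#' @param Z optional numeric condition matrix.
#' @return list of class `cca_result`: `total_inertia`,
#'   `constrained_inertia`, `conditioned_inertia`, `residual_inertia`,
#'   `r2` (constrained / (total - conditioned)), `fraction_total`
#'   (constrained / total), `eigenvalues`, `rank`.
#' @export
cca <- function(Y, X, Z = NULL) {
  tr <- ca_transform(Y)
  dec <- cca_decompose(tr$Q, tr$r, X, Z)
  closure <- abs(dec$constrained + dec$conditioned + dec$residual - dec$total)
  if (closure > 1e-8 * max(1, dec$total)) {
    stop("inertia decomposition failed to close (", closure, ")")
  }
  sv <- svd(dec$fitted)$d
  eig <- sv[sv^2 > max(sv^2, 0) * 1e-12]^2
  denom <- dec$total - dec$conditioned
  structure(list(total_inertia = dec$total,
                 constrained_inertia = dec$constrained,
                 conditioned_inertia = dec$conditioned,
                 residual_inertia = dec$residual,
                 r2 = if (denom > 0) dec$constrained / denom else NaN,
                 fraction_total = dec$constrained / dec$total,
                 eigenvalues = eig,
                 rank = dec$rank_x),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("CCA: total inertia %.4f | constrained %.4f | conditioned %.4f | residual %.4f\n",
              x$total_inertia, x$constrained_inertia, x$conditioned_inertia,
              x$residual_inertia))
  cat(sprintf("  r2 = %.4f (fraction of total inertia %.4f)\n",
              x$r2, x$fraction_total))
  invisible(x)
}

#' Permutation test for a (partial) CCA
#'
#' Pseudo-F is `(constrained / q) / (residual / (n - q - z - 1))` with `q`
#' and `z` the ranks of constraints and conditions. Without conditions the
#' rows of the constraint matrix are permuted (equivalent to permuting the
#' community rows); with conditions, residuals of the reduced model are
#' permuted. `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`.
#'
#' @param Y,X,Z as in [cca()].
#' @param n_perm number of permutations, >= 99.
#' @param seed integer seed.
#' @return list with `p`, `F_obs`, `n_perm`.
#' @export
permutation_test <- function(Y, X, Z = NULL, n_perm = 999, seed) {
  stopifnot(n_perm >= 99)
  tr <- ca_transform(Y)
  Q <- tr$Q
  r <- tr$r
  n <- nrow(Q)
  X <- as.matrix(X)
  pseudo_f <- function(dec) {
    df_res <- n - dec$rank_x - dec$rank_z - 1
    (dec$constrained / dec$rank_x) / (dec$residual / df_res)
  }
  obs <- cca_decompose(Q, r, X, Z, on_rank_deficient = "error")
  if (obs$rank_x < 1) stop("constraint matrix has rank 0 after centring")
  if (n - obs$rank_x - obs$rank_z - 1 < 1) {
    stop("model saturated: no residual degrees of freedom for the pseudo-F")
  }
  F_obs <- pseudo_f(obs)
  count <- 0L
  withr::with_seed(seed, {
    if (is.null(Z)) {
      for (b in seq_len(n_perm)) {
        perm <- sample.int(n)
        dec <- cca_decompose(Q, r, X[perm, , drop = FALSE], NULL,
                             on_rank_deficient = "keep")
        if (pseudo_f(dec) >= F_obs) count <- count + 1L
      }
    } else {
      # reduced-model (residual) permutation
      Zw <- weight_design(Z, r)
      qz <- qr(Zw)
      fit_z <- qr.fitted(qz, Q)
      Qres <- Q - fit_z
      Xw <- weight_design(X, r) - qr.fitted(qz, weight_design(X, r))
      qx <- qr(Xw)
      df_res <- n - obs$rank_x - obs$rank_z - 1
      for (b in seq_len(n_perm)) {
        Qp <- Qres[sample.int(n), , drop = FALSE]
        # re-residualise against Z: permuted residuals leak into the
        # conditioned space, which must not count as unexplained inertia
        Qp <- Qp - qr.fitted(qz, Qp)
        constr <- sum(qr.fitted(qx, Qp)^2)
        Fp <- (constr / obs$rank_x) / ((sum(Qp^2) - constr) / df_res)
        if (Fp >= F_obs) count <- count + 1L
      }
    }
  })
  list(p = (1 + count) / (1 + n_perm), F_obs = F_obs, n_perm = n_perm)
}

#' Forward selection of constraint variables for CCA
#'
#' Iteratively adds the candidate with the smallest marginal permutation
#' p-value (ties broken by larger added inertia, then input order),
#' conditioning on the variables already selected, while `p <= p_enter`.
#' After each addition, any included variable whose conditional p-value
#' (given the other included variables) exceeds `p_exit` is dropped.
#' Candidates that add no rank to the current design are never co-selected.
#'
#' @param Y community table.
#' @param candidates numeric matrix of candidate variables (named columns).
#' @param p_enter,p_exit inclusion/exclusion thresholds (defaults 0.05 and
#'   0.1).
#' @param n_perm permutations per test (default 199).
#' @param seed integer seed.
#' @param Z optional condition matrix applied throughout.
#' @return character vector of selected column names (possibly empty),
#'   with attribute `history` (data.frame of steps).
#' @export
forward_select <- function(Y, candidates, p_enter = 0.05, p_exit = 0.1,
                           n_perm = 199, seed, Z = NULL) {
  candidates <- as.matrix(candidates)
  if (is.null(colnames(candidates))) {
    colnames(candidates) <- paste0("v", seq_len(ncol(candidates)))
  }
  stopifnot(ncol(candidates) >= 1)
  included <- character()
  history <- list()
  step <- 0
  repeat {
    step <- step + 1
    if (step > 4 * ncol(candidates)) break  # safety against cycling
    cond <- if (length(included)) {
      cbind(Z, candidates[, included, drop = FALSE])
    } else Z
    remaining <- setdiff(colnames(candidates), included)
    best <- NULL
    for (v in remaining) {
      xv <- candidates[, v, drop = FALSE]
      # rank guard: skip candidates collinear with the current design
      aug <- cbind(cond, xv)
      if (qr(scale(aug, scale = FALSE))$rank <=
          (if (is.null(cond)) 0 else qr(scale(cond, scale = FALSE))$rank)) next
      pt <- permutation_test(Y, xv, Z = cond, n_perm = n_perm,
                             seed = stable_hash(seed, "fwd", step, v))
      inertia <- cca(Y, xv, Z = cond)$constrained_inertia
      cand <- list(v = v, p = pt$p, inertia = inertia,
                   order = match(v, colnames(candidates)))
      if (is.null(best) ||
          cand$p < best$p ||
          (cand$p == best$p && cand$inertia > best$inertia + 1e-12) ||
          (cand$p == best$p && abs(cand$inertia - best$inertia) <= 1e-12 &&
           cand$order < best$order)) {
        best <- cand
      }
    }
    changed <- FALSE
    if (!is.null(best) && best$p <= p_enter) {
      included <- c(included, best$v)
      history[[length(history) + 1]] <-
        data.frame(step = step, action = "add", variable = best$v, p = best$p)
      changed <- TRUE
    }
    # backward pass: drop included variables with conditional p > p_exit
    repeat {
      if (length(included) < 1) break
      ps <- vapply(included, function(v) {
        others <- setdiff(included, v)
        cz <- if (length(others)) cbind(Z, candidates[, others, drop = FALSE]) else Z
        permutation_test(Y, candidates[, v, drop = FALSE], Z = cz,
                         n_perm = n_perm,
                         seed = stable_hash(seed, "bwd", step, v))$p
      }, numeric(1))
      if (max(ps) <= p_exit) break
      worst <- included[which.max(ps)]
      included <- setdiff(included, worst)
      history[[length(history) + 1]] <-
        data.frame(step = step, action = "drop", variable = worst, p = max(ps))
      changed <- TRUE
    }
    if (!changed) break
  }
  structure(included,
            history = if (length(history)) do.call(rbind, history) else
              data.frame(step = integer(), action = character(),
                         variable = character(), p = numeric()))
}

#' Variance inflation factor filtering
#'
#' Iteratively removes the column with the largest VIF while any VIF
#' exceeds the threshold. `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from the
#' OLS regression (with intercept) of column j on all other columns; an
#' exactly collinear column has infinite VIF.
#'
#' @param X numeric matrix with at least 2 named columns.
#' @param threshold VIF cutoff (default 10).
#' @return the reduced matrix, with attribute `removed` (character) and
#'   `vif` (final VIFs).
#' @export
vif_filter <- function(X, threshold = 10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(ncol(X) >= 2)
  removed <- character()
  repeat {
    if (ncol(X) < 2) break
    v <- vif_values(X)
    if (max(v) <= threshold) break
    worst <- colnames(X)[which.max(v)]
    removed <- c(removed, worst)
    X <- X[, setdiff(colnames(X), worst), drop = FALSE]
  }
  attr(X, "removed") <- removed
  attr(X, "vif") <- if (ncol(X) >= 2) vif_values(X) else
    stats::setNames(1, colnames(X))
  X
}

#' @rdname vif_filter
#' @return `vif_values`: named vector of VIFs for each column of `X`.
#' @export
vif_values <- function(X) {
  X <- as.matrix(X)
  vapply(seq_len(ncol(X)), function(j) {
    y <- X[, j]
    others <- cbind(1, X[, -j, drop = FALSE])
    fit <- qr.fitted(qr(others), y)
    sst <- sum((y - mean(y))^2)
    if (sst == 0) return(Inf)
    r2 <- 1 - sum((y - fit)^2) / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(colnames(X))
}

#' Two-set CCA variation partitioning
#'
#' Partitions the chi-square inertia of the community table into the
#' fractions uniquely explained by the host variable set, uniquely by the
#' environment set, jointly shared, and residual — all as fractions of the
#' total inertia (raw fractions sum to 1). Adjusted fractions use a
#' permutation bias correction: for each component model the adjusted R2
#' is `1 - (1 - R2) / (1 - mean(R2_perm))` over `n_perm` row permutations
#' of its constraints (Ezekiel's formula is biased for CCA); adjusted
#' fractions may be negative. Significance of each unique fraction is a
#' residual-permutation test of the corresponding partial model.
#'
#' @param Y community table.
#' @param X_host,X_env non-empty numeric constraint matrices (after
#'   forward selection / VIF filtering).
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return list of class `varpart_result`: `fractions` and
#'   `adj_fractions` (named: host_unique, env_unique, shared, residual),
#'   `p_host`, `p_env`, `total_inertia`.
#' @export
varpart2 <- function(Y, X_host, X_env, n_perm = 999, seed) {
  X_host <- as.matrix(X_host)
  X_env <- as.matrix(X_env)
  stopifnot(ncol(X_host) >= 1, ncol(X_env) >= 1)
  tr <- ca_transform(Y)
  Q <- tr$Q
  r <- tr$r
  n <- nrow(Q)
  both <- cbind(X_host, X_env)
  if (qr(scale(both, scale = FALSE))$rank <
      qr(scale(X_host, scale = FALSE))$rank + qr(scale(X_env, scale = FALSE))$rank) {
    # overlapping column spaces are fine for partitioning, but a fully
    # rank-deficient union is not
    if (qr(scale(both, scale = FALSE))$rank == 0) stop("union constraint matrix has rank 0")
  }
  total <- sum(Q^2)
  frac <- function(X) cca_decompose(Q, r, X, NULL, "keep")$constrained / total
  r2_h <- frac(X_host)
  r2_e <- frac(X_env)
  r2_he <- frac(both)
  host_unique <- r2_he - r2_e
  env_unique <- r2_he - r2_h
  shared <- r2_h + r2_e - r2_he
  fractions <- c(host_unique = host_unique, env_unique = env_unique,
                 shared = shared, residual = 1 - r2_he)
  adj <- function(X, r2, tag) {
    perm_r2 <- withr::with_seed(stable_hash(seed, "adj", tag), {
      vapply(seq_len(n_perm), function(b) frac(X[sample.int(n), , drop = FALSE]),
             numeric(1))
    })
    1 - (1 - r2) / (1 - mean(perm_r2))
  }
  a_h <- adj(X_host, r2_h, "h")
  a_e <- adj(X_env, r2_e, "e")
  a_he <- adj(both, r2_he, "he")
  adj_fractions <- c(host_unique = a_he - a_e, env_unique = a_he - a_h,
                     shared = a_h + a_e - a_he, residual = 1 - a_he)
  p_host <- permutation_test(Y, X_host, Z = X_env, n_perm = n_perm,
                             seed = stable_hash(seed, "p", "host"))$p
  p_env <- permutation_test(Y, X_env, Z = X_host, n_perm = n_perm,
                            seed = stable_hash(seed, "p", "env"))$p
  structure(list(fractions = fractions, adj_fractions = adj_fractions,
                 p_host = p_host, p_env = p_env, total_inertia = total),
            class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, ...) {
  cat("CCA variation partitioning (fractions of total inertia):\n")
  m <- rbind(raw = x$fractions, adjusted = x$adj_fractions)
  print(round(m, 4))
  cat(sprintf("  p(host unique) = %.4g, p(environment unique) = %.4g\n",
              x$p_host, x$p_env))
  invisible(x)
}

#' Effect of the cultivation step (sample-type CCA)
#'
#' CCA of the joint source + culture incidence table constrained by sample
#' type (source vs culture) and conditioned on station, quantifying how
#' much community structure the cultivation step itself explains. Stations
#' represented by only one sample kind carry no within-station contrast
#' and are dropped with a warning.
#'
#' @param all_samples joint [count_table] (jointly rarefied; converted to
#'   presence/absence internally unless `presence_absence = FALSE`).
#' @param frame a [sample_frame] covering all samples.
#' @param n_perm,seed permutation-test settings.
#' @param presence_absence analyse incidences (default) or raw counts.
#' @return list with `cca` (a `cca_result`), `p` and `n_samples`.
#' @export
sample_type_cca <- function(all_samples, frame, n_perm = 999, seed,
                            presence_absence = TRUE) {
  meta <- frame[match(rownames(all_samples), frame$sample_id), ]
  if (anyNA(meta$sample_id)) stop("sample(s) missing from metadata")
  kinds_per_station <- tapply(meta$kind, meta$station,
                              function(k) length(unique(k)))
  bad <- names(kinds_per_station)[kinds_per_station < 2]
  if (length(bad)) {
    warning("station(s) with a single sample kind dropped: ",
            paste(bad, collapse = ", "))
  }
  keep <- !(meta$station %in% bad)
  if (!any(keep)) stop("no station with both sample kinds")
  Y <- ct_matrix(all_samples)[keep, , drop = FALSE]
  if (presence_absence) Y <- (Y > 0) + 0L
  Y <- Y[, colSums(Y) > 0, drop = FALSE]
  meta <- meta[keep, ]
  X <- matrix(as.numeric(meta$kind == "culture"), ncol = 1,
              dimnames = list(NULL, "sample_type"))
  Z <- dummy_matrix(meta$station)
  if (ncol(Z) == 0) Z <- NULL
  res <- cca(Y, X, Z = Z)
  pt <- permutation_test(Y, X, Z = Z, n_perm = n_perm, seed = seed)
  list(cca = res, p = pt$p, n_samples = nrow(Y))
}

#' Dummy-code a factor for use as a CCA constraint/condition
#' @param f a factor or character vector.
#' @return numeric indicator matrix with one column per non-reference level.
#' @export
dummy_matrix <- function(f) {
  f <- factor(f)
  if (nlevels(f) < 2) return(matrix(0, length(f), 0))
  m <- stats::model.matrix(~f)[, -1, drop = FALSE]
  colnames(m) <- paste0("st_", levels(f)[-1])
  rownames(m) <- NULL
  m
}
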