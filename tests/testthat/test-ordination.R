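test_that("pcnm returns orthogonal eigenvectors and matches the PCoA oracle", {
  # 4 equidistant points
  d4 <- matrix(1, 4, 4) - diag(4)
  p4 <- pcnm(d4, truncation = 1.5)
  expect_lte(ncol(p4$vectors), 3)
  g <- crossprod(p4$vectors)
  expect_lt(max(abs(g - diag(ncol(g)))), 1e-10)

  # equally spaced points on a line: compare against explicit double-centring
  x <- seq(0, 9)
  d <- as.matrix(dist(x))
  p <- pcnm(d)
  expect_equal(p$truncation, 1)  # MST longest edge on the line
  o <- bf_pcnm(d, 1)
  expect_equal(p$values, o$values, tolerance = 1e-8)
  for (k in seq_along(p$values)) {
    # eigenvectors defined up to sign
    expect_equal(min(sum((p$vectors[, k] - o$vectors[, k])^2),
                     sum((p$vectors[, k] + o$vectors[, k])^2)), 0,
                 tolerance = 1e-8)
  }
  # leading PCNM is a single-sign-change trend along the line
  v1 <- p$vectors[, 1]
  expect_equal(sum(diff(sign(v1)) != 0), 1)

  # a 23-point distance matrix yields at most 22 eigenvectors
  withr::with_seed(5, {
    pts <- matrix(runif(46), 23, 2)
    p23 <- pcnm(as.matrix(dist(pts)))
    expect_lte(ncol(p23$vectors), 22)
  })
  expect_error(pcnm(matrix(0, 2, 2)), "at least 3")
})

test_that("cca reproduces closed-form cases and conserves inertia", {
  Y <- matrix(c(10, 0, 0, 10), 2, 2,
              dimnames = list(c("s1", "s2"), c("a", "b")))
  X <- matrix(c(0, 1), 2, 1, dimnames = list(NULL, "grp"))
  fit <- cca(Y, X)
  expect_equal(fit$total_inertia, 1)     # 2x2 diagonal CA
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(fit$residual_inertia, 0, tolerance = 1e-10)

  # constant constraint explains nothing
  withr::with_seed(9, {
    Y2 <- matrix(rpois(60, 8) + 1, 6, 10,
                 dimnames = list(paste0("s", 1:6), paste0("o", 1:10)))
  })
  fit2 <- cca(Y2, matrix(1, 6, 1))
  expect_equal(fit2$constrained_inertia, 0, tolerance = 1e-12)

  # inertia decomposition closes with a condition present
  withr::with_seed(10, {
    X2 <- matrix(rnorm(12), 6, 2)
    Z2 <- matrix(rnorm(6), 6, 1)
  })
  fit3 <- cca(Y2, X2, Z = Z2)
  expect_equal(fit3$constrained_inertia + fit3$conditioned_inertia +
                 fit3$residual_inertia, fit3$total_inertia, tolerance = 1e-10)

  expect_error(cca(Y2, cbind(a = X2[, 1], b = X2[, 1])), "collinear.*b")
})

test_that("cca r2 is monotone in nested constraint sets and 1 at full rank", {
  withr::with_seed(21, {
    Y <- matrix(rpois(15 * 12, 6) + 1, 15, 12,
                dimnames = list(paste0("s", 1:15), paste0("o", 1:12)))
    X <- matrix(rnorm(15 * 6), 15, 6)
  })
  r2s <- vapply(1:6, function(k) cca(Y, X[, 1:k, drop = FALSE])$r2, numeric(1))
  expect_true(all(diff(r2s) >= -1e-10))
  full <- cbind(X, matrix(rnorm(15 * 8), 15, 8))  # rank spans sample space
  expect_equal(cca(Y, full)$r2, 1, tolerance = 1e-8)
})

test_that("cca agrees with the vegan reference on a random table", {
  skip_if_not_installed("vegan")
  withr::with_seed(33, {
    Y <- matrix(rpois(20 * 15, 5) + 1, 20, 15,
                dimnames = list(paste0("s", 1:20), paste0("o", 1:15)))
    X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("x1", "x2")))
    Z <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "z"))
  })
  mine <- cca(Y, X, Z = Z)
  ref <- vegan::cca(Y ~ x1 + x2 + Condition(z),
                    data = as.data.frame(cbind(X, z = Z[, 1])))
  expect_equal(mine$total_inertia, ref$tot.chi, tolerance = 1e-8)
  expect_equal(mine$constrained_inertia, ref$CCA$tot.chi, tolerance = 1e-8)
  expect_equal(mine$conditioned_inertia, ref$pCCA$tot.chi, tolerance = 1e-8)
})

test_that("permutation test p-values behave per the formula and calibrate", {
  # perfect group indicator (identical rows within groups): observed F is
  # maximal (zero residual) -> p = 1/(1+n_perm)
  withr::with_seed(4, {
    protos <- matrix(rpois(40, 6) + 1, 4, 10)
    Y <- protos[rep(1:4, each = 4), ]
    dimnames(Y) <- list(paste0("s", 1:16), paste0("o", 1:10))
  })
  X <- dummy_matrix(rep(letters[1:4], each = 4))
  pt <- permutation_test(Y, X, n_perm = 99, seed = 1)
  expect_equal(pt$p, 1 / 100)
  expect_error(permutation_test(Y, X, n_perm = 50, seed = 1), "99")

  # null calibration: X independent of Y
  ps <- vapply(1:60, function(s) {
    withr::with_seed(s, {
      prof <- rexp(30); prof <- prof / sum(prof)
      Yn <- t(stats::rmultinom(20, 400, prof))
      dimnames(Yn) <- list(paste0("s", 1:20), paste0("o", 1:30))
      Xn <- matrix(rnorm(40), 20, 2)
      Zn <- matrix(rnorm(20), 20, 1)
    })
    permutation_test(Yn, Xn, Z = Zn, n_perm = 99, seed = 70000 + s)$p
  }, numeric(1))
  expect_gt(mean(ps), 0.35)            # roughly uniform, not inflated
  expect_lt(mean(ps <= 0.05), 0.2)
})

test_that("vif_filter matches the per-column OLS oracle and removes duplicates", {
  withr::with_seed(12, {
    X <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, paste0("v", 1:5)))
    X[, 2] <- X[, 1] * 0.95 + rnorm(20, 0, 0.1)
  })
  expect_equal(unname(vif_values(X)), bf_vif(X), tolerance = 1e-10)

  # centred orthogonal columns -> VIF 1, nothing removed
  withr::with_seed(13, {
    Q <- qr.Q(qr(cbind(1, matrix(rnorm(72), 9, 4))))[, -1]
  })
  colnames(Q) <- paste0("q", 1:4)
  out <- vif_filter(Q)
  expect_length(attr(out, "removed"), 0)
  expect_true(all(abs(attr(out, "vif") - 1) < 1e-10))

  # exact duplicate among otherwise independent columns: one of the pair
  # removed, the rest untouched
  withr::with_seed(19, {
    X2 <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("w", 1:3)))
  })
  X2 <- cbind(X2, dup = X2[, 1])
  out2 <- vif_filter(X2)
  expect_length(attr(out2, "removed"), 1)
  expect_true(attr(out2, "removed") %in% c("w1", "dup"))
})

test_that("forward selection picks a dominant variable and guards collinearity", {
  withr::with_seed(7, {
    grp <- rep(c(0, 1), each = 8)
    Y <- rbind(t(stats::rmultinom(8, 300, c(8, 4, 1, 1, 1, 1))),
               t(stats::rmultinom(8, 300, c(1, 1, 1, 1, 4, 8))))
    dimnames(Y) <- list(paste0("s", 1:16), paste0("o", 1:6))
    noise <- matrix(rnorm(32), 16, 2)
  })
  cand <- cbind(grp = grp, n1 = noise[, 1], n2 = noise[, 2],
                grp_copy = grp)
  sel <- forward_select(Y, cand, n_perm = 99, seed = 5)
  expect_equal(sel[1], "grp", ignore_attr = TRUE)
  expect_false("grp_copy" %in% sel)  # rank guard: duplicate never co-selected

  # no candidate reaching p_enter -> empty selection
  withr::with_seed(8, {
    Yn <- t(stats::rmultinom(16, 300, rep(1, 6)))
    dimnames(Yn) <- dimnames(Y)
  })
  sel2 <- forward_select(Yn, noise, n_perm = 99, seed = 6)
  expect_length(sel2, 0)
})

test_that("varpart2 fractions behave in the redundancy and orthogonal limits", {
  withr::with_seed(14, {
    grp <- rep(c(0, 1), each = 10)
    grp2 <- rep(c(0, 1), 10)
    Y <- t(sapply(seq_len(20), function(i) {
      base <- c(5, 5, 5, 5) + 6 * grp[i] * c(1, 0, 0, 0) +
        6 * grp2[i] * c(0, 0, 0, 1)
      stats::rmultinom(1, 400, base)
    }))
    dimnames(Y) <- list(paste0("s", 1:20), paste0("o", 1:4))
  })
  Xh <- matrix(grp, ncol = 1, dimnames = list(NULL, "h"))
  Xe <- matrix(grp2, ncol = 1, dimnames = list(NULL, "e"))

  # identical sets: uniques collapse to ~0, shared carries the signal
  vp_same <- varpart2(Y, Xh, cbind(e = grp), n_perm = 99, seed = 2)
  expect_lt(abs(vp_same$fractions[["host_unique"]]), 1e-10)
  expect_lt(abs(vp_same$fractions[["env_unique"]]), 1e-10)
  expect_gt(vp_same$fractions[["shared"]], 0.1)

  # orthogonal independent effects: shared ~ 0, both uniques positive
  vp <- varpart2(Y, Xh, Xe, n_perm = 99, seed = 3)
  expect_equal(sum(vp$fractions), 1, tolerance = 1e-10)
  expect_lt(abs(vp$fractions[["shared"]]), 0.05)
  expect_gt(vp$fractions[["host_unique"]], 0.05)
  expect_gt(vp$fractions[["env_unique"]], 0.05)
  expect_lte(vp$p_host, 0.05)
  expect_lte(vp$p_env, 0.05)
})

test_that("sample_type_cca isolates the cultivation effect", {
  b <- tiny_bundle()
  joint <- count_table(rbind(ct_matrix(b$sources), ct_matrix(b$cultures)))
  res <- sample_type_cca(joint, b$frame, n_perm = 99, seed = 4)
  expect_gte(res$cca$r2, 0)
  expect_lte(res$cca$r2, 1)

  # cultures disjoint in membership from sources: large effect, minimal p
  withr::with_seed(31, {
    src <- t(sapply(1:2, function(i) c(stats::rmultinom(1, 100, c(2, 1)), 0L, 0L)))
    cul <- t(sapply(1:8, function(i) c(0L, 0L, stats::rmultinom(1, 50, c(1, 1)))))
  })
  dimnames(src) <- list(c("SRC_A", "SRC_B"), paste0("O", 1:4))
  dimnames(cul) <- list(paste0("c", 1:8), paste0("O", 1:4))
  frame <- sample_frame(data.frame(
    sample_id = c("SRC_A", "SRC_B", paste0("c", 1:8)),
    kind = c("source", "source", rep("culture", 8)),
    station = c("A", "B", rep(c("A", "B"), each = 4)),
    source_sample_id = c(NA, NA, rep(c("SRC_A", "SRC_B"), each = 4))))
  res2 <- sample_type_cca(count_table(rbind(src, cul)), frame,
                          n_perm = 99, seed = 5)
  expect_gt(res2$cca$r2, 0.5)
  expect_equal(res2$p, 1 / 100)

  # a station with only one kind is dropped with a warning
  frame_bad <- frame
  frame_bad$station[frame_bad$sample_id == "SRC_B"] <- "C"
  expect_warning(res3 <- sample_type_cca(count_table(rbind(src, cul)),
                                         sample_frame(frame_bad),
                                         n_perm = 99, seed = 6),
                 "single sample kind")
  expect_lt(res3$n_samples, 6)
})
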