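test_that("lottery randomisation preserves the abundance multiset and station pools", {
  b <- tiny_bundle()
  rd <- lottery_randomise(b$cultures, b$sources, b$frame, seed = 7)
  expect_s3_class(rd$table, "count_table")
  check_null_invariants(rd, b$cultures, b$frame)

  m_obs <- ct_matrix(b$cultures)
  m_ran <- ct_matrix(rd$table)
  for (s in rownames(m_obs)) {
    # richness, totals, multiset, hence Shannon, exactly preserved
    expect_equal(sort(m_ran[s, m_ran[s, ] > 0]),
                 sort(m_obs[s, m_obs[s, ] > 0]), ignore_attr = TRUE)
    expect_equal(shannon(m_ran[s, ]), shannon(m_obs[s, ]))
  }
  # membership confined to the station pool: source-present AND culture-seen
  culture_union <- colnames(m_obs)[colSums(m_obs) > 0]
  for (s in rownames(m_obs)) {
    src <- ct_matrix(b$sources)[b$frame$source_sample_id[match(s, b$frame$sample_id)], ]
    pool <- intersect(names(src)[src > 0], culture_union)
    expect_true(all(colnames(m_ran)[m_ran[s, ] > 0] %in% pool))
  }
})

test_that("lottery with a pool of exactly k OTUs is forced, and errors are named", {
  otus <- c("a", "b", "c")
  cultures <- count_table(matrix(c(5L, 3L, 0L), 1, 3,
                                 dimnames = list("C1", otus)))
  sources <- count_table(matrix(c(10L, 1L, 0L), 1, 3,
                                dimnames = list("S1", otus)))
  frame <- sample_frame(data.frame(
    sample_id = c("S1", "C1"), kind = c("source", "culture"),
    station = "A", source_sample_id = c(NA, "S1")))
  rd <- lottery_randomise(cultures, sources, frame, seed = 1)
  expect_setequal(colnames(rd$table)[ct_matrix(rd$table)[1, ] > 0], c("a", "b"))

  # pool smaller than observed richness is an error naming the culture
  sources2 <- count_table(matrix(c(10L, 0L, 0L), 1, 3,
                                 dimnames = list("S1", otus)))
  expect_error(lottery_randomise(cultures, sources2, frame, seed = 1),
               "pool.*C1")
  cultures0 <- count_table(matrix(0L, 1, 3, dimnames = list("C1", otus)))
  expect_error(lottery_randomise(cultures0, sources, frame, seed = 1),
               "zero reads")
})

test_that("lottery selection probability is proportional to source abundance", {
  otus <- c("X", "Y", "Z")
  cultures <- count_table(matrix(c(7L, 0L, 0L), 1, 3,
                                 dimnames = list("C1", otus)))
  # make every pool OTU culture-eligible via a second station's cultures
  cultures_all <- count_table(rbind(ct_matrix(cultures),
                                    C2 = c(0L, 2L, 2L)))
  sources <- count_table(matrix(c(90L, 9L, 1L), 1, 3,
                                dimnames = list("S1", otus)))
  frame <- sample_frame(data.frame(
    sample_id = c("S1", "C1", "C2"), kind = c("source", "culture", "culture"),
    station = "A", source_sample_id = c(NA, "S1", "S1")))
  picks <- vapply(1:10000, function(s) {
    rd <- lottery_randomise(cultures_all, sources, frame, seed = s)
    colnames(rd$table)[ct_matrix(rd$table)["C1", ] > 0]
  }, character(1))
  expect_equal(mean(picks == "X"), 0.90, tolerance = 0.012)
})

test_that("quasiswap preserves margins and fill per block and actually mixes", {
  # [[2,0],[0,2]]: exactly two tables share these margins and fill
  # (exhaustive enumeration) - the diagonal and the anti-diagonal
  ct <- count_table(matrix(c(2L, 0L, 0L, 2L), 2, 2,
                           dimnames = list(c("c1", "c2"), c("o1", "o2"))))
  frame <- sample_frame(data.frame(
    sample_id = c("s0", "c1", "c2"), kind = c("source", "culture", "culture"),
    station = "A", source_sample_id = c(NA, "s0", "s0")))
  seen <- character()
  for (s in 1:20) {
    rd <- quasiswap_randomise(ct, frame, seed = s)
    m <- ct_matrix(rd$table)
    expect_true(identical(unname(m), matrix(c(2L, 0L, 0L, 2L), 2, 2)) ||
                  identical(unname(m), matrix(c(0L, 2L, 2L, 0L), 2, 2)))
    check_null_invariants(rd, ct, frame)
    seen <- c(seen, paste(m, collapse = ","))
  }
  expect_gte(length(unique(seen)), 2)  # both members actually reached

  # [[1,1],[1,1]]: margins and fill conserved under any amount of mixing
  ct2 <- count_table(matrix(1L, 2, 2, dimnames = dimnames(ct)))
  rd2 <- quasiswap_randomise(ct2, frame, seed = 3, n_sweeps = 2500)
  check_null_invariants(rd2, ct2, frame)

  # 5x8 random block: conservation on every replicate, plus non-degeneracy
  withr::with_seed(42, {
    m <- matrix(rpois(40, 3) * rbinom(40, 1, 0.6), 5, 8,
                dimnames = list(paste0("c", 1:5), paste0("o", 1:8)))
    m[1, 1] <- m[1, 1] + 5L  # ensure positive row/col sums
    m <- m + 1L
  })
  ct3 <- count_table(m)
  frame3 <- sample_frame(data.frame(
    sample_id = c("s0", rownames(m)), kind = c("source", rep("culture", 5)),
    station = "B", source_sample_id = c(NA, rep("s0", 5))))
  outs <- lapply(1:200, function(s) {
    rd <- quasiswap_randomise(ct3, frame3, seed = s)
    check_null_invariants(rd, ct3, frame3)
    ct_matrix(rd$table)
  })
  expect_gte(length(unique(lapply(outs, paste, collapse = ","))), 2)
})

test_that("single-culture stations are returned unchanged with a warning", {
  b <- tiny_bundle()
  frame <- b$frame
  frame$station[frame$sample_id == "C5"] <- "C_alone"
  frame$station[frame$sample_id == "C4"] <- "A"  # keep every other block >= 2
  frame <- sample_frame(frame)
  expect_warning(rd <- quasiswap_randomise(b$cultures, frame, seed = 1),
                 "single culture")
  expect_identical(ct_matrix(rd$table)["C5", ], ct_matrix(b$cultures)["C5", ])
})

test_that("ensembles are reproducible and replicates independent of the stream", {
  b <- tiny_bundle()
  ens1 <- make_ensemble("lottery", b$cultures, b$sources, b$frame,
                        n_replicates = 10, base_seed = 99)
  ens2 <- make_ensemble("lottery", b$cultures, b$sources, b$frame,
                        n_replicates = 10, base_seed = 99)
  all1 <- ensemble_map(ens1, function(rd) ct_matrix(rd$table))
  all2 <- ensemble_map(ens2, function(rd) ct_matrix(rd$table))
  expect_identical(all1, all2)
  # replicate 7 computed alone equals replicate 7 from the full stream
  expect_identical(ct_matrix(ens1$get(7)$table), all1[[7]])
  # different base seed gives a different ensemble
  ens3 <- make_ensemble("lottery", b$cultures, b$sources, b$frame,
                        n_replicates = 10, base_seed = 100)
  expect_false(identical(ct_matrix(ens3$get(1)$table), all1[[1]]))
})

test_that("lottery long-run inclusion frequency increases with source abundance", {
  b <- gen_scenario(small_cfg(seed = 8))
  ens <- make_ensemble("lottery", b$cultures, b$sources, b$frame,
                       n_replicates = 500, base_seed = 12)
  incl <- Reduce(`+`, ensemble_map(ens, function(rd) colSums(ct_matrix(rd$table) > 0)))
  src_tot <- colSums(ct_matrix(b$sources))
  keep <- incl > 0 | src_tot > 0
  rho <- stats::cor(src_tot[keep], incl[keep], method = "spearman")
  expect_gt(rho, 0)
})
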