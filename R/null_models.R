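#' Lottery randomisation of culture microbiomes
#'
#' Re-assembles every culture community from its local source community
#' under a pure lottery: the observed OTUs of each culture are replaced by
#' OTUs drawn without replacement from the station's candidate pool, with
#' selection probability proportional to source abundance (weights
#' renormalised after each draw). The candidate pool for a station is the
#' set of OTUs with positive counts in that station's source sample,
#' intersected with the OTUs seen at least once in any culture (bacteria
#' that never survive culturing are not eligible). The observed abundance
#' values of the culture (sorted decreasing) are assigned to the drawn
#' OTUs in draw order, so per-sample richness, total reads, the abundance
#' multiset — and hence Shannon diversity and evenness — are preserved
#' exactly.
#'
#' @param cultures culture-only [count_table].
#' @param sources source [count_table].
#' @param frame a [sample_frame] resolving each culture to its
#'   `source_sample_id`.
#' @param seed integer RNG seed.
#' @param replicate_index bookkeeping index stored in the result.
#' @return a list of class `randomised_dataset`: `table` ([count_table]
#'   with the same sample and OTU ids as `cultures`), `procedure`
#'   (`"lottery"`), `seed`, `replicate_index`.
#' @export
lottery_randomise <- function(cultures, sources, frame, seed,
                              replicate_index = NA_integer_) {
  stopifnot(is_count_table(cultures), is_count_table(sources))
  culture_union <- colnames(cultures)[colSums(cultures) > 0]
  src_of <- stats::setNames(frame$source_sample_id, frame$sample_id)
  m <- ct_matrix(cultures)
  out <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  withr::with_seed(seed, {
    for (s in rownames(m)) {
      obs <- m[s, ]
      k <- sum(obs > 0)
      if (sum(obs) == 0) stop("culture with zero reads: ", s)
      src_id <- src_of[[s]]
      if (is.null(src_id) || is.na(src_id) || !(src_id %in% rownames(sources))) {
        stop("culture ", s, " does not resolve to a source sample")
      }
      src <- ct_matrix(sources)[src_id, ]
      pool <- intersect(names(src)[src > 0], culture_union)
      if (length(pool) < k) {
        stop(sprintf("candidate pool (%d OTUs) smaller than observed richness (%d) for culture %s",
                     length(pool), k, s))
      }
      drawn <- if (length(pool) == 1) pool else
        sample(pool, k, replace = FALSE, prob = src[pool])
      out[s, drawn] <- as.integer(sort(obs[obs > 0], decreasing = TRUE))
    }
  })
  structure(list(table = count_table(out), procedure = "lottery",
                 seed = seed, replicate_index = replicate_index),
            class = "randomised_dataset")
}

#' Station-constrained quasiswap randomisation
#'
#' Randomises abundances among the cultures of each station independently
#' while preserving, exactly and per station block: every row (sample)
#' total, every column (OTU) total, and the matrix fill (number of zero
#' cells). OTU incidences therefore never move between stations, and OTUs
#' that are abundant overall stay abundant — the null retains everything
#' except which host got which reads. Each block is randomised as an
#' independent draw: a Patefield ([stats::r2dtable()]) sample with the
#' observed margins, whose fill is then driven to the observed fill by
#' random 2x2 diagonal transfers, followed by `n_sweeps` sweeps of
#' fill-preserving unit moves to mix abundances conditional on the
#' incidence pattern.
#'
#' @param cultures culture-only [count_table].
#' @param frame a [sample_frame] giving each culture's `station`.
#' @param seed integer RNG seed.
#' @param n_sweeps abundance-mixing length in sweeps (one sweep = one
#'   trial per non-zero cell); default 100.
#' @param replicate_index bookkeeping index stored in the result.
#' @return a `randomised_dataset` (see [lottery_randomise()]) with
#'   `procedure = "swap"`.
#' @export
quasiswap_randomise <- function(cultures, frame, seed, n_sweeps = 100L,
                                replicate_index = NA_integer_) {
  stopifnot(is_count_table(cultures))
  station_of <- stats::setNames(frame$station, frame$sample_id)
  st <- station_of[rownames(cultures)]
  if (anyNA(st)) stop("culture sample(s) missing from sample_frame")
  m <- ct_matrix(cultures)
  withr::with_seed(seed, {
    for (block_station in unique(st)) {
      rows <- which(st == block_station)
      if (length(rows) < 2) {
        warning("station ", block_station,
                " has a single culture; block returned unchanged")
        next
      }
      block <- m[rows, , drop = FALSE]
      cols <- which(colSums(block) > 0)
      if (length(cols) < 2) next
      sub <- block[, cols, drop = FALSE]
      start <- stats::r2dtable(1, rowSums(sub), colSums(sub))[[1]]
      storage.mode(start) <- "integer"
      filled <- quasiswap_fill(start, sum(sub > 0), max_trials = 1e8)
      m[rows, cols] <- quasiswap_chain(filled, n_sweeps * sum(sub > 0))
    }
  })
  structure(list(table = count_table(m), procedure = "swap",
                 seed = seed, replicate_index = replicate_index),
            class = "randomised_dataset")
}

#' Reproducible ensemble of randomised datasets
#'
#' Builds a lazy ensemble: replicate `r` is generated on demand from the
#' substream seed `stable_hash(base_seed, procedure, r)`, so replicates are
#' mutually independent, reproducible in isolation, and never all held in
#' memory. Use [ensemble_map()] to stream a summary function over the
#' replicates.
#'
#' @param procedure `"lottery"` or `"swap"`.
#' @param cultures,sources,frame inputs of the underlying procedure
#'   (`sources` is ignored for `"swap"`).
#' @param n_replicates number of replicates (the reference analysis uses
#'   1000).
#' @param base_seed integer master seed.
#' @param n_sweeps burn-in for the swap procedure.
#' @return a list of class `ensemble` with `$get(r)` returning replicate
#'   `r` as a `randomised_dataset`, plus `n_replicates` and `procedure`.
#' @export
make_ensemble <- function(procedure = c("lottery", "swap"), cultures,
                          sources = NULL, frame, n_replicates, base_seed,
                          n_sweeps = 100L) {
  procedure <- match.arg(procedure)
  stopifnot(n_replicates >= 1)
  if (procedure == "lottery" && is.null(sources)) {
    stop("lottery ensemble needs source communities")
  }
  get <- function(r) {
    stopifnot(r >= 1, r <= n_replicates)
    s <- stable_hash(base_seed, procedure, r)
    if (procedure == "lottery") {
      lottery_randomise(cultures, sources, frame, seed = s, replicate_index = r)
    } else {
      quasiswap_randomise(cultures, frame, seed = s, n_sweeps = n_sweeps,
                          replicate_index = r)
    }
  }
  structure(list(get = get, n_replicates = n_replicates,
                 procedure = procedure),
            class = "ensemble")
}

#' Stream a function over an ensemble
#'
#' @param ensemble an [make_ensemble()] object.
#' @param f function taking a `randomised_dataset` and returning a small
#'   summary; replicates are generated, summarised and discarded one at a
#'   time, so peak memory does not grow with the replicate count.
#' @param .progress unused hook for now.
#' @return list of `f` results, one per replicate.
#' @export
ensemble_map <- function(ensemble, f, .progress = FALSE) {
  lapply(seq_len(ensemble$n_replicates), function(r) f(ensemble$get(r)))
}

#' Assert the conservation laws of a randomised dataset
#'
#' Lottery replicates must preserve each sample's richness, total reads
#' and abundance multiset; swap replicates must preserve per-station row
#' totals, column totals and fill. Violations are errors naming the
#' replicate — a biased ensemble is worse than no ensemble.
#'
#' @param rd a `randomised_dataset`.
#' @param cultures the observed culture [count_table].
#' @param frame the [sample_frame] (needed for swap blocks).
#' @return invisibly TRUE.
#' @export
check_null_invariants <- function(rd, cultures, frame) {
  lab <- sprintf("%s replicate %s", rd$procedure, rd$replicate_index)
  obs <- ct_matrix(cultures)
  ran <- ct_matrix(rd$table)
  if (!identical(sort(rownames(obs)), sort(rownames(ran)))) {
    stop(lab, ": sample ids differ from observed")
  }
  ran <- ran[rownames(obs), colnames(obs), drop = FALSE]
  if (rd$procedure == "lottery") {
    for (s in rownames(obs)) {
      a <- sort(obs[s, obs[s, ] > 0])
      b <- sort(ran[s, ran[s, ] > 0])
      if (!identical(as.integer(a), as.integer(b))) {
        stop(lab, ": abundance multiset not preserved for sample ", s)
      }
    }
  } else {
    st <- stats::setNames(frame$station, frame$sample_id)[rownames(obs)]
    for (b in unique(st)) {
      o <- obs[st == b, , drop = FALSE]
      r <- ran[st == b, , drop = FALSE]
      if (!identical(rowSums(o), rowSums(r))) stop(lab, ": row totals broken in station ", b)
      if (!identical(colSums(o), colSums(r))) stop(lab, ": column totals broken in station ", b)
      if (sum(o == 0) != sum(r == 0)) stop(lab, ": fill broken in station ", b)
    }
  }
  invisible(TRUE)
}
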