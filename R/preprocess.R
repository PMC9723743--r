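#' Zero out counts below a noise floor
#'
#' Sequencing blanks typically contain a handful of stray reads per OTU, so
#' counts below a small threshold cannot be distinguished from
#' cross-contamination. Every count strictly below `threshold` is set to
#' zero; counts at or above it are untouched ("below four" means a count of
#' exactly 4 survives). OTUs whose column becomes all-zero are retained but
#' recorded in the `"flagged_otus"` attribute.
#'
#' @param table a [count_table].
#' @param threshold integer reads, >= 0. The default 4 reflects the
#'   worst blank contamination commonly seen in marker-gene runs.
#' @return a [count_table] with attribute `flagged_otus` (character vector
#'   of OTUs that lost all their reads).
#' @export
noise_floor_filter <- function(table, threshold = 4L) {
  stopifnot(is_count_table(table), threshold >= 0)
  m <- ct_matrix(table)
  had <- colSums(m) > 0
  m[m < threshold] <- 0L
  out <- count_table(m)
  attr(out, "flagged_otus") <- colnames(m)[had & colSums(m) == 0]
  out
}

#' Remove flagged (e.g. organelle) OTUs
#'
#' 16S amplicon data from algal cultures is dominated by chloroplast and
#' mitochondrial reads; these are flagged upstream by taxonomy and removed
#' here. The per-label removed-read fraction is reported so the provenance
#' record can state how much signal was organellar.
#'
#' @param table a [count_table].
#' @param flags a data.frame with columns `otu_id` and `label`, or a named
#'   list OTU id -> character vector of labels.
#' @return list with `table` (flagged OTUs dropped) and `removed_fraction`
#'   (named numeric per label, plus `"total"`), fractions of the input reads.
#' @export
drop_flagged_otus <- function(table, flags) {
  stopifnot(is_count_table(table))
  if (is.data.frame(flags)) {
    stopifnot(all(c("otu_id", "label") %in% names(flags)))
    flag_list <- split(as.character(flags$label), as.character(flags$otu_id))
  } else {
    flag_list <- lapply(flags, as.character)
  }
  total <- sum(table)
  labels <- unique(unlist(flag_list, use.names = FALSE))
  reads_per_otu <- colSums(table)
  frac <- vapply(labels, function(lb) {
    otus <- names(flag_list)[vapply(flag_list, function(x) lb %in% x, logical(1))]
    otus <- intersect(otus, colnames(table))
    if (total == 0) 0 else sum(reads_per_otu[otus]) / total
  }, numeric(1))
  drop <- intersect(names(flag_list), colnames(table))
  keep <- setdiff(colnames(table), drop)
  m <- ct_matrix(table)[, keep, drop = FALSE]
  frac <- c(frac, total = if (total == 0) 0 else sum(reads_per_otu[drop]) / total)
  list(table = count_table(m), removed_fraction = frac)
}

#' Rarefy samples to a fixed depth
#'
#' Samples with fewer than `min_reads` total reads are discarded; each
#' remaining sample is subsampled once, without replacement, to exactly
#' `depth` reads (a multivariate hypergeometric draw). Culture and source
#' tables are rarefied by separate calls with their own depths.
#'
#' @param table a [count_table].
#' @param depth target reads per sample, >= 1.
#' @param min_reads minimum total for a sample to be kept; must be >=
#'   `depth` (a sample below `depth` cannot be subsampled to it). Default
#'   `depth`.
#' @param seed integer RNG seed; one draw per sample per seed.
#' @return a [count_table] of the retained samples, each summing to
#'   `depth`, with attribute `dropped_samples`.
#' @export
rarefy <- function(table, depth, min_reads = depth, seed) {
  stopifnot(is_count_table(table), depth >= 1)
  if (min_reads < depth) {
    stop(sprintf("min_reads (%d) < depth (%d): retained samples could not be rarefied",
                 min_reads, depth))
  }
  totals <- rowSums(table)
  keep <- totals >= min_reads
  m <- ct_matrix(table)[keep, , drop = FALSE]
  withr::with_seed(seed, {
    for (i in seq_len(nrow(m))) {
      row <- m[i, ]
      tot <- sum(row)
      if (tot == depth) next
      reads <- rep.int(seq_along(row), row)
      drawn <- reads[sample.int(tot, depth)]
      m[i, ] <- tabulate(drawn, nbins = length(row))
    }
  })
  out <- count_table(m)
  attr(out, "dropped_samples") <- rownames(table)[!keep]
  out
}

#' Remove nested-function overlap from an annotation map
#'
#' When an OTU is assigned both a narrow function and a broader one that
#' contains it (directly or through a chain of nestings), keeping both
#' would double-count the capability and inflate functional diversity. The
#' broad label is removed from that OTU's set; the most specific annotation
#' wins. Applied transitively over the nesting relation.
#'
#' @param fmap a [function_map] (its nesting relation must be acyclic,
#'   which the constructor guarantees).
#' @return a curated [function_map] with the same nesting relation.
#' @export
curate_functions <- function(fmap) {
  stopifnot(inherits(fmap, "function_map"))
  anc <- transitive_broads(fmap$nesting)
  assignments <- lapply(fmap$assignments, function(fns) {
    broads <- unique(unlist(anc[intersect(fns, names(anc))], use.names = FALSE))
    setdiff(fns, broads)
  })
  function_map(assignments, fmap$nesting)
}

# narrow -> all (transitively) broader labels
transitive_broads <- function(nesting) {
  direct <- split(nesting$broad, nesting$narrow)
  anc <- direct
  repeat {
    grown <- FALSE
    for (n in names(anc)) {
      up <- unique(unlist(anc[intersect(anc[[n]], names(anc))], use.names = FALSE))
      new <- union(anc[[n]], up)
      if (length(new) > length(anc[[n]])) {
        anc[[n]] <- new
        grown <- TRUE
      }
    }
    if (!grown) break
  }
  anc
}

#' Sum reads into a sample-by-function table
#'
#' The abundance of function `f` in sample `s` is the total reads in `s`
#' of OTUs whose (curated) annotation set contains `f`. Unannotated OTUs
#' contribute to no function; functions observed in no sample are dropped.
#'
#' @param table a [count_table].
#' @param fmap a curated [function_map].
#' @return an integer matrix of class `function_table` (samples x
#'   functions), possibly with zero columns.
#' @export
annotate_functions <- function(table, fmap) {
  stopifnot(is_count_table(table), inherits(fmap, "function_map"))
  fns <- sort(unique(unlist(fmap$assignments, use.names = FALSE)))
  m <- ct_matrix(table)
  out <- matrix(0L, nrow(m), length(fns),
                dimnames = list(rownames(m), fns))
  for (otu in intersect(names(fmap$assignments), colnames(m))) {
    f <- fmap$assignments[[otu]]
    if (length(f)) out[, f] <- out[, f] + m[, otu]
  }
  out <- out[, colSums(out) > 0, drop = FALSE]
  class(out) <- c("function_table", "matrix", "array")
  out
}

#' Convert counts to presence/absence
#'
#' @param table a [count_table], `function_table` or plain matrix.
#' @return a plain 0/1 integer matrix of the same shape. Idempotent.
#' @export
to_incidence <- function(table) {
  m <- unclass(table)
  class(m) <- NULL
  attr(m, "flagged_otus") <- NULL
  attr(m, "dropped_samples") <- NULL
  storage.mode(m) <- "integer"
  (m > 0L) + 0L
}

#' One-call preprocessing of a culture/source bundle
#'
#' Applies the standard order: noise floor, organelle removal, then
#' rarefaction of cultures and sources to their own depths. Returns the
#' processed tables plus a provenance record (thresholds, removed read
#' fractions under both orderings of floor and organelle removal, dropped
#' samples) suitable for JSON serialisation.
#'
#' @param cultures,sources [count_table]s sharing an OTU universe.
#' @param noise_floor integer, see [noise_floor_filter()].
#' @param organelle_flags optional flags for [drop_flagged_otus()].
#' @param depth_culture,depth_source rarefaction depths (defaults 538 and
#'   2484 reads, typical marker-gene depths for low- and high-biomass
#'   samples).
#' @param min_reads_culture,min_reads_source retention thresholds, default
#'   the respective depth.
#' @param seed integer seed for the rarefaction draws.
#' @return list with `cultures`, `sources` (rarefied [count_table]s) and
#'   `provenance` (a plain list).
#' @export
preprocess_bundle <- function(cultures, sources, noise_floor = 4L,
                              organelle_flags = NULL,
                              depth_culture = 538L, depth_source = 2484L,
                              min_reads_culture = depth_culture,
                              min_reads_source = depth_source,
                              seed) {
  prov <- list(noise_floor = noise_floor, depth_culture = depth_culture,
               depth_source = depth_source, seed = seed)
  stage <- function(tb, depth, min_reads, sub) {
    if (!is.null(organelle_flags)) {
      # report organelle fractions both before and after the noise floor:
      # the right ordering is not knowable from a finished table alone
      before <- drop_flagged_otus(tb, organelle_flags)$removed_fraction
      after <- drop_flagged_otus(noise_floor_filter(tb, noise_floor),
                                 organelle_flags)$removed_fraction
      prov[[paste0("organelle_fraction_", sub)]] <<-
        list(before_floor = as.list(before), after_floor = as.list(after))
      tb <- drop_flagged_otus(tb, organelle_flags)$table
    }
    tb <- noise_floor_filter(tb, noise_floor)
    rarefy(tb, depth, min_reads, seed = stable_hash(seed, "rarefy", sub))
  }
  cult <- stage(cultures, depth_culture, min_reads_culture, "culture")
  src <- stage(sources, depth_source, min_reads_source, "source")
  prov$dropped_culture_samples <- attr(cult, "dropped_samples")
  prov$dropped_source_samples <- attr(src, "dropped_samples")
  list(cultures = cult, sources = src, provenance = prov)
}
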