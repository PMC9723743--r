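#' Shannon diversity (natural log)
#'
#' `H = -sum p_i log p_i` over positive entries, in nats. An all-zero
#' vector has no defined diversity and returns `NaN` with a warning rather
#' than silently propagating.
#'
#' @param counts non-negative numeric vector.
#' @param base logarithm base; default `exp(1)` (nats), the convention of
#'   the classic vegan implementation.
#' @return a single numeric value.
#' @export
shannon <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stop("negative counts")
  tot <- sum(counts)
  if (tot == 0) {
    warning("Shannon undefined for an all-zero community")
    return(NaN)
  }
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = base))
}

#' Per-sample functional Shannon diversity and richness
#'
#' @param ftable a `function_table` from [annotate_functions()].
#' @return data.frame with `sample_id`, `shannon` (nats; `NaN` when the
#'   sample carries no annotated reads) and `richness` (number of functions
#'   with positive abundance).
#' @export
function_indices <- function(ftable) {
  m <- unclass(ftable)
  sh <- suppressWarnings(apply(m, 1, shannon))
  data.frame(sample_id = rownames(m),
             shannon = as.numeric(sh),
             richness = as.integer(rowSums(m > 0)),
             row.names = NULL)
}

#' Mean pairwise phylogenetic distance within a community
#'
#' Unweighted MPD: the mean patristic distance over all unordered pairs of
#' distinct OTUs present in the community, ignoring abundances.
#'
#' @param incidence logical/0-1 vector named by OTU id, or a character
#'   vector of present OTU ids.
#' @param dist a [phylo_distances] covering all present OTUs.
#' @return numeric; `NaN` (with warning) when fewer than 2 OTUs are present.
#' @export
mpd_within <- function(incidence, dist) {
  otus <- present_otus(incidence)
  missing <- setdiff(otus, rownames(dist))
  if (length(missing)) stop("OTU(s) missing from distance matrix: ",
                            paste(missing, collapse = ", "))
  n <- length(otus)
  if (n < 2) {
    warning("MPD undefined for a community of fewer than 2 OTUs")
    return(NaN)
  }
  d <- dist[otus, otus]
  sum(d[upper.tri(d)]) / (n * (n - 1) / 2)
}

#' Mean pairwise phylogenetic distance between two communities
#'
#' The mean patristic distance over all ordered cross pairs `(i in A, j in
#' B)`, unweighted. OTUs shared by both communities contribute
#' zero-distance pairs, so two identical communities have distance 0.
#'
#' @param incidence_a,incidence_b communities as in [mpd_within()].
#' @param dist a [phylo_distances].
#' @return numeric; `NaN` (with warning) when either community is empty.
#' @export
mpd_between <- function(incidence_a, incidence_b, dist) {
  a <- present_otus(incidence_a)
  b <- present_otus(incidence_b)
  if (length(a) == 0 || length(b) == 0) {
    warning("between-community MPD undefined for an empty community")
    return(NaN)
  }
  missing <- setdiff(c(a, b), rownames(dist))
  if (length(missing)) stop("OTU(s) missing from distance matrix: ",
                            paste(missing, collapse = ", "))
  mean(dist[a, b, drop = FALSE])
}

present_otus <- function(incidence) {
  if (is.character(incidence)) return(unique(incidence))
  if (is.null(names(incidence))) stop("incidence vector must be named by OTU id")
  names(incidence)[incidence > 0]
}

#' Bray-Curtis dissimilarity on incidences (Sorensen)
#'
#' On presence/absence data the Bray-Curtis index reduces to the Sorensen
#' dissimilarity `1 - 2|A.B| / (|A| + |B|)`.
#'
#' @param a,b communities as in [mpd_within()].
#' @return numeric in `[0, 1]`; `NaN` (with warning) when both are empty.
#' @export
bray_curtis_incidence <- function(a, b) {
  sa <- present_otus(a)
  sb <- present_otus(b)
  if (length(sa) + length(sb) == 0) {
    warning("Bray-Curtis undefined for two empty communities")
    return(NaN)
  }
  1 - 2 * length(intersect(sa, sb)) / (length(sa) + length(sb))
}

#' Checkerboard C-score
#'
#' For each unordered pair of OTUs the number of checkerboard units is
#' `CU = (R_i - S)(R_j - S)` where `R` is the number of samples an OTU
#' occupies and `S` the number of samples shared. Mutual exclusion raises
#' the score; recurring coexistence lowers it. The normalised variant
#' divides each CU by `R_i * R_j`, bounding it in `[0, 1]`. OTUs occupying
#' no sample are excluded (their normalised CU is undefined).
#'
#' @param incidence sample-by-OTU binary matrix.
#' @param normalise logical; return the normalised score (default TRUE,
#'   the headline variant) or raw checkerboard units.
#' @return mean (normalised) checkerboard units over OTU pairs; `NaN` with
#'   a warning when fewer than 2 OTUs are occupied.
#' @export
c_score <- function(incidence, normalise = TRUE) {
  x <- (unclass(incidence) > 0) + 0
  x <- x[, colSums(x) > 0, drop = FALSE]
  p <- ncol(x)
  if (p < 2) {
    warning("C-score undefined with fewer than 2 occupied OTUs")
    return(NaN)
  }
  R <- colSums(x)
  S <- crossprod(x)                     # shared-sample counts
  A <- R - S                            # column-recycled: A[i, j] = R_i - S_ij
  cu <- A * t(A)                        # (R_i - S_ij)(R_j - S_ij)
  if (normalise) cu <- cu / (R %o% R)
  mean(cu[upper.tri(cu)])
}

#' Per-dataset mean diversity indices
#'
#' Computes the full index panel used to compare observed and randomised
#' culture datasets: per-sample indices are averaged over samples,
#' per-pair indices over all unordered sample pairs, and the C-score is a
#' dataset-level quantity. Undefined (`NaN`-flagged) values are excluded
#' from each mean and counted.
#'
#' @param table the culture [count_table] (source samples never enter this
#'   panel).
#' @param dist a [phylo_distances] or NULL to skip phylogenetic indices.
#' @param fmap a curated [function_map] or NULL to skip functional indices.
#' @param which character subset of
#'   `c("shannon_otu","shannon_fun","richness_fun","mpd_within","bc_otu",
#'   "bc_fun","mpd_between","c_score","c_score_raw")`.
#' @return named numeric vector of dataset means, with attribute
#'   `n_undefined` (named integer count of excluded values per index).
#' @export
dataset_summary <- function(table, dist = NULL, fmap = NULL,
                            which = c("shannon_otu", "shannon_fun",
                                      "richness_fun", "mpd_within", "bc_otu",
                                      "bc_fun", "mpd_between", "c_score",
                                      "c_score_raw")) {
  which <- match.arg(which, several.ok = TRUE)
  m <- ct_matrix(table)
  n <- nrow(m)
  pairs <- if (n >= 2) utils::combn(n, 2) else matrix(integer(), 2, 0)
  out <- c()
  ndef <- c()
  put <- function(name, values) {
    vals <- values[!is.nan(values)]
    out[name] <<- if (length(vals)) mean(vals) else NaN
    ndef[name] <<- sum(is.nan(values))
  }
  suppressWarnings({
    if ("shannon_otu" %in% which) {
      put("shannon_otu", apply(m, 1, shannon))
    }
    if (!is.null(fmap) && any(c("shannon_fun", "richness_fun") %in% which)) {
      fi <- function_indices(annotate_functions(table, fmap))
      if ("shannon_fun" %in% which) put("shannon_fun", fi$shannon)
      if ("richness_fun" %in% which) put("richness_fun", as.numeric(fi$richness))
    }
    if (!is.null(dist) && "mpd_within" %in% which) {
      put("mpd_within", apply(m, 1, function(r) mpd_within(r > 0, dist)))
    }
    if ("bc_otu" %in% which) {
      inc <- to_incidence(table)
      put("bc_otu", pair_apply(pairs, function(i, j)
        bray_curtis_incidence(inc[i, ], inc[j, ])))
    }
    if (!is.null(fmap) && "bc_fun" %in% which) {
      finc <- to_incidence(annotate_functions(table, fmap))
      put("bc_fun", pair_apply(pairs, function(i, j)
        bray_curtis_incidence(finc[i, ], finc[j, ])))
    }
    if (!is.null(dist) && "mpd_between" %in% which) {
      inc <- to_incidence(table)
      put("mpd_between", pair_apply(pairs, function(i, j)
        mpd_between(inc[i, ], inc[j, ], dist)))
    }
    if ("c_score" %in% which) put("c_score", c_score(m, normalise = TRUE))
    if ("c_score_raw" %in% which) put("c_score_raw", c_score(m, normalise = FALSE))
  })
  attr(out, "n_undefined") <- ndef
  out
}

pair_apply <- function(pairs, f) {
  if (ncol(pairs) == 0) return(NaN)
  vapply(seq_len(ncol(pairs)),
         function(k) f(pairs[1, k], pairs[2, k]), numeric(1))
}
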