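#' Construct a sample-by-OTU count table
#'
#' The central container of the package: a non-negative integer matrix with
#' samples as rows and OTUs as columns, both carrying unique identifiers.
#' All joins between objects are by identifier, never by position, so
#' randomisation routines are free to reorder.
#'
#' @param counts numeric matrix coercible to integer, samples as rows.
#'   Must have unique, non-empty `rownames` (sample ids) and `colnames`
#'   (OTU ids) unless supplied separately.
#' @param sample_ids,otu_ids optional character vectors overriding the
#'   dimnames of `counts`.
#' @return An integer matrix of class `count_table`.
#' @export
count_table <- function(counts, sample_ids = rownames(counts),
                        otu_ids = colnames(counts)) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(sample_ids) && nrow(counts) == 0) sample_ids <- character()
  if (is.null(otu_ids) && ncol(counts) == 0) otu_ids <- character()
  if (is.null(sample_ids) || is.null(otu_ids)) {
    stop("count_table needs sample and OTU identifiers (dimnames)")
  }
  sample_ids <- as.character(sample_ids)
  otu_ids <- as.character(otu_ids)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(otu_ids)) {
    stop("duplicate OTU identifiers: ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  }
  if (length(sample_ids) != nrow(counts) || length(otu_ids) != ncol(counts)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  if (anyNA(counts)) stop("count table contains missing values")
  if (any(counts < 0)) stop("count table contains negative entries")
  if (any(counts != round(counts))) stop("count table contains non-integer entries")
  mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, otu_ids)
  class(counts) <- c("count_table", "matrix", "array")
  counts
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d OTUs, %d reads total\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Test or strip the count_table class
#' @param x an object.
#' @return `is_count_table` a logical; `ct_matrix` the bare integer matrix.
#' @export
is_count_table <- function(x) inherits(x, "count_table")

#' @rdname is_count_table
#' @export
ct_matrix <- function(x) {
  y <- unclass(x)
  class(y) <- NULL
  attr(y, "flagged_otus") <- NULL
  y
}

#' Read a tab-separated count table
#'
#' Accepts either orientation and normalises to samples-as-rows. The first
#' column holds row identifiers and the header row holds column identifiers.
#' Lines starting with `#` are ignored.
#'
#' @param path file path of a UTF-8, tab-delimited table.
#' @param orientation `"samples_as_rows"` (default) or `"otus_as_rows"`.
#' @return a [count_table].
#' @export
read_count_table <- function(path,
                             orientation = c("samples_as_rows", "otus_as_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, row.names = 1,
                          colClasses = "character", quote = "")
  m <- as.matrix(df)
  num <- suppressWarnings(array(as.numeric(m), dim(m), dimnames(m)))
  bad <- which(is.na(num) | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-integer cell '%s' at row '%s', column '%s' in %s",
                 m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]],
                 colnames(m)[bad[1, 2]], path))
  }
  if (orientation == "otus_as_rows") num <- t(num)
  count_table(num)
}

#' Write a count table as TSV (samples as rows)
#' @param table a [count_table].
#' @param path output file path.
#' @export
write_count_table <- function(table, path) {
  stopifnot(is_count_table(table))
  df <- data.frame(sample_id = rownames(table), ct_matrix(table),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct per-sample metadata
#'
#' A data frame keyed by `sample_id` with the mandatory columns `kind`
#' (`"source"` or `"culture"`), `station` and `habitat` (`"sediment"` or
#' `"water"`), an optional `source_sample_id` linking each culture to the
#' environmental sample its host was isolated from, and any number of
#' numeric environmental covariates (salinity in PSU, nutrient
#' concentrations in ug/L, coordinates, ...). Missing covariates are legal;
#' operations that need one fail fast by name via [require_covariates()].
#'
#' @param df a data.frame with at least `sample_id`, `kind`, `station`.
#' @return the validated data.frame with class `sample_frame`.
#' @export
sample_frame <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  needed <- c("sample_id", "kind", "station")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("sample_frame missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample_frame")
  if (!all(df$kind %in% c("source", "culture"))) {
    stop("kind must be 'source' or 'culture'")
  }
  if (any(is.na(df$station) | !nzchar(df$station))) stop("station must be non-empty")
  if (!"source_sample_id" %in% names(df)) df$source_sample_id <- NA_character_
  cult <- df$kind == "culture"
  src_ids <- df$sample_id[df$kind == "source"]
  dangling <- cult & !(df$source_sample_id %in% src_ids)
  if (any(dangling)) {
    stop("culture(s) with unresolved source_sample_id: ",
         paste(df$sample_id[dangling], collapse = ", "))
  }
  class(df) <- c("sample_frame", "data.frame")
  df
}

#' @rdname sample_frame
#' @param path file path of a tab-delimited metadata table.
#' @export
read_sample_frame <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE, quote = "")
  sample_frame(df)
}

#' @rdname sample_frame
#' @param frame a `sample_frame`.
#' @export
write_sample_frame <- function(frame, path) {
  utils::write.table(frame, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fail fast when a named covariate is absent
#' @param frame a [sample_frame].
#' @param covariates character vector of required column names.
#' @export
require_covariates <- function(frame, covariates) {
  miss <- setdiff(covariates, names(frame))
  if (length(miss)) {
    stop("required covariate(s) missing from sample_frame: ",
         paste(miss, collapse = ", "))
  }
  bad <- covariates[vapply(frame[covariates], function(x) anyNA(x), logical(1))]
  if (length(bad)) {
    stop("covariate(s) contain missing values: ", paste(bad, collapse = ", "))
  }
  invisible(frame)
}

#' Patristic distances between the tips of a phylogeny
#'
#' Reads a Newick tree and returns the matrix of patristic distances (sum of
#' branch lengths along the path between two tips), the phylogenetic
#' backbone of all MPD-type indices.
#'
#' @param tree a file path to a Newick file, a Newick string, or an
#'   [ape::phylo] object. Branch lengths are required on every edge.
#' @return a symmetric matrix of class `phylo_distances` with zero diagonal.
#' @export
tree_to_distances <- function(tree) {
  phy <- as_phylo(tree)
  if (is.null(phy$edge.length) || anyNA(phy$edge.length) ||
      length(phy$edge.length) != nrow(phy$edge)) {
    stop("tree has missing branch lengths")
  }
  if (anyDuplicated(phy$tip.label)) stop("duplicate tip labels in tree")
  d <- ape::cophenetic.phylo(phy)
  d <- d[phy$tip.label, phy$tip.label]
  phylo_distances(d)
}

# Coerce path / newick string / phylo to phylo.
as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1) {
    if (grepl("\\(", tree)) return(ape::read.tree(text = tree))
    return(ape::read.tree(tree))
  }
  stop("cannot interpret 'tree' as a phylogeny")
}

#' Construct/validate a patristic distance matrix
#' @param dist symmetric non-negative matrix with zero diagonal and
#'   matching dimnames (OTU ids).
#' @return the matrix with class `phylo_distances`.
#' @export
phylo_distances <- function(dist) {
  dist <- as.matrix(dist)
  if (is.null(rownames(dist)) || !identical(rownames(dist), colnames(dist))) {
    stop("phylo_distances needs identical row and column OTU ids")
  }
  if (any(dist < 0)) stop("negative patristic distance")
  if (any(abs(diag(dist)) > 1e-12)) stop("non-zero diagonal in distance matrix")
  if (max(abs(dist - t(dist))) > 1e-8 * max(1, max(dist))) {
    stop("distance matrix is not symmetric")
  }
  dist <- (dist + t(dist)) / 2
  diag(dist) <- 0
  class(dist) <- c("phylo_distances", "matrix", "array")
  dist
}

#' Construct a functional annotation map
#'
#' Holds OTU -> set-of-function assignments (FAPROTAX-style) plus a nesting
#' relation between function labels: `(narrow, broad)` means the narrow
#' function is a special case of the broad one (e.g. sulphate respiration
#' within respiration of sulfur compounds). The relation must be acyclic;
#' [curate_functions()] uses it to strip double counting.
#'
#' @param assignments named list: OTU id -> character vector of function
#'   labels (may be empty; unannotated OTUs may simply be absent).
#' @param nesting data.frame with character columns `narrow` and `broad`,
#'   or NULL for no nesting.
#' @return a list of class `function_map` with elements `assignments` and
#'   `nesting`.
#' @export
function_map <- function(assignments, nesting = NULL) {
  if (is.null(names(assignments)) && length(assignments) > 0) {
    stop("assignments must be a named list keyed by OTU id")
  }
  assignments <- lapply(assignments, function(x) unique(as.character(x)))
  if (is.null(nesting)) {
    nesting <- data.frame(narrow = character(), broad = character(),
                          stringsAsFactors = FALSE)
  }
  nesting <- as.data.frame(nesting, stringsAsFactors = FALSE)
  if (!all(c("narrow", "broad") %in% names(nesting))) {
    stop("nesting needs columns 'narrow' and 'broad'")
  }
  nesting$narrow <- as.character(nesting$narrow)
  nesting$broad <- as.character(nesting$broad)
  if (any(nesting$narrow == nesting$broad)) stop("function nested within itself")
  check_acyclic(nesting)
  structure(list(assignments = assignments, nesting = nesting),
            class = "function_map")
}

# Kahn-style topological check on the nesting relation.
check_acyclic <- function(nesting) {
  edges <- unique(nesting[, c("narrow", "broad")])
  while (nrow(edges) > 0) {
    # a 'leaf' is a label that is never a broad target (nothing nests in it)
    leaves <- setdiff(edges$narrow, edges$broad)
    if (length(leaves) == 0) stop("cycle in function nesting relation")
    edges <- edges[!(edges$narrow %in% leaves), , drop = FALSE]
  }
  invisible(TRUE)
}

#' Read/write functional annotation maps
#'
#' The assignment file is tab-delimited `otu_id<TAB>fn1;fn2;...` (the second
#' field may be empty); the nesting file is `narrow<TAB>broad`, one pair per
#' line. `#`-prefixed lines are ignored in both.
#'
#' @param assignments_path,nesting_path file paths; `nesting_path` may be
#'   NULL.
#' @return a [function_map].
#' @export
read_function_map <- function(assignments_path, nesting_path = NULL) {
  lines <- grep("^#", readLines(assignments_path, warn = FALSE),
                value = TRUE, invert = TRUE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  otus <- vapply(parts, `[`, character(1), 1)
  fns <- lapply(parts, function(p) {
    if (length(p) < 2 || !nzchar(p[2])) character() else
      strsplit(p[2], ";", fixed = TRUE)[[1]]
  })
  names(fns) <- otus
  nesting <- NULL
  if (!is.null(nesting_path)) {
    nesting <- utils::read.table(nesting_path, header = FALSE, sep = "\t",
                                 comment.char = "#", stringsAsFactors = FALSE,
                                 col.names = c("narrow", "broad"), quote = "")
  }
  function_map(fns, nesting)
}

#' @rdname read_function_map
#' @param fmap a [function_map].
#' @export
write_function_map <- function(fmap, assignments_path, nesting_path = NULL) {
  lines <- vapply(names(fmap$assignments), function(o) {
    paste0(o, "\t", paste(fmap$assignments[[o]], collapse = ";"))
  }, character(1))
  writeLines(lines, assignments_path)
  if (!is.null(nesting_path)) {
    utils::write.table(fmap$nesting, nesting_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(assignments_path)
}

#' Host (culture) genetic distances and traits
#'
#' @param culture_ids character vector of culture sample ids.
#' @param genetic_dist symmetric culture-by-culture p-distance matrix
#'   (proportion of differing sites, in `[0, 1]`, zero diagonal).
#' @param traits data.frame of numeric host covariates (one row per
#'   culture, e.g. mean cell perimeter in um), or NULL.
#' @return a list of class `host_frame`.
#' @export
host_frame <- function(culture_ids, genetic_dist, traits = NULL) {
  genetic_dist <- as.matrix(genetic_dist)
  if (!identical(dim(genetic_dist), c(length(culture_ids), length(culture_ids)))) {
    stop("genetic_dist dimensions do not match culture_ids")
  }
  if (any(genetic_dist < 0) || any(genetic_dist > 1)) {
    stop("p-distances must lie in [0, 1]")
  }
  if (max(abs(genetic_dist - t(genetic_dist))) > 1e-12) {
    stop("genetic_dist is not symmetric")
  }
  if (any(abs(diag(genetic_dist)) > 1e-12)) stop("non-zero diagonal in genetic_dist")
  dimnames(genetic_dist) <- list(culture_ids, culture_ids)
  if (!is.null(traits)) {
    traits <- as.data.frame(traits)
    if (nrow(traits) != length(culture_ids)) stop("traits rows != culture_ids")
    rownames(traits) <- culture_ids
  }
  structure(list(culture_ids = as.character(culture_ids),
                 genetic_dist = genetic_dist, traits = traits),
            class = "host_frame")
}

#' Consistency report for a data bundle
#'
#' Report-only validation: cross-references the count table, metadata, tree
#' and function map and lists problems without throwing. Unannotated OTUs
#' are informational (roughly half of real OTUs carry no functional
#' annotation); OTUs missing from the tree are fatal for phylogenetic
#' indices only.
#'
#' @param table a [count_table].
#' @param frame a [sample_frame].
#' @param tree a [phylo_distances] or NULL.
#' @param fmap a [function_map] or NULL.
#' @return a list of class `validation_report` with character vectors
#'   `fatal`, `fatal_phylo` and `info`; `is_clean()` is TRUE when both
#'   fatal slots are empty.
#' @export
validate_bundle <- function(table, frame, tree = NULL, fmap = NULL) {
  fatal <- character()
  fatal_phylo <- character()
  info <- character()
  unmatched <- setdiff(rownames(table), frame$sample_id)
  if (length(unmatched)) {
    fatal <- c(fatal, paste0("sample(s) absent from metadata: ",
                             paste(unmatched, collapse = ", ")))
  }
  cult <- frame[frame$kind == "culture", , drop = FALSE]
  dangling <- setdiff(stats::na.omit(cult$source_sample_id),
                      frame$sample_id[frame$kind == "source"])
  if (length(dangling)) {
    fatal <- c(fatal, paste0("dangling source_sample_id: ",
                             paste(dangling, collapse = ", ")))
  }
  if (!is.null(tree)) {
    occupied <- colnames(table)[colSums(table) > 0]
    missing <- setdiff(occupied, rownames(tree))
    if (length(missing)) {
      fatal_phylo <- c(fatal_phylo,
                       paste0("OTU(s) absent from tree (phylogenetic indices ",
                              "unavailable): ", paste(missing, collapse = ", ")))
    }
  }
  if (!is.null(fmap)) {
    unann <- setdiff(colnames(table), names(fmap$assignments))
    unann <- union(unann, names(Filter(function(x) length(x) == 0,
                                       fmap$assignments)))
    unann <- intersect(unann, colnames(table))
    if (length(unann)) {
      info <- c(info, sprintf("%d/%d OTUs without function assignment",
                              length(unann), ncol(table)))
    }
  }
  structure(list(fatal = fatal, fatal_phylo = fatal_phylo, info = info),
            class = "validation_report")
}

#' @rdname validate_bundle
#' @param report a `validation_report`.
#' @export
is_clean <- function(report) {
  length(report$fatal) == 0 && length(report$fatal_phylo) == 0
}

#' @export
print.validation_report <- function(x, ...) {
  if (is_clean(x) && length(x$info) == 0) {
    cat("validation: clean\n")
  } else {
    for (m in x$fatal) cat("FATAL:", m, "\n")
    for (m in x$fatal_phylo) cat("FATAL (phylo):", m, "\n")
    for (m in x$info) cat("info:", m, "\n")
  }
  invisible(x)
}

#' Deterministic substream seed derivation
#'
#' Hashes any sequence of scalars into a 32-bit non-negative integer, used
#' to give every replicate / culture / stage its own reproducible RNG
#' substream so that adding replicates never perturbs earlier ones.
#'
#' @param ... scalars (coerced to character) identifying the substream.
#' @return an integer in `[0, 2^31 - 30)`.
#' @export
stable_hash <- function(...) {
  parts <- unlist(lapply(list(...), as.character), use.names = FALSE)
  h <- 5381
  for (s in parts) {
    for (k in utf8ToInt(s)) h <- (h * 33 + k) %% 2147483629
    h <- (h * 33 + 124) %% 2147483629  # separator, so c("ab","c") != c("a","bc")
  }
  as.integer(h)
}
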