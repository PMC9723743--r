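#' Occurrence frequencies vs source relative abundances
#'
#' For the Sloan neutral model: over the cultures of the included stations,
#' `f_i` is the fraction of cultures containing OTU `i`, and `p_i` is the
#' OTU's mean relative abundance across the included stations' source
#' samples. OTUs observed in cultures but absent from every included
#' source (`p = 0`, `f > 0`) cannot be fit and are returned separately in
#' the `"unfittable"` attribute. Frequencies are only meaningful with
#' several cultures per station, hence the analysis is typically limited
#' to the stations with most isolates.
#'
#' @param cultures,sources [count_table]s.
#' @param frame a [sample_frame].
#' @param stations character vector of stations to include; each must have
#'   a source sample and at least 2 cultures.
#' @return data.frame with columns `otu`, `p`, `f` (only OTUs with
#'   `p > 0` or `f > 0`), attribute `unfittable` (data.frame of `p = 0,
#'   f > 0` OTUs), attribute `n_cultures`.
#' @export
occurrence_frequencies <- function(cultures, sources, frame, stations) {
  st_of <- stats::setNames(frame$station, frame$sample_id)
  cult_ids <- rownames(cultures)[st_of[rownames(cultures)] %in% stations]
  if (length(cult_ids) < 2) stop("fewer than 2 cultures in the included stations")
  per_station <- table(st_of[cult_ids])
  if (any(per_station < 2)) {
    stop("station(s) with fewer than 2 cultures: ",
         paste(names(per_station)[per_station < 2], collapse = ", "))
  }
  src_frame <- frame[frame$kind == "source" & frame$station %in% stations, ]
  src_ids <- intersect(src_frame$sample_id, rownames(sources))
  missing_st <- setdiff(stations, st_of[src_ids])
  if (length(missing_st)) {
    stop("station(s) without a source sample: ", paste(missing_st, collapse = ", "))
  }
  sm <- ct_matrix(sources)[src_ids, , drop = FALSE]
  rel <- sm / rowSums(sm)
  p <- colMeans(rel)
  f <- colMeans(ct_matrix(cultures)[cult_ids, , drop = FALSE] > 0)
  otus <- union(names(p)[p > 0], names(f)[f > 0])
  out <- data.frame(otu = otus, p = as.numeric(p[otus]),
                    f = as.numeric(f[otus]), row.names = NULL)
  out$p[is.na(out$p)] <- 0
  out$f[is.na(out$f)] <- 0
  unfit <- out[out$p == 0 & out$f > 0, , drop = FALSE]
  out <- out[out$p > 0, , drop = FALSE]
  attr(out, "unfittable") <- unfit
  attr(out, "n_cultures") <- length(cult_ids)
  out
}

#' Predicted occurrence frequency under the Sloan neutral model
#'
#' A taxon at metacommunity relative abundance `p` in a local community of
#' `N` individuals with migration parameter `m` has a local relative
#' abundance distributed Beta(N m p, N m (1 - p)); it is detected when at
#' least `detection_limit` of the `N` reads belong to it, so the expected
#' occurrence frequency is `1 - pbeta(detection_limit / N, ...)`.
#'
#' @param m migration parameter, > 0 (dimensionless).
#' @param p vector of source relative abundances in (0, 1].
#' @param N local community size in reads (the rarefaction depth).
#' @param detection_limit detection threshold in reads (default 1).
#' @return vector of predicted frequencies in `[0, 1]`.
#' @export
sloan_predict <- function(m, p, N, detection_limit = 1) {
  a <- N * m * p
  b <- N * m * (1 - p)
  if (any(a < 1e-12) || any(b < 1e-12)) {
    warning("N*m*p underflow; shape parameters clamped")
    a <- pmax(a, 1e-12)
    b <- pmax(b, 1e-12)
  }
  1 - stats::pbeta(detection_limit / N, a, b)
}

#' Fit the Sloan neutral community model
#'
#' Least-squares estimation of the migration parameter `m`: minimises
#' `sum (f_i - fhat_i(m))^2` over a log-spaced grid on
#' `[1e-6, 1e3]` followed by local refinement with [stats::optimise()].
#' Goodness of fit is Efron's pseudo R-squared, which may be negative when
#' the model fits worse than the mean.
#'
#' @param pf data.frame with columns `p` (in (0, 1]) and `f` (in [0, 1]),
#'   e.g. from [occurrence_frequencies()]. At least 5 OTUs.
#' @param N community size in reads (default 538, a typical culture
#'   rarefaction depth).
#' @param detection_limit detection threshold in reads (default 1).
#' @return a list of class `neutral_fit`: `m`, `N`, `detection_limit`,
#'   `pseudo_r2`, `n_otus_fit` and `table` (per-OTU `p`, `f`, `fhat`).
#' @export
fit_neutral <- function(pf, N = 538, detection_limit = 1) {
  pf <- pf[pf$p > 0, , drop = FALSE]
  if (nrow(pf) < 5) stop("need at least 5 OTUs with p > 0 to fit the neutral model")
  stopifnot(all(pf$p <= 1), all(pf$f >= 0), all(pf$f <= 1))
  sse <- function(m) {
    sum((pf$f - suppressWarnings(sloan_predict(m, pf$p, N, detection_limit)))^2)
  }
  grid <- 10^seq(-6, 3, length.out = 181)
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimise(function(lm) sse(exp(lm)), lower = log(lo), upper = log(hi))
  m <- exp(opt$minimum)
  if (!is.finite(opt$objective)) stop("neutral-model optimisation did not converge")
  fhat <- suppressWarnings(sloan_predict(m, pf$p, N, detection_limit))
  structure(list(m = m, N = N, detection_limit = detection_limit,
                 pseudo_r2 = pseudo_r2_efron(pf$f, fhat),
                 n_otus_fit = nrow(pf),
                 table = data.frame(otu = if ("otu" %in% names(pf)) pf$otu else
                                    seq_len(nrow(pf)),
                                    p = pf$p, f = pf$f, fhat = fhat,
                                    row.names = NULL)),
            class = "neutral_fit")
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat(sprintf("Sloan neutral model: m = %.4g (N = %d, detection %g reads)\n",
              x$m, as.integer(x$N), x$detection_limit))
  cat(sprintf("  %d OTUs fit, Efron pseudo-R2 = %.3f\n", x$n_otus_fit, x$pseudo_r2))
  invisible(x)
}

#' Efron's pseudo R-squared
#'
#' `1 - sum((f - fhat)^2) / sum((f - mean(f))^2)`. Equals 1 for a perfect
#' fit, 0 for a constant-mean predictor, and is negative when the model
#' predicts worse than the mean.
#'
#' @param f observed values.
#' @param fhat predicted values, same length (>= 2).
#' @return numeric; `NaN` with a warning when `f` has zero variance.
#' @export
pseudo_r2_efron <- function(f, fhat) {
  stopifnot(length(f) == length(fhat), length(f) >= 2)
  sst <- sum((f - mean(f))^2)
  if (sst == 0) {
    warning("pseudo R-squared undefined: observed values have zero variance")
    return(NaN)
  }
  1 - sum((f - fhat)^2) / sst
}
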