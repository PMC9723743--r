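#' One-sided empirical counts of randomised values around an observed value
#'
#' @param observed a single numeric value.
#' @param randomised numeric vector of per-replicate values (>= 1).
#' @return named integer vector `c(n_below, n_equal, n_above)` with ties
#'   counted as equal.
#' @export
empirical_counts <- function(observed, randomised) {
  stopifnot(length(observed) == 1, length(randomised) >= 1)
  c(n_below = sum(randomised < observed),
    n_equal = sum(randomised == observed),
    n_above = sum(randomised > observed))
}

#' Significance code for an observed-vs-ensemble comparison
#'
#' The comparison is one-sided toward the side opposite the bulk of the
#' randomised distribution (the side is picked from the position of the
#' observed value relative to the randomised mean): `"***"` when all
#' randomised values lie strictly on one side of the observed value,
#' `"**"` when between 1 and 10 values are equal to or on the opposite
#' side, `"ns"` otherwise.
#'
#' @param observed,randomised as in [empirical_counts()].
#' @return list with `code`, `side` (`"lower"` if the observed value sits
#'   below the randomised mean, else `"upper"`), `counts` and
#'   `n_opposite` (values equal to or beyond the observed value).
#' @export
significance_code <- function(observed, randomised) {
  counts <- empirical_counts(observed, randomised)
  side <- if (observed < mean(randomised)) "lower" else "upper"
  n_opposite <- if (side == "lower") {
    counts[["n_below"]] + counts[["n_equal"]]
  } else {
    counts[["n_above"]] + counts[["n_equal"]]
  }
  code <- if (n_opposite == 0) "***" else if (n_opposite <= 10) "**" else "ns"
  list(code = code, side = side, counts = counts, n_opposite = n_opposite)
}

#' Observed-vs-randomised comparison of the diversity index panel
#'
#' For each ensemble replicate the per-dataset mean indices
#' ([dataset_summary()]) are computed streaming (replicates are generated,
#' validated against their conservation laws with
#' [check_null_invariants()], summarised and discarded). For every index
#' and every procedure the observed mean is compared with the distribution
#' of randomised means via [significance_code()].
#'
#' @param bundle a [gen_scenario()] result or any list with `cultures`,
#'   `sources`, `frame`, `dist`, `fmap`.
#' @param ensembles named list of [make_ensemble()] objects (typically
#'   `list(lottery = ..., swap = ...)`).
#' @param which index subset, see [dataset_summary()].
#' @param check validate every replicate's conservation laws (default
#'   TRUE; violations are errors naming the replicate).
#' @return list of class `ensemble_result_set`: `observed` (named vector),
#'   `randomised` (list per procedure: replicate x index matrix of means)
#'   and `comparison` (data.frame: index, procedure, observed, mean,
#'   sd, side, n_opposite, code).
#' @export
run_fig5 <- function(bundle, ensembles,
                     which = c("shannon_otu", "shannon_fun", "richness_fun",
                               "mpd_within", "bc_otu", "bc_fun",
                               "mpd_between", "c_score", "c_score_raw"),
                     check = TRUE) {
  observed <- dataset_summary(bundle$cultures, bundle$dist, bundle$fmap, which)
  randomised <- lapply(ensembles, function(ens) {
    rows <- ensemble_map(ens, function(rd) {
      if (check) check_null_invariants(rd, bundle$cultures, bundle$frame)
      dataset_summary(rd$table, bundle$dist, bundle$fmap, which)
    })
    do.call(rbind, rows)
  })
  comparison <- do.call(rbind, lapply(names(randomised), function(proc) {
    do.call(rbind, lapply(names(observed), function(ix) {
      vals <- randomised[[proc]][, ix]
      sc <- significance_code(observed[[ix]], vals)
      data.frame(index = ix, procedure = proc, observed = observed[[ix]],
                 mean = mean(vals), sd = stats::sd(vals), side = sc$side,
                 n_opposite = sc$n_opposite, code = sc$code,
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(observed = observed, randomised = randomised,
                 comparison = comparison),
            class = "ensemble_result_set")
}

#' @export
print.ensemble_result_set <- function(x, ...) {
  print(x$comparison, digits = 4)
  invisible(x)
}

#' Variation partitioning of observed vs randomised datasets
#'
#' Applies [varpart2()] with identical variable sets and seeds to the
#' observed culture table and to every replicate of each ensemble, and
#' compares the observed adjusted unique fractions to the replicate
#' distributions with [empirical_counts()].
#'
#' @param bundle as in [run_fig5()].
#' @param ensembles named list of [make_ensemble()] objects.
#' @param X_host,X_env constraint matrices (rows aligned with the culture
#'   samples).
#' @param n_perm permutations for the observed partition.
#' @param n_perm_replicate permutations per replicate partition (smaller
#'   by default: 1000 replicates x full permutation budgets are wasteful).
#' @param seed integer seed.
#' @return list of class `fig6_result`: `observed` (a `varpart_result`),
#'   `replicates` (per procedure, data.frame of adjusted fractions and
#'   p-values), `summary` (per procedure mean +/- sd and comparison
#'   counts).
#' @export
run_fig6 <- function(bundle, ensembles, X_host, X_env, n_perm = 999,
                     n_perm_replicate = 99, seed) {
  observed <- varpart2(bundle$cultures, X_host, X_env, n_perm = n_perm,
                       seed = stable_hash(seed, "obs"))
  replicates <- lapply(ensembles, function(ens) {
    rows <- ensemble_map(ens, function(rd) {
      vp <- varpart2(rd$table[rownames(bundle$cultures), , drop = FALSE],
                     X_host, X_env, n_perm = n_perm_replicate,
                     seed = stable_hash(seed, "rep", rd$procedure,
                                        rd$replicate_index))
      data.frame(host_unique = vp$adj_fractions[["host_unique"]],
                 env_unique = vp$adj_fractions[["env_unique"]],
                 raw_host_unique = vp$fractions[["host_unique"]],
                 raw_env_unique = vp$fractions[["env_unique"]],
                 p_host = vp$p_host, p_env = vp$p_env)
    })
    do.call(rbind, rows)
  })
  summary <- do.call(rbind, lapply(names(replicates), function(proc) {
    df <- replicates[[proc]]
    do.call(rbind, lapply(c("host_unique", "env_unique"), function(fr) {
      obs <- observed$adj_fractions[[fr]]
      sc <- significance_code(obs, df[[fr]])
      data.frame(procedure = proc, fraction = fr, observed = obs,
                 mean = mean(df[[fr]]), sd = stats::sd(df[[fr]]),
                 n_opposite = sc$n_opposite, code = sc$code,
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(observed = observed, replicates = replicates,
                 summary = summary),
            class = "fig6_result")
}

#' Default host/environment constraint matrices for a scenario bundle
#'
#' Host set: PCNM eigenvectors of the host genetic p-distances plus the
#' standardised host traits. Environment set: PCNM eigenvectors of the
#' between-station geographic distances (expanded to cultures) plus
#' habitat and standardised, log-transformed environmental covariates.
#'
#' @param bundle a [gen_scenario()] result.
#' @param n_pcnm_host,n_pcnm_env maximum eigenvectors kept per set.
#' @return list with matrices `X_host` and `X_env`, rows aligned with
#'   `rownames(bundle$cultures)`.
#' @export
scenario_design <- function(bundle, n_pcnm_host = 5, n_pcnm_env = 3) {
  ids <- rownames(bundle$cultures)
  gd <- bundle$hosts$genetic_dist[ids, ids]
  ph <- pcnm(gd)
  Xh <- ph$vectors[, seq_len(min(n_pcnm_host, ncol(ph$vectors))), drop = FALSE]
  colnames(Xh) <- paste0("host_", colnames(Xh))
  tr <- bundle$hosts$traits
  if (!is.null(tr)) {
    Xh <- cbind(Xh, scale(as.matrix(tr[ids, , drop = FALSE])))
  }
  meta <- bundle$frame[match(ids, bundle$frame$sample_id), ]
  st <- unique(meta[, c("station", "x_km", "y_km")])
  Xe_list <- list()
  if (nrow(st) >= 3) {
    sd_mat <- as.matrix(stats::dist(st[, c("x_km", "y_km")]))
    dimnames(sd_mat) <- list(st$station, st$station)
    pe <- pcnm(sd_mat)
    sp <- pe$vectors[match(meta$station, st$station),
                     seq_len(min(n_pcnm_env, ncol(pe$vectors))), drop = FALSE]
    colnames(sp) <- paste0("space_", seq_len(ncol(sp)))
    Xe_list$space <- sp
  }
  Xe_list$habitat <- matrix(as.numeric(meta$habitat == "water"), ncol = 1,
                            dimnames = list(NULL, "habitat_water"))
  env_cov <- intersect(c("salinity", "nitrite"), names(meta))
  if (length(env_cov)) {
    ev <- as.matrix(meta[, env_cov, drop = FALSE])
    ev[, intersect("nitrite", env_cov)] <-
      log1p(ev[, intersect("nitrite", env_cov)])
    sd0 <- apply(ev, 2, stats::sd)
    ev <- ev[, sd0 > 0, drop = FALSE]
    if (ncol(ev)) Xe_list$env <- scale(ev)
  }
  Xe <- do.call(cbind, Xe_list)
  # drop constant/collinear environment columns (few stations = few dof)
  keep <- apply(Xe, 2, stats::sd) > 1e-12
  Xe <- Xe[, keep, drop = FALSE]
  q <- qr(scale(Xe, scale = FALSE))
  Xe <- Xe[, q$pivot[seq_len(q$rank)], drop = FALSE]
  rownames(Xh) <- rownames(Xe) <- ids
  list(X_host = Xh, X_env = Xe)
}

#' Run the full pipeline from a single configuration
#'
#' simulate -> preprocess -> randomise -> indices -> neutral fit ->
#' variation partitioning -> compare, fully driven by one configuration
#' list and reproducible from it alone (a missing seed is refused). The
#' JSON report contains no timestamps, so identical configurations yield
#' byte-identical reports.
#'
#' @param config a list (or path to a JSON file) with elements `seed`
#'   (required), and optionally `scenario` (arguments to
#'   [scenario_config()] besides seed), `n_replicates` (default 100),
#'   `n_perm` (default 199), `n_sweeps` (default 100), `depth_culture`
#'   (default 538), `depth_source` (default 2484), `noise_floor` (default
#'   4), `neutral_stations` (default: all stations).
#' @param out_dir optional directory; when given, the report
#'   (`report.json`) and processed tables are written there.
#' @return the report as a list (invisibly written to disk when `out_dir`
#'   is set).
#' @export
run_all <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$seed)) stop("config must name a seed (no silent nondeterminism)")
  cfgargs <- c(config$scenario, list(seed = stable_hash(config$seed, "scenario")))
  cfg <- do.call(scenario_config, cfgargs)
  n_rep <- config$n_replicates %||% 100L
  n_perm <- config$n_perm %||% 199L
  n_sweeps <- config$n_sweeps %||% 100L
  log_stage <- function(...) message(sprintf(...))

  log_stage("stage simulate: seed %d", cfg$seed)
  bundle <- gen_scenario(cfg)

  log_stage("stage preprocess")
  prep <- preprocess_bundle(bundle$cultures, bundle$sources,
                            noise_floor = config$noise_floor %||% 4L,
                            depth_culture = config$depth_culture %||% 538L,
                            depth_source = config$depth_source %||% 2484L,
                            seed = stable_hash(config$seed, "preprocess"))
  bundle$cultures <- prep$cultures
  bundle$sources <- prep$sources
  bundle$frame <- bundle$frame[bundle$frame$sample_id %in%
                                 c(rownames(prep$cultures), rownames(prep$sources)), ]

  log_stage("stage randomise: %d replicates per procedure", n_rep)
  ens <- list(
    lottery = make_ensemble("lottery", bundle$cultures, bundle$sources,
                            bundle$frame, n_replicates = n_rep,
                            base_seed = stable_hash(config$seed, "lottery")),
    swap = make_ensemble("swap", bundle$cultures, frame = bundle$frame,
                         n_replicates = n_rep,
                         base_seed = stable_hash(config$seed, "swap"),
                         n_sweeps = n_sweeps))

  log_stage("stage indices")
  fig5 <- run_fig5(bundle, ens)

  log_stage("stage neutral-fit")
  stations <- config$neutral_stations %||%
    unique(bundle$frame$station[bundle$frame$kind == "culture"])
  pf_obs <- occurrence_frequencies(bundle$cultures, bundle$sources,
                                   bundle$frame, stations)
  depth <- config$depth_culture %||% 538L
  # the fit follows the usual convention: only taxa actually observed in
  # the local communities enter (f > 0); source taxa that never appear in
  # any culture say nothing about the migration process
  fit_obs <- fit_neutral(pf_obs[pf_obs$f > 0, ], N = depth)
  r2_ens <- lapply(ens, function(e) {
    unlist(ensemble_map(e, function(rd) {
      pf <- occurrence_frequencies(rd$table, bundle$sources, bundle$frame,
                                   stations)
      fit_neutral(pf[pf$f > 0, ], N = depth)$pseudo_r2
    }))
  })

  log_stage("stage varpart")
  design <- scenario_design(bundle)
  fig6 <- run_fig6(bundle, ens, design$X_host, design$X_env,
                   n_perm = n_perm, n_perm_replicate = max(99, n_perm %/% 2),
                   seed = stable_hash(config$seed, "varpart"))

  report <- list(
    config = config,
    observed_indices = as.list(fig5$observed),
    fig5 = fig5$comparison,
    neutral_fit = list(m = fit_obs$m, pseudo_r2 = fit_obs$pseudo_r2,
                       n_otus_fit = fit_obs$n_otus_fit),
    neutral_r2_ensembles = lapply(r2_ens, function(v)
      list(mean = mean(v), sd = stats::sd(v))),
    varpart_observed = list(fractions = as.list(fig6$observed$fractions),
                            adj_fractions = as.list(fig6$observed$adj_fractions),
                            p_host = fig6$observed$p_host,
                            p_env = fig6$observed$p_env),
    fig6 = fig6$summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, dataframe = "rows")
    write_count_table(bundle$cultures, file.path(out_dir, "cultures_processed.tsv"))
    write_count_table(bundle$sources, file.path(out_dir, "sources_processed.tsv"))
    utils::write.table(fig5$comparison, file.path(out_dir, "fig5_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
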