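#' Scenario configuration for the synthetic-data generator
#'
#' Describes a world of several stations, each holding a diverse bacterial
#' source community (hundreds of OTUs with heavy-tailed lognormal
#' abundances), from which low-richness host microbiomes (1-19 OTUs, mean
#' about 8) are assembled by a mixture of abundance-proportional lottery
#' recruitment, host-linked selection with phylogenetic signal, and
#' phylogenetic limiting similarity (competition). The three process
#' strengths default to 0, i.e. the exact neutral lottery.
#'
#' @param n_stations number of stations (each contributes one source
#'   sample).
#' @param n_otus_pool regional OTU pool size.
#' @param abund_meanlog,abund_sdlog lognormal parameters of OTU abundances
#'   (dimensionless log-reads; sdlog 1.5 gives the heavy tail typical of
#'   16S surveys).
#' @param station_occupancy fraction of the pool present at a station.
#' @param station_turnover fraction of a station's membership replaced
#'   relative to the previous station, in `[0, 1]`.
#' @param n_cultures_per_station cultures (hosts) isolated per station.
#' @param richness_lambda Poisson mean of culture richness, truncated to
#'   `[1, 19]` (default 8, matching low-richness host microbiomes).
#' @param selection_strength sigma_host >= 0: multiplier strength of
#'   host-affinity selection on the lottery weight (0 = neutral).
#' @param phylo_signal >= 0: Brownian rate of host-affinity evolution
#'   along the bacterial tree (0 = affinities i.i.d. across OTUs).
#' @param competition_strength rho >= 0: limiting-similarity scale in
#'   patristic branch-length units (0 = no competition).
#' @param culturable_fraction fraction of the regional pool able to
#'   survive the common-garden (culture) environment; only these OTUs can
#'   be recruited into host microbiomes (default 0.5, mirroring the
#'   roughly half of environmental taxa that grow under lab conditions).
#' @param n_functions number of clade-structured function labels.
#' @param source_depth,culture_depth approximate total reads per source /
#'   culture sample before rarefaction.
#' @param seed master seed; every stochastic draw flows from it through
#'   named substreams, so adding cultures never perturbs earlier ones.
#' @return a validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_stations = 6L, n_otus_pool = 300L,
                            abund_meanlog = 0, abund_sdlog = 1.5,
                            station_occupancy = 0.6, station_turnover = 0.3,
                            n_cultures_per_station = 10L,
                            richness_lambda = 8,
                            selection_strength = 0, phylo_signal = 0,
                            competition_strength = 0,
                            culturable_fraction = 0.5, n_functions = 30L,
                            source_depth = 50000L, culture_depth = 2000L,
                            seed) {
  cfg <- list(n_stations = as.integer(n_stations),
              n_otus_pool = as.integer(n_otus_pool),
              abund_meanlog = abund_meanlog, abund_sdlog = abund_sdlog,
              station_occupancy = station_occupancy,
              station_turnover = station_turnover,
              n_cultures_per_station = as.integer(n_cultures_per_station),
              richness_lambda = richness_lambda,
              selection_strength = selection_strength,
              phylo_signal = phylo_signal,
              competition_strength = competition_strength,
              culturable_fraction = culturable_fraction,
              n_functions = as.integer(n_functions),
              source_depth = as.integer(source_depth),
              culture_depth = as.integer(culture_depth),
              seed = as.integer(seed))
  stopifnot(cfg$n_stations >= 1, cfg$n_otus_pool >= 2,
            cfg$n_cultures_per_station >= 1, cfg$richness_lambda > 0,
            cfg$selection_strength >= 0, cfg$phylo_signal >= 0,
            cfg$competition_strength >= 0, cfg$n_functions >= 1,
            cfg$culturable_fraction > 0, cfg$culturable_fraction <= 1,
            cfg$station_occupancy > 0, cfg$station_occupancy <= 1,
            cfg$station_turnover >= 0, cfg$station_turnover <= 1,
            cfg$abund_sdlog >= 0)
  if (is.na(cfg$seed)) stop("scenario_config requires a seed")
  structure(cfg, class = "scenario_config")
}

#' A selective/competitive preset of [scenario_config()]
#'
#' Convenience wrapper switching on host selection, phylogenetic signal
#' and competition at strengths that produce a clear but not caricatural
#' host imprint (see the methods vignette for the calibration rationale).
#'
#' @param seed master seed.
#' @param ... overrides passed to [scenario_config()].
#' @export
scenario_selective <- function(seed, ...) {
  args <- list(selection_strength = 2, phylo_signal = 0.1,
               competition_strength = 50, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(scenario_config, args)
}

#' Random pure-birth (Yule) phylogeny
#'
#' Generates the bacterial OTU tree: a Yule topology with the exponential
#' branch lengths of the pure-birth process, tips labelled
#' `OTU_0001, ...`. Deterministic per seed.
#'
#' @param n_otus number of tips (>= 2).
#' @param seed integer seed.
#' @return an [ape::phylo] object (serialise with [ape::write.tree()]).
#' @export
gen_tree <- function(n_otus, seed) {
  if (n_otus < 2) stop("a tree needs at least 2 tips")
  phy <- withr::with_seed(seed, ape::rphylo(n_otus, birth = 1, death = 0))
  phy$tip.label <- sprintf("OTU_%04d", seq_len(n_otus))
  phy
}

#' Generate source communities for every station
#'
#' Station 1 draws its membership from the regional pool at the configured
#' occupancy; each subsequent station keeps a fraction `1 - turnover` of
#' the previous station's members and replaces the rest with OTUs not
#' present there (at `turnover = 1` adjacent stations share no OTUs, pool
#' permitting; at 0 they are identical). Abundances of present OTUs are
#' lognormal deviates scaled to roughly `source_depth` reads and rounded.
#'
#' @param cfg a [scenario_config()].
#' @return list with `table` (source [count_table], one sample per
#'   station, ids `SRC_<station>`) and `frame` (a [sample_frame] with
#'   station coordinates and environmental covariates).
#' @export
gen_sources <- function(cfg) {
  pool <- sprintf("OTU_%04d", seq_len(cfg$n_otus_pool))
  k_target <- max(2L, round(cfg$station_occupancy * cfg$n_otus_pool))
  stations <- sprintf("ST%02d", seq_len(cfg$n_stations))
  counts <- matrix(0L, cfg$n_stations, cfg$n_otus_pool,
                   dimnames = list(paste0("SRC_", stations), pool))
  members_prev <- NULL
  withr::with_seed(stable_hash(cfg$seed, "sources"), {
    for (s in seq_len(cfg$n_stations)) {
      if (is.null(members_prev)) {
        members <- sample(pool, k_target)
      } else {
        n_keep <- round((1 - cfg$station_turnover) * length(members_prev))
        kept <- if (n_keep > 0) sample(members_prev, n_keep) else character()
        fresh_pool <- setdiff(pool, members_prev)
        n_new <- min(k_target - n_keep, length(fresh_pool))
        members <- c(kept, if (n_new > 0) sample(fresh_pool, n_new) else character())
      }
      ab <- stats::rlnorm(length(members), cfg$abund_meanlog, cfg$abund_sdlog)
      reads <- round_to_total(ab, cfg$source_depth)
      counts[s, members] <- reads
      members_prev <- members
    }
    coords <- matrix(stats::runif(2 * cfg$n_stations, 0, 100), ncol = 2,
                     dimnames = list(stations, c("x_km", "y_km")))
    frame <- data.frame(
      sample_id = rownames(counts),
      kind = "source",
      station = stations,
      habitat = rep_len(c("sediment", "water"), cfg$n_stations),
      source_sample_id = NA_character_,
      x_km = coords[, 1], y_km = coords[, 2],
      salinity = round(stats::rnorm(cfg$n_stations, 29.6, 3), 2),
      nitrite = round(stats::rlnorm(cfg$n_stations, log(30), 0.8), 2),
      stringsAsFactors = FALSE)
  })
  list(table = count_table(counts), frame = sample_frame(frame))
}

# scale positive weights to integers summing exactly to `total`, every
# entry at least 1 (largest-remainder rounding)
round_to_total <- function(w, total) {
  stopifnot(all(w > 0), total >= length(w))
  raw <- w / sum(w) * (total - length(w))
  fl <- floor(raw)
  rem <- total - length(w) - sum(fl)
  extra <- integer(length(w))
  if (rem > 0) {
    idx <- order(raw - fl, decreasing = TRUE)[seq_len(rem)]
    extra[idx] <- 1L
  }
  as.integer(fl + extra + 1L)
}

#' Generate host genotypes and host-OTU affinities
#'
#' Hosts are placed on their own random Yule tree; their pairwise genetic
#' p-distances are the (scaled) patristic distances, so host relatedness
#' is well defined. The affinity `a(h, i)` of host `h` for OTU `i` is a
#' zero-mean Gaussian field with covariance `K_host (x) (phylo_signal *
#' V_bact + I)`: correlated between hosts in proportion to their
#' relatedness (identical genotypes get identical affinity rows) and,
#' when `phylo_signal > 0`, evolving as Brownian motion along the
#' bacterial tree so closely related bacteria elicit similar host
#' affinities.
#'
#' @param cfg a [scenario_config()].
#' @param tree the bacterial [ape::phylo] from [gen_tree()].
#' @param sources output of [gen_sources()] (fixes the number of hosts per
#'   station).
#' @return list with `hosts` (a [host_frame] with a `cell_perimeter_um`
#'   trait), `affinity` (host x OTU matrix, rows standardised), and
#'   `station_of_host` (named character).
#' @export
gen_hosts <- function(cfg, tree, sources) {
  n_hosts <- cfg$n_stations * cfg$n_cultures_per_station
  stations <- sources$frame$station
  host_ids <- sprintf("CUL_%s_%02d",
                      rep(stations, each = cfg$n_cultures_per_station),
                      sequence(rep(cfg$n_cultures_per_station, cfg$n_stations)))
  station_of_host <- stats::setNames(rep(stations, each = cfg$n_cultures_per_station),
                                     host_ids)
  withr::with_seed(stable_hash(cfg$seed, "hosts"), {
    host_tree <- if (n_hosts >= 2) ape::rphylo(n_hosts, 1, 0) else NULL
    if (!is.null(host_tree)) {
      # random tip assignment: host relatedness independent of station
      host_tree$tip.label <- sample(host_ids)
      hd <- ape::cophenetic.phylo(host_tree)[host_ids, host_ids]
      gd <- hd / max(hd) * 0.05       # intraspecific p-distances are small
    } else {
      gd <- matrix(0, 1, 1, dimnames = list(host_ids, host_ids))
    }
    # host relatedness kernel (exponential in p-distance); the range is
    # kept short relative to the mean distance so that an appreciable part
    # of the affinity variance discriminates between hosts rather than
    # being a common component shared by all of them
    K_host <- exp(-gd / max(0.4 * mean(gd[upper.tri(gd)]), 1e-9))
    if (n_hosts == 1) K_host <- matrix(1, 1, 1, dimnames = list(host_ids, host_ids))
    V_b <- ape::vcv(tree)[tree$tip.label, tree$tip.label]
    V_b <- V_b / mean(diag(V_b))
    S_otu <- cfg$phylo_signal * V_b + diag(nrow(V_b))
    Z <- matrix(stats::rnorm(n_hosts * nrow(V_b)), n_hosts, nrow(V_b))
    affinity <- mat_sqrt(K_host) %*% Z %*% mat_sqrt(S_otu)
    dimnames(affinity) <- list(host_ids, tree$tip.label)
    # per-host standardisation keeps selection_strength on a common scale
    affinity <- t(scale(t(affinity)))
    # correlated host trait: Brownian-like along the host tree + noise
    base <- if (n_hosts >= 2) mat_sqrt(K_host) %*% stats::rnorm(n_hosts) else
      matrix(stats::rnorm(1))
    perim <- 50 + 8 * as.numeric(base) + stats::rnorm(n_hosts, 0, 2)
  })
  hosts <- host_frame(host_ids, gd,
                      traits = data.frame(cell_perimeter_um = round(perim, 2)))
  list(hosts = hosts, affinity = affinity, station_of_host = station_of_host)
}

# symmetric PSD matrix square root via eigendecomposition (tolerates exact
# duplicates, unlike chol)
mat_sqrt <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Assemble host microbiomes (cultures) with known ground truth
#'
#' Each culture from station `s` draws a richness `k` (Poisson truncated
#' to `[1, 19]`) and recruits `k` OTUs sequentially, without replacement,
#' from the station's source community with weight
#' `w(i) = p_is * exp(sigma * a(h, i)) * (1 - exp(-d_min(i)/rho))`,
#' where `p_is` is source relative abundance, `a` the host affinity,
#' and `d_min` the patristic distance to the nearest already-recruited OTU
#' (the competition factor is 1 for the first draw and when `rho = 0`).
#' With all strengths at 0 this is exactly the neutral lottery. Abundances
#' are lognormal deviates ranked to draw order (first recruit largest) and
#' scaled to about `culture_depth` reads.
#'
#' @param cfg a [scenario_config()].
#' @param sources output of [gen_sources()].
#' @param dist the bacterial [phylo_distances].
#' @param hosts output of [gen_hosts()].
#' @return list with `table` (culture [count_table]), `frame` (culture
#'   rows of a [sample_frame]) and `truth` (`ground_truth`: per-culture
#'   recruit/channel table, the affinity matrix, and `m_true`, the Sloan
#'   migration parameter implied by the generator when
#'   `selection_strength = 0`, else `NA`).
#' @export
gen_cultures <- function(cfg, sources, dist, hosts) {
  src_m <- ct_matrix(sources$table)
  src_of_station <- stats::setNames(rownames(src_m), sources$frame$station)
  host_ids <- hosts$hosts$culture_ids
  otus <- colnames(src_m)
  counts <- matrix(0L, length(host_ids), length(otus),
                   dimnames = list(host_ids, otus))
  recruits <- vector("list", length(host_ids))
  names(recruits) <- host_ids
  # the common-garden filter: a fixed random subset of the pool survives
  # culturing, identical for every host and station
  culturable <- withr::with_seed(stable_hash(cfg$seed, "culturable"), {
    sample(otus, max(2L, round(cfg$culturable_fraction * length(otus))))
  })
  for (h in host_ids) {
    st <- hosts$station_of_host[[h]]
    src <- src_m[src_of_station[[st]], ]
    present <- intersect(names(src)[src > 0], culturable)
    p <- src[present] / sum(src[present])
    aff <- hosts$affinity[h, present]
    sel_fac <- exp(pmin(pmax(cfg$selection_strength * aff, -40), 40))
    withr::with_seed(stable_hash(cfg$seed, "culture", h), {
      k <- draw_truncated_pois(cfg$richness_lambda, 1L, 19L)
      if (k > length(present)) {
        warning("richness capped at source richness for ", h)
        k <- length(present)
      }
      chosen <- character(k)
      channel <- character(k)
      for (j in seq_len(k)) {
        avail <- setdiff(present, chosen[seq_len(j - 1)])
        w_lot <- p[avail]
        comp <- rep(1, length(avail))
        if (cfg$competition_strength > 0 && j > 1) {
          dmin <- apply(dist[avail, chosen[seq_len(j - 1)], drop = FALSE], 1, min)
          comp <- 1 - exp(-dmin / cfg$competition_strength)
        }
        w_full <- w_lot * sel_fac[avail] * comp
        if (!any(w_full > 0)) w_full <- w_lot * comp  # selection overflow guard
        if (!any(w_full > 0)) {
          # every remaining candidate is fully excluded by competition
          # (zero patristic distance to a resident): community saturated
          chosen <- chosen[seq_len(j - 1)]
          channel <- channel[seq_len(j - 1)]
          warning("recruitment stopped at richness ", j - 1, " for ", h,
                  ": competition excludes all remaining candidates")
          break
        }
        pick <- if (length(avail) == 1) avail else
          sample(avail, 1, prob = w_full)
        chosen[j] <- pick
        # attribution: did the selection factor raise this OTU's odds
        # relative to the lottery-plus-competition baseline?
        p_full <- w_full[pick] / sum(w_full)
        p_base <- (w_lot * comp)[pick] / sum(w_lot * comp)
        channel[j] <- if (cfg$selection_strength > 0 && p_full > p_base)
          "selection" else "lottery"
      }
      k <- length(chosen)
      ab <- sort(stats::rlnorm(k, meanlog = 3, sdlog = 1.2), decreasing = TRUE)
      counts[h, chosen] <- round_to_total(ab, cfg$culture_depth)
    })
    recruits[[h]] <- data.frame(otu = chosen, channel = channel,
                                stringsAsFactors = FALSE)
  }
  st_row <- match(hosts$station_of_host[host_ids], sources$frame$station)
  frame <- data.frame(
    sample_id = host_ids,
    kind = "culture",
    station = unname(hosts$station_of_host[host_ids]),
    habitat = sources$frame$habitat[st_row],
    source_sample_id = unname(src_of_station[hosts$station_of_host[host_ids]]),
    x_km = sources$frame$x_km[st_row],
    y_km = sources$frame$y_km[st_row],
    salinity = sources$frame$salinity[st_row],
    nitrite = sources$frame$nitrite[st_row],
    stringsAsFactors = FALSE)
  m_true <- if (cfg$selection_strength == 0) {
    implied_sloan_m(src_m[, culturable, drop = FALSE], cfg) } else NA_real_
  truth <- structure(list(recruits = recruits, affinity = hosts$affinity,
                          culturable = culturable, m_true = m_true),
                     class = "ground_truth")
  list(table = count_table(counts), frame = frame, truth = truth)
}

draw_truncated_pois <- function(lambda, lo, hi) {
  for (i in 1:1000) {
    k <- stats::rpois(1, lambda)
    if (k >= lo && k <= hi) return(as.integer(k))
  }
  as.integer(pmin(pmax(round(lambda), lo), hi))
}

# Best-fit Sloan m for the generator's own expected occurrence
# frequencies under the neutral lottery: P(OTU recruited into a culture of
# richness ~ lambda) ~ 1 - (1 - p)^lambda, averaged over stations.
implied_sloan_m <- function(src_m, cfg) {
  src_m <- src_m[, colSums(src_m) > 0, drop = FALSE]
  rel <- src_m / rowSums(src_m)
  p <- colMeans(rel)
  keep <- p > 0
  f_exp <- colMeans(1 - (1 - rel[, keep, drop = FALSE])^cfg$richness_lambda)
  pf <- data.frame(p = p[keep], f = f_exp)
  fit <- try(fit_neutral(pf, N = cfg$culture_depth, detection_limit = 1),
             silent = TRUE)
  if (inherits(fit, "try-error")) NA_real_ else fit$m
}

#' Clade-structured functional annotation
#'
#' Draws `n_functions` internal nodes of the bacterial tree (uniformly
#' among nodes subtending at most half the tips) and assigns each a
#' function label carried by every tip in its clade, producing the strong
#' phylogenetic conservatism of real trait annotations. When one chosen
#' clade lies inside another, the corresponding labels are declared nested
#' (narrow within broad).
#'
#' @param tree the bacterial [ape::phylo].
#' @param n_functions number of clades/labels to draw.
#' @param seed integer seed.
#' @return a [function_map].
#' @export
gen_function_map <- function(tree, n_functions, seed) {
  n_tip <- length(tree$tip.label)
  clades <- ape::prop.part(tree)        # tip sets of every internal node
  sizes <- lengths(clades)
  eligible <- which(sizes >= 2 & sizes <= ceiling(n_tip / 2))
  withr::with_seed(seed, {
    picked <- sample(eligible, min(n_functions, length(eligible)),
                     replace = FALSE)
  })
  labels <- sprintf("fn_%03d", seq_along(picked))
  tip_sets <- lapply(clades[picked], function(ix) tree$tip.label[ix])
  assignments <- stats::setNames(
    lapply(tree$tip.label, function(t)
      labels[vapply(tip_sets, function(s) t %in% s, logical(1))]),
    tree$tip.label)
  pairs <- list()
  for (i in seq_along(tip_sets)) {
    for (j in seq_along(tip_sets)) {
      if (i != j && length(tip_sets[[i]]) < length(tip_sets[[j]]) &&
          all(tip_sets[[i]] %in% tip_sets[[j]])) {
        pairs[[length(pairs) + 1]] <-
          data.frame(narrow = labels[i], broad = labels[j])
      }
    }
  }
  nesting <- if (length(pairs)) do.call(rbind, pairs) else NULL
  function_map(assignments, nesting)
}

#' Generate a complete synthetic scenario bundle
#'
#' Runs tree, source, host, culture and function-map generation from one
#' [scenario_config()] and returns everything the downstream analysis
#' needs, with ground truth attached.
#'
#' @param cfg a [scenario_config()].
#' @return list of class `scenario_bundle`: `cultures`, `sources`
#'   ([count_table]s), `frame` (joint [sample_frame]), `tree`
#'   ([ape::phylo]), `dist` ([phylo_distances]), `fmap` (curated
#'   [function_map]), `hosts` ([host_frame]), `truth`, `cfg`.
#' @export
gen_scenario <- function(cfg) {
  tree <- gen_tree(cfg$n_otus_pool, stable_hash(cfg$seed, "tree"))
  dist <- phylo_distances(ape::cophenetic.phylo(tree))
  sources <- gen_sources(cfg)
  hosts <- gen_hosts(cfg, tree, sources)
  cultures <- gen_cultures(cfg, sources, dist, hosts)
  fmap <- curate_functions(gen_function_map(tree, cfg$n_functions,
                                            stable_hash(cfg$seed, "fmap")))
  frame <- sample_frame(rbind(as.data.frame(sources$frame)[names(cultures$frame)],
                              cultures$frame))
  structure(list(cultures = cultures$table, sources = sources$table,
                 frame = frame, tree = tree, dist = dist, fmap = fmap,
                 hosts = hosts$hosts, truth = cultures$truth, cfg = cfg),
            class = "scenario_bundle")
}

#' Write a scenario bundle to disk as plain text
#'
#' Emits the TSV/Newick file set ([read_count_table()]-compatible tables,
#' the tree, metadata, function map and nesting) plus `ground_truth.json`.
#'
#' @param bundle a [gen_scenario()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(bundle$cultures, file.path(dir, "cultures.tsv"))
  write_count_table(bundle$sources, file.path(dir, "sources.tsv"))
  write_sample_frame(bundle$frame, file.path(dir, "samples.tsv"))
  ape::write.tree(bundle$tree, file.path(dir, "otus.nwk"))
  write_function_map(bundle$fmap, file.path(dir, "functions.tsv"),
                     file.path(dir, "function_nesting.tsv"))
  truth <- list(
    m_true = bundle$truth$m_true,
    recruits = lapply(bundle$truth$recruits, function(df)
      list(otu = df$otu, channel = df$channel)))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
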