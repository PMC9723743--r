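# nullassembly

Null-model analysis of host-associated microbiome assembly.

Low-richness microbiomes of cultured micro-eukaryote hosts (diatoms, other
protists) are shaped by a mix of processes: a neutral *lottery*, in which a
bacterium's chance of joining a host is proportional to its abundance in
the environmental source community; host-linked *selection* with a
phylogenetic signal; and *competition* (limiting similarity) between
bacteria. `nullassembly` provides the full toolchain for separating these
signals when you have sample-by-OTU count tables for host cultures and
their source communities, a bacterial phylogeny, host genetic distances and
a functional annotation map:

* **Preprocessing** — noise floor on read counts, organelle-flag removal,
  rarefaction without replacement, curation of nested function labels
  (`noise_floor_filter()`, `drop_flagged_otus()`, `rarefy()`,
  `curate_functions()`, `annotate_functions()`).
* **Two bespoke null models** — `lottery_randomise()` re-assembles each
  culture from its station's source community with probability
  proportional to source abundance, preserving every sample's abundance
  multiset exactly (so Shannon diversity is invariant by construction);
  `quasiswap_randomise()` randomises abundances among the cultures of each
  station while preserving row totals, column totals and matrix fill.
  `make_ensemble()` streams 1000 reproducible replicates of either.
* **Diversity panel** — Shannon *H* (nats), functional richness,
  unweighted mean pairwise phylogenetic distance within and between
  communities, incidence Bray–Curtis (Sørensen), and the checkerboard
  C-score `mean[(R_i - S)(R_j - S)]` in raw and normalised
  (`/(R_i R_j)`) form.
* **Sloan neutral community model** — occurrence frequency of taxon *i*
  across cultures predicted as
  `f̂_i = 1 − BetaCDF(d/N; N m p_i, N m (1 − p_i))`, with the migration
  parameter *m* estimated by least squares and goodness of fit scored by
  Efron's pseudo-R² (`occurrence_frequencies()`, `fit_neutral()`).
* **Constrained correspondence analysis** — chi-square inertia
  decomposition with conditioning, PCNM spatial/phylogenetic eigenvectors,
  permutation tests (residual permutation under the reduced model),
  forward selection, VIF filtering and two-set variation partitioning with
  permutation-corrected adjusted R² (`cca()`, `pcnm()`, `forward_select()`,
  `vif_filter()`, `varpart2()`, `sample_type_cca()`).
* **A synthetic-data generator with ground truth** — `gen_scenario()`
  builds multi-station worlds (heavy-tailed source communities, a Yule
  bacterial phylogeny, host genotypes, clade-structured function labels)
  and assembles host microbiomes by lottery × selection × competition with
  known per-recruit attribution, so the whole inference chain can be
  validated without any sequence data.

## Worked example

Simulate a world with host selection and competition switched on, compare
the observed cultures against 100 lottery and 100 swap randomisations, fit
the neutral model, and partition variation between host and environment:

```r
library(nullassembly)

cfg    <- scenario_selective(seed = 7)   # 6 stations x 10 cultures
bundle <- gen_scenario(cfg)

ens <- list(
  lottery = make_ensemble("lottery", bundle$cultures, bundle$sources,
                          bundle$frame, n_replicates = 100, base_seed = 71),
  swap    = make_ensemble("swap", bundle$cultures, frame = bundle$frame,
                          n_replicates = 100, base_seed = 72))

fig5 <- run_fig5(bundle, ens)
subset(fig5$comparison, index %in% c("shannon_otu", "mpd_within",
                                     "bc_otu", "c_score"))
#>          index procedure observed  mean      sd  side n_opposite code
#> 1  shannon_otu   lottery    1.561 1.561 0.00000 upper        100   ns
#> 4   mpd_within   lottery    8.214 8.089 0.06422 upper          0  ***
#> 5       bc_otu   lottery    0.908 0.902 0.00421 upper          7   **
#> 8      c_score   lottery    0.881 0.866 0.00419 upper          0  ***
#> 10 shannon_otu      swap    1.561 1.571 0.02068 lower         30   ns
#> 13  mpd_within      swap    8.214 8.111 0.04627 upper          2   **
#> 14      bc_otu      swap    0.908 0.911 0.00292 lower         13   ns
#> 17     c_score      swap    0.881 0.888 0.00152 lower          0  ***
```

Reading the panel: the observed Shannon index equals every lottery
replicate exactly (the lottery preserves each sample's abundance multiset —
`n_opposite = 100` ties, coded `ns`), the observed within-community
phylogenetic diversity exceeds all 100 lottery means (`***`, the
overdispersion signature of competition), and the observed C-score (0.881)
sits between the lottery mean (0.866, more aggregated) and the swap mean
(0.888, more segregated) — the pattern expected when lottery recruitment
and host selection both act.

```r
pf  <- occurrence_frequencies(bundle$cultures, bundle$sources, bundle$frame,
                              unique(bundle$frame$station))
fit_neutral(pf[pf$f > 0, ], N = cfg$culture_depth)
#> Sloan neutral model: m = 0.001033 (N = 2000, detection 1 reads)
#>   112 OTUs fit, Efron pseudo-R2 = 0.259

design <- scenario_design(bundle)
varpart2(bundle$cultures, design$X_host, design$X_env,
         n_perm = 999, seed = 73)
#> CCA variation partitioning (fractions of total inertia):
#>          host_unique env_unique shared residual
#> raw           0.1132     0.1381 0.0110   0.7378
#> adjusted      0.0228     0.0684 0.0018   0.9069
#>   p(host unique) = 0.003, p(environment unique) = 0.001
```

The host uniquely explains 11.3% of the inertia (adjusted 2.3%,
p = 0.003) and the environment 13.8% (adjusted 6.8%, p = 0.001): selection
is detectable but the environmental imprint dominates, as expected when
lottery recruitment from distinct source communities does most of the
assembling.

## Command line

A thin CLI over the same functions ships in `inst/cli/nullassembly.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/nullassembly.R", package = "nullassembly"))')" \
  run-all --config config.json --out results/
```

Subcommands: `simulate`, `preprocess`, `randomise`, `indices`,
`neutral-fit`, `varpart`, `run-all`. `run-all` executes
simulate → preprocess → randomise → indices → neutral-fit → varpart →
compare from a single JSON config (a seed is mandatory; identical configs
produce byte-identical reports).

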