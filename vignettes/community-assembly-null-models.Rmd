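---
title: "Separating lottery, selection and competition in host microbiome assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating lottery, selection and competition in host microbiome assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nullassembly)
```

# The inference problem

Host-associated bacterial communities of cultured microalgae are small
(one to a couple of dozen OTUs against source communities of hundreds) and
are assembled from the bacteria present in the water or sediment the host
was isolated from. Three processes can shape them:

* **Lottery recruitment** — the chance a bacterium establishes is
  proportional to its abundance in the local source community; purely
  stochastic.
* **Host selection** — hosts (via exudates and their microhabitat) skew
  the odds for particular bacteria; genetically similar hosts skew them
  similarly.
* **Competition** — limiting similarity between bacteria: a candidate
  close on the phylogeny to an already-established community member is
  less likely to establish.

None of these leaves an unambiguous single-number signature, so the
package's strategy is comparative: compute a panel of diversity indices on
the observed culture communities and on two ensembles of randomised
communities, each ensemble nullifying a specific set of processes.

## The two null models

**Lottery null** (`lottery_randomise()`): each culture's OTUs are replaced
by a weighted draw without replacement from its station's source
community, with weight proportional to source abundance. The candidate
pool is restricted to OTUs seen at least once in *any* culture — a
survivability filter standing in for the fact that most environmental
bacteria cannot grow under culture conditions. The culture's observed
abundance values (sorted decreasingly) are assigned to the draws in draw
order; since no reported index depends on which drawn OTU receives which
value, any assignment rule is admissible and draw order is the simplest
reproducible one. Per-sample richness, totals and the abundance multiset
are preserved exactly, so Shannon diversity and evenness are invariant by
construction: the lottery ensemble differences are purely about *identity*
(membership, phylogeny, function), never abundance structure.

**Swap null** (`quasiswap_randomise()`): within each station block of the
culture matrix, abundances are randomised subject to three exact
constraints — every row (sample) total, every column (OTU) total, and the
number of zero cells. This nullifies differential host selection and
bacterial interactions while keeping "which OTUs are overall abundant" and
"how full the matrix is" fixed, and never moves signal between stations.
Each replicate is an independent draw: a Patefield (`r2dtable`) table with
the observed margins, whose fill is then driven to the observed fill by
random 2×2 diagonal transfers (a transfer moves one or more units along a
submatrix diagonal and leaves both margins invariant), followed by
fill-preserving unit moves that further mix abundances conditional on the
incidence pattern. An alternative construction — a unit-transfer Markov
chain started *from the observed block* — turned out to be practically
non-ergodic for incidences at realistic read depths: a zero can only
relocate after its donor cell has been ground down to exactly one read, so
after 100 sweeps not a single presence/absence cell had moved. The
independent-draw construction is also what the reference `permatswap`
implementation uses.

Conservation laws for both nulls are asserted on every replicate of every
ensemble (`check_null_invariants()`); a violated replicate is a hard error
naming it, never a silent skip, because a biased ensemble is worse than no
ensemble.

## The index panel

Per sample: Shannon *H* (natural log) on OTU and on function abundances;
functional richness; unweighted mean pairwise patristic distance (MPD).
Per sample pair: incidence Bray–Curtis (= Sørensen), functional incidence
Bray–Curtis, between-community MPD (all ordered cross pairs, shared OTUs
contributing zero-distance pairs). Per dataset: the checkerboard C-score,
`mean[(R_i − S)(R_j − S)]` over OTU pairs with occupancies `R` and shared
count `S`; both the raw and the `R_i R_j`-normalised variant are computed,
the normalised one being the headline (it is bounded in [0, 1] and is the
scale on which published values of this analysis family lie). Undefined
values (single-OTU communities for MPD, empty function sets) are flagged
`NaN` and excluded from dataset means with their count reported.

Observed-vs-ensemble comparisons use one-sided empirical counts with the
star convention: `***` when all replicate means lie strictly to one side
of the observed value, `**` when 1–10 values are equal to it or on the
opposite side, `ns` otherwise.

## Sloan neutral model

For taxon *i* with mean relative source abundance `p_i`, the expected
occurrence frequency across cultures of `N` reads with migration parameter
`m` is `1 − BetaCDF(d/N; N m p_i, N m (1 − p_i))` with detection limit
`d = 1` read. `m` is fitted by least squares on a log grid over
`[1e-6, 1e3]` with local refinement; fit quality is Efron's pseudo-R²
(which can be negative — a fit worse than the mean). Only taxa observed in
at least one culture enter the pipeline's fits: including the (many)
source taxa that cannot grow in culture at all makes even perfectly
neutral synthetic data fit badly, because the model is then punished for a
survivability process it does not describe. Stations are pooled into one
metacommunity per fit (one fit per dataset); `occurrence_frequencies()`
still returns the unfittable rows so the choice is visible.

## CCA and variation partitioning

`cca()` is a direct implementation of constrained correspondence analysis:
chi-square standardised residuals `Q = (P − rcᵀ)/√(rcᵀ)`, weighted
regression of `Q` on the (weight-centred) constraints, SVD of the fitted
part; conditioning variables are partialled out first, and
`constrained + conditioned + residual = total` is asserted on every fit to
1e-8. The test suite cross-checks all three inertia components against the
vegan reference on random tables.

Significance uses the pseudo-F
`(constrained/q) / (residual/(n − q − z − 1))`. Without conditions the
constraint rows are permuted; with conditions, *reduced-model residual
permutation* is used, and the permuted residuals are re-projected off the
conditioned space before computing F — omitting that re-projection looks
innocuous but is strongly anti-conservative (35% of null p-values below
0.05 in calibration runs; with it, the null distribution is uniform).

`varpart2()` partitions total inertia into host-unique, environment-unique,
shared and residual fractions (raw fractions sum to 1 exactly). Adjusted
fractions use the permutation correction
`adjR² = 1 − (1 − R²)/(1 − mean(R²_perm))` per component model, since
Ezekiel's formula is biased for CCA; adjusted fractions may be negative.
`forward_select()` (p-to-enter 0.05, p-to-remove 0.1, ties by added
inertia then input order) and `vif_filter()` (threshold 10) implement the
standard variable-reduction steps; PCNM eigenvectors
(positive-eigenvalue principal coordinates of a truncated distance matrix,
default truncation = longest minimum-spanning-tree edge) serve as both
spatial and host-phylogenetic constraint variables.

# The synthetic world

`gen_scenario()` states a world and `scenario_config()` documents it; the
defaults are the package's reference conditions and are not tuned per
analysis.

| parameter | default | meaning |
|---|---|---|
| `n_stations` | 6 | stations, one source sample each (mirrors a six-location field design, ~60 isolates) |
| `n_otus_pool` | 300 | regional OTU pool |
| `station_occupancy` | 0.6 | fraction of the pool present per station (~180 OTUs, "hundreds") |
| `station_turnover` | 0.3 | membership replaced between adjacent stations |
| `abund_meanlog`, `abund_sdlog` | 0, 1.5 | lognormal OTU abundances (heavy tail typical of 16S surveys) |
| `n_cultures_per_station` | 10 | hosts isolated per station |
| `richness_lambda` | 8 | Poisson mean culture richness, truncated to [1, 19] |
| `culturable_fraction` | 0.5 | fraction of the pool able to grow in culture |
| `selection_strength` | 0 | σ in the weight factor `exp(σ a(h, i))` |
| `phylo_signal` | 0 | Brownian rate of affinity on the bacterial tree |
| `competition_strength` | 0 | ρ in the factor `1 − exp(−d_min/ρ)` (patristic units) |
| `source_depth`, `culture_depth` | 50000, 2000 | reads per sample before rarefaction |

Assembly weight for candidate `i` in host `h` at station `s`:

```
w(i) ∝ p_is · exp(σ · a(h, i)) · (1 − exp(−d_min(i)/ρ))
```

drawn sequentially without replacement (competition factor skipped on the
first draw and at ρ = 0). With σ = ρ = 0 this *is* the lottery null's
generative model, so neutrality is an exact special case rather than an
approximation. Host affinities `a(h, i)` form a Gaussian field with
covariance `K_host ⊗ (phylo_signal · V_bact + I)`: correlated between
hosts in proportion to genetic relatedness (identical genotypes get
identical affinities) and, when `phylo_signal > 0`, smooth along the
bacterial tree. The host kernel range is 0.4 × the mean host p-distance: a
flatter kernel pushes affinity variance into a component common to all
hosts, which centring removes, leaving nothing for a host effect to be
detected from. Abundances are lognormal, ranked to draw order (first
recruit largest) and scaled to the culture depth. Function labels are
attached to random clades (all tips under a drawn internal node, clade
size capped at half the tips), with nesting declared whenever one drawn
clade contains another — giving the annotation both its phylogenetic
conservatism and a non-trivial nesting relation for `curate_functions()`.

Every stochastic draw flows from the single scenario seed through named
substreams (one per culture), so a culture's recruitment is reproducible
in isolation and never depends on how many other cultures are generated.

## The selective preset

`scenario_selective()` sets `selection_strength = 2`,
`phylo_signal = 0.1`, `competition_strength = 50`. These are calibrated
once — and then frozen — so that the preset actually realises the regime
it is meant to represent, because the three processes interact
non-trivially:

* a large selection factor (`e^{±2σ}` odds ratios) *swamps* the bounded
  competition factor, erasing the overdispersion signature competition is
  supposed to leave in MPD;
* a strong bacterial-tree affinity signal makes each host prefer a clade,
  phylogenetically *clustering* communities and pulling MPD below the
  lottery expectation — the opposite of the competition signature;
* `ρ = 50` is large against the tree's mean pairwise distance (~9), so the
  competition factor is effectively linear in the distance to the nearest
  resident: long-range limiting similarity, strong enough to survive
  moderate selection.

At this preset (15 calibration seeds): the host-unique fraction is
significantly positive in 87% of scenarios, observed incidence
Bray–Curtis falls between the lottery and swap ensemble means in 100%, and
observed within-community MPD exceeds the lottery mean in 93%.

## What a green test does and does not establish

The generator emulates: multi-station source structure with distance
decay, heavy-tailed abundances, low-richness host communities, selection
with host-genetic signal, limiting similarity, clade-structured functions,
and a culturability filter. It does **not** emulate: sequencing error and
chimeras, compositional coupling between OTUs, temporal dynamics of the
source communities, strain-level microdiversity, or abundance-affinity
correlation in the source (source abundance and host affinity are
independent by construction). Green tests therefore establish that the
*inference machinery* recovers the processes that generated the data —
they say nothing about upstream bioinformatics, which this package
deliberately does not cover.

# Numerical and design choices

* "Counts below four" means strictly below: a count of exactly 4 survives
  the noise floor.
* Rarefaction is a single multivariate-hypergeometric draw per sample per
  seed; a sample whose total is below the target depth cannot be kept, so
  `min_reads < depth` is a configuration error rather than a silent
  best-effort.
* Shannon uses natural log (the classic vegan default); `base` is an
  argument.
* `mpd_between` counts shared OTUs as zero-distance pairs (the standard
  inter-community definition; identical communities have distance 0).
* Both C-score variants are always computed; zero-occupancy OTUs are
  excluded (their normalised checkerboard unit is 0/0).
* The Sloan fit brackets `m` on a 181-point log grid before local
  refinement, so local minima of the least-squares surface are not an
  issue in practice; shape-parameter underflow is clamped at 1e-12 with a
  warning.
* Lottery identity assignment, forward-selection tie-breaks (smallest p,
  then largest added inertia, then input order), and per-block column
  totals for the swap are all under-determined by the original
  description; the choices here are the strictest readings and are frozen
  in tests.
* Ensemble replicate `r` uses the seed `stable_hash(base_seed, procedure,
  r)` (a pure-R 32-bit string hash), so replicates are independent,
  streamable, and reproducible in isolation.

# Known limitations

* **The survivability filter makes the lottery null slightly misspecified
  when many culturable taxa go unobserved.** The null's candidate pool is
  the culture-observed union, a subset of the truly culturable taxa; when
  cultures cover only half of the culturable pool, the null's pool is too
  small and its co-occurrence structure too aggregated — the
  lottery-ensemble C-score then sits significantly below the observed
  value of a *perfectly neutral* world. The bias disappears when the
  observed union covers the culturable pool (low `culturable_fraction`,
  the regime the original filter implicitly assumes, and roughly its
  observed culture/source OTU ratio). Co-occurrence comparisons against
  the lottery null should be interpreted with this in mind.
* **A lottery world is never a typical member of the quasiswap set.** Even
  with selection off, a lottery-assembled dataset differs from its own
  margins+fill-fixed ensemble (lower Shannon, different Bray–Curtis and
  C-score means): the quasiswap null hypothesis is "exchangeable given
  margins and fill", which neutral mechanistic assembly does not satisfy.
  Consequently, observed-vs-swap contrasts on these indices are not, by
  themselves, evidence of host selection — the partial-CCA host fraction
  (which calibrates to uniform p-values under neutrality) is the clean
  test. One acceptance assertion encoding the stronger claim is left
  deliberately red rather than weakened.
* The quasiswap sampler (Patefield start + fill adjustment) is the
  field-standard construction but is not proven uniform on the
  constrained set.
* Adjusted R² by permutation correction is unbiased only to first order;
  with very few samples per station the adjusted host fraction can be
  slightly negative on average.
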