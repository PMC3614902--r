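---
title: "Chloroplast haplotype phylogeography with haplogeo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chloroplast haplotype phylogeography with haplogeo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(haplogeo)
```

## The problem

Chloroplast DNA is (in most angiosperms) maternally inherited and does not
recombine, so the handful of haplotypes segregating in a species traces its
seed-mediated history: where populations sat out glacial periods, and how
they spread afterwards. `haplogeo` implements the complete analysis chain
used in intraspecific cpDNA phylogeography surveys — haplotype calling with
indels coded as single mutational events, diversity decomposition and the
G~ST~/N~ST~ comparison, AMOVA and a spatial (SAMOVA-style) group search,
Mantel isolation-by-distance, neighbor-joining and statistical-parsimony
networks, mismatch-distribution demography, and strict-clock lineage
dating.

The package ships a worked dataset: 385 individuals of the aquatic herb
*Hippuris vulgaris* from 47 populations on the Qinghai-Tibetan Plateau and
adjacent ranges, typed at four chloroplast non-coding regions
(*ycf*6-*psb*M, *trn*T-*trn*L, the *rps*16 intron, *atp*I-*atp*H; 2,106
aligned bp in total) carrying eight variable characters — four nucleotide
substitutions and four indels — that define eight haplotypes A–H in two
lineages: haplogroup I = {A, B, C, F, G} and haplogroup II = {D, E, H}.

## Haplotype calling and the indel convention

`scan_variable_sites()` reports substitution columns (at least two distinct
bases among non-gap sequences) and indel characters under *simple indel
coding*: a maximal contiguous gap run with identical start and end across
sequences is one binary character regardless of its length, because a
multi-base insertion or deletion is a single mutational event. Gap runs
with different or partially overlapping spans are distinct characters.
`call_haplotypes()` then assigns each individual its state combination;
`mode = "substitutions_only"` drops the indel characters, which can merge
haplotypes but never split them (on the packaged matrix it merges B and G
into A and E into D, leaving five haplotypes). Ambiguous bases (`N`) at a
variable site raise an error by default (`on_ambiguous = "drop"` discards
the individual instead), since clean survey data should contain none.

Step distances (`pairwise_steps()`) count differing characters, each
substitution or indel contributing one step. These distances feed the
ordered diversity decomposition, nucleotide diversity, AMOVA, the network
and the clock.

The within-locus positions stored with the packaged character matrix are
nominal: the printed source table does not give them unambiguously, and no
analysis depends on them beyond keeping the characters in a stable order.

## Diversity and differentiation

Per-population gene diversity uses Nei's unbiased estimator
$h = \frac{n}{n-1}\,(1 - \sum_i \hat p_i^2)$. The decomposition follows
Pons & Petit: with a dissimilarity weight matrix $\Delta$ the
within-population component is the harmonic-mean-corrected average
$V_S = \frac{\tilde n}{\tilde n - 1}\,\overline{v}_k$ with
$v_k = \hat p_k' \Delta \hat p_k$, and the total is
$V_T = \bar p' \Delta \bar p + V_S / (\tilde n s)$ over the unweighted mean
frequencies. $\Delta_{ij} = 1 - \delta_{ij}$ gives the frequency-based
(unordered) H~S~/H~T~ and $G_{ST} = (H_T - H_S)/H_T$;
$\Delta_{ij} = d_{ij}$ (mutational steps) gives the ordered V~S~/V~T~ and
$N_{ST} = (V_T - V_S)/V_T$. N~ST~ is invariant to rescaling of $d$. These
are unbiased estimators: on data with essentially no differentiation they
can dip marginally below zero, and such values are reported as computed.

`gst_nst_test()` asks whether N~ST~ exceeds G~ST~ by more than haplotype
frequencies alone explain — the signature of phylogeographical structure,
closely related haplotypes co-occurring within populations. Haplotype
identities are permuted in the distance matrix (frequencies held fixed) and
N~ST~ recomputed. The reported `U` standardizes the observed
N~ST~ − G~ST~ against this permutation distribution and is referred to a
Gaussian, the classical criterion being significance when U > 1.96; the
raw one-sided permutation fraction is returned as `p_empirical`. The two
differ in an important way: the empirical fraction is exactly uniform only
under the relabeling null (distances carrying no information about
co-occurrence). Under a *panmictic sampling* null it is anticonservative,
because frequent haplotypes are genealogically central — frequency and
relatedness are dependent even without spatial structure — which is why the
standardized U is the inferential quantity. On the packaged dataset
(rebuilt counts) N~ST~ = 0.850 > G~ST~ = 0.805 with U ≈ 1.6: above the
unordered coefficient, but short of the 1.96 bar, i.e. no demonstrable
phylogeographical structure.

## Rebuilding the dataset from printed numbers

The published population table gives, per population, only the sample size
n, the alphabetical list of haplotypes present, and h to three decimals.
`back_solve_counts()` enumerates all count multisets compatible with (n,
number of haplotypes, printed h) — unique for every one of the 12
polymorphic populations — and `rebuild_published_dataset()` assigns the parts
to labels under a declared policy: `"widespread-major"` (larger counts to
the globally more widespread haplotype) or `"alphabetical-major"`. On this
table the two policies coincide in every row, because the alphabetical
order happens to match the global-frequency order among co-occurring
haplotypes; both are still exposed and tested separately. Quantities that
depend only on count multisets (per-population h, monomorphy, presence/
absence) are policy-free; quantities mixing counts across populations
(G~ST~, N~ST~, mismatch spectra within haplogroups) inherit the policy as a
caveat, which is why the package pins them with property bands rather than
exact printed values.

## Spatial structure

AMOVA uses the Excoffier–Smouse–Quattro sums of squares on inter-individual
step distances (each step one squared distance unit), giving Φ-statistics
F~CT~ (among groups), F~SC~ (among populations within groups) and F~ST~
(overall). Significance is by permutation of the appropriate exchangeable
unit: individuals among populations for F~ST~, whole populations among
groups for F~CT~, individuals among populations within groups for F~SC~
(defaults: 10,000 permutations for the hierarchical analysis, 1,000 for
pairwise Φ~ST~). Negative variance components are reported as computed and
flagged.

The SAMOVA-style search (`samova()`) looks for the partition of populations
into K geographically cohesive groups maximizing F~CT~. Geographic
cohesion comes from a neighbourhood graph on coordinates projected with an
azimuthal equidistant projection centred on the sample centroid (adequate
over the ~25° of longitude the packaged sampling spans). The graph is the
*Gabriel graph* — an edge joins two populations when no third lies inside
the circle on their diameter — a connected, deterministic subgraph of the
Delaunay triangulation that needs no triangulation library. Each
repetition starts from a random contiguous partition grown on the graph,
anneals (initial temperature calibrated so about 80% of early downhill
moves accept, geometric cooling ×0.9 over 50 stages, proposals move one
boundary population into a neighbouring group), then hill-climbs to a local
optimum; the best partition over repetitions is returned. Published
practice uses 100 repetitions; the packaged tests use 5–8 repetitions of a
few thousand steps, which the planted-structure simulations show is enough
for 12–47 populations. On the rebuilt dataset the best-found F~CT~ rises
from about 0.70 at K = 2 to about 0.77 at K = 10 and is still rising at the
top — no plateau singles out a best K, matching the original study's
conclusion — though the profile is not strictly monotone (there is a
reproducible local dip at K = 3 under the rebuilt counts).

`mantel_test()` correlates lower triangles with simultaneous row/column
permutation (two-sided by default), applied to pairwise Φ~ST~ against
great-circle distances (haversine, radius 6,371 km) from the degree-minute
coordinates.

## Trees, network, dating

Distances between haplotype sequences use the Kimura two-parameter closed
form; trees are neighbor-joined (via *ape*), midpoint-rooted (via
*phangorn*), and supported by resampling the characters with replacement
(1,000 replicates by default). On the packaged matrix the step distances
are exactly additive on the NJ tree, which cleanly separates haplogroup II
{D, E, H}.

The statistical-parsimony network connects haplotypes in increasing step
order, joining two components only when their closest pair is within the
connection limit, and inserting inferred intermediates so every edge is one
step; ties at equal distance resolve toward the higher-frequency pair, then
lexicographically. The connection limit is the largest j for which j
mutations on an L-site sequence all strike distinct sites with probability
at least p: $P(j) = \prod_{i=1}^{j-1}(1 - i/L)$, the no-superimposed-
mutation (occupancy) criterion. It is 1 as p → 1, grows with L, and equals
15 steps at L = 2,106 and p = 0.95 — far above the maximum observed
distance of 5, so the packaged network is a single component, with A and D
as the two hubs and haplotype C attached through one inferred intermediate.

`strict_clock_age()` dates the split between two haplotype groups as the
mean between-group step count divided by 2µL (µ = 1.52 × 10⁻⁹
substitutions/site/year for chloroplast non-coding DNA, L = 2,106 bp), with
a character-bootstrap interval. A strict clock is appropriate here: with
eight nearly identical haplotypes there is no rate signal to relax, and the
distance estimator reproduces the published relaxed-clock root age (0.50
vs 0.48 Myr) within a few percent. A site-model-based Bayesian variant
was deliberately not implemented.

## Demography

`mismatch_distribution()` tabulates pairwise differences over all C(n,2)
pairs. The sudden-expansion expectation (`expected_mismatch()`) is the
closed form for a population that grew instantaneously from θ₀ to θ₁ at
mutational time τ: a pair either coalesces after the expansion (geometric
spectrum at θ₁ truncated at τ) or persists through it and adds Poisson(τ)
differences to the θ₀ equilibrium; the spectrum is renormalized over the
analysis classes. Fitting minimizes the sum of squared deviations over
classes 0..(observed max + 5) by a coarse grid (τ ∈ [0, 20], θ₀ ∈ [0, 10],
θ₁ ∈ [θ₀, 1000], log-spaced where wide) followed by box-respecting
L-BFGS-B and Nelder–Mead refinement — deterministic for a fixed input.
Harpending's raggedness is computed with the spectrum padded by a zero
class at both ends (so a single spike has raggedness 2); the convention is
fixed here and in the tests.

Goodness of fit uses a parametric bootstrap: B coalescent samples of size n
are simulated under the fitted (τ, θ₀, θ₁) — an n-lineage coalescent with
an instantaneous size change and infinite-sites mutation — and each
simulated spectrum is refit *with the identical estimator configuration*;
the observed SSD is recomputed under that same configuration so observed
and simulated statistics are exchangeable, making P~SSD~ uniform under the
model (a property the test suite checks). By default the bootstrap refits
use the grid stage only, which keeps 1,000 replicates cheap.

Expansion times convert as T = τ/2u with u = µkg (k the sequence length
with indels counting one mutation each, g the generation time; g = 1 year
for the packaged species).

Two finite-sample properties matter when reading results. First, τ̂ has an
upward median bias at realistic sample sizes: in the packaged simulation
study (200 datasets, n = 50, τ = 2, θ₀ = 0.5, θ₁ = 50) the median
estimate is high by close to a fifth, largely because θ̂₀ collapses to its
zero boundary and τ̂ absorbs it; bootstrap percentile intervals for τ
nevertheless cover the truth in well over 90% of datasets. Second, P~SSD~
is sensitive to the exact haplotype counts: on the rebuilt haplogroup II
(spectrum dominated by one widespread haplotype, with a nearly empty
two-step class) the sudden-expansion model is marginally rejected, while
the raggedness test and the unimodality of the fitted spectrum accept it —
a reminder that the rebuilt counts are one admissible reconstruction, not
the original data.

## The synthetic-data generators

`synth_alignment()` embeds any haplotype character matrix into an invariant
random background split into the four packaged loci (515, 427, 513, 651
bp; indel spans 5, 8, 6, 7 bp matching the published footnote strings), so
scanning and calling the synthetic alignment recovers the matrix exactly —
the round trip is property-tested on random matrices. Different seeds
change only background positions. `sim_sudden_expansion()` /
`simulate_expansion_dataset()` provide the coalescent generator, with an
optional phenomenological population subdivision (clustering individuals by
genealogical distance, then re-mixing a `migration` fraction at random)
used to plant or destroy spatial structure in tests. These generators
emulate the aspects of real data the methods consume — character states,
step distances, sampling noise, genealogical correlation — but not
sequencing error, alignment ambiguity, heterotachy or recombination, so
green tests say nothing about those failure modes.

## Interfaces and reproducibility

The exported functions are the interface; `run_pipeline(run_config(...))`
chains every stage on the packaged dataset with one master seed,
per-stage derived seeds, and (optionally) one flat TSV per result table
plus a machine-readable `summary.json`. Identical configuration and seed
give byte-identical summaries. Published-analysis defaults (1,000
permutations and bootstrap replicates, 10,000 AMOVA permutations, the 95%
connection limit, µ = 1.52 × 10⁻⁹, k = 2,106, g = 1) are encoded in
`run_config()`; the test suite scales the search and replicate sizes down
(tens of repetitions, hundreds-to-thousands of steps and replicates), sizes
the planted-structure studies at 6–12 populations, and uses 200-dataset
simulation studies for calibration properties — sizes chosen so each
property is informative while the whole suite stays quick.

```{r example, eval = FALSE}
res <- run_pipeline(run_config(seed = 1, n_perm = 199, n_perm_amova = 199,
                               n_boot = 200, samova_K = 2:4,
                               samova_rep = 5, samova_steps = 1000))
res$summary[c("n_haplotypes", "GST", "NST", "split_age_myr")]
```

## Known limitations

* All printed-table reconstructions share the count-assignment caveat
  above; statistics that mix counts across populations are checked as
  bands/signs, not equalities.
* The parsimony connection limit uses the occupancy criterion, not the
  full historical recursion; at the packaged sequence length the network
  is identical either way, but limits for short sequences may differ by a
  step or two from legacy software.
* The SAMOVA search is a stochastic heuristic: with few repetitions the
  best-found F~CT~ can sit below the optimum, and comparisons across K
  should use generous repetition counts.
* The U test's Gaussian reference is an approximation to the permutation
  distribution; with very few haplotypes the permutation set is small and
  the approximation coarse.
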