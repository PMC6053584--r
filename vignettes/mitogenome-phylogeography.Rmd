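---
title: "Methods: whole-mitogenome phylogeography with mitophylogeo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-mitogenome phylogeography with mitophylogeo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitophylogeo)
```

## What the package does

`mitophylogeo` analyses alignments of whole mitochondrial genomes sampled
from multiple populations — the data regime of marine-fish phylogeography
surveys, where on the order of 150 near-identical sequences of ~16.6 kb come
from 10–14 sampling locations. Because mtDNA is effectively clonal and
maternally inherited, the whole genome behaves as a single non-recombining
locus: every analysis here treats a sequence as one haplotype and builds on
the matrix of pairwise nucleotide differences.

The stages are: (1) optional base calling from two-strand microarray
intensities, (2) variable-site classification and haplotype collapsing,
(3) diversity statistics, (4) AMOVA-based structure inference (global,
pairwise, and spatially constrained), (5) neighbor-joining phylogeny with
bootstrap and outgroup-calibrated clock dating, (6) a statistical-parsimony
haplotype network, (7) mismatch-distribution expansion dating, and (8) a
Monte Carlo randomization test of phylogeographic structure. A
structured-coalescent simulator with known truth backs the test suite.

## Microarray base calling

Each position is interrogated on both strands by four channels (A, C, G, T).
The call is the channel with the highest intensity; its confidence is the
differential signal-to-noise ratio

$$\mathrm{dS/N} = \frac{I_{(1)} - I_{(2)}}{\sum_b I_b},$$

the gap between the two strongest signals relative to the total. Calls
agreeing on both strands with dS/N ≥ 0.13 on each are *strong*; calls with
0.10 ≤ dS/N < 0.13 are retained only when they agree with the reference
(*weak_ref*); anything else — strand disagreement, dS/N < 0.10, or a dead
spot — is *ambiguous* and the position is excluded from downstream analyses.
The two thresholds are exposed as arguments (`strong`, `weak`) with these
defaults; they are empirical instrument calibrations, not tunables of the
statistics.

## Site classification conventions

Coordinates are 1-based and inclusive throughout. A column is *variable*
when ≥ 2 nucleotide states occur among unambiguous characters;
*parsimony-informative* when ≥ 2 states each occur in ≥ 2 sequences;
otherwise a *singleton*, so `variable = informative + singletons` holds for
substitution sites. Each unordered pair of bases observed at a site is
tallied as a transition (A/G, C/T) or transversion, so a triallelic site
contributes one variable site but several changes — this keeps the
substitution accounting consistent with 3–4-fold degenerate sites being
reported separately. Columns containing any ambiguity code are excluded
wholesale (the conservative reading of "unresolvable positions were
excluded"), and pure gap-versus-base variation is counted as an indel site,
not a substitution. Tandem-repeat arrays are collapsed to one repeat unit
before analysis; `collapse_tandem_repeats()` returns the old→new coordinate
map so annotations can be carried across.

## Diversity and the mismatch model

Haplotype diversity is Nei's unbiased estimator
$H_d = \frac{n}{n-1}(1 - \sum_i p_i^2)$; nucleotide diversity π is the mean
per-site pairwise difference with pairwise deletion of gaps and ambiguities
(complete deletion is available via a flag; pairwise deletion is the default
because it uses all resolvable sites per pair, the common convention for
these estimators).

The mismatch distribution is the histogram of pairwise differences over all
$\binom{n}{2}$ pairs. The sudden-expansion model is derived from the
two-epoch pairwise coalescent: measuring time in units of $1/(2u)$ (with $u$
the per-genome, per-generation mutation rate), the coalescence hazard of a
pair is $1/\theta_1$ more recently than the expansion time τ and
$1/\theta_0$ before it, and mutations accrue as a Poisson process of rate 1.
The probability of observing $k$ differences integrates to incomplete-gamma
closed forms (`expected_mismatch()`); at τ = 0 it collapses to the geometric
equilibrium $\theta^k/(1+\theta)^{k+1}$, and for $\theta_1 \to \infty$,
$\theta_0 \to 0$ it approaches the Poisson wave with mean τ. Fitting is
bounded least squares of the observed relative frequencies over
$(\tau, \theta_0, \theta_1)$ with $0 \le \theta_0 \le \theta_1$, from three
deterministic starting points; the sum of squared deviations is reported so
alternative fits are comparable. A degenerate histogram (all pairs
identical) short-circuits to τ̂ = 0 with a flag.

## Clock conventions

`divergence_rate(mean_distance, calibration_age)` defines the *two-lineage*
divergence rate (substitutions/site/year); the per-lineage rate is half of
it. Expansion dating uses the per-lineage genome rate
$u = \text{lineage rate} \times L$ in $t = \tau / (2u)$. This pairing — a
two-lineage rate from the calibration, a one-lineage genome rate in the
τ-to-time conversion — is the only bookkeeping under which both of the
standard published quantities (a rate of order $10^{-8}$ from a
few-Myr calibration at ~4% divergence, and expansion times of order
$10^5$ years from τ ≈ 20 on a 16.6-kb genome) come out simultaneously; it is
asserted as a round-trip identity in the tests. The printed waiting time
between substitutions is $1/(\text{rate} \times L)$ computed from unrounded
inputs. Node dating on the NJ tree assumes a strict clock: the rate is the
*mean* root-to-tip path length divided by the calibration age, and each
node's age is its mean path to descendant tips divided by that rate.
Mean-path (rather than single-path) averaging makes dated ages deterministic
and reproducible on non-ultrametric trees. The root is placed at the
midpoint of the outgroup's pendant edge; with a distant outgroup this
midpoint is a good proxy for the divergence point, and the residual bias is
covered by the recovery tolerance below.

## AMOVA, pairwise Phi-ST and the FDR correction

Pairwise nucleotide-difference counts enter the molecular-variance framework
as squared distances. Sums of squares come from pair sums
($SSD = \sum_{i<j} \delta^2_{ij}/N$ and its within-stratum analogues), and
variance components from the standard unequal-sample-size coefficients. The
two-level analysis yields Φ~ST~; the three-level analysis yields Φ~CT~
(among groups), Φ~SC~ (among populations within groups) and Φ~ST~. The
permutation schemes follow the hierarchy: individuals among populations for
Φ~ST~, whole populations among groups for Φ~CT~, individuals among
populations within groups for Φ~SC~. P-values use the unbiased
$(b+1)/(B+1)$ convention so no test reports exactly zero. Default
permutation counts follow survey practice (10^5 for the global AMOVA, 10^4
for Mantel); the pipeline exposes them as configuration and records the
count and seed in every output.

Negative Φ estimates (sampling noise around zero) are retained internally;
clamping to .000 is a rendering option only, matching how such tables are
usually printed. For the family of $m$ pairwise tests the modified
false-discovery-rate correction is applied as the fixed critical level
$\alpha / \sum_{i=1}^m 1/i$ — the reading that reproduces the published
critical levels at both family sizes — with the step-up procedure available
through `p.adjust`-style workflows if preferred. Populations with fewer than
3 samples are excluded from pairwise comparisons by default (`min_pop_n`),
since a two-sample population cannot support a meaningful within-population
variance.

Isolation by distance correlates linearized genetic distance
$\Phi/(1-\Phi)$ with great-circle distance (haversine, R = 6371 km) over
population pairs, with one-tailed row/column permutation significance; cells
with Φ = 1 have infinite linearized distance and are excluded with a
warning. PCoA is classical metric scaling; axes with negative eigenvalues
are dropped from the percent-variance denominator.

## SAMOVA search

The spatial AMOVA searches over geographically contiguous K-partitions of
populations for the grouping maximizing Φ~CT~. Contiguity comes from a
Delaunay-derived neighbor graph on locally projected coordinates (complete
graph below 4 populations; path graph for collinear sites; nearest-neighbor
augmentation if the empty-circumcircle pass leaves an isolated vertex).
Each of `n_runs` independent simulated-annealing runs starts from a random
contiguity-respecting partition grown from K seeds; a proposal moves one
border population to an adjacent group (groups stay non-empty), accepted
when it improves Φ~CT~ and otherwise with probability
$\exp(\Delta/T)$ under geometric cooling ($T_0 = 0.1$, ratio 0.9 per 100
steps — Φ is bounded by 1, so $T_0$ is a tenth of the statistic's scale).
"Iterations" in the survey-literature sense are independent runs; the
steps-per-run is a separate configuration default. The reported Φ~CT~ is
always recomputed exactly by `amova()` on the reported grouping (asserted in
the tests), and for ≤ 8 populations at K = 2 the annealing optimum is
verified against exhaustive enumeration of contiguous bipartitions. The
Φ~CT~ p-value permutes populations among groups; with few populations this
permutation set is small and the p-value correspondingly granular, which is
why the output records the permutation count.

## Statistical-parsimony network

The connection limit is the largest number of steps $j$ for which the
probability that a $j$-step connection is parsimonious is at least the
chosen confidence (0.90 here). We model a pair of sequences differing at $j$
of $m$ sites with a per-site Poisson substitution process whose intensity λ
is the Jukes–Cantor correction of $p = j/m$; the connection is parsimonious
when every differing site changed exactly once and no identical site hides
an even number of hits, giving

$$P_{\mathrm{pars}}(j) = P(X=1 \mid \text{differ})^{\,j}\,
  P(X=0 \mid \text{same})^{\,m-j}.$$

The implementation evaluates the conditional terms by a truncated recursion
over the Poisson series; the test suite re-derives them from the analytic
closed forms. The limit is non-decreasing in sequence length and decreasing
in confidence, both asserted as properties.

Network construction joins haplotypes in order of increasing distance (ties
broken by total haplotype frequency, then lexicographic ids, so the result
is deterministic); joins beyond the limit leave separate components, and
multi-step joins are filled with latent single-step nodes. Latent nodes are
abstract step counters, not base-by-base ancestral reconstructions — the
network is a visualization of mutational adjacency, not an ancestral-state
claim. Alternative equal-length connections between the same two components
are retained as explicit reticulation loops by default (`resolve_loops =
TRUE` reduces to a spanning forest); an indel step counts as one change,
consistent with indels being counted among variable sites. With no limit and
unique distances the joins reduce to the minimum spanning tree, which is the
oracle used in the tests.

## Monte Carlo test of phylogeographic structure

A partition model assigns each included population to one of (typically
four) partitions; tips of excluded populations are pruned. The observed
statistic is the parsimony length $L$ of this partition character on the
tree — computed by the Hartigan generalization of the Fitch downpass, which
is exact on multifurcating trees (the set-intersection rule is its binary
special case) and is verified against a unit-cost Sankoff dynamic program.
The null distribution permutes tip states uniformly among the included tips,
keeping partition counts fixed; randomizing states on the fixed observed
topology (rather than drawing random topologies) is the interpretation that
preserves the per-model sample counts and makes the tail probability
well-defined. C% is the *inclusive* tail,
$100 \times \#\{L_{\text{rand}} \le L_{\text{obs}}\}/n_{\text{rand}}$, and
can legitimately print 0.00 when no permutation attains the observed
clustering. Because $L$ is integer-valued, the raw inclusive tail is
discrete and conservative under the null; the calibration test therefore
checks uniformity of the tie-randomized rank of $L_{\text{obs}}$ among the
null lengths, the standard discreteness correction. The test reports the
full null multiset so users can apply any tail convention.

## The synthetic-data generator

`sim_config()` / `generate_dataset()` implement a structured coalescent:
demes of haploid size `Ne` exchanging lineages at `migration_rate` per
lineage per generation (island model), or merging into ancestral demes at
`split_time` (optionally in two tiers via `group_split`), or a single
population with a sudden size change for expansion scenarios. Mutation is
finite-sites with transition bias (`ts_tv_ratio`, default 7.6, the
transition:transversion ratio typical of these surveys), so multiple hits
and multiallelic sites can occur, and optional single-base deletions become
inherited gap characters. Defaults emulate the published survey regime: 14
populations, 153 genomes of 16,576 bp, per-site nucleotide diversity of
order $2\times 10^{-3}$ within populations and a between-population fixation
index of order 0.1 (Ne = 5×10⁴ haploid, splits 6×10³ generations ago,
μ = 2×10⁻⁸/site/generation). Generations and years are conflated at 1:1 in
simulation truth; unit conversion lives only in the clock module, so there
is a single place where calendar time enters. The truth sidecar records the
generating tree, TMRCA, group labels, expansion τ, and a low-mutation
approximation of the expected fixation index (from expected coalescence
times for the split model, from the island-model equilibrium otherwise).

What the generator does *not* emulate: selection, recombination (mtDNA is
assumed clonal), repeat-array copy-number polymorphism, base-composition
heterogeneity along the genome, and sequencing artifacts other than the
Gaussian intensity noise of the microarray module. Passing recovery tests
therefore demonstrates correctness of the estimators under the neutral
clonal model, not robustness to those real-data complications.

## Numerical choices and degenerate inputs

- Neighbor joining delegates to the standard Saitou–Nei implementation;
  negative branch lengths are clamped to zero with the deficit pushed onto
  the adjacent edges of the same node, preserving path lengths.
- Bootstrap supports are percentages of column-resampled NJ replicates
  containing each bipartition, stored as internal node labels; they are
  invariant to input row order (asserted).
- All-zero intensity quartets call as ambiguous rather than erroring; an
  all-identical alignment yields zero diversity, a one-class mismatch
  histogram, and a degenerate expansion fit rather than failures.
- One logical pipeline seed fans out to per-stage seeds through a recorded
  multiplicative-congruential step, so any stage can be rerun in isolation
  from the logged seed; identical seeds give byte-identical report bundles.
- Problem sizes in the test suite are chosen to keep the full run at desk
  scale: oracle suites use ≤ 12-sample AMOVA instances and 20-tip trees,
  null calibrations use 200 runs at 500 permutations, recovery studies use
  20 replicates, and the end-to-end run uses the full 14-population,
  153-genome, 16.6-kb default configuration with reduced permutation
  counts.

## Known limitations

- Tree inference is distance-based (NJ); Bayesian tree inference and
  posterior node supports are outside the package's scope, and clock dating
  is applied to the NJ tree. Haplogroup naming is a curator decision, not an
  output.
- The connection-limit model is a principled reconstruction of
  statistical-parsimony's probability calculation, not a line-for-line port
  of any particular legacy implementation; the published network topology
  depends on that limit only through a threshold, which is why the tests pin
  the model's properties (monotonicity, dual-route agreement) rather than a
  specific limit value.
- The SAMOVA p-value inherits the granularity of permuting few populations
  among groups.
- Swimming (shortest marine path) distances are accepted as a user-supplied
  matrix; only great-circle distances are computed natively.
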