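# mitophylogeo

Phylogeographic analysis of whole-mitogenome alignments in R.

Population surveys of marine fish increasingly sequence the complete
mitochondrial genome (~16.6 kb in Atlantic cod) for every individual. At
that resolution nearly every fish carries a unique haplotype, so the
classical frequency-based toolbox has to operate directly on the matrix of
pairwise nucleotide differences. `mitophylogeo` packages that workflow for
population geneticists: it takes an aligned FASTA (or generates synthetic
data with known truth), a sample-to-population table, and population
coordinates, and produces the full set of structure, diversity, phylogeny,
network, and dating results such a survey reports.

## What it computes

- **Microarray base calling** with the differential signal-to-noise rule
  dS/N = (I₍₁₎ − I₍₂₎)/ΣI: strong calls at dS/N ≥ 0.13 on both strands,
  weaker reference-confirming calls at 0.10 ≤ dS/N < 0.13, ambiguity
  otherwise.
- **Site classification**: variable, parsimony-informative and singleton
  sites, transitions/transversions, indel and multiallelic sites;
  haplotype collapsing and tandem-repeat reduction to one unit.
- **Diversity**: haplotype diversity H_d = n/(n−1)(1 − Σp²), nucleotide
  diversity π with pairwise deletion.
- **AMOVA** (2- and 3-level) on pairwise difference counts with permutation
  p-values: Φ_ST, Φ_CT, Φ_SC; pairwise Φ_ST matrices with the modified
  false-discovery-rate critical level p_crit = α/Σ(1/i); Mantel tests of
  isolation by distance on linearized Φ/(1−Φ) vs great-circle distance;
  PCoA; contingency χ².
- **SAMOVA**: simulated-annealing search over geographically contiguous
  population groupings maximizing Φ_CT.
- **Phylogeny**: neighbor joining on absolute nucleotide differences,
  column-bootstrap supports, outgroup rooting, and strict-clock node ages
  calibrated on an outgroup split (e.g. 3.8 Mya); τ = 2μt expansion dating
  from the mismatch distribution via a two-epoch sudden-expansion fit.
- **Statistical-parsimony haplotype network** with a probability-based
  connection limit and latent single-step intermediates.
- **Monte Carlo randomization test of phylogeographic structure**: Fitch
  parsimony length L of a population-partition character on the tree versus
  10,000 tip-state permutations; C% is the inclusive tail
  100·#(L_rand ≤ L_obs)/n_rand.

A structured-coalescent simulator (`sim_config()`, `generate_dataset()`)
generates island-model, split-model, or sudden-expansion datasets with a
truth sidecar, so every estimator is testable without downloads.

## Worked example

```r
library(mitophylogeo)

cfg <- sim_config(n_populations = 4, samples_per_pop = 6, seq_length = 2000,
  per_site_mu = 1e-6, Ne = 5000, split_time = 1500, seed = 7)
ds <- generate_dataset(cfg)

classify_sites(ds$alignment)
#> # A tibble: 1 x 7
#>   n_variable n_parsimony_informative n_singleton n_transitions n_transversions
#> 1        161                     108          53           149              14
```

161 of the 2,000 positions are variable, 108 of them parsimony informative,
with the strong transition bias (149:14) the mutation model was given.

```r
d <- difference_matrix(ds$alignment)
amova(d, ds$samples, n_perm = 999, seed = 1)
#> AMOVA (2-level), 999 permutations
#>   source                df    SS sigma2 percent
#> 1 among populations      3  181.   7.26    30.1
#> 2 within populations    20  338.  16.9     69.9
#> 3 total                 23  519.  24.1    100
#>   phi_st = 0.3008 (p = 0.001)
```

30.1% of molecular variance lies among these four recently split
populations (Φ_ST = 0.30), significant at p = 0.001 over 999 permutations
of individuals among populations.

```r
clk <- divergence_rate(0.039, 3.8e6, 16576)
clk
#> Clock: divergence rate 1.03e-08 subs/site/year (lineage rate 5.13e-09),
#>        calibrated at 3.8e+06 years
round(expansion_time(23.39, clk))
#> 137489
connection_limit(16576, 0.90)
#> Connection limit: 59 steps at 90% confidence (16576 bp)
```

A 3.9% mean distance over a 3.8-Myr calibration gives a divergence rate of
1.03 × 10⁻⁸ substitutions/site/year; a fitted mismatch τ of 23.39 then
dates the expansion to ≈ 137 kya. At 90% confidence, haplotypes up to 59
mutational steps apart are connected in the 16.6-kb parsimony network.

For a one-command run over all stages, see `run_pipeline()` /
`pipeline_config()` (YAML configs supported), or the thin CLI at
`inst/exec/mitophylogeo`:

```sh
inst/exec/mitophylogeo simulate --seed 1 --out synthetic/
inst/exec/mitophylogeo run --config cfg.yaml
```

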