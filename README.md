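# episwarm

Detection of SNP-SNP interactions (epistasis) in case-control genotype data
with a discrete particle swarm optimizer, for researchers benchmarking or
applying heuristic interaction search on genotype panels where exhaustive
scanning of all C(M, K) SNP combinations is out of reach.

The optimizer searches the space of K-subsets of SNP indices with three
additions to the plain swarm: **opposition-based learning** (each candidate
position x is evaluated together with its mirror 1 + M − x, guarding against
premature convergence), a **dynamic inertia weight**
W = (max c − c_snp) / (max c − min c) driven by per-SNP counters of pbest
membership (suspected SNPs are exploited, rarely seen SNPs keep exploring),
and an exhaustive **post-search** over all K-subsets of the 10 most visited
SNPs. Fitness is the plug-in mutual information in bits between the joint
genotype of a SNP set X and the binary phenotype Y,

    MI(X; Y) = H(X) + H(Y) − H(X, Y),

reported together with its likelihood-ratio companion test
(G = 2n·MI in nats, df reduced for empty genotype cells) and a Bonferroni
correction over all C(M, K) candidate sets. The package also ships the
standard benchmark apparatus: a penetrance-model case-control simulator
(Hardy-Weinberg background SNPs with MAF ~ U[0.05, 0.5], retrospective
sampling of causal genotypes from a calibrated penetrance table) and the
Power 1 / Power 2 detection-power metrics, plus a plain-PSO baseline for
paired comparisons.

## Worked example

Simulate a 50-SNP panel of 1000 cases and 1000 controls with a planted
two-locus interaction (the packaged benchmark model: penetrance elevated
4-fold when both SNPs carry a minor allele, MAFs 0.4, prevalence 0.1), then
search it:

```r
library(episwarm)

model <- strong_effect_model()
sim <- simulate_epistasis(model, n_cases = 1000, n_controls = 1000,
                          n_snps = 50, seed = 42)
sim$truth
#> # A tibble: 2 × 3
#>   index snp_id model
#>   <int> <chr>  <chr>
#> 1     2 SNP2   strong_effect
#> 2    47 SNP47  strong_effect

fit <- detect_interactions(sim$data, particles = 50, iterations = 50,
                           seed = 7)
fit
#> <epi_result> oblpso, K = 2, P = 50, T = 50
#>   detected set: SNP2, SNP47  (indices 2, 47)
#>   interaction MI = 0.09618 bits; individual MI = 0.04618, 0.04741
#>   G = 266.7 (df 8), p = 5.03e-53, Bonferroni p = 6.16e-50
```

The optimizer recovers the planted pair. The interaction MI (0.096 bits) is
about twice the MI of either SNP alone (0.046, 0.047 bits) — the joint signal
exceeds the marginal ones — and the G-test of the 9 × 2
genotype-by-phenotype table rejects independence overwhelmingly even after
Bonferroni correction over all 1225 pairs. `tidy(fit)` returns the per-SNP
table (including the swarm's visit counters), `glance(fit)` a one-row
summary, and `autoplot(fit)` the best-so-far fitness trace.
`detect_interactions(..., runs = 20)` aggregates restarts into a table of
distinct detected pairs with detection counts, and
`run_power_experiment()` scores Power 1 (exact recovery, no false positives)
and Power 2 (fraction of truth SNPs recovered) over batches of simulated
datasets.

A command-line interface wrapping the same functions is installed at
`system.file("cli", "episwarm", package = "episwarm")`, with subcommands
`simulate`, `detect` and `evaluate`.

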