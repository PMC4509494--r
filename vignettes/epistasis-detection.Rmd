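---
title: "Swarm search for SNP-SNP interactions: model, simulator and benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swarm search for SNP-SNP interactions: model, simulator and benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episwarm)
```

## The problem

Complex-disease susceptibility is often driven by joint, non-additive effects
of several variants (epistasis) that single-marker association scans miss
entirely. Exhaustively testing all $\binom{M}{K}$ combinations of $M$ SNPs at
interaction order $K$ is infeasible beyond small panels, so the search has to
be heuristic. episwarm implements a discrete particle swarm optimizer over the
space of $K$-subsets of SNP indices, scored by the mutual information between
the joint genotype and the case-control phenotype, together with the
simulator and power metrics needed to benchmark it.

Input data are individuals-by-SNPs tables of genotypes coded 0/1/2 (copies of
the minor allele, collapsed to the three genotype classes) with a binary
`phenotype` column (0 = control, 1 = case).

## Fitness: plug-in mutual information

A candidate solution is a set $X$ of $K$ SNPs. Its fitness is the plug-in
mutual information with the phenotype $Y$,
$$\mathrm{MI}(X; Y) = H(X) + H(Y) - H(X, Y),$$
estimated from the empirical joint distribution over the $3^K \times 2$
genotype-phenotype contingency table, with the convention $0 \log 0 = 0$.

MI is attractive here because it is cheap (one pass over the table), makes no
parametric assumption about the interaction pattern, and is comparable across
combination orders. All reported MI values are in **bits** (base-2
logarithms); this is a package convention, chosen so that the binary
phenotype bounds MI at exactly 1 bit. Two estimator facts matter for
interpreting results:

* the plug-in estimate is non-negative and can only **grow** when a SNP is
  added to a set ($\widehat{\mathrm{MI}}(\{i,j\}) \ge
  \widehat{\mathrm{MI}}(\{i\})$), so interaction MI must always be read
  against the MI of its constituent SNPs, and
* on null data the plug-in MI is biased upward by roughly
  $\mathrm{df} / (2 n \ln 2)$ bits, which is why the package reports a proper
  test alongside.

For reporting, `snp_gtest()` provides the likelihood-ratio $G$-test that is
the natural companion of an MI fitness: $G = 2 n \cdot \mathrm{MI}$ in nats,
compared against a $\chi^2$ with
$(\text{occupied genotype cells} - 1)(2 - 1)$ degrees of freedom (cells empty
in both phenotype classes carry no likelihood and are dropped from the df);
a table with a single occupied genotype row gives $p = 1$. A
Bonferroni-corrected value over all $\binom{M}{K}$ candidate sets is reported
with it. This choice of test is a design decision of this package — MI-based
epistasis tools rarely state their test, and Pearson's $\chi^2$ would be an
equally defensible choice; we prefer the $G$-test because it is exactly a
monotone transform of the fitness, so the ranking by fitness and the ranking
by evidence agree.

## The optimizer

Each of $P$ particles carries a position (an ordered $K$-tuple of distinct
SNP indices in $[1, M]$), a velocity per dimension in $[1-M, M-1]$, and its
personal best `pbest`; the swarm shares a global best `gbest`. Initialization
(iteration 1) draws positions uniformly over $K$-subsets and velocities
uniformly over their domain; each pbest starts at its particle's position.
Each of the remaining $T - 1$ iterations applies, per particle:

1. **Dynamic inertia.** The package keeps a counter per SNP of how often it
   has appeared in any pbest since initialization. Dimension $k$ of a
   particle gets inertia
   $W = (\max c - c_{\mathrm{pbest}_k}) / (\max c - \min c)$:
   a SNP that keeps showing up in personal bests (a suspected signal) gets
   $W \approx 0$ and its particle exploits locally, while a rarely seen SNP
   gets $W \approx 1$ and keeps exploring. When all counters are equal the
   ratio is undefined and the static inertia (default 0.65) is used.
2. **Velocity.** $\tilde v = W v + C_1 r_1 (\mathrm{pbest}_k - x_k) +
   C_2 r_2 (\mathrm{gbest}_k - x_k)$ with fresh $r_1, r_2 \sim U(0,1)$ per
   dimension; a component outside $[1-M, M-1]$ is replaced by a uniform draw
   from that interval.
3. **Position.** $x_k + v_k$, truncated toward zero if it lands in $[1, M]$,
   otherwise replaced by a uniform random integer in $[1, M]$. If two
   dimensions then collide on the same SNP, the colliding dimension is
   resampled uniformly from the unused indices — a SNP combination is a set,
   and a duplicated index would degenerate the contingency table.
4. **Opposition-based learning.** The opposite position $1 + M - x$ (an
   involution on the index range) is evaluated alongside the position, and
   pbest becomes the fittest of \{position, opposite, previous pbest\}. Exact
   ties retain the previous pbest, then prefer the position over its
   opposite — stability under ties keeps runs reproducible. Evaluating the
   mirrored candidate costs one extra fitness evaluation per particle per
   iteration and buys global coverage: premature convergence into one region
   leaves the mirrored region under simultaneous scrutiny.
5. **Global best.** gbest is replaced only by a *strictly* fitter pbest, so
   the gbest fitness trace is non-decreasing by construction. The occupancy
   counters then accrue every SNP occurrence in every pbest (only pbest
   contents are counted; opposite positions that were not adopted do not
   contribute).

After the last iteration a **post-search** ranks all SNPs by their occupancy
counter (ties broken by ascending index), takes the `top_n` (default 10) most
visited ones, and evaluates every $K$-subset of them exhaustively; the answer
is the swarm best unless some subset is strictly fitter. The post-search can
only improve the final MI, and with `top_n = M` it degenerates to a full
exhaustive scan — a property the test suite uses to check global optimality
on small panels.

The **plain PSO baseline** (`variant = "pso"`) is the identical loop with the
static inertia everywhere, pbest challenged by the position only (no
opposition), and no post-search. It is included so that power comparisons
attribute gains to those three ingredients rather than to the swarm
machinery itself.

Opposite positions are evaluated for every particle at every iteration, not
only on improvement: the cost is a factor of two in fitness evaluations, and
per-run memoisation of MI values (positions recur heavily once the swarm
concentrates) claws most of it back.

### Defaults and reproducibility

Defaults are $P = 100$, $T = 100$, $C_1 = C_2 = 2$, static inertia $0.65$,
`top_n = 10`, $K = 2$ — the standard settings for PSO searches of this kind
at the $M \approx 100$ scale. $P \cdot T$ (the evaluation budget) is the
knob that trades time for power; the benchmarks below run comfortably at
$P = T = 50$. A single seeded RNG stream drives initialization, the
per-dimension $r_1, r_2$ draws, out-of-range resampling and duplicate
resolution, in that documented order, so `seed` makes a run (and a
`runs > 1` restart sequence) bit-reproducible.

## The simulator

`simulate_epistasis()` emulates the standard benchmark design for two-locus
methods: a case-control panel in which $K$ causal SNPs follow a penetrance
model and the remaining SNPs are noise.

A disease model is a table of penetrances $f(g) = P(\text{case} \mid g)$ over
the $3^K$ joint genotypes, plus the causal MAFs and the population prevalence
$p$. `calibrate_penetrance()` scales a qualitative *shape* so that
$\sum_g f(g) P_{\mathrm{HWE}}(g) = p$ exactly, refusing shapes that would
push any penetrance above 1. Sampling is retrospective, matching the fixed
case/control totals of the design: case genotypes are drawn from
$P(g \mid \text{case}) \propto f(g) P_{\mathrm{HWE}}(g)$, control genotypes
from $P(g \mid \text{control}) \propto (1 - f(g)) P_{\mathrm{HWE}}(g)$, which
preserves the identity
$p\,P(g|\text{case}) + (1-p)\,P(g|\text{control}) = P_{\mathrm{HWE}}(g)$.
Background SNPs draw a MAF uniformly from $[0.05, 0.5]$ and genotypes i.i.d.
under Hardy-Weinberg equilibrium, identically in cases and controls: no
linkage disequilibrium anywhere, and no missing genotypes (the optimizer has
no missing-data rule, so the loader rejects them).

Four parameterized archetypes cover the usual benchmark spectrum:

* `threshold_both_minor` — penetrance elevated iff both SNPs carry a minor
  allele; marginal *and* interactive effects.
* `inverse_marginal` — SNP a's minor allele is a risk factor on a
  non-carrier SNP b background but protective when both carry minors. The
  literature describes this pattern qualitatively; the concrete table here
  (elevation $\times(1+\theta)$, inversion $\times 1/(1+\theta)$) is this
  package's parameterization.
* `zz` — parity checkerboard (elevated iff $g_a + g_b$ is odd), which has
  *exactly* zero single-locus marginal effect under HWE at MAF 0.5: since
  $P(g \text{ odd}) = 1/2$ at MAF 0.5, each row of the table averages to the
  same marginal penetrance.
* `xor` — carrier-XOR (elevated iff exactly one SNP carries a minor allele);
  its marginal effect vanishes where the carrier probability is $1/2$, i.e.
  at MAF $1 - 1/\sqrt 2 \approx 0.293$.

Published two-locus tables whose numeric values live outside this package
can be supplied directly as 3 × 3 tables (`penetrance_shape(table = ...)`).

What the simulator does **not** emulate — and what passing benchmarks
therefore cannot certify — includes linkage disequilibrium between markers
(real panels have correlated nulls, which inflates the top null MI),
genotyping error and missingness, population structure, and multiple
simultaneous interactions. Power numbers from this generator are upper bounds
on what the same settings achieve on real panels.

## Detection power

For a batch of $N$ simulated datasets with known truth,

* **Power 1** $= \frac{1}{N}\sum_i x_i$, where $x_i = 1$ only if the reported
  set equals the truth set exactly — no false positives tolerated;
* **Power 2** $= \frac{1}{KN}\sum_i y_i$, where $y_i$ counts truth SNPs in
  the $K$ reported ones — partial credit.

Power 2 $\ge$ Power 1 identically. Both score the method's *final reported
set* (the post-searched swarm best), not the counter ranking — the counters
are internal state, the reported set is the method's answer.

`run_power_experiment()` simulates $N$ datasets per model and runs every
method at every $(P, T)$ setting on the *same* datasets, with all sub-seeds
pre-drawn from one master seed, so method comparisons are paired and the
whole report is reproducible from a single integer.

## Benchmark scale and numerical choices

The committed benchmark model (`strong_effect_model()`) is
`threshold_both_minor` with effect $\theta = 3$, MAFs 0.4/0.4 and prevalence
0.1 — a strong marginal-plus-interactive architecture. The package's power
study runs $N = 20$ datasets of 1000 cases / 1000 controls over $M = 50$
SNPs with $P = T = 50$: desk-scale sizes, chosen so the full paired
comparison (both variants, 40 optimizer runs) completes in well under a
minute while leaving the causal pair's MI clearly above every background
pair (verified per-fixture by an exhaustive scan before the power runs). At
these settings the opposition-based variant recovers the planted pair in
essentially every dataset (Power 1 = Power 2 = 1 in the shipped benchmark);
the plain baseline is close behind on this easy model — the gap widens on
weaker effects and larger $M$, where the evaluation budget binds.

Numerical conventions, collected in one place: MI in bits; $0 \log 0 = 0$;
velocity truncation toward zero (`int`), mirroring integer conversion in the
update rule; ties as described above (previous pbest first, strict
inequality for gbest, ascending index in the counter ranking); the static
inertia 0.65 doubles as the degenerate-counter fallback of the dynamic
weight; duplicate indices after a position update resampled from the unused
indices; background MAF range $[0.05, 0.5]$ closed on both ends.

## Known limitations

* One interaction per dataset: the optimizer reports a single $K$-set;
  multiple simultaneous interactions require repeated runs
  (`runs > 1`) and inspection of the aggregated report.
* Sensitivity to strong main effects: because plug-in MI of a pair dominates
  the MI of its members, a SNP with a strong marginal signal drags many
  partners into high-fitness pairs; the individual-MI columns in the report
  exist precisely to flag this.
* The plug-in MI is biased upward in small samples; for $K > 2$ on small
  panels the $3^K$-cell table gets sparse quickly and both the fitness and
  the $G$-test degrade.
* No LD handling: in correlated panels the "distinct SNPs" constraint does
  not prevent near-duplicate selections.
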