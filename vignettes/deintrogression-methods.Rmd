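---
title: "Simulating marker-guided de-introgression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating marker-guided de-introgression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deintrogress)
```

## The problem

A genetically differentiated native population — a local livestock breed, a
captive population of an endangered wild species — suffers an introgression
event: exogenous individuals enter and interbreed for a few generations
before anyone intervenes. The manager's task is *de-introgression*: choose,
generation by generation, which individuals reproduce and how many offspring
each contributes, so that exogenous alleles are purged and the native genetic
background is recovered, using only molecular marker information (no
pedigree is assumed available to the manager, although the simulator records
one to measure the consequences).

`deintrogress` is an individual-based, forward-in-time simulator of this
whole process. It exists to quantify two questions: how much native genome
can markers of a given informativeness recover, and what inbreeding cost the
recovery exacts.

## Simulation model

**Genome and founders.** Each individual carries one chromosome of 20
Morgans (a 1-Morgan variant is supported) with 2000 evenly spaced neutral
background loci and 5–20 evenly spaced marker loci, all on the same genetic
map. Founders are unrelated, non-inbred, and carry two globally unique
allele IDs at every background locus, so the base generation is fully
heterozygous and segregates `2N` alleles per locus. This makes the
background loci maximally informative: the founder origin (native or
exogenous) of every allele copy in every descendant is recoverable exactly,
and observed homozygosity equals identity by descent. *Native
representation* (NR), the fraction of background allele copies descending
from native founders, is the primary outcome; at generation 0 it equals one
minus the introgression fraction by construction.

**Reproduction.** Gametes receive a Poisson-distributed number of
crossovers (mean = map length in Morgans, no interference) at uniform
positions; the starting haplotype is chosen with probability 1/2. Markers
and background loci inherit from the same crossover realization, so the
linkage disequilibrium that builds up during admixture — and that makes
markers informative about the neutral background — is represented
physically. Population size `N` and the 50/50 sex ratio are constant every
generation: each generation produces exactly `N` offspring, `N/2` of each
sex by random permutation.

**Phases.** (1) Founding: `N` founders of which `n_exogenous` are
exogenous, sexes of the exogenous founders drawn Bernoulli(1/2) with the
native founders filling the quota. (2) Admixture, 1–5 generations: each
offspring draws its sire uniformly with replacement from the males and its
dam from the females. (3) Management, 10 generations, described next.

## Management strategies

**Truncation on native-allele counts** (`strategy = "marker_count"`). Used
with diagnostic and diagnostic-like panels: each generation, within each
sex, the individuals with the maximum count of the designated native allele
(0..2M copies over M markers) are selected — ties all enter, and selecting
sex-wise maxima guarantees at least one parent of each sex. Offspring slots
are then allocated uniformly at random among the selected (the realized
contributions are multinomial, not equal). Under a per-parent offspring cap
(5 or 10), draws are limited to parents below the cap; if the selected set
cannot supply `N` slots, the next count tier is admitted until it can —
population size is the hard constraint, so the cap widens the parent pool
rather than shrinking the population.

**Distance minimization** (`strategy = "distance"`). Used with
non-diagnostic panels: integer contributions per candidate (summing to `N`
in each sex) are chosen to minimize a genetic distance between the native
reference frequencies (assumed known without error) and the expected
next-generation frequencies \(p'_{am} = \sum_i c_i\, g_{iam}\), where
\(g_{iam}\) is 1, 0.5 or 0 as parent \(i\) is homozygous, heterozygous or
non-carrier, and each sex is weighted to supply half the gene pool. Three
distances are implemented (all averaged over the M markers, a monotone
rescaling chosen for comparability across panel sizes): the Cavalli-Sforza
& Edwards chord distance, Nei's minimum distance, and the Kullback–Leibler
divergence taken reference-first, \(D(p \,\|\, p')\), since the goal is that
the next generation resemble the original native population. The study this
package reproduces found all three equivalent in practice; KL is the
default.

**Optimizer.** The integer program is solved by simulated annealing. A move
transfers one offspring slot between two same-sex parents (feasibility —
sums, non-negativity, cap — is preserved by construction). The initial
temperature is calibrated so that a median uphill move from the
equal-contribution start is accepted with probability about 1/2 (probed on
200 pilot moves); cooling is geometric with factor 0.95 per temperature
step of `100 × (number of candidates)` moves; the search stops after 50
consecutive steps without improvement, with a hard ceiling of 200 steps as
a safety guard. All knobs are exposed via `sa_control()` and the YAML
config. The returned plan is never worse than the equal-contribution start,
and on small instances (≤ 8 candidates) it matches exhaustive enumeration
in the test suite.

**Mating.** Given contributions, sires and dams are expanded into `N` slots
each and paired by solving the `N × N` linear assignment problem minimizing
total parental coancestry (Hungarian algorithm, implemented in C++ —
shortest augmenting path, O(n³)). Since an offspring's inbreeding equals
its parents' coancestry, this minimizes next-generation mean F given the
contributions. Slot orders are shuffled under the replicate's RNG before
solving so ties among optimal assignments break reproducibly.

## Marker panels

| Scheme | Alleles | Native freqs | Exogenous freqs |
|---|---|---|---|
| diagnostic | 2 | 1, 0 | 0, 1 |
| diagnostic_like | 2 | 0.80, 0.20 | 0.20, 0.80 |
| extra_diagnostic_like | 2 | f, 1−f (f ∈ 0.7…0.99) | 0.5, 0.5 |
| non_diagnostic | 4 | 0.80, 0.07, 0.06, 0.07 | 0.07, 0.80, 0.06, 0.07 |

Founder marker genotypes are drawn in Hardy–Weinberg proportions from the
origin population's frequencies, independently across markers: the model
deliberately starts with no within-population LD, so any marker–background
association available to management is generated by the admixture process
itself. The diagnostic scheme is deterministic (natives fixed for allele 1,
exogenous for allele 2). Arbitrary frequency tables are accepted through
`marker_panel()` for exploration beyond the named schemes.

## Measured consequences

Per generation and replicate: NR; mean pedigree inbreeding F (tabular
method; maintained incrementally by the generational recursion, which is
exact for discrete non-overlapping generations and is cross-checked against
the full tabular computation in the tests); mean coancestry over all
ordered pairs including self-pairs (the "mean coancestry of the group"
convention — the alternative excluding self-pairs shifts levels but not
trends, and only trends are interpreted); observed homozygosity at the
background loci; effective size \(N_e = 1/(2\Delta F)\) with
\(\Delta F = (F_t - F_{t-1})/(1 - F_{t-1})\), reported as `Inf` when
inbreeding did not increase; and the number of contributing parents, which
drives the \(N_e\) dynamics under truncation selection.

## What the simulator does and does not emulate

The base-generation design (every founder heterozygous for private alleles
at 2000 neutral loci) is an idealization that makes origin tracking exact
and homozygosity equal IBD; real populations start with standing
homozygosity and imperfect origin information, so absolute NR and
homozygosity levels are not directly transferable — comparisons *between*
strategies are the meaningful output. Likewise the model omits mutation,
selection on the background loci, overlapping generations, multiple
chromosomes, mortality, and genotyping error; reference frequencies for
distance-based management are known without error. Passing tests therefore
demonstrate correctness of the simulation and optimization machinery and
reproduction of the study conditions, not field-readiness of any particular
management prescription.

## Numerical and design choices

* Background loci at positions \((\ell-0.5)\,\mathrm{len}/L\), markers at
  \((m-0.5)\,\mathrm{len}/M\): even spacing for both, interleaved at
  distinct coordinates.
* Allele IDs are `2i-1, 2i` for founder `i`, giving O(1) origin lookup.
* KL with an empty expected class would be infinite; `p'` is floored at
  `1e-9` inside the logarithm, preserving the (desirable) strong penalty
  for eliminating a reference allele while keeping the objective finite.
* The chord distance's inner term `2(1 − Σ√(pp'))` is clamped at 0 against
  floating-point negatives.
* Contributions are integer offspring counts, not continuous proportions:
  reproduction physically requires integers, and it makes the annealer's
  search space finite.
* One RNG stream per replicate, seeded `base_seed + replicate_index`; the
  C++ kernels draw from R's RNG, so a replicate is bit-reproducible from
  its seed alone, including annealing and tie-breaking.
* Sex-wise maxima in truncation selection (rather than the global maximum
  plus a patched-in second sex) — the two coincide whenever the global
  maximum is attained in both sexes, and the sex-wise rule handles the
  one-sex-dominant case without a special branch.

## Problem sizes used in the checks

The acceptance computations reproduce the study's central table cells at
full size — N = 100, 2000 background loci, 20 markers, 5 admixture plus 10
managed generations, 20 replicates per scenario — which this implementation
completes in seconds per replicate (truncation strategies) to a few minutes
per scenario (annealing strategies). Property-style checks (recombination
fractions against Haldane's map function, drift neutrality of unmanaged NR,
optimizer-vs-enumeration equalities) use reduced population and locus
counts chosen to keep Monte-Carlo error well inside the asserted bounds;
the qualitative strategy-ordering checks use the same 20 replicates per
cell, since the smallest ordered gap (diagnostic-like versus non-diagnostic
NR, about 0.02) is of the same order as the Monte-Carlo standard error of a
cell mean and needs the full averaging to resolve.

## Known limitations

Annealing is stochastic: on large instances it returns the best plan found,
not a certified optimum (the equal-contribution bound is guaranteed). The
cap-relaxation rule (admit the next count tier) is one reasonable reading
of how a practitioner would keep `N` constant under an infeasible cap;
alternatives (e.g. reducing N) would change the F trade-off. Ne estimates
from single-generation ΔF are noisy early in management when very few
parents contribute, and are reported as `Inf` in generations where mean F
happens to decrease.
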