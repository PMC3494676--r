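# deintrogress

Individual-based forward simulation of **marker-guided de-introgression**:
recovering the native genetic background of a population after exogenous
individuals have entered and admixed for several generations.

The intended users are conservation and animal-breeding researchers asking
how far molecular markers of a given informativeness can go in purging
introgressed alleles from a captive or closely managed population, and what
inbreeding cost the purge exacts.

## The model in brief

A native population of constant size *N* (50/50 sex ratio) receives
`n_exogenous` foreign founders, mates at random for 1–5 generations
(admixture), and is then managed for 10 generations. Each individual
carries one 20-Morgan chromosome with 2000 neutral multiallelic background
loci and *M* = 5–20 marker loci on the same genetic map; founders are fully
heterozygous for globally unique alleles, so the founder origin of every
allele copy is recoverable and **native representation**

> NR = fraction of background allele copies descending from native founders

is measured exactly each generation, alongside pedigree inbreeding *F*,
mean coancestry, observed homozygosity and the effective size
*N*<sub>e</sub> = 1/(2ΔF).

Two management strategies decide who reproduces and how much:

* **Truncation on native-allele counts** (diagnostic / diagnostic-like
  panels): per sex, the individuals carrying the most copies of the
  designated native allele are selected and offspring are allocated among
  them at random, optionally capped per parent (5 or 10).
* **Distance minimization** (non-diagnostic panels): integer contributions
  *c<sub>i</sub>* minimize a genetic distance — Cavalli-Sforza & Edwards
  chord, Nei minimum, or Kullback–Leibler *D(p‖p′)* — between the native
  reference frequencies *p<sub>am</sub>* and the expected offspring
  frequencies *p′<sub>am</sub>* = Σ<sub>i</sub> c<sub>i</sub>
  g<sub>iam</sub>, solved by simulated annealing (C++ kernel).

Matings are then arranged by minimum-coancestry assignment (Hungarian
algorithm, C++).

## Worked example

```r
library(deintrogress)

cfg <- scenario_config(N = 100, n_exogenous = 10, admix_generations = 5,
                       manage_generations = 10, scheme = "diagnostic",
                       n_markers = 20, strategy = "marker_count",
                       replicates = 5, base_seed = 42)
res <- run_scenario(cfg)
res
#> <scenario_result> diagnostic/marker_count cap=none, 10 exo of N=100, 5+10 generations, 5 reps
#>   final NR = 0.984 +/- 0.003   final F = 0.140 +/- 0.024
subset(res$per_generation, replicate == 1 & generation %in% c(5, 6, 9, 15),
       select = c(generation, phase, NR, mean_F, Ne, n_parents))
#>    generation      phase        NR     mean_F        Ne n_parents
#> 6           5  admixture 0.9284650 0.01849609 204.78049        NA
#> 7           6 management 0.9946975 0.01237305       Inf        11
#> 10          9 management 0.9931450 0.08113976  31.92547        86
#> 16         15 management 0.9930275 0.10603520 107.48771        86
```

Ten exogenous founders put NR at 0.90; five generations of drift leave it
near 0.93 in this replicate. Management with 20 diagnostic (private-allele)
markers recovers NR ≈ 0.98–0.99 within the first generations — after which
all candidates tie on marker score, selection becomes effectively random
and NR plateaus — while mean inbreeding climbs to ≈ 0.14 across replicates,
the side-effect of funnelling reproduction through the few purest parents
(note the 11 contributing parents in the first managed generation, and the
much larger parent pools once purity is reached). An offspring cap
(`cap = 5`) or the distance strategy
(`scheme = "non_diagnostic", strategy = "distance"`) trades recovery for
lower F.

A shell front end wrapping the same functions lives at
`inst/cli/deintrogress.R`:

```sh
Rscript inst/cli/deintrogress.R run --config scenario.yaml --out results/
Rscript inst/cli/deintrogress.R grid --table scheme --out results/
```

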