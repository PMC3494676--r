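# Brute-force oracles and small fixture builders, independent of the code
# paths they check.

# All permutations of 1:n (n small).
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

# Minimum-cost assignment by exhaustive permutation search.
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  best <- Inf
  for (p in all_permutations(n)) {
    v <- sum(cost[cbind(seq_len(n), p)])
    if (v < best) best <- v
  }
  best
}

# All compositions of N into k non-negative parts, each at most cap.
all_compositions <- function(N, k, cap = N) {
  if (k == 1L) {
    if (N <= cap) return(list(N)) else return(list())
  }
  out <- list()
  for (x in 0:min(N, cap)) {
    for (rest in all_compositions(N - x, k - 1L, cap)) {
      out[[length(out) + 1L]] <- c(x, rest)
    }
  }
  out
}

# Exhaustive minimum of a genetic distance over all feasible integer
# contribution plans (both sexes), for tiny instances.
brute_force_contributions <- function(pop, kind, N, cap = NULL) {
  males <- which(pop$sex == "M"); females <- which(pop$sex == "F")
  capv <- if (is.null(cap)) N else cap
  best <- Inf
  for (cm in all_compositions(N, length(males), capv)) {
    if (all(cm == 0)) next
    for (cf in all_compositions(N, length(females), capv)) {
      if (all(cf == 0)) next
      plan <- list(male_idx = males, male_c = cm,
                   female_idx = females, female_c = cf)
      p_exp <- expected_frequencies(plan, pop)
      v <- genetic_distance(pop$panel$native_freqs, p_exp, kind)
      if (v < best) best <- v
    }
  }
  best
}

# Small population with marker genotypes overridden column-by-column.
# genotypes: list of 2-row matrices (hap_a; hap_b), one per individual.
make_test_pop <- function(sexes, genotypes, panel,
                          map = genetic_map(1, n_loci = 10,
                                            n_markers = panel$M)) {
  N <- length(sexes)
  pop <- found_population(N, 0, panel, map)
  pop$sex <- sexes
  pop$ped$sex <- sexes
  for (i in seq_len(N)) {
    pop$mkA[, i] <- genotypes[[i]][1, ]
    pop$mkB[, i] <- genotypes[[i]][2, ]
  }
  pop
}

# Homozygous / heterozygous genotype helpers for M markers.
geno_hom <- function(allele, M) matrix(allele, 2, M)
geno_het <- function(a1, a2, M) rbind(rep(a1, M), rep(a2, M))
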