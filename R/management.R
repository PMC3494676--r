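#' Count native marker alleles per individual
#'
#' For each individual, the number of allele copies (0..2M) at the marker
#' loci equal to the panel's designated native allele. Under the diagnostic
#' scheme that allele is truly private to the native population; under
#' diagnostic-like schemes it is merely the allele most frequent in natives,
#' so the count is a noisy proxy for purity.
#'
#' @param pop A `population`.
#' @param panel A `marker_panel` (defaults to the one stored in `pop`).
#' @return Integer vector of length `pop$N`.
#' @export
count_native_alleles <- function(pop, panel = pop$panel) {
  a <- panel$native_allele
  colSums(pop$mkA == a) + colSums(pop$mkB == a)
}

#' Truncation selection on native-allele counts
#'
#' Within each sex, the candidates achieving that sex's maximum native-allele
#' count are selected; all ties enter the selected set. Selecting sex-wise
#' maxima guarantees at least one male and one female, so both sexes can
#' supply half the gametes even when the overall best individuals are all of
#' one sex (in the extreme, a single best female mothers all offspring).
#'
#' @param pop A `population`.
#' @param panel A `marker_panel`.
#' @return List with integer index vectors `males`, `females` (columns of
#'   `pop`) and the `counts` vector.
#' @export
select_max_native <- function(pop, panel = pop$panel) {
  counts <- count_native_alleles(pop, panel)
  males <- which(pop$sex == "M"); females <- which(pop$sex == "F")
  list(males = males[counts[males] == max(counts[males])],
       females = females[counts[females] == max(counts[females])],
       counts = counts)
}

#' Randomly allocate offspring among selected parents of one sex
#'
#' The `N` parent slots of one sex (one per offspring) are assigned
#' uniformly at random, with replacement, among the selected candidates, so
#' realized contributions differ between individuals. With an offspring cap,
#' draws are restricted to candidates still below the cap; if the selected
#' set cannot supply `N` slots under the cap, the next-best native-allele
#' count tiers are admitted until it can (population size is a hard
#' constraint).
#'
#' @param selected Integer indices of the selected candidates of this sex.
#' @param N Number of offspring slots to fill.
#' @param cap Maximum offspring per parent (`NULL` = unrestricted; the study
#'   uses 5 and 10).
#' @param candidates All candidate indices of this sex, best-tier first is
#'   not required; used only for cap relaxation.
#' @param counts Native-allele counts aligned with the population columns;
#'   used only for cap relaxation.
#' @return List: `idx` (parent indices, possibly extended by relaxation) and
#'   integer `c` (offspring counts per parent, `sum(c) == N`).
#' @export
allocate_contributions_random <- function(selected, N, cap = NULL,
                                          candidates = NULL, counts = NULL) {
  stopifnot(length(selected) >= 1L, N >= 1L)
  if (!is.null(cap)) {
    stopifnot(cap >= 1L)
    while (cap * length(selected) < N) {
      pool <- setdiff(candidates, selected)
      if (length(pool) == 0L)
        stop("offspring cap infeasible even with all candidates selected")
      nxt <- max(counts[pool])
      selected <- c(selected, pool[counts[pool] == nxt])
    }
  }
  k <- length(selected)
  if (is.null(cap)) {
    cvec <- tabulate(sample.int(k, N, replace = TRUE), nbins = k)
  } else {
    cvec <- integer(k)
    for (slot in seq_len(N)) {
      open <- which(cvec < cap)
      pick <- open[sample.int(length(open), 1L)]
      cvec[pick] <- cvec[pick] + 1L
    }
  }
  list(idx = selected, c = as.integer(cvec))
}

# Assemble and validate a contribution plan (one sire and one dam per
# offspring, so each sex's contributions sum to N).
contribution_plan <- function(male_idx, male_c, female_idx, female_c, N,
                              cap = NULL) {
  stopifnot(sum(male_c) == N, sum(female_c) == N,
            all(male_c >= 0L), all(female_c >= 0L),
            any(male_c > 0L), any(female_c > 0L))
  if (!is.null(cap))
    stopifnot(all(male_c <= cap), all(female_c <= cap))
  structure(list(male_idx = male_idx, male_c = as.integer(male_c),
                 female_idx = female_idx, female_c = as.integer(female_c),
                 N = as.integer(N)),
            class = "contribution_plan")
}

# Gamete allele probabilities g_iam laid out as an (A*M) x N matrix, row
# (m-1)*A + a: 1 for aa homozygotes, 0.5 for heterozygotes carrying a, 0
# otherwise. Same layout as as.vector(panel$native_freqs).
marker_gamete_probs <- function(pop, panel = pop$panel) {
  A <- panel$A; M <- panel$M
  g <- matrix(0, A * M, pop$N)
  for (a in seq_len(A)) {
    rows <- (seq_len(M) - 1L) * A + a
    g[rows, ] <- ((pop$mkA == a) + (pop$mkB == a)) / 2
  }
  g
}

#' Expected marker frequencies under a contribution plan
#'
#' The expected allele frequency in the next generation is
#' \eqn{p'_{am} = \sum_i c_i g_{iam}} with \eqn{c_i} the relative
#' contribution of parent `i` and \eqn{g_{iam}} the probability a gamete
#' from `i` carries allele `a` of marker `m` (1 for `aa` homozygotes, 0.5
#' for heterozygotes, 0 otherwise). Each sex supplies half the gene pool, so
#' male and female contributions are each weighted by `c_i / (2N)`.
#'
#' @param plan A contribution plan (list with `male_idx`, `male_c`,
#'   `female_idx`, `female_c`).
#' @param pop A `population`.
#' @param panel A `marker_panel`.
#' @return Numeric `A x M` matrix of expected frequencies; columns sum to 1.
#' @export
expected_frequencies <- function(plan, pop, panel = pop$panel) {
  g <- marker_gamete_probs(pop, panel)
  N <- sum(plan$male_c)
  stopifnot(sum(plan$female_c) == N)
  p <- 0.5 * (g[, plan$male_idx, drop = FALSE] %*% (plan$male_c / N)) +
       0.5 * (g[, plan$female_idx, drop = FALSE] %*% (plan$female_c / N))
  matrix(p, nrow = panel$A, ncol = panel$M)
}

#' Genetic distances between a reference and an expected frequency table
#'
#' All three distances are averaged over the `M` markers (a monotone
#' rescaling that leaves the optimum unchanged but makes values comparable
#' across panel sizes):
#'
#' * `chord` (Cavalli-Sforza & Edwards):
#'   \eqn{\frac{2}{\pi M} \sum_m \sqrt{2 (1 - \sum_a \sqrt{p_{am} p'_{am}})}}
#' * `nei_min` (Nei's minimum):
#'   \eqn{\frac{1}{M} \sum_m [ (\sum_a p_{am}^2 + \sum_a p'^2_{am})/2 -
#'   \sum_a p_{am} p'_{am} ]}
#' * `kl` (Kullback-Leibler, reference first):
#'   \eqn{\frac{1}{M} \sum_m \sum_a p_{am} \ln(p_{am}/p'_{am})} with the
#'   conventions \eqn{0 \ln(0/x) = 0} and `p'` floored at `1e-9` inside the
#'   log, so eliminating a reference allele is strongly (but finitely)
#'   penalized.
#'
#' @param p Reference frequencies (`A x M` matrix, or vector for `M = 1`).
#' @param p_prime Expected frequencies, same shape.
#' @param kind `"chord"`, `"nei_min"` or `"kl"`.
#' @return Non-negative scalar; 0 iff `p_prime == p` (for `nei_min`, given
#'   both are frequency tables).
#' @examples
#' genetic_distance(c(1, 0), c(0.5, 0.5), "kl")      # log(2)
#' genetic_distance(c(1, 0), c(0, 1), "nei_min")     # 1
#' @export
genetic_distance <- function(p, p_prime, kind = c("kl", "chord", "nei_min")) {
  kind <- match.arg(kind)
  p <- as.matrix(p); p_prime <- as.matrix(p_prime)
  if (!identical(dim(p), dim(p_prime)))
    stop("frequency tables must have identical dimensions")
  M <- ncol(p)
  switch(kind,
    chord = {
      inner <- pmax(0, 2 * (1 - colSums(sqrt(p * p_prime))))
      (2 / (pi * M)) * sum(sqrt(inner))
    },
    nei_min = {
      sum((colSums(p^2) + colSums(p_prime^2)) / 2 - colSums(p * p_prime)) / M
    },
    kl = {
      q <- pmax(p_prime, 1e-9)
      terms <- ifelse(p > 0, p * log(p / q), 0)
      sum(terms) / M
    })
}

#' Simulated-annealing control parameters
#'
#' @param cooling Geometric cooling factor per temperature step.
#' @param moves_per_candidate Moves attempted per temperature step, per
#'   candidate parent (total moves per step = this times the number of
#'   candidates of both sexes).
#' @param stall_temps Stop after this many consecutive temperature steps
#'   without improvement of the best solution.
#' @param max_temps Hard ceiling on temperature steps.
#' @param pilot_moves Random moves probed from the initial plan to calibrate
#'   the initial temperature so roughly half of uphill moves are accepted.
#' @return List of class `sa_control`.
#' @export
sa_control <- function(cooling = 0.95, moves_per_candidate = 100,
                       stall_temps = 50, max_temps = 200, pilot_moves = 200) {
  stopifnot(cooling > 0, cooling < 1, moves_per_candidate >= 1,
            stall_temps >= 1, max_temps >= 1)
  structure(list(cooling = cooling,
                 moves_per_candidate = as.integer(moves_per_candidate),
                 stall_temps = as.integer(stall_temps),
                 max_temps = as.integer(max_temps),
                 pilot_moves = as.integer(pilot_moves)),
            class = "sa_control")
}

# Integer split of N offspring slots over k parents, as equal as possible;
# the remainder is spread over a random subset.
even_split <- function(N, k) {
  base <- N %/% k
  cvec <- rep.int(base, k)
  extra <- N - base * k
  if (extra > 0L) {
    pick <- resample(seq_len(k), extra)
    cvec[pick] <- cvec[pick] + 1L
  }
  as.integer(cvec)
}

#' Optimize contributions by simulated annealing
#'
#' Finds integer offspring counts per candidate parent (summing to `N`
#' within each sex) minimizing the chosen genetic distance between the
#' reference native frequencies stored in the panel and the expected
#' next-generation frequencies. Annealing moves transfer one offspring slot
#' between two same-sex parents; worse moves are accepted with probability
#' `exp(-delta / T)` under a geometric cooling schedule calibrated on a
#' pilot sample. The returned plan is never worse than the
#' equal-contribution initialization.
#'
#' Uses the session RNG (including inside the C++ kernel); seed with
#' [set.seed()].
#'
#' @param pop A `population`.
#' @param kind Distance to minimize: `"kl"`, `"chord"` or `"nei_min"`.
#' @param cap Maximum offspring per parent (`NULL` = unrestricted).
#' @param panel A `marker_panel`; its `native_freqs` are the reference,
#'   assumed known without error.
#' @param control An [sa_control()] list.
#' @return A `contribution_plan` with attribute `objective` (the achieved
#'   distance).
#' @export
optimize_contributions_sa <- function(pop, kind = c("kl", "chord", "nei_min"),
                                      cap = NULL, panel = pop$panel,
                                      control = sa_control()) {
  kind <- match.arg(kind)
  males <- which(pop$sex == "M"); females <- which(pop$sex == "F")
  stopifnot(length(males) >= 1L, length(females) >= 1L)
  N <- pop$N
  if (!is.null(cap) &&
      (cap * length(males) < N || cap * length(females) < N))
    stop("offspring cap infeasible for the available candidates")
  g <- marker_gamete_probs(pop, panel)
  c0m <- even_split(N, length(males))
  c0f <- even_split(N, length(females))
  kind_code <- match(kind, c("chord", "nei_min", "kl")) - 1L
  res <- cpp_sa_optimize(g[, males, drop = FALSE], g[, females, drop = FALSE],
                         as.numeric(panel$native_freqs),
                         panel$A, panel$M, N,
                         if (is.null(cap)) -1L else as.integer(cap),
                         kind_code, c0m, c0f,
                         control$cooling,
                         control$moves_per_candidate *
                           (length(males) + length(females)),
                         control$stall_temps, control$max_temps,
                         control$pilot_moves)
  plan <- contribution_plan(males, res$cm, females, res$cf, N, cap)
  attr(plan, "objective") <- res$value
  plan
}
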