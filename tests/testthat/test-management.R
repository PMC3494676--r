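test_that("native-allele counts span 0..2M as expected", {
  panel <- make_panel("diagnostic", 20)
  set.seed(1)
  pop <- make_test_pop(c("M", "M", "F", "F"),
                       list(geno_hom(1L, 20),        # pure native
                            geno_hom(2L, 20),        # pure exogenous
                            geno_het(1L, 2L, 20),    # heterozygous everywhere
                            geno_hom(1L, 20)),
                       panel)
  expect_equal(unname(count_native_alleles(pop)), c(40L, 0L, 20L, 40L))

  panel5 <- make_panel("diagnostic", 5)
  pop5 <- make_test_pop(c("M", "F"), list(geno_het(1L, 2L, 5), geno_hom(1L, 5)),
                        panel5)
  expect_equal(unname(count_native_alleles(pop5)), c(5L, 10L))
})

test_that("truncation selection takes sex-wise maxima with all ties", {
  panel <- make_panel("diagnostic", 20)
  set.seed(1)
  # males with 40 and 38 native alleles; females both with 40
  pop <- make_test_pop(c("M", "M", "F", "F"),
                       list(geno_hom(1L, 20),
                            rbind(c(rep(1L, 19), 2L), rep(1L, 20)),
                            geno_hom(1L, 20),
                            geno_hom(1L, 20)),
                       panel)
  sel <- select_max_native(pop)
  expect_equal(sel$males, 1L)
  expect_equal(sel$females, c(3L, 4L))

  # one sex's best is below the global maximum: still one per sex selected
  pop2 <- make_test_pop(c("M", "M", "F", "F"),
                        list(geno_het(1L, 2L, 20), geno_hom(2L, 20),
                             geno_hom(1L, 20), geno_hom(2L, 20)),
                        panel)
  sel2 <- select_max_native(pop2)
  expect_equal(sel2$males, 1L)   # best male has 20 < global max 40
  expect_equal(sel2$females, 3L)

  # all tied: everyone selected, management becomes random
  pop3 <- make_test_pop(rep(c("M", "F"), each = 2),
                        rep(list(geno_hom(1L, 20)), 4), panel)
  sel3 <- select_max_native(pop3)
  expect_equal(sel3$males, c(1L, 2L))
  expect_equal(sel3$females, c(3L, 4L))
})

test_that("random allocation: single parent takes all N slots", {
  set.seed(8)
  a <- allocate_contributions_random(5L, N = 100)
  expect_equal(a$idx, 5L)
  expect_equal(a$c, 100L)
})

test_that("random allocation under a tight cap fills every parent to the cap", {
  set.seed(8)
  a <- allocate_contributions_random(1:20, N = 100, cap = 5)
  expect_equal(sort(a$idx), 1:20)
  expect_equal(a$c, rep(5L, 20))  # pigeonhole
})

test_that("random allocation is uniform in expectation", {
  set.seed(12)
  tot <- c(0, 0)
  reps <- 800
  for (i in seq_len(reps)) {
    a <- allocate_contributions_random(c(3L, 9L), N = 10)
    tot <- tot + a$c
  }
  phat <- tot[1] / (10 * reps)
  se <- sqrt(0.5 * 0.5 / (10 * reps))
  expect_lt(abs(phat - 0.5), 3 * se)
})

test_that("an infeasible cap admits the next native-count tier", {
  set.seed(4)
  counts <- c(10, 10, 8, 8, 8, 7)   # indices 1..6 of this sex
  a <- allocate_contributions_random(c(1L, 2L), N = 20, cap = 5,
                                     candidates = 1:6, counts = counts)
  expect_setequal(a$idx, 1:5)       # tier of 8s admitted, 7 not needed
  expect_equal(sum(a$c), 20L)
  expect_true(all(a$c <= 5L))
  expect_error(allocate_contributions_random(1L, N = 20, cap = 5,
                                             candidates = 1L, counts = 10),
               "infeasible")
})

test_that("expected frequencies follow the gamete-probability formula", {
  panel <- make_panel("diagnostic_like", 5)
  set.seed(2)
  # single homozygous aa pair -> p' = (1, 0)
  pop <- make_test_pop(c("M", "F"), list(geno_hom(1L, 5), geno_hom(1L, 5)),
                       panel)
  plan <- list(male_idx = 1L, male_c = 4L, female_idx = 2L, female_c = 4L)
  expect_equal(expected_frequencies(plan, pop),
               matrix(c(1, 0), 2, 5))

  # heterozygous sire + aa dam -> p'_a = 1/2 * 0.5 + 1/2 * 1 = 3/4
  pop <- make_test_pop(c("M", "F"), list(geno_het(1L, 2L, 5), geno_hom(1L, 5)),
                       panel)
  expect_equal(expected_frequencies(plan, pop),
               matrix(c(0.75, 0.25), 2, 5))

  # equal contributions reproduce the parental allele frequency
  pop <- make_test_pop(c("M", "M", "F", "F"),
                       list(geno_hom(1L, 5), geno_hom(2L, 5),
                            geno_het(1L, 2L, 5), geno_het(1L, 2L, 5)),
                       panel)
  plan <- list(male_idx = 1:2, male_c = c(2L, 2L),
               female_idx = 3:4, female_c = c(2L, 2L))
  freq1 <- (2 + 0 + 1 + 1) / 8
  expect_equal(expected_frequencies(plan, pop),
               matrix(c(freq1, 1 - freq1), 2, 5))
  expect_equal(colSums(expected_frequencies(plan, pop)), rep(1, 5))
})

test_that("distances match closed forms and vanish iff distributions agree", {
  expect_equal(genetic_distance(c(1, 0), c(0.5, 0.5), "kl"), log(2))
  expect_equal(genetic_distance(c(1, 0), c(0, 1), "nei_min"), 1)
  p <- matrix(c(0.8, 0.2, 0.5, 0.5), 2, 2)
  for (kind in c("kl", "chord", "nei_min")) {
    expect_equal(genetic_distance(p, p, kind), 0)
  }
  # non-negativity and sensitivity on random frequency pairs
  set.seed(6)
  for (i in 1:25) {
    a <- matrix(stats::runif(8, 0.05, 1), 4, 2); a <- sweep(a, 2, colSums(a), "/")
    b <- matrix(stats::runif(8, 0.05, 1), 4, 2); b <- sweep(b, 2, colSums(b), "/")
    for (kind in c("kl", "chord", "nei_min")) {
      expect_gte(genetic_distance(a, b, kind), 0)
    }
  }
  # averaging over loci: duplicating a marker leaves the distance unchanged
  expect_equal(genetic_distance(cbind(c(1, 0), c(1, 0)),
                                cbind(c(0.5, 0.5), c(0.5, 0.5)), "kl"),
               log(2))
  expect_error(genetic_distance(c(1, 0), c(0.5, 0.25, 0.25), "kl"),
               "identical dimensions")
})

test_that("annealing finds the exact optimum on an enumerable instance", {
  panel <- make_panel("diagnostic_like", 2)
  set.seed(10)
  # aa parents can reach the (0.8, 0.2)-reference-optimal plan exactly? no:
  # reference is (0.8, 0.2); best plan mixes aa and bb parents
  pop <- make_test_pop(c("M", "M", "M", "F", "F", "F"),
                       list(geno_hom(1L, 2), geno_hom(2L, 2), geno_het(1L, 2L, 2),
                            geno_hom(1L, 2), geno_het(1L, 2L, 2), geno_hom(2L, 2)),
                       panel)
  for (kind in c("kl", "chord", "nei_min")) {
    oracle <- brute_force_contributions(pop, kind, N = 6)
    plan <- optimize_contributions_sa(pop, kind = kind)
    expect_equal(attr(plan, "objective"), oracle, tolerance = 1e-10)
    p_exp <- expected_frequencies(plan, pop)
    expect_equal(genetic_distance(panel$native_freqs, p_exp, kind),
                 attr(plan, "objective"), tolerance = 1e-10)
  }
  # capped variant still matches the capped brute force
  oracle_cap <- brute_force_contributions(pop, "kl", N = 6, cap = 3)
  plan_cap <- optimize_contributions_sa(pop, kind = "kl", cap = 3)
  expect_true(all(plan_cap$male_c <= 3, plan_cap$female_c <= 3))
  expect_equal(attr(plan_cap, "objective"), oracle_cap, tolerance = 1e-10)
})

test_that("annealing drives distance to zero when purity is attainable", {
  panel <- make_panel("diagnostic", 2)
  set.seed(13)
  pop <- make_test_pop(c("M", "M", "F", "F"),
                       list(geno_hom(1L, 2), geno_hom(2L, 2),
                            geno_hom(1L, 2), geno_hom(2L, 2)),
                       panel)
  plan <- optimize_contributions_sa(pop, kind = "nei_min")
  expect_equal(attr(plan, "objective"), 0)
  expect_equal(plan$male_c, c(4L, 0L))
  expect_equal(plan$female_c, c(4L, 0L))
})

test_that("annealing never returns worse than the equal-contribution plan", {
  panel <- make_panel("non_diagnostic", 4)
  set.seed(21)
  map <- genetic_map(2, 20, 4)
  pop <- found_population(12, 6, panel, map)
  pop <- admix_generation(pop)
  males <- which(pop$sex == "M"); females <- which(pop$sex == "F")
  eq_plan <- list(male_idx = males,
                  male_c = rep(12 %/% length(males), length(males)),
                  female_idx = females,
                  female_c = rep(12 %/% length(females), length(females)))
  # pad if uneven
  eq_plan$male_c[1] <- 12 - sum(eq_plan$male_c[-1])
  eq_plan$female_c[1] <- 12 - sum(eq_plan$female_c[-1])
  for (kind in c("kl", "chord", "nei_min")) {
    eq_obj <- genetic_distance(panel$native_freqs,
                               expected_frequencies(eq_plan, pop), kind)
    plan <- optimize_contributions_sa(pop, kind = kind)
    expect_lte(attr(plan, "objective"), eq_obj + 1e-12)
  }
})
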