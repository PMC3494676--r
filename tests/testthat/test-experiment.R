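small_cfg <- function(...) {
  defaults <- list(N = 12, n_exogenous = 4, admix_generations = 2,
                   manage_generations = 3, scheme = "diagnostic",
                   n_markers = 5, n_loci = 50, map_length = 2,
                   replicates = 2, base_seed = 7)
  do.call(scenario_config, utils::modifyList(defaults, list(...)))
}

test_that("configuration validates its fields", {
  expect_error(scenario_config(N = 101), "N")
  expect_error(scenario_config(n_exogenous = 200))
  expect_error(scenario_config(strategy = "psychic"))
  expect_error(scenario_config(cap = 0))
  cfg <- small_cfg()
  expect_s3_class(cfg, "scenario_config")
  expect_null(cfg$cap)
})

test_that("identical seeds give bit-identical metric tables", {
  cfg <- small_cfg()
  a <- run_replicate(cfg, 1)
  b <- run_replicate(cfg, 1)
  expect_identical(a, b)
  c2 <- run_replicate(cfg, 2)
  expect_false(identical(a$NR, c2$NR))
})

test_that("without introgression NR stays exactly 1 under any management", {
  cfg <- small_cfg(n_exogenous = 0)
  r <- run_replicate(cfg, 1)
  expect_true(all(r$NR == 1))
  cfg2 <- small_cfg(n_exogenous = 0, scheme = "non_diagnostic",
                    strategy = "distance", distance = "kl")
  r2 <- run_replicate(cfg2, 1)
  expect_true(all(r2$NR == 1))
})

test_that("replicate tables have the documented shape", {
  cfg <- small_cfg()
  r <- run_replicate(cfg, 1)
  expect_equal(nrow(r), 1 + 2 + 3)
  expect_equal(r$generation, 0:5)
  expect_equal(r$phase, c("base", rep("admixture", 2), rep("management", 3)))
  expect_true(all(c("NR", "mean_F", "mean_coancestry", "obs_homozygosity",
                    "Ne", "n_parents") %in% names(r)))
  expect_true(all(r$NR >= 0 & r$NR <= 1))
  expect_true(all(r$mean_F >= 0 & r$mean_F <= 1))
  expect_true(all(is.na(r$n_parents[r$phase != "management"])))
  expect_true(all(r$n_parents[r$phase == "management"] >= 2))
})

test_that("scenario summaries aggregate final-generation NR and F", {
  res <- run_scenario(small_cfg())
  expect_equal(nrow(res$per_generation), 2 * 6)
  s <- res$summary
  last <- res$per_generation[res$per_generation$generation == 5, ]
  expect_equal(s$NR_mean, mean(last$NR))
  expect_equal(s$F_mean, mean(last$mean_F))
  expect_equal(s$NR_se, stats::sd(last$NR) / sqrt(2))
  # single replicate: SE undefined
  s1 <- run_scenario(small_cfg(replicates = 1))$summary
  expect_true(is.na(s1$NR_se))
  expect_equal(s1$NR_mean,
               run_replicate(small_cfg(), 1)$NR[6])
})

test_that("a replicate can carry its full pedigree for export", {
  r <- run_replicate(small_cfg(), 1, keep_pedigree = TRUE)
  ped <- attr(r, "pedigree")
  expect_equal(nrow(ped), 12 * 6)  # N individuals x (1 + 2 + 3) generations
  expect_true(all(is.na(ped$sire[ped$generation == 0])))
  expect_true(all(!is.na(ped$sire[ped$generation > 0])))
  # metrics themselves are unchanged by the flag
  expect_equal(r$NR, run_replicate(small_cfg(), 1)$NR)
})

test_that("YAML configs round-trip including cap and annealer overrides", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("N: 12", "n_exogenous: 4", "admix_generations: 2",
               "manage_generations: 3", "scheme: non_diagnostic",
               "n_markers: 5", "n_loci: 50", "map_length: 2",
               "strategy: distance", "distance: kl", "cap: none",
               "replicates: 2", "base_seed: 7", "sa_cooling: 0.9",
               "sa_stall_temps: 10"), f)
  cfg <- read_scenario_yaml(f)
  expect_s3_class(cfg, "scenario_config")
  expect_null(cfg$cap)
  expect_equal(cfg$sa$cooling, 0.9)
  expect_equal(cfg$sa$stall_temps, 10L)
  expect_equal(cfg$scheme, "non_diagnostic")

  writeLines(c("N: 12", "n_exogenous: 2", "cap: 5", "replicates: 1",
               "n_loci: 20", "n_markers: 5"), f)
  cfg2 <- read_scenario_yaml(f)
  expect_equal(cfg2$cap, 5L)
})

test_that("results are written as CSV with a provenance header", {
  res <- run_scenario(small_cfg(replicates = 1))
  d <- file.path(tempdir(), "deintrogress-out")
  paths <- save_results(res, d)
  expect_true(all(file.exists(file.path(d, c("per_generation.csv",
                                             "summary.csv")))))
  first <- readLines(file.path(d, "summary.csv"), n = 1)
  expect_match(first, "^# deintrogress scenario")
  tab <- utils::read.csv(file.path(d, "per_generation.csv"), comment.char = "#")
  expect_equal(nrow(tab), 6)
  unlink(d, recursive = TRUE)
})

test_that("grid runners emit one tidy row per cell", {
  grid <- run_scheme_grid(schemes = c("diagnostic", "diagnostic_like"),
                          caps = list(NULL, 2), n_exogenous = c(2, 4),
                          replicates = 1, base_seed = 3,
                          N = 8, admix_generations = 1,
                          manage_generations = 2, n_markers = 5,
                          n_loci = 30, map_length = 2)
  expect_equal(nrow(grid), 8)
  expect_setequal(unique(grid$cap), c("none", "2"))
  expect_true(all(grid$NR_mean >= 0 & grid$NR_mean <= 1))

  fg <- run_freq_grid(freqs = 0.9, n_exogenous = 2, replicates = 1,
                      base_seed = 5, N = 8, admix_generations = 1,
                      manage_generations = 2, n_markers = 5,
                      n_loci = 30, map_length = 2)
  expect_equal(nrow(fg), 1)
  expect_equal(fg$native_allele_freq, 0.9)
  expect_equal(fg$scheme, "extra_diagnostic_like")
})
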