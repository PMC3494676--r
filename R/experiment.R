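#' Scenario configuration
#'
#' Bundles every knob of a de-introgression scenario. Defaults are the
#' study's central conditions: N = 100 with 10 exogenous founders, 5
#' generations of admixture, 10 generations of management, 20 markers on a
#' 20-Morgan chromosome with 2000 background loci, 20 replicates.
#'
#' @param N Population size, constant across generations (study: 100 or 20).
#' @param n_exogenous Exogenous founders (10--50% of `N`).
#' @param admix_generations Random-mating generations before management
#'   begins (1--5).
#' @param manage_generations Managed generations (study: 10).
#' @param scheme Marker scheme, see [make_panel()].
#' @param n_markers Markers in the panel (5--20).
#' @param native_allele_freq Native-allele frequency for
#'   `extra_diagnostic_like` panels.
#' @param strategy `"marker_count"` (truncation selection on native-allele
#'   counts with random allocation) or `"distance"` (simulated-annealing
#'   contribution optimization).
#' @param distance Distance minimized under `strategy = "distance"`.
#' @param cap Maximum offspring per parent (`NULL`, 5 or 10).
#' @param map_length Chromosome length in Morgans (20, or 1 for the
#'   high-LD variant).
#' @param n_loci Background loci (2000).
#' @param replicates Monte-Carlo replicates (20).
#' @param base_seed Integer; replicate `r` seeds the RNG with
#'   `base_seed + r`.
#' @param sa A [sa_control()] list for the annealer.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(N = 100, n_exogenous = 10, admix_generations = 5,
                            manage_generations = 10,
                            scheme = "diagnostic", n_markers = 20,
                            native_allele_freq = NULL,
                            strategy = c("marker_count", "distance"),
                            distance = c("kl", "chord", "nei_min"),
                            cap = NULL, map_length = 20, n_loci = 2000,
                            replicates = 20, base_seed = 1,
                            sa = sa_control()) {
  strategy <- match.arg(strategy)
  distance <- match.arg(distance)
  N <- as.integer(N)
  stopifnot(N >= 2L, N %% 2L == 0L,
            n_exogenous >= 0L, n_exogenous <= N,
            admix_generations >= 0L, manage_generations >= 0L,
            n_markers >= 1L, replicates >= 1L)
  if (!is.null(cap)) stopifnot(cap >= 1L)
  cfg <- structure(
    list(N = N, n_exogenous = as.integer(n_exogenous),
         admix_generations = as.integer(admix_generations),
         manage_generations = as.integer(manage_generations),
         scheme = scheme, n_markers = as.integer(n_markers),
         native_allele_freq = native_allele_freq,
         strategy = strategy, distance = distance,
         cap = if (is.null(cap)) NULL else as.integer(cap),
         map_length = map_length, n_loci = as.integer(n_loci),
         replicates = as.integer(replicates),
         base_seed = as.integer(base_seed),
         sa = sa),
    class = "scenario_config")
  cfg
}

#' Read a scenario configuration from a YAML file
#'
#' Flat key/value file; keys match [scenario_config()] arguments, with
#' `cap: none` (or omitted) for no restriction and optional `sa_*` keys
#' (`sa_cooling`, `sa_moves_per_candidate`, `sa_stall_temps`,
#' `sa_max_temps`) overriding the annealing schedule.
#'
#' @param path Path to the YAML file.
#' @return A `scenario_config`.
#' @export
read_scenario_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare key "N" as a boolean; map it back
  names(raw)[names(raw) == "FALSE"] <- "N"
  if (!is.null(raw$cap) && identical(raw$cap, "none")) raw$cap <- NULL
  sa_keys <- grep("^sa_", names(raw), value = TRUE)
  sa_args <- stats::setNames(raw[sa_keys], sub("^sa_", "", sa_keys))
  raw[sa_keys] <- NULL
  raw$sa <- do.call(sa_control, sa_args)
  do.call(scenario_config, raw)
}

# One managed generation: choose contributions by the configured strategy,
# arrange minimum-coancestry matings, breed. Returns the new population and
# the number of contributing parents.
manage_generation <- function(pop, cfg) {
  if (cfg$strategy == "marker_count") {
    sel <- select_max_native(pop)
    males <- which(pop$sex == "M"); females <- which(pop$sex == "F")
    am <- allocate_contributions_random(sel$males, pop$N, cfg$cap,
                                        candidates = males,
                                        counts = sel$counts)
    af <- allocate_contributions_random(sel$females, pop$N, cfg$cap,
                                        candidates = females,
                                        counts = sel$counts)
    plan <- contribution_plan(am$idx, am$c, af$idx, af$c, pop$N, cfg$cap)
  } else {
    plan <- optimize_contributions_sa(pop, kind = cfg$distance, cap = cfg$cap,
                                      control = cfg$sa)
  }
  matings <- min_coancestry_matings(plan, pop$K)
  list(pop = next_generation(pop, matings$sire, matings$dam),
       n_parents = sum(plan$male_c > 0L) + sum(plan$female_c > 0L))
}

#' Run a single replicate of a scenario
#'
#' Founds the base population, runs the admixture period, then the managed
#' period, recording metrics each generation. Deterministic given
#' `(cfg, replicate_index)`: the RNG is seeded with
#' `cfg$base_seed + replicate_index` at the start.
#'
#' @param cfg A `scenario_config`.
#' @param replicate_index Integer replicate label (1-based).
#' @param keep_pedigree If `TRUE`, the replicate's full pedigree is attached
#'   to the result as attribute `"pedigree"` (for [export_pedigree()]).
#' @return Data frame with one row per generation: `replicate`,
#'   `generation`, `phase`, `NR`, `mean_F`, `mean_coancestry`,
#'   `obs_homozygosity`, `Ne`, `n_parents`.
#' @export
run_replicate <- function(cfg, replicate_index = 1L, keep_pedigree = FALSE) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$base_seed + replicate_index)
  panel <- make_panel(cfg$scheme, cfg$n_markers, cfg$native_allele_freq)
  map <- genetic_map(cfg$map_length, cfg$n_loci, cfg$n_markers)
  pop <- found_population(cfg$N, cfg$n_exogenous, panel, map)
  rows <- vector("list", 1L + cfg$admix_generations + cfg$manage_generations)
  rows[[1L]] <- metrics_record(pop, replicate_index, "base")
  k <- 1L
  for (g in seq_len(cfg$admix_generations)) {
    F_prev <- mean_inbreeding(pop)
    pop <- admix_generation(pop)
    k <- k + 1L
    rows[[k]] <- metrics_record(pop, replicate_index, "admixture", F_prev)
  }
  for (g in seq_len(cfg$manage_generations)) {
    F_prev <- mean_inbreeding(pop)
    step <- manage_generation(pop, cfg)
    pop <- step$pop
    k <- k + 1L
    rows[[k]] <- metrics_record(pop, replicate_index, "management", F_prev,
                                step$n_parents)
  }
  out <- do.call(rbind, rows)
  if (keep_pedigree) attr(out, "pedigree") <- pop$ped
  out
}

#' Run a scenario across replicates
#'
#' @param cfg A `scenario_config`.
#' @return List of class `scenario_result`: `per_generation` (long table
#'   over replicates and generations) and `summary` (one row: mean and
#'   standard error across replicates of final-generation `NR` and
#'   `mean_F`). SE is `NA` with a single replicate.
#' @export
run_scenario <- function(cfg) {
  per_gen <- do.call(rbind, lapply(seq_len(cfg$replicates),
                                   function(r) run_replicate(cfg, r)))
  last <- per_gen[per_gen$generation ==
                    cfg$admix_generations + cfg$manage_generations, ]
  se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  summary <- data.frame(
    scheme = cfg$scheme,
    strategy = cfg$strategy,
    distance = if (cfg$strategy == "distance") cfg$distance else NA_character_,
    cap = if (is.null(cfg$cap)) "none" else as.character(cfg$cap),
    N = cfg$N,
    n_exogenous = cfg$n_exogenous,
    admix_generations = cfg$admix_generations,
    native_allele_freq = if (is.null(cfg$native_allele_freq)) NA_real_
                         else cfg$native_allele_freq,
    replicates = cfg$replicates,
    NR_mean = mean(last$NR), NR_se = se(last$NR),
    F_mean = mean(last$mean_F), F_se = se(last$mean_F)
  )
  structure(list(config = cfg, per_generation = per_gen, summary = summary),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<scenario_result> %s/%s cap=%s, %d exo of N=%d, %d+%d generations, %d reps\n",
    s$scheme, s$strategy, s$cap, s$n_exogenous, s$N,
    x$config$admix_generations, x$config$manage_generations, s$replicates))
  cat(sprintf("  final NR = %.3f +/- %.3f   final F = %.3f +/- %.3f\n",
              s$NR_mean, s$NR_se, s$F_mean, s$F_se))
  invisible(x)
}

#' Scenario grid over native-allele frequencies and introgression levels
#'
#' Runs the extra-diagnostic-like design (native allele at frequency `f` in
#' natives, 0.5 in the exogenous population; 20 markers; truncation
#' selection; no offspring cap) over a grid of `f` values and numbers of
#' exogenous founders, with 5 admixture and 10 managed generations.
#'
#' @param freqs Native-allele frequencies to sweep.
#' @param n_exogenous Numbers of exogenous founders to sweep.
#' @param replicates Replicates per cell.
#' @param base_seed Seed offset; each cell gets a distinct derived seed.
#' @param ... Further arguments passed to [scenario_config()].
#' @return Data frame of cell summaries (one row per cell).
#' @export
run_freq_grid <- function(freqs = c(0.7, 0.8, 0.9, 0.95, 0.99),
                          n_exogenous = c(10, 20, 30, 40, 50),
                          replicates = 20, base_seed = 1, ...) {
  cells <- expand.grid(f = freqs, exo = n_exogenous)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- scenario_config(n_exogenous = cells$exo[i],
                           scheme = "extra_diagnostic_like",
                           native_allele_freq = cells$f[i],
                           strategy = "marker_count",
                           replicates = replicates,
                           base_seed = base_seed + 1000L * i, ...)
    run_scenario(cfg)$summary
  })
  do.call(rbind, out)
}

#' Scenario grid over marker schemes and offspring caps
#'
#' Runs the three marker schemes (diagnostic and diagnostic-like under
#' truncation selection; non-diagnostic under Kullback-Leibler
#' distance minimization) crossed with offspring-cap settings and
#' introgression levels, with 5 admixture and 10 managed generations and
#' 20 markers.
#'
#' @param schemes Marker schemes to sweep.
#' @param caps List of cap settings (`NULL` = no restriction).
#' @param n_exogenous Numbers of exogenous founders to sweep.
#' @param replicates Replicates per cell.
#' @param base_seed Seed offset; each cell gets a distinct derived seed.
#' @param ... Further arguments passed to [scenario_config()].
#' @return Data frame of cell summaries.
#' @export
run_scheme_grid <- function(schemes = c("diagnostic", "diagnostic_like",
                                        "non_diagnostic"),
                            caps = list(NULL, 10, 5),
                            n_exogenous = c(10, 20, 30, 40, 50),
                            replicates = 20, base_seed = 1, ...) {
  out <- list()
  i <- 0L
  for (sc in schemes) for (cap in caps) for (exo in n_exogenous) {
    i <- i + 1L
    cfg <- scenario_config(
      n_exogenous = exo, scheme = sc,
      strategy = if (sc == "non_diagnostic") "distance" else "marker_count",
      distance = "kl", cap = cap,
      replicates = replicates, base_seed = base_seed + 1000L * i, ...)
    out[[i]] <- run_scenario(cfg)$summary
  }
  do.call(rbind, out)
}

#' Write scenario results to CSV
#'
#' Emits `per_generation.csv` and `summary.csv` under `dir`, with a header
#' comment recording the configuration (including annealer defaults) for
#' provenance.
#'
#' @param result A `scenario_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
save_results <- function(result, dir) {
  stopifnot(inherits(result, "scenario_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$config
  hdr <- sprintf(
    "# deintrogress scenario: %s", jsonlite::toJSON(
      cfg[setdiff(names(cfg), "sa")], auto_unbox = TRUE, null = "null"))
  paths <- file.path(dir, c("per_generation.csv", "summary.csv"))
  for (j in 1:2) {
    con <- file(paths[j], "w")
    writeLines(hdr, con)
    utils::write.csv(if (j == 1) result$per_generation else result$summary,
                     con, row.names = FALSE)
    close(con)
  }
  invisible(paths)
}
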