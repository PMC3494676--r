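#' Minimum-coancestry mate assignment
#'
#' Expands each sire into as many sire slots as his offspring count and each
#' dam likewise (both lists have length `N`), then solves the `N x N` linear
#' assignment problem minimizing the summed pairwise coancestry of mated
#' parents, via the Hungarian algorithm. Because an offspring's inbreeding
#' coefficient equals its parents' coancestry, this minimizes the mean
#' inbreeding of the next generation given the contributions.
#'
#' Slot orders are shuffled with the session RNG before solving, so ties
#' among equally optimal assignments are broken reproducibly under
#' [set.seed()].
#'
#' @param plan A contribution plan (`male_idx`, `male_c`, `female_idx`,
#'   `female_c`; both sexes summing to the same `N`).
#' @param kinship Kinship matrix over the current generation's columns
#'   (e.g. `pop$K`).
#' @return Data frame with `N` rows, columns `sire` and `dam` (population
#'   column indices), one row per offspring; per-parent pair counts equal
#'   the plan's offspring counts exactly.
#' @examples
#' K <- matrix(c(.5, 0, .25, 0,  0, .5, 0, .25,  .25, 0, .5, 0,  0, .25, 0, .5), 4)
#' plan <- list(male_idx = c(1, 2), male_c = c(1, 1),
#'              female_idx = c(3, 4), female_c = c(1, 1))
#' min_coancestry_matings(plan, K)  # avoids the related pairs
#' @export
min_coancestry_matings <- function(plan, kinship) {
  sire_slots <- rep(plan$male_idx, plan$male_c)
  dam_slots <- rep(plan$female_idx, plan$female_c)
  n <- length(sire_slots)
  if (length(dam_slots) != n)
    stop("sire and dam slot totals differ; contribution plan is infeasible")
  sire_slots <- resample(sire_slots, n)
  dam_slots <- resample(dam_slots, n)
  cost <- kinship[sire_slots, dam_slots, drop = FALSE]
  assign <- cpp_hungarian(cost)
  data.frame(sire = sire_slots, dam = dam_slots[assign])
}
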