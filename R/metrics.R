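#' Native founder representation
#'
#' The fraction of the `2 N L` background allele copies in the current
#' generation whose founder of origin was native. Founder allele IDs are
#' unique, so origin is recovered exactly; at generation 0 this equals
#' 1 minus the introgression fraction by construction.
#'
#' @param pop A `population`.
#' @return Proportion in \[0, 1\].
#' @export
native_representation <- function(pop) {
  (sum(pop$allele_native[pop$nmA]) + sum(pop$allele_native[pop$nmB])) /
    (2 * length(pop$nmA))
}

#' Mean pedigree inbreeding of a generation
#'
#' @param pop A `population`; its `Fped` holds each individual's pedigree
#'   inbreeding coefficient (the coancestry of its parents).
#' @return Mean F over the generation's individuals.
#' @export
mean_inbreeding <- function(pop) mean(pop$Fped)

#' Mean pedigree coancestry of a generation
#'
#' Mean kinship over all `N^2` ordered pairs of the current generation,
#' including self-coancestries (the "mean coancestry of the group"
#' convention; only trends are compared across strategies, so the
#' convention matters less than its consistency).
#'
#' @param pop A `population`.
#' @return Mean coancestry.
#' @export
mean_coancestry <- function(pop) mean(pop$K)

#' Observed homozygosity at the background loci
#'
#' Fraction of individual-by-locus genotypes whose two allele IDs are
#' identical. Founders are fully heterozygous by construction, so this is
#' also the identity-by-descent rate and tracks pedigree inbreeding.
#'
#' @param pop A `population`.
#' @return Proportion in \[0, 1\].
#' @export
observed_homozygosity <- function(pop) mean(pop$nmA == pop$nmB)

#' Effective population size from the rate of inbreeding
#'
#' \eqn{\Delta F = (F_t - F_{t-1}) / (1 - F_{t-1})} and
#' \eqn{N_e = 1 / (2 \Delta F)}; reported as `Inf` when inbreeding did not
#' increase.
#'
#' @param F_prev Mean inbreeding of the previous generation.
#' @param F_curr Mean inbreeding of the current generation.
#' @return Effective size (possibly `Inf`).
#' @examples
#' effective_size(0, 0.1)  # 5
#' @export
effective_size <- function(F_prev, F_curr) {
  dF <- (F_curr - F_prev) / (1 - F_prev)
  if (is.na(dF) || dF <= 0) return(Inf)
  1 / (2 * dF)
}

# One row of per-generation output.
metrics_record <- function(pop, replicate, phase, F_prev = NA_real_,
                           n_parents = NA_integer_) {
  F_curr <- mean_inbreeding(pop)
  data.frame(
    replicate = replicate,
    generation = pop$generation,
    phase = phase,
    NR = native_representation(pop),
    mean_F = F_curr,
    mean_coancestry = mean_coancestry(pop),
    obs_homozygosity = observed_homozygosity(pop),
    Ne = if (is.na(F_prev)) NA_real_ else effective_size(F_prev, F_curr),
    n_parents = n_parents
  )
}
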