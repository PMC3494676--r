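#' Build a founder genome
#'
#' Founders carry two distinct, globally unique allele IDs at every
#' background locus: founder `i` carries alleles `2i - 1` and `2i` at all
#' `L` loci. Every founder is therefore heterozygous everywhere, the base
#' generation segregates `2 * N0` alleles per locus, and the founder origin
#' of any descendant allele copy is recoverable as `ceiling(id / 2)` —
#' observed homozygosity doubles as an identity-by-descent measure. Marker
#' genotypes are drawn from the panel's origin-population frequencies.
#'
#' @param founder_index Integer, unique within the base population.
#' @param origin `"native"` or `"exogenous"`.
#' @param panel A `marker_panel`.
#' @param map A `genetic_map`.
#' @return A list of class `genome`: integer vectors `nm_a`, `nm_b`
#'   (background allele IDs, length `map$L`) and `mk_a`, `mk_b` (marker
#'   alleles, length `map$M`), plus `origin`.
#' @export
build_founder_genome <- function(founder_index, origin = c("native", "exogenous"),
                                 panel, map) {
  origin <- match.arg(origin)
  stopifnot(inherits(map, "genetic_map"), founder_index >= 1L)
  i <- as.integer(founder_index)
  mk <- draw_founder_marker_genotype(panel, origin)
  structure(
    list(nm_a = rep.int(2L * i - 1L, map$L),
         nm_b = rep.int(2L * i, map$L),
         mk_a = mk$hap_a,
         mk_b = mk$hap_b,
         origin = origin),
    class = "genome"
  )
}

# Draw one crossover realization: Poisson(length) breakpoints uniform on the
# chromosome, no interference, plus the starting haplotype (0 = a, 1 = b).
draw_crossovers <- function(map) {
  k <- stats::rpois(1L, map$length)
  bp <- if (k > 0L) sort.int(stats::runif(k, 0, map$length)) else numeric(0)
  list(k = k, breakpoints = bp, start = if (stats::runif(1) < 0.5) 0L else 1L)
}

# Haplotype phase (0/1) at each map position for a given crossover
# realization: parity of the number of breakpoints to the left.
crossover_phase <- function(positions, breakpoints, start) {
  (start + findInterval(positions, breakpoints)) %% 2L
}

# Apply a crossover realization to a pair of haplotype vectors.
recombine <- function(hap_a, hap_b, positions, breakpoints, start) {
  ph <- crossover_phase(positions, breakpoints, start)
  out <- hap_a
  sw <- ph == 1L
  out[sw] <- hap_b[sw]
  out
}

#' Sample a gamete from a genome
#'
#' A Poisson-distributed number of crossovers (mean = map length in Morgans,
#' no interference) is placed uniformly on the chromosome; the starting
#' parental haplotype is chosen with probability 1/2. Background loci and
#' markers inherit jointly from the same crossover realization, preserving
#' the linkage disequilibrium between markers and the neutral background
#' that marker-guided management exploits.
#'
#' Uses the session RNG; seed with [set.seed()].
#'
#' @param genome A `genome` (see [build_founder_genome()]), or any list with
#'   `nm_a`, `nm_b`, `mk_a`, `mk_b`.
#' @param map The `genetic_map` the genome was built on.
#' @return List with `nm` (background allele IDs) and `mk` (marker alleles).
#' @export
sample_gamete <- function(genome, map) {
  co <- draw_crossovers(map)
  list(nm = recombine(genome$nm_a, genome$nm_b, map$nm_pos,
                      co$breakpoints, co$start),
       mk = recombine(genome$mk_a, genome$mk_b, map$mk_pos,
                      co$breakpoints, co$start))
}
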