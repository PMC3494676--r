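#' Build a genetic map for a single chromosome
#'
#' The simulated genome is one chromosome of fixed map length carrying two
#' interleaved sets of loci: `n_loci` neutral multiallelic background loci
#' used only to measure outcomes (native representation, homozygosity), and
#' `n_markers` marker loci used by the management strategies. Both sets are
#' evenly spaced on the same map, so markers and background loci are
#' physically linked and inherit from the same crossover realization.
#'
#' Background loci sit at positions \eqn{(\ell - 0.5) \cdot \mathrm{length}/L}
#' and markers at \eqn{(m - 0.5) \cdot \mathrm{length}/M}; for the default
#' configuration (L = 2000, M <= 20) the two sets never coincide.
#'
#' @param length_morgans Map length in Morgans. The expected number of
#'   crossovers per meiosis equals this length (Poisson model, no
#'   interference). Default 20; a 1-Morgan genome is also supported.
#' @param n_loci Number of neutral background loci (default 2000).
#' @param n_markers Number of marker loci.
#' @return An object of class `genetic_map`: a list with elements `length`,
#'   `nm_pos`, `mk_pos`, `L`, `M`.
#' @examples
#' map <- genetic_map(20, n_loci = 2000, n_markers = 20)
#' head(map$nm_pos)
#' @export
genetic_map <- function(length_morgans = 20, n_loci = 2000, n_markers = 20) {
  stopifnot(length(length_morgans) == 1L, length_morgans > 0,
            n_loci >= 1L, n_markers >= 1L)
  nm <- (seq_len(n_loci) - 0.5) * length_morgans / n_loci
  mk <- (seq_len(n_markers) - 0.5) * length_morgans / n_markers
  structure(
    list(length = length_morgans,
         nm_pos = nm,
         mk_pos = mk,
         L = as.integer(n_loci),
         M = as.integer(n_markers)),
    class = "genetic_map"
  )
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("<genetic_map> 1 chromosome, %g M, %d background loci, %d markers\n",
              x$length, x$L, x$M))
  invisible(x)
}
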