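# sample() without the scalar-x surprise
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

#' Found an admixed base population
#'
#' Builds generation 0: `N` unrelated, non-inbred founders, half male and
#' half female, of which `n_exogenous` are of exogenous origin. Exogenous
#' founders' sexes are drawn Bernoulli(1/2) (redrawn in the rare case a sex
#' quota is exceeded) and native founders fill the remaining slots so the
#' sex ratio is exactly 50/50. Every founder is heterozygous for two unique
#' allele IDs at each of the `map$L` background loci; marker genotypes are
#' drawn per the panel scheme.
#'
#' @param N Population size (even). The study uses 100 and 20.
#' @param n_exogenous Number of exogenous founders (introgression fraction
#'   `n_exogenous / N`; the study spans 10--50%).
#' @param panel A `marker_panel`.
#' @param map A `genetic_map`.
#' @return An object of class `population`: generation index, per-individual
#'   `id`, `sex`, `Fped` (pedigree inbreeding), haplotype matrices `nmA`,
#'   `nmB` (`L x N` background allele IDs) and `mkA`, `mkB` (`M x N` marker
#'   alleles), the kinship matrix `K` of the current generation, the
#'   accumulated pedigree `ped`, and `allele_native`, the origin lookup for
#'   founder allele IDs.
#' @examples
#' set.seed(1)
#' pop <- found_population(20, 4, make_panel("diagnostic", 5), genetic_map(1, 50, 5))
#' native_representation(pop)  # 0.8 exactly
#' @export
found_population <- function(N, n_exogenous, panel, map) {
  N <- as.integer(N); n_exogenous <- as.integer(n_exogenous)
  stopifnot(N >= 2L, N %% 2L == 0L, n_exogenous >= 0L, n_exogenous <= N,
            inherits(panel, "marker_panel"), inherits(map, "genetic_map"))
  half <- N %/% 2L
  repeat {
    exo_sex <- resample(c("M", "F"), n_exogenous, replace = TRUE)
    if (sum(exo_sex == "M") <= half && sum(exo_sex == "F") <= half) break
  }
  origin <- c(rep("exogenous", n_exogenous), rep("native", N - n_exogenous))
  sex <- c(exo_sex,
           rep("M", half - sum(exo_sex == "M")),
           rep("F", half - sum(exo_sex == "F")))

  nmA <- matrix(rep(2L * seq_len(N) - 1L, each = map$L), nrow = map$L)
  nmB <- nmA + 1L
  mkA <- matrix(0L, nrow = map$M, ncol = N)
  mkB <- matrix(0L, nrow = map$M, ncol = N)
  for (i in seq_len(N)) {
    g <- draw_founder_marker_genotype(panel, origin[i])
    mkA[, i] <- g$hap_a
    mkB[, i] <- g$hap_b
  }

  structure(
    list(generation = 0L,
         N = N,
         id = seq_len(N),
         sex = sex,
         Fped = numeric(N),
         nmA = nmA, nmB = nmB, mkA = mkA, mkB = mkB,
         K = diag(0.5, N),
         ped = data.frame(id = seq_len(N), sire = NA_integer_,
                          dam = NA_integer_, sex = sex, generation = 0L),
         allele_native = rep(origin == "native", each = 2L),
         panel = panel,
         map = map),
    class = "population"
  )
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> generation %d, N=%d (%d M / %d F), %d loci, %d markers\n",
              x$generation, x$N, sum(x$sex == "M"), sum(x$sex == "F"),
              x$map$L, x$map$M))
  cat(sprintf("  NR=%.4f  meanF=%.4f  obs.hom=%.4f\n",
              native_representation(x), mean(x$Fped),
              observed_homozygosity(x)))
  invisible(x)
}

# Produce the next generation from explicit matings. sire_idx/dam_idx are
# column indices into the current generation, one entry per offspring.
# Kinship and inbreeding propagate by the generational recursion
#   f(o1, o2) = 1/4 [f(s1,s2) + f(s1,d2) + f(d1,s2) + f(d1,d2)],
#   f(o, o)   = (1 + f(s, d)) / 2,
# exact here because parents always belong to the previous generation.
next_generation <- function(pop, sire_idx, dam_idx) {
  N <- pop$N
  stopifnot(length(sire_idx) == N, length(dam_idx) == N,
            all(pop$sex[sire_idx] == "M"), all(pop$sex[dam_idx] == "F"))
  map <- pop$map
  L <- map$L; M <- map$M
  nmA <- matrix(0L, L, N); nmB <- matrix(0L, L, N)
  mkA <- matrix(0L, M, N); mkB <- matrix(0L, M, N)
  for (j in seq_len(N)) {
    s <- sire_idx[j]; d <- dam_idx[j]
    co <- draw_crossovers(map)
    nmA[, j] <- recombine(pop$nmA[, s], pop$nmB[, s], map$nm_pos,
                          co$breakpoints, co$start)
    mkA[, j] <- recombine(pop$mkA[, s], pop$mkB[, s], map$mk_pos,
                          co$breakpoints, co$start)
    co <- draw_crossovers(map)
    nmB[, j] <- recombine(pop$nmA[, d], pop$nmB[, d], map$nm_pos,
                          co$breakpoints, co$start)
    mkB[, j] <- recombine(pop$mkA[, d], pop$mkB[, d], map$mk_pos,
                          co$breakpoints, co$start)
  }

  Kp <- pop$K
  Fo <- Kp[cbind(sire_idx, dam_idx)]
  Ko <- 0.25 * (Kp[sire_idx, sire_idx, drop = FALSE] +
                Kp[sire_idx, dam_idx,  drop = FALSE] +
                Kp[dam_idx,  sire_idx, drop = FALSE] +
                Kp[dam_idx,  dam_idx,  drop = FALSE])
  diag(Ko) <- 0.5 * (1 + Fo)

  half <- N %/% 2L
  sex <- resample(c(rep("M", half), rep("F", half)), N)
  ids <- max(pop$ped$id) + seq_len(N)

  pop$ped <- rbind(pop$ped,
                   data.frame(id = ids,
                              sire = pop$id[sire_idx],
                              dam = pop$id[dam_idx],
                              sex = sex,
                              generation = pop$generation + 1L))
  pop$generation <- pop$generation + 1L
  pop$id <- ids
  pop$sex <- sex
  pop$Fped <- Fo
  pop$K <- Ko
  pop$nmA <- nmA; pop$nmB <- nmB; pop$mkA <- mkA; pop$mkB <- mkB
  pop
}

#' Advance one generation of random admixture
#'
#' The admixture period between the introgression event and the start of
#' management: each of the `N` offspring draws its sire uniformly with
#' replacement from the males and its dam uniformly from the females.
#' Offspring sexes are an exact N/2 : N/2 random permutation (population
#' size and sex ratio are held constant throughout).
#'
#' @param pop A `population`.
#' @return The next-generation `population`.
#' @export
admix_generation <- function(pop) {
  stopifnot(inherits(pop, "population"))
  males <- which(pop$sex == "M"); females <- which(pop$sex == "F")
  stopifnot(length(males) >= 1L, length(females) >= 1L)
  sire_idx <- resample(males, pop$N, replace = TRUE)
  dam_idx <- resample(females, pop$N, replace = TRUE)
  next_generation(pop, sire_idx, dam_idx)
}

#' Pedigree kinship matrix (tabular method)
#'
#' Computes the additive-relationship-based kinship (coancestry) matrix from
#' a pedigree by the standard tabular method: founders are unrelated and
#' non-inbred (`f(i,i) = 1/2`, `f(i,j) = 0`), and for a non-founder `i` with
#' parents `s`, `d`: `f(i,j) = [f(s,j) + f(d,j)] / 2` for earlier `j` and
#' `f(i,i) = [1 + f(s,d)] / 2`.
#'
#' @param ped Data frame with columns `id`, `sire`, `dam` (NA for founders),
#'   ordered so that parents precede offspring (generation order suffices).
#' @param members Optional vector of ids to subset the returned matrix to.
#' @return Symmetric kinship matrix with dimnames = ids.
#' @examples
#' ped <- data.frame(id = 1:3, sire = c(NA, NA, 1), dam = c(NA, NA, 2))
#' kinship_matrix(ped)
#' @export
kinship_matrix <- function(ped, members = NULL) {
  n <- nrow(ped)
  idx <- match(ped$sire, ped$id)
  idy <- match(ped$dam, ped$id)
  if (any(!is.na(ped$sire) & is.na(idx)) || any(!is.na(ped$dam) & is.na(idy)))
    stop("pedigree references a parent with no record")
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- idx[i]; d <- idy[i]
    if (is.na(s) && is.na(d)) {
      A[i, i] <- 0.5
      next
    }
    if (is.na(s) || is.na(d))
      stop("individuals must have either both parents recorded or neither")
    if (s >= i || d >= i)
      stop("pedigree is not sorted parents-first")
    prev <- seq_len(i - 1L)
    row <- 0.5 * (A[s, prev] + A[d, prev])
    A[i, prev] <- row
    A[prev, i] <- row
    A[i, i] <- 0.5 * (1 + A[s, d])
  }
  dimnames(A) <- list(ped$id, ped$id)
  if (!is.null(members)) {
    pos <- match(members, ped$id)
    if (anyNA(pos)) stop("some members are not in the pedigree")
    A <- A[pos, pos, drop = FALSE]
  }
  A
}

#' Export a pedigree as 3-column text
#'
#' Writes `id sire dam` (0 for unknown parents), one line per individual.
#'
#' @param pop A `population` (or a pedigree data frame with `id`, `sire`,
#'   `dam`).
#' @param file Output path.
#' @export
export_pedigree <- function(pop, file) {
  ped <- if (inherits(pop, "population")) pop$ped else pop
  out <- data.frame(id = ped$id,
                    sire = ifelse(is.na(ped$sire), 0L, ped$sire),
                    dam = ifelse(is.na(ped$dam), 0L, ped$dam))
  utils::write.table(out, file, row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  invisible(out)
}
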