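#' Construct a marker panel from explicit allele-frequency tables
#'
#' Low-level constructor. Columns are markers, rows are alleles; each column
#' of each frequency matrix must sum to 1. All named schemes share allele
#' labels between populations (allele 1 in the native table is the same
#' allele 1 in the exogenous table), and allele 1 is the designated "native"
#' allele used by count-based management.
#'
#' @param native_freqs Numeric matrix (alleles x markers) of allele
#'   frequencies in the native base population.
#' @param exogenous_freqs Same shape, frequencies in the exogenous population.
#' @param scheme Character label for the panel.
#' @param native_allele Row index of the allele treated as native by
#'   count-based selection (default 1).
#' @return An object of class `marker_panel`.
#' @seealso [make_panel()] for the named schemes.
#' @export
marker_panel <- function(native_freqs, exogenous_freqs, scheme = "custom",
                         native_allele = 1L) {
  native_freqs <- as.matrix(native_freqs)
  exogenous_freqs <- as.matrix(exogenous_freqs)
  if (!identical(dim(native_freqs), dim(exogenous_freqs)))
    stop("native and exogenous frequency tables must have identical dimensions")
  if (any(native_freqs < 0) || any(exogenous_freqs < 0))
    stop("allele frequencies must be non-negative")
  if (any(abs(colSums(native_freqs) - 1) > 1e-8) ||
      any(abs(colSums(exogenous_freqs) - 1) > 1e-8))
    stop("allele frequencies must sum to 1 at every marker")
  native_allele <- as.integer(native_allele)
  if (native_allele < 1L || native_allele > nrow(native_freqs))
    stop("native_allele out of range")
  structure(
    list(scheme = scheme,
         M = ncol(native_freqs),
         A = nrow(native_freqs),
         native_freqs = unname(native_freqs),
         exogenous_freqs = unname(exogenous_freqs),
         native_allele = native_allele),
    class = "marker_panel"
  )
}

#' Build one of the named marker panels
#'
#' Four informativeness regimes are supported, all with the same frequency
#' profile repeated across the `M` markers:
#'
#' * `diagnostic`: private alleles. Native individuals are fixed for allele 1,
#'   exogenous for allele 2, so allele origin is unambiguous.
#' * `diagnostic_like`: biallelic, native 0.80/0.20, exogenous 0.20/0.80.
#'   Management still treats allele 1 as if private, which it is not.
#' * `extra_diagnostic_like`: biallelic, native `f`/(1-`f`) for
#'   `f` in \{0.7, 0.8, 0.9, 0.95, 0.99\}, exogenous 0.5/0.5 — the worst case
#'   where the assumed-native allele is equally common in the foreign pool.
#' * `non_diagnostic`: four alleles, native (0.80, 0.07, 0.06, 0.07),
#'   exogenous (0.07, 0.80, 0.06, 0.07); intended for distance-based
#'   management with reference frequencies assumed known without error.
#'
#' @param scheme One of `"diagnostic"`, `"diagnostic_like"`,
#'   `"extra_diagnostic_like"`, `"non_diagnostic"`.
#' @param M Number of markers (the study varies 5 to 20).
#' @param native_allele_freq Frequency `f` of the native allele in the native
#'   population; required for (and only for) `extra_diagnostic_like`.
#' @return A `marker_panel`.
#' @examples
#' make_panel("diagnostic", 20)
#' make_panel("extra_diagnostic_like", 20, native_allele_freq = 0.99)
#' @export
make_panel <- function(scheme = c("diagnostic", "diagnostic_like",
                                  "extra_diagnostic_like", "non_diagnostic"),
                       M = 20, native_allele_freq = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(M >= 1L)
  fr <- switch(scheme,
    diagnostic = list(nat = c(1, 0), exo = c(0, 1)),
    diagnostic_like = list(nat = c(0.8, 0.2), exo = c(0.2, 0.8)),
    extra_diagnostic_like = {
      if (is.null(native_allele_freq))
        stop("native_allele_freq is required for the extra_diagnostic_like scheme")
      ok <- vapply(c(0.7, 0.8, 0.9, 0.95, 0.99),
                   function(v) isTRUE(all.equal(v, native_allele_freq)),
                   logical(1))
      if (!any(ok))
        stop("native_allele_freq must be one of 0.7, 0.8, 0.9, 0.95, 0.99")
      list(nat = c(native_allele_freq, 1 - native_allele_freq),
           exo = c(0.5, 0.5))
    },
    non_diagnostic = list(nat = c(0.80, 0.07, 0.06, 0.07),
                          exo = c(0.07, 0.80, 0.06, 0.07))
  )
  if (scheme != "extra_diagnostic_like" && !is.null(native_allele_freq))
    stop("native_allele_freq is only meaningful for extra_diagnostic_like")
  marker_panel(matrix(fr$nat, nrow = length(fr$nat), ncol = M),
               matrix(fr$exo, nrow = length(fr$exo), ncol = M),
               scheme = scheme)
}

#' Draw founder marker genotypes
#'
#' For the diagnostic scheme the genotype is deterministic (native founders
#' homozygous for allele 1, exogenous for allele 2). For all other schemes the
#' two allele copies at each marker are drawn independently from the origin
#' population's frequencies (Hardy-Weinberg in the base generation, no
#' base-generation linkage disequilibrium within an origin group).
#'
#' Uses the session RNG; seed with [set.seed()] for reproducibility.
#'
#' @param panel A `marker_panel`.
#' @param origin `"native"` or `"exogenous"`.
#' @return List with integer vectors `hap_a`, `hap_b` of length `panel$M`.
#' @export
draw_founder_marker_genotype <- function(panel, origin = c("native", "exogenous")) {
  origin <- match.arg(origin)
  stopifnot(inherits(panel, "marker_panel"))
  if (panel$scheme == "diagnostic") {
    a <- if (origin == "native") 1L else 2L
    return(list(hap_a = rep(a, panel$M), hap_b = rep(a, panel$M)))
  }
  fr <- if (origin == "native") panel$native_freqs else panel$exogenous_freqs
  draw_hap <- function() {
    vapply(seq_len(panel$M),
           function(m) sample.int(panel$A, 1L, prob = fr[, m]),
           integer(1))
  }
  list(hap_a = draw_hap(), hap_b = draw_hap())
}

#' Serialize a marker panel to JSON
#'
#' Round-trippable with [panel_from_json()]; used for config provenance.
#'
#' @param panel A `marker_panel`.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
panel_to_json <- function(panel, path = NULL) {
  stopifnot(inherits(panel, "marker_panel"))
  obj <- list(scheme = panel$scheme,
              M = panel$M, A = panel$A,
              native_allele = panel$native_allele,
              native_freqs = panel$native_freqs,
              exogenous_freqs = panel$exogenous_freqs)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname panel_to_json
#' @param json JSON string or path to a JSON file.
#' @export
panel_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  marker_panel(obj$native_freqs, obj$exogenous_freqs,
               scheme = obj$scheme, native_allele = obj$native_allele)
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("<marker_panel> scheme=%s, M=%d markers, %d alleles each\n",
              x$scheme, x$M, x$A))
  cat("  native freqs:   ", paste(format(x$native_freqs[, 1]), collapse = " "), "\n")
  cat("  exogenous freqs:", paste(format(x$exogenous_freqs[, 1]), collapse = " "), "\n")
  invisible(x)
}
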