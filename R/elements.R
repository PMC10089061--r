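#' @keywords internal
"_PACKAGE"

#' @useDynLib znmt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

# Isotope masses (Da) and natural abundances, IUPAC 2013 values.
# Only the elements occurring in metallothionein ion species are carried.
.isotopes <- list(
  H  = list(mass = c(1.00782503207, 2.0141017778),
            abundance = c(0.999885, 0.000115)),
  C  = list(mass = c(12.0, 13.0033548378),
            abundance = c(0.9893, 0.0107)),
  N  = list(mass = c(14.0030740048, 15.0001088982),
            abundance = c(0.99636, 0.00364)),
  O  = list(mass = c(15.9949146196, 16.9991317, 17.999161),
            abundance = c(0.99757, 0.00038, 0.00205)),
  S  = list(mass = c(31.972071, 32.97145876, 33.9678669, 35.96708076),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Zn = list(mass = c(63.9291422, 65.9260334, 66.9271273, 67.9248442,
                     69.9253193),
            abundance = c(0.4917, 0.2773, 0.0404, 0.1845, 0.0061)),
  Na = list(mass = 22.9897692809, abundance = 1.0)
)

# Abundance-weighted average atomic masses, derived from .isotopes so the
# two mass pathways cannot drift apart.
.average_mass <- vapply(.isotopes, function(e) sum(e$mass * e$abundance),
                        numeric(1))

.monoisotopic_mass <- vapply(.isotopes, function(e) e$mass[which.max(e$abundance)],
                             numeric(1))

# Elemental composition of each amino-acid residue as found in a chain
# (free amino acid minus one water).
.residue_formula <- list(
  G = c(C = 2, H = 3,  N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5,  N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5,  N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7,  N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9,  N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7,  N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6,  N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5,  N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8,  N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7,  N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7,  N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9,  N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9,  N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

.element_order <- c("C", "H", "N", "O", "S", "Zn", "Na")

#' Create an elemental composition
#'
#' An `elemental_composition` is a named integer vector over the elements
#' C, H, N, O, S, Zn, Na. Compositions add under `+` and can be scaled by
#' non-negative integers, which is all the species bookkeeping needs.
#'
#' @param ... Named element counts, e.g. `composition(C = 2, H = 5, N = 1, O = 2)`.
#' @return An `elemental_composition` object.
#' @examples
#' composition(C = 2, H = 5, N = 1, O = 2)  # glycine
#' @export
composition <- function(...) {
  x <- c(...)
  if (length(x) == 0) x <- stats::setNames(numeric(0), character(0))
  bad <- setdiff(names(x), .element_order)
  if (length(bad) > 0) {
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  }
  out <- stats::setNames(rep(0, length(.element_order)), .element_order)
  out[names(x)] <- x
  if (any(out < 0)) stop("element counts must be non-negative")
  structure(out, class = "elemental_composition")
}

#' @export
`+.elemental_composition` <- function(e1, e2) {
  do.call(composition, as.list(unclass(e1) + unclass(e2)))
}

#' @export
print.elemental_composition <- function(x, ...) {
  nz <- x[x > 0]
  cat("<elemental_composition> ",
      paste0(names(nz), ifelse(nz > 1, nz, ""), collapse = ""),
      "\n", sep = "")
  cat("  average mass ", format(composition_mass(x), digits = 8), " Da\n",
      sep = "")
  invisible(x)
}

#' Mass of an elemental composition
#'
#' @param comp An `elemental_composition`.
#' @param kind `"average"` (abundance-weighted) or `"monoisotopic"`.
#' @return Mass in Da.
#' @export
composition_mass <- function(comp, kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  m <- if (kind == "average") .average_mass else .monoisotopic_mass
  sum(unclass(comp) * m[names(comp)])
}

#' Elemental composition of a protein sequence
#'
#' Sums residue formulas and adds one water for the termini. The result is
#' the neutral, fully reduced, fully protonated reference state from which
#' all ion species are derived.
#'
#' @param seq A `protein_sequence` or a plain one-letter string.
#' @return An `elemental_composition`.
#' @examples
#' composition_from_sequence("G")
#' @export
composition_from_sequence <- function(seq) {
  s <- if (inherits(seq, "protein_sequence")) seq$residues else seq
  aa <- strsplit(toupper(s), "")[[1]]
  unknown <- setdiff(aa, names(.residue_formula))
  if (length(unknown) > 0) {
    stop("unknown residue letter(s): ", paste(unique(unknown), collapse = ", "))
  }
  counts <- Reduce(`+`, .residue_formula[aa])
  do.call(composition, as.list(counts)) + composition(H = 2, O = 1)
}
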