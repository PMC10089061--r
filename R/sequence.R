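#' Packaged human metallothionein-2 sequence
#'
#' Returns the canonical human MT2A sequence (UniProt P02795, initiator
#' methionine retained, no acetylation): 61 residues, 20 cysteines, average
#' apo mass about 6.0 kDa. MT2 binds up to seven Zn2+ in two thiolate
#' clusters; the packaged cluster maps in [cluster_map()] index into this
#' sequence. Any other sequence can be substituted via [read_protein_fasta()].
#'
#' @return A `protein_sequence`: list with `residues` (one-letter string)
#'   and `name`.
#' @examples
#' seq <- mt2_sequence()
#' nchar(seq$residues)
#' @export
mt2_sequence <- function() {
  protein_sequence(
    "MDPNCSCAAGDSCTCAGSCKCKECKCTSCKKSCCSCCPVGCAKCAQGCICKGASDKCSCCA",
    name = "MT2"
  )
}

#' Construct a protein sequence object
#'
#' @param residues One-letter amino-acid string (canonical 20 letters).
#' @param name Label.
#' @return A `protein_sequence`.
#' @export
protein_sequence <- function(residues, name = "protein") {
  residues <- toupper(gsub("\\s", "", residues))
  letters <- strsplit(residues, "")[[1]]
  bad <- setdiff(letters, names(.residue_formula))
  if (length(bad) > 0) {
    stop("non-canonical residue letter(s): ", paste(unique(bad), collapse = ", "))
  }
  structure(list(residues = residues, name = name), class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat("<protein_sequence> ", x$name, ": ", nchar(x$residues), " residues, ",
      cys_count(x), " Cys\n", sep = "")
  cat("  ", x$residues, "\n", sep = "")
  invisible(x)
}

#' @rdname protein_sequence
#' @param x A `protein_sequence`.
#' @export
cys_count <- function(x) {
  lengths(regmatches(x$residues, gregexpr("C", x$residues)))
}

#' Cys positions of a sequence (1-based residue indices)
#' @param seq A `protein_sequence`.
#' @return Integer vector of residue positions.
#' @export
cys_positions <- function(seq) {
  which(strsplit(seq$residues, "")[[1]] == "C")
}

#' Read a protein sequence from FASTA
#'
#' @param path Path to a FASTA file; the first record is used.
#' @return A `protein_sequence`.
#' @export
read_protein_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  protein_sequence(as.character(recs[[1]]),
                   name = attr(recs[[1]], "name") %||% "protein")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
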