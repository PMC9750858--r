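# Amino-acid and substitution-string utilities shared across modules.

#' Standard amino acids
#'
#' The 20 standard amino acids as one-letter codes, alphabetical.
#'
#' @return Character vector of length 20.
#' @export
standard_aa <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

aa_check <- function(aa, arg = "aa") {
  bad <- setdiff(unique(aa), standard_aa())
  if (length(bad) > 0) {
    stop(sprintf("non-standard amino acid(s) in `%s`: %s",
                 arg, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(aa)
}

#' Format substitutions as variant strings
#'
#' Encodes substitutions in the field's usual notation, e.g. `"K59Q"` for a
#' single and `"K59Q+F159A"` for a double (positions in ascending order,
#' joined by `+`).
#'
#' @param wt,position,aa Parallel vectors (wild-type residue, 1-based
#'   position, substituted residue). For doubles pass length-2 vectors.
#' @return A single variant string.
#' @export
format_variant <- function(wt, position, aa) {
  ord <- order(position)
  paste0(wt[ord], position[ord], aa[ord], collapse = "+")
}

#' Parse variant strings
#'
#' Inverse of [format_variant()]: turns `"K59Q+F159A"` into a tibble with one
#' row per substitution.
#'
#' @param x Character vector of variant strings.
#' @return Tibble with columns `variant`, `wt`, `position`, `aa`.
#' @export
parse_variant <- function(x) {
  parts <- stringr::str_split(x, stringr::fixed("+"))
  purrr::map2_dfr(x, parts, function(v, p) {
    m <- stringr::str_match(p, "^([A-Z])(\\d+)([A-Z])$")
    if (anyNA(m[, 1])) {
      stop(sprintf("malformed substitution in variant '%s'", v), call. = FALSE)
    }
    tibble::tibble(variant = v, wt = m[, 2],
                   position = as.integer(m[, 3]), aa = m[, 4])
  })
}

#' Translate a coding sequence
#'
#' Thin wrapper over [Biostrings::translate()] accepting a plain character
#' CDS.
#'
#' @param cds Character scalar, nucleotide coding sequence (length a multiple
#'   of 3).
#' @return Character scalar, the protein sequence (stops as `*`).
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1)
  if (nchar(cds) %% 3 != 0) stop("CDS length is not a multiple of 3", call. = FALSE)
  as.character(Biostrings::translate(Biostrings::DNAString(cds)))
}

# Split a CDS into codons (character vector, 1-based codon index).
split_codons <- function(cds) {
  n <- nchar(cds) %/% 3
  substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

#' Genetic code lookup
#'
#' @param codon Character vector of codons (ACGT triplets).
#' @return One-letter amino acids (`*` for stop codons).
#' @export
codon_to_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}
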