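# Bundled reconstruction of the PYR1 binding-pocket double-site mutagenesis
# (DSM) design: 19 pocket positions, 15 unrestricted (any amino acid except
# Cys/Pro), 4 restricted (62, 81, 87, 110), proximity window 8 (strict), and
# variant-level curation of distal doubles.
#
# The original per-position design file is not redistributed here. This
# reconstruction is SYNTHETIC: it is built in code from the published design
# constraints (which positions, which are restricted, Cys/Pro exclusion) and
# the published library totals (301 singles; 6,291 proximal doubles; 37,797
# single + double nonsynonymous mutants). Restricted subset sizes are the
# unique balanced solution of those totals; subset identities are chosen by
# BLOSUM62 similarity to wild type; the curated-double list preserves the
# published count, not the (unpublished) identities. See the methods
# vignette for the full derivation.

#' PYR1 pocket position table
#'
#' The 19 binding-pocket positions targeted by the DSM design with their
#' wild-type residues, and whether each position is restricted.
#'
#' @return Tibble `position`, `wt`, `restricted`.
#' @export
pyr1_positions <- function() {
  tibble::tibble(
    position = c(59L, 62L, 81L, 83L, 87L, 89L, 92L, 94L, 108L, 110L,
                 117L, 120L, 122L, 141L, 159L, 160L, 163L, 164L, 167L),
    wt = c("K", "I", "V", "V", "L", "A", "S", "E", "F", "I",
           "L", "Y", "S", "E", "F", "A", "V", "V", "N"),
    restricted = c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE,
                   FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                   FALSE, FALSE, FALSE)
  )
}

#' PYR1 protein sequence (synthetic reference copy)
#'
#' The 191-residue PYR1 receptor sequence used by the bundled design and the
#' synthetic reference CDS. Wild-type identities at all 19 pocket positions
#' agree with published PYR1 mutation nomenclature (K59, V81, V83, L87, A89,
#' S92, F108, Y120, S122, F159, A160, V164, ...).
#'
#' @return Character scalar, length 191.
#' @export
pyr1_protein <- function() {
  paste0(
    "MPSELTPEERSELKNSIAEFHTYQLDPGSCSSLHAQRIHA",
    "PPELVWSIVRRFDKPQTYKHFIKSCSVEQNFEMRVGCTRD",
    "VIVISGLPANTSTERLDILDDERRVTGFSIIGGEHRLTNY",
    "KSVTTVHRFEKENRIWTVVLESYVVDMPEGNSEDDTRMFA",
    "DTVVKLNLQKLATVAEAMARNSGDGSGSQVT"
  )
}

# BLOSUM62 rows for the wild types occurring at restricted positions.
# Used only to pick a deterministic, conservative restricted subset.
blosum62_row <- function(wt) {
  rows <- list(
    I = c(A = -1, R = -3, N = -3, D = -3, C = -1, Q = -3, E = -3, G = -4,
          H = -3, I = 4, L = 2, K = -3, M = 1, F = 0, P = -3, S = -2,
          T = -1, W = -3, Y = -1, V = 3),
    V = c(A = 0, R = -3, N = -3, D = -3, C = -1, Q = -2, E = -2, G = -3,
          H = -3, I = 3, L = 1, K = -2, M = 1, F = -1, P = -2, S = -2,
          T = 0, W = -3, Y = -1, V = 4),
    L = c(A = -1, R = -2, N = -3, D = -4, C = -1, Q = -2, E = -3, G = -4,
          H = -3, I = 2, L = 4, K = -2, M = 2, F = 0, P = -3, S = -2,
          T = -1, W = -2, Y = -1, V = 1)
  )
  if (is.null(rows[[wt]])) stop("no BLOSUM62 row bundled for ", wt)
  rows[[wt]]
}

# Top-k substitutions for `wt` by BLOSUM62 score (excluding wt, C, P),
# ties broken alphabetically.
restricted_subset <- function(wt, k) {
  row <- blosum62_row(wt)
  cand <- setdiff(names(row), c(wt, "C", "P"))
  cand <- cand[order(-row[cand], cand)]
  sort(cand[seq_len(k)])
}

# Restricted subset sizes at positions 62/81/87/110. Given 15 unrestricted
# positions x 17 alleles, the published totals force the sizes to sum to 46
# (301 singles) and to reproduce 6,291 proximal doubles under the strict
# window-8 rule; (11, 14, 11, 10) is the balanced integer solution.
pyr1_restricted_sizes <- function() {
  c(`62` = 11L, `81` = 14L, `87` = 11L, `110` = 10L)
}

#' The bundled PYR1 DSM library design (synthetic reconstruction)
#'
#' Builds the 19-position design: unrestricted positions take all amino
#' acids except the wild type, cysteine and proline (17 alleles);
#' restricted positions 62/81/87/110 take BLOSUM62-conservative subsets of
#' sizes 11/14/11/10. With `curated = TRUE` (default) a deterministic list
#' of 5,368 distal double mutants is excluded, reproducing the published
#' library size of 37,797 single + double nonsynonymous mutants; the
#' identities of the originally curated doubles are not public, so the
#' excluded set is an evenly spaced sample of the distal enumeration and is
#' labelled synthetic.
#'
#' @param curated Apply the variant-level exclusion list (default `TRUE`).
#' @return A `dsm_design`.
#' @export
pyr1_design <- function(curated = TRUE) {
  pos <- pyr1_positions()
  sizes <- pyr1_restricted_sizes()
  overrides <- lapply(names(sizes), function(p) {
    wt <- pos$wt[pos$position == as.integer(p)]
    restricted_subset(wt, sizes[[p]])
  })
  names(overrides) <- names(sizes)
  design <- build_allele_sets(pos[c("position", "wt")],
                              global_exclusions = c("C", "P"),
                              overrides = overrides, window = 8)
  if (!curated) return(design)
  doubles <- enumerate_doubles(design)
  distal <- doubles$variant[doubles$pool == "distal"]
  n_excl <- length(distal) + sum(doubles$pool == "proximal") +
    sum(lengths(design$alleles)) - 37797L
  stopifnot(n_excl > 0, n_excl <= length(distal))
  idx <- unique(round(seq(1, length(distal), length.out = n_excl)))
  stopifnot(length(idx) == n_excl)
  new_dsm_design(tibble::as_tibble(design[c("position", "wt", "alleles")]),
                 window = 8, global_exclusions = c("C", "P"),
                 excluded_doubles = tibble::tibble(variant = distal[idx]))
}

#' Synthetic PYR1 reference CDS
#'
#' Back-translation of [pyr1_protein()] with the bundled yeast codon usage
#' table, adjusted so no 15-mer repeats (guaranteeing unambiguous oligo
#' homology arms). This is a synthetic stand-in for the physical plasmid
#' sequence, which is not printed in the literature; it encodes exactly the
#' PYR1 protein above.
#'
#' @return Character scalar CDS (573 nt).
#' @export
pyr1_reference_cds <- function() {
  cache <- dsm_cache()
  if (is.null(cache$pyr1_cds)) {
    cache$pyr1_cds <- back_translate(pyr1_protein())
  }
  cache$pyr1_cds
}

dsm_cache <- local({
  env <- new.env(parent = emptyenv())
  function() env
})
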