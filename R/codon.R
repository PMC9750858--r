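# Codon usage tables, mutant codon selection, and back-translation.

#' Load a codon usage table
#'
#' Reads a TSV with columns `aa`, `codon`, `fraction` and normalizes the
#' fractions within each amino acid. The bundled default
#' (`scer_codon_usage.tsv`) is a Saccharomyces cerevisiae usage table, the
#' expression host of the yeast two-hybrid sensor screens.
#'
#' @param path Path to a usage TSV; default the bundled yeast table.
#' @return Tibble `aa`, `codon`, `fraction` (fractions sum to 1 per aa).
#' @export
codon_usage_table <- function(path = NULL) {
  cache <- dsm_cache()
  if (is.null(path)) {
    if (!is.null(cache$default_usage)) return(cache$default_usage)
    path <- system.file("extdata", "scer_codon_usage.tsv", package = "dsmkit")
    cache_default <- TRUE
  } else {
    cache_default <- FALSE
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(
    aa = readr::col_character(),
    codon = readr::col_character(),
    fraction = readr::col_double()
  ))
  stopifnot(all(nchar(tab$codon) == 3),
            all(grepl("^[ACGT]{3}$", tab$codon)))
  aa_check(tab$aa, "aa")
  mism <- tab$aa != codon_to_aa(tab$codon)
  if (any(mism)) {
    stop("codon/aa mismatch in usage table: ",
         paste(tab$codon[mism], collapse = ", "), call. = FALSE)
  }
  tab <- dplyr::mutate(dplyr::group_by(tab, .data$aa),
                       fraction = .data$fraction / sum(.data$fraction))
  tab <- dplyr::ungroup(tab)
  if (cache_default) cache$default_usage <- tab
  tab
}

#' Choose the replacement codon for a substitution
#'
#' Returns the highest-usage codon for the target amino acid; ties are broken
#' alphabetically. One replacement codon per substitution keeps the pool
#' arithmetic one oligo per designed mutant.
#'
#' @param target_aa One-letter amino acid to install.
#' @param wt_codon The wild-type codon being replaced.
#' @param usage Codon usage tibble (see [codon_usage_table()]).
#' @return A codon (character scalar), never equal to `wt_codon`.
#' @export
choose_codon <- function(target_aa, wt_codon, usage = codon_usage_table()) {
  aa_check(target_aa, "target_aa")
  stopifnot(grepl("^[ACGT]{3}$", wt_codon))
  if (identical(target_aa, codon_to_aa(wt_codon))) {
    stop(sprintf("null mutation: target %s equals translation of %s",
                 target_aa, wt_codon), call. = FALSE)
  }
  ranked <- codon_rank_list(usage)
  cand <- ranked[[target_aa]]
  if (is.null(cand)) {
    stop("usage table has no codons for amino acid ", target_aa, call. = FALSE)
  }
  cand <- cand[cand != wt_codon] # cannot happen for aa != wt, but guard
  cand[1]
}

# per-aa codons ranked by usage (desc), ties alphabetical; memoised on the
# usage table's content
codon_rank_list <- function(usage) {
  key <- paste0("rank_", rlang::hash(usage))
  cache <- dsm_cache()
  if (is.null(cache[[key]])) {
    ord <- order(usage$aa, -usage$fraction, usage$codon)
    cache[[key]] <- split(usage$codon[ord], usage$aa[ord])
  }
  cache[[key]]
}

#' Back-translate a protein to a synthetic CDS
#'
#' Greedy left-to-right back-translation using the highest-usage codon at
#' each site, demoting to lower-ranked codons where needed so that the
#' resulting CDS contains no repeated k-mer (default 15 nt). Uniqueness of
#' all 15-mers guarantees that any oligo homology arm of >= 15 nt maps to a
#' single site. Deterministic: no randomness.
#'
#' @param protein One-letter protein sequence (no stops).
#' @param usage Codon usage tibble.
#' @param unique_kmer Length of the k-mers forced to be unique (default 15).
#' @return Character scalar CDS (3x protein length).
#' @export
back_translate <- function(protein, usage = codon_usage_table(),
                           unique_kmer = 15) {
  aas <- strsplit(protein, "")[[1]]
  aa_check(aas, "protein")
  ranked <- split(usage[order(-usage$fraction, usage$codon), ]$codon,
                  usage[order(-usage$fraction, usage$codon), ]$aa)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  cds <- character(length(aas))
  prefix <- ""
  for (i in seq_along(aas)) {
    placed <- FALSE
    for (codon in ranked[[aas[i]]]) {
      cand <- paste0(prefix, codon)
      kmers <- tail_kmers(cand, unique_kmer, n_new = 3)
      if (!any(vapply(kmers, function(k) !is.null(seen[[k]]), logical(1)))) {
        for (k in kmers) seen[[k]] <- TRUE
        cds[i] <- codon
        prefix <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf("cannot avoid a repeated %d-mer at codon %d", unique_kmer, i),
           call. = FALSE)
    }
  }
  paste0(cds, collapse = "")
}

# the k-mers ending within the last n_new bases of s
tail_kmers <- function(s, k, n_new) {
  n <- nchar(s)
  if (n < k) return(character(0))
  ends <- seq(max(k, n - n_new + 1), n)
  substring(s, ends - k + 1, ends)
}
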