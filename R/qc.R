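# Library completeness QC from amplicon sequencing: per-read variant calls
# against the designed space and coverage statistics.

#' Globally align one read to the reference CDS
#'
#' Needleman-Wunsch global alignment with affine gap penalties
#' (via [Biostrings::pairwiseAlignment()]).
#'
#' @param read Character scalar, the read sequence.
#' @param reference_cds Character scalar, the reference.
#' @param gap_opening,gap_extension Affine gap penalties (defaults 10, 0.5).
#' @return A list: `aligned_read`, `aligned_ref` (gapped strings),
#'   `n_mismatch`, `n_gap` (gap columns), `score`.
#' @export
align_read <- function(read, reference_cds, gap_opening = 10,
                       gap_extension = 0.5) {
  stopifnot(nchar(read) > 0)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(read),
    subject = Biostrings::DNAString(reference_cds),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_opening, gapExtension = gap_extension)
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  pc <- strsplit(p, "")[[1]]; sc <- strsplit(s, "")[[1]]
  gaps <- pc == "-" | sc == "-"
  list(aligned_read = p, aligned_ref = s,
       n_mismatch = sum(!gaps & pc != sc),
       n_gap = sum(gaps),
       score = Biostrings::score(aln))
}

# Classify one full-length, gap-free read by protein-level comparison.
classify_protein_diff <- function(read_seq, ref_codons, ref_aa, design_env) {
  read_codons <- split_codons(read_seq)
  read_aa <- codon_to_aa(read_codons)
  diff <- which(read_aa != ref_aa)
  if (length(diff) == 0) {
    return(list(class = "wildtype", subs = "", reason = ""))
  }
  subs <- format_variant(ref_aa[diff], diff, read_aa[diff])
  if (length(diff) == 1 && !is.null(design_env$singles[[subs]])) {
    return(list(class = "designed_single", subs = subs, reason = ""))
  }
  if (length(diff) == 2 && !is.null(design_env$doubles[[subs]])) {
    return(list(class = "designed_double", subs = subs, reason = ""))
  }
  list(class = "undesigned", subs = subs, reason = "")
}

design_lookup <- function(design) {
  singles <- enumerate_singles(design)
  doubles <- enumerate_doubles(design)
  e <- new.env(parent = emptyenv())
  e$singles <- new.env(hash = TRUE, parent = emptyenv())
  e$doubles <- new.env(hash = TRUE, parent = emptyenv())
  for (v in singles$variant) assign(v, TRUE, envir = e$singles)
  for (v in doubles$variant) assign(v, TRUE, envir = e$doubles)
  e$n_singles <- nrow(singles)
  e$n_doubles <- nrow(doubles)
  e
}

#' Call variants for a batch of amplicon reads
#'
#' Reads are full-length amplicons over the designed region. Equal-length
#' reads are compared to the reference positionally; length-discordant reads
#' go through the affine-gap aligner and any read with a gap in the designed
#' region is discarded (indels in an amplicon library are synthesis or
#' sequencing artifacts under the substitution-only error model). Reads are
#' classified at the protein level: `wildtype`, `designed_single`,
#' `designed_double`, `undesigned` (including > 2 amino-acid changes), or
#' `discarded` (with a reason code).
#'
#' @param reads Tibble with columns `read_id`, `sequence` (or a character
#'   vector of sequences).
#' @param reference_cds Reference CDS (character scalar).
#' @param design A `dsm_design` defining the designed variant space.
#' @return Tibble `read_id`, `class`, `subs`, `n_mismatch`, `n_indel`,
#'   `reason`.
#' @export
call_variants <- function(reads, reference_cds, design) {
  if (is.character(reads)) {
    reads <- tibble::tibble(read_id = paste0("read", seq_along(reads)),
                            sequence = reads)
  }
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  ref_codons <- split_codons(reference_cds)
  ref_aa <- codon_to_aa(ref_codons)
  lookup <- design_lookup(design)
  n_ref <- nchar(reference_cds)

  # classification depends only on the sequence: dedupe before the work
  uniq <- unique(reads$sequence)
  res <- purrr::map(uniq, function(s) {
    if (nchar(s) == n_ref) {
      a <- strsplit(s, "")[[1]]; b <- strsplit(reference_cds, "")[[1]]
      nm <- sum(a != b)
      cl <- classify_protein_diff(s, ref_codons, ref_aa, lookup)
      c(cl, list(n_mismatch = nm, n_indel = 0L))
    } else if (nchar(s) < 0.5 * n_ref) {
      list(class = "discarded", subs = "", reason = "partial",
           n_mismatch = NA_integer_, n_indel = NA_integer_)
    } else {
      aln <- align_read(s, reference_cds)
      if (aln$n_gap > 0) {
        list(class = "discarded", subs = "", reason = "indel",
             n_mismatch = aln$n_mismatch, n_indel = aln$n_gap)
      } else {
        cl <- classify_protein_diff(s, ref_codons, ref_aa, lookup)
        c(cl, list(n_mismatch = aln$n_mismatch, n_indel = 0L))
      }
    }
  })
  res_tbl <- tibble::tibble(
    sequence = uniq,
    class = purrr::map_chr(res, "class"),
    subs = purrr::map_chr(res, "subs"),
    n_mismatch = purrr::map_int(res, ~ as.integer(.x$n_mismatch)),
    n_indel = purrr::map_int(res, ~ as.integer(.x$n_indel)),
    reason = purrr::map_chr(res, "reason")
  )
  out <- dplyr::left_join(reads[c("read_id", "sequence")], res_tbl,
                          by = "sequence")
  out$sequence <- NULL
  out
}

#' Library completeness from variant calls
#'
#' A designed variant counts as observed when its read count reaches
#' `min_reads`. Completeness fractions are computed over the designed single
#' and double sets separately.
#'
#' @param calls Tibble from [call_variants()].
#' @param design The `dsm_design` the library was built from.
#' @param min_reads Minimum supporting reads per variant (default 1, i.e.
#'   presence/absence).
#' @return An object of class `completeness_report`: a list with
#'   `summary` (one-row tibble: totals, class tallies, `singles_observed`,
#'   `doubles_observed`, `singles_completeness`, `doubles_completeness`,
#'   `min_reads`) and `per_variant` (tibble `variant`, `tier`, `n_reads`,
#'   `observed`).
#' @export
completeness_report <- function(calls, design, min_reads = 1) {
  stopifnot(min_reads >= 1)
  singles <- enumerate_singles(design)
  doubles <- enumerate_doubles(design)
  designed <- dplyr::bind_rows(
    tibble::tibble(variant = singles$variant, tier = "single"),
    tibble::tibble(variant = doubles$variant, tier = "double"))
  counts <- dplyr::count(
    calls[calls$class %in% c("designed_single", "designed_double"), ],
    .data$subs, name = "n_reads")
  per_variant <- dplyr::left_join(designed, counts,
                                  by = c(variant = "subs"))
  per_variant$n_reads[is.na(per_variant$n_reads)] <- 0L
  per_variant$observed <- per_variant$n_reads >= min_reads

  tally <- table(factor(calls$class, levels = c(
    "wildtype", "designed_single", "designed_double", "undesigned",
    "discarded")))
  sng <- per_variant$tier == "single"
  summary <- tibble::tibble(
    n_reads = nrow(calls),
    n_wildtype = as.integer(tally[["wildtype"]]),
    n_designed_single = as.integer(tally[["designed_single"]]),
    n_designed_double = as.integer(tally[["designed_double"]]),
    n_undesigned = as.integer(tally[["undesigned"]]),
    n_discarded = as.integer(tally[["discarded"]]),
    singles_observed = sum(per_variant$observed[sng]),
    doubles_observed = sum(per_variant$observed[!sng]),
    singles_completeness =
      if (any(sng)) mean(per_variant$observed[sng]) else 0,
    doubles_completeness =
      if (any(!sng)) mean(per_variant$observed[!sng]) else 0,
    overall_completeness =
      if (nrow(per_variant) > 0) mean(per_variant$observed) else 0,
    min_reads = as.integer(min_reads)
  )
  structure(list(summary = summary, per_variant = per_variant),
            class = "completeness_report")
}

#' @export
print.completeness_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<completeness_report> %d reads; singles %d/%d (%.1f%%), doubles %d/%d (%.1f%%) at min_reads %d\n",
    s$n_reads, s$singles_observed,
    sum(x$per_variant$tier == "single"), 100 * s$singles_completeness,
    s$doubles_observed, sum(x$per_variant$tier == "double"),
    100 * s$doubles_completeness, s$min_reads))
  invisible(x)
}

#' @rdname completeness_report
#' @param x A `completeness_report`.
#' @param ... Unused.
#' @method glance completeness_report
#' @export
glance.completeness_report <- function(x, ...) x$summary

#' @rdname completeness_report
#' @method tidy completeness_report
#' @export
tidy.completeness_report <- function(x, ...) x$per_variant

#' Write a completeness report to disk
#'
#' Per-variant calls as TSV and the summary as JSON.
#'
#' @param report A `completeness_report`.
#' @param tsv,json Output paths.
#' @return Invisibly, `c(tsv, json)`.
#' @export
write_completeness <- function(report, tsv, json) {
  readr::write_tsv(report$per_variant, tsv)
  jsonlite::write_json(as.list(report$summary), json, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(tsv, json))
}
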