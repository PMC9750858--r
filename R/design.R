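# Mutational design space: candidate positions, per-position allele sets,
# exact enumeration of single/double variants, proximity partitioning.

#' Build per-position allele sets for a saturation-mutagenesis design
#'
#' Constructs a `dsm_design` object from a table of candidate positions.
#' The default allele set at each position is the 20 standard amino acids
#' minus the wild type and minus `global_exclusions` (cysteine and proline by
#' default; both introduce folding liabilities in a buried binding pocket).
#' Optionally the sets are filtered by a per-mutant stability table
#' (externally computed Rosetta ddG values), and explicit per-position
#' overrides replace the computed set entirely — this is how manually curated
#' restricted positions are expressed.
#'
#' @param positions Data frame with columns `position` (1-based residue index
#'   in the reference protein) and `wt` (one-letter wild-type residue).
#' @param global_exclusions Amino acids never allowed as substitutions.
#'   Default `c("C", "P")`.
#' @param overrides Named list mapping position (as character or integer
#'   name) to an explicit allele vector, replacing the computed set.
#' @param stability Optional data frame `position`, `aa`, `ddg` of predicted
#'   stability changes (Rosetta energy units).
#' @param ddg_threshold If given together with `stability`, substitutions
#'   with `ddg` greater than the threshold are dropped.
#' @param window Proximity window (residues) used when partitioning double
#'   mutants into oligo pools; two positions are *proximal* when they are
#'   separated by fewer than `window` residues, i.e. `abs(i - j) < window`.
#'   Default 8.
#' @param excluded_doubles Optional data frame with a `variant` column of
#'   double-variant strings (e.g. `"K59Q+I62A"`) removed from the enumerated
#'   design (variant-level manual curation).
#' @return A `dsm_design` object: a tibble of positions with an `alleles`
#'   list-column, plus design-level attributes.
#' @examples
#' d <- build_allele_sets(data.frame(position = c(10, 20), wt = c("K", "F")))
#' lengths(d$alleles) # 17 17
#' @export
build_allele_sets <- function(positions,
                              global_exclusions = c("C", "P"),
                              overrides = NULL,
                              stability = NULL,
                              ddg_threshold = NULL,
                              window = 8,
                              excluded_doubles = NULL) {
  positions <- tibble::as_tibble(positions)
  stopifnot(all(c("position", "wt") %in% names(positions)))
  positions$position <- as.integer(positions$position)
  aa_check(positions$wt, "wt")
  if (length(global_exclusions)) aa_check(global_exclusions, "global_exclusions")
  if (is.unsorted(positions$position, strictly = TRUE)) {
    stop("positions must be strictly increasing and unique", call. = FALSE)
  }
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), as.character(positions$position))
    if (length(unknown) > 0) {
      stop("override(s) reference unknown position(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(stability)) {
    stability <- tibble::as_tibble(stability)
    stopifnot(all(c("position", "aa", "ddg") %in% names(stability)))
    if (anyDuplicated(stability[c("position", "aa")]) > 0) {
      stop("duplicate (position, aa) rows in stability table", call. = FALSE)
    }
  }

  alleles <- purrr::map2(positions$position, positions$wt, function(pos, wt) {
    ov <- overrides[[as.character(pos)]]
    if (!is.null(ov)) {
      ov <- sort(unique(ov))
      aa_check(ov, sprintf("override[%d]", pos))
      if (wt %in% ov) {
        stop(sprintf("override at position %d contains the wild type (%s)",
                     pos, wt), call. = FALSE)
      }
      return(ov)
    }
    set <- setdiff(standard_aa(), c(wt, global_exclusions))
    if (!is.null(stability) && !is.null(ddg_threshold)) {
      tab <- stability[stability$position == pos, ]
      if (nrow(tab) > 0) {
        unstable <- tab$aa[tab$ddg > ddg_threshold]
        set <- setdiff(set, unstable)
      }
    }
    sort(set)
  })

  out <- tibble::tibble(position = positions$position,
                        wt = positions$wt,
                        alleles = alleles)
  new_dsm_design(out, window = window,
                 global_exclusions = global_exclusions,
                 excluded_doubles = excluded_doubles)
}

new_dsm_design <- function(tbl, window, global_exclusions,
                           excluded_doubles = NULL) {
  stopifnot(window >= 0)
  if (!is.null(excluded_doubles)) {
    excluded_doubles <- tibble::as_tibble(excluded_doubles)
    stopifnot("variant" %in% names(excluded_doubles))
  }
  structure(tbl,
            class = c("dsm_design", class(tbl)),
            window = window,
            global_exclusions = global_exclusions,
            excluded_doubles = excluded_doubles)
}

#' @export
print.dsm_design <- function(x, ...) {
  cat(sprintf("<dsm_design> %d positions, %d single alleles, window %d\n",
              nrow(x), sum(lengths(x$alleles)), attr(x, "window")))
  NextMethod()
}

design_window <- function(design) attr(design, "window")

wt_lookup <- function(design) {
  stats::setNames(design$wt, as.character(design$position))
}

#' Enumerate all designed single mutants
#'
#' One row per single substitution, ordered by position then amino acid.
#'
#' @param design A `dsm_design`.
#' @return Tibble `variant`, `position`, `wt`, `aa`, `tier`.
#' @export
enumerate_singles <- function(design) {
  stopifnot(inherits(design, "dsm_design"))
  tbl <- tibble::as_tibble(design[c("position", "wt", "alleles")])
  out <- tidyr::unnest(dplyr::rename(tbl, aa = "alleles"), "aa")
  out <- dplyr::arrange(out, .data$position, .data$aa)
  dplyr::mutate(out,
                variant = paste0(.data$wt, .data$position, .data$aa),
                tier = "single",
                .before = 1)[, c("variant", "position", "wt", "aa", "tier")]
}

#' Enumerate all designed double mutants
#'
#' Every unordered pair of substitutions at two *distinct* positions, minus
#' any variant-level curation recorded in the design
#' (`excluded_doubles`). Ordered by first position, first amino acid, second
#' position, second amino acid.
#'
#' @param design A `dsm_design`.
#' @param apply_exclusions Apply the design's curated exclusion list
#'   (default `TRUE`).
#' @return Tibble `variant`, `position1`, `aa1`, `position2`, `aa2`, `tier`,
#'   `pool` (`"proximal"` or `"distal"` by the design's window).
#' @export
enumerate_doubles <- function(design, apply_exclusions = TRUE) {
  stopifnot(inherits(design, "dsm_design"))
  n <- nrow(design)
  if (n < 2) {
    return(tibble::tibble(variant = character(), position1 = integer(),
                          aa1 = character(), position2 = integer(),
                          aa2 = character(), tier = character(),
                          pool = character()))
  }
  pairs <- utils::combn(seq_len(n), 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    grid <- tidyr::expand_grid(aa1 = design$alleles[[i]],
                               aa2 = design$alleles[[j]])
    tibble::tibble(position1 = design$position[i], aa1 = grid$aa1,
                   position2 = design$position[j], aa2 = grid$aa2,
                   wt1 = design$wt[i], wt2 = design$wt[j])
  })
  out <- dplyr::mutate(out,
    variant = paste0(.data$wt1, .data$position1, .data$aa1, "+",
                     .data$wt2, .data$position2, .data$aa2),
    tier = "double",
    pool = ifelse(abs(.data$position1 - .data$position2) < design_window(design),
                  "proximal", "distal"))
  out <- dplyr::arrange(out, .data$position1, .data$aa1,
                        .data$position2, .data$aa2)
  excl <- attr(design, "excluded_doubles")
  if (apply_exclusions && !is.null(excl)) {
    out <- dplyr::anti_join(out, excl["variant"], by = "variant")
  }
  out[, c("variant", "position1", "aa1", "position2", "aa2", "tier", "pool")]
}

#' Partition double mutants into proximal and distal pools
#'
#' A double is *proximal* when its two positions are separated by fewer than
#' `window` residues (`abs(i - j) < window`): such pairs must be installed by
#' a single double-mutant oligo, because two sequential single-oligo rounds
#' of nicking mutagenesis cannot edit sites whose homology arms overlap.
#' All other doubles are *distal*.
#'
#' @param doubles Tibble of double variants (as from [enumerate_doubles()]).
#' @param window Proximity window in residues (default 8, strict inequality).
#' @return The input tibble with a recomputed `pool` column.
#' @export
partition_by_proximity <- function(doubles, window = 8) {
  stopifnot(all(c("position1", "position2") %in% names(doubles)))
  if ("tier" %in% names(doubles) && any(doubles$tier != "double")) {
    stop("partition_by_proximity expects double variants only", call. = FALSE)
  }
  dplyr::mutate(doubles,
                pool = ifelse(abs(.data$position1 - .data$position2) < window,
                              "proximal", "distal"))
}

#' Summary counts for a library design
#'
#' @param design A `dsm_design`.
#' @param codon_assignments Optional tibble `variant`, `codons` mapping each
#'   protein variant to one or more DNA realizations; when given, a
#'   DNA-level variant total is reported alongside the protein-level counts.
#' @return One-row tibble: `n_positions`, `n_singles`, `n_doubles`,
#'   `n_proximal`, `n_distal`, `n_total` (singles + doubles, protein level)
#'   and `n_dna` (`NA` unless `codon_assignments` given).
#' @export
library_report <- function(design, codon_assignments = NULL) {
  singles <- enumerate_singles(design)
  doubles <- enumerate_doubles(design)
  n_dna <- NA_integer_
  if (!is.null(codon_assignments)) {
    ca <- tibble::as_tibble(codon_assignments)
    stopifnot("variant" %in% names(ca))
    n_dna <- nrow(ca)
  }
  tibble::tibble(
    n_positions = nrow(design),
    n_singles = nrow(singles),
    n_doubles = nrow(doubles),
    n_proximal = sum(doubles$pool == "proximal"),
    n_distal = sum(doubles$pool == "distal"),
    n_total = nrow(singles) + nrow(doubles),
    n_dna = n_dna
  )
}

#' @rdname library_report
#' @param x A `dsm_design`.
#' @param ... Unused.
#' @method glance dsm_design
#' @export
glance.dsm_design <- function(x, ...) library_report(x)

#' Write a variant table to TSV
#'
#' One row per variant, substitutions encoded as `"K59Q"` /
#' `"K59Q+F159A"`; row order is the deterministic enumeration order.
#'
#' @param variants Tibble from [enumerate_singles()] or
#'   [enumerate_doubles()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  readr::write_tsv(variants, path)
  invisible(path)
}
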