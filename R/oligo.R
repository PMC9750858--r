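# Mutagenic oligo design for nicking mutagenesis: codon replacement plus
# melting-temperature-sized homology arms, with an in-silico application
# oracle.

#' Oligo design parameters
#'
#' @param min_arm_tm Minimum homology-arm melting temperature in degrees C
#'   (default 60).
#' @param min_arm_len,max_arm_len Arm length bounds in nt (defaults 15, 40).
#' @param max_oligo_len Maximum total oligo length in nt (default 90).
#' @param oligo_conc,na_conc Strand and monovalent salt concentrations
#'   (mol/L) for the nearest-neighbor Tm model.
#' @return A list of class `oligo_params`.
#' @export
oligo_params <- function(min_arm_tm = 60, min_arm_len = 15, max_arm_len = 40,
                         max_oligo_len = 90, oligo_conc = 5e-7,
                         na_conc = 1) {
  stopifnot(min_arm_len <= max_arm_len, min_arm_tm > 0, min_arm_len >= 8)
  structure(list(min_arm_tm = min_arm_tm, min_arm_len = min_arm_len,
                 max_arm_len = max_arm_len, max_oligo_len = max_oligo_len,
                 oligo_conc = oligo_conc, na_conc = na_conc),
            class = "oligo_params")
}

grow_arm <- function(reference, from, to, side, params) {
  # side "5": arm ends at position `from`-1 and grows leftward;
  # side "3": arm starts at position `to`+1 and grows rightward.
  n <- nchar(reference)
  len <- params$min_arm_len
  repeat {
    if (side == "5") {
      start <- from - len
      if (start < 1) {
        stop(sprintf(
          "5' arm runs past the CDS start (edit at nt %d, need %d nt arm)",
          from, len), call. = FALSE)
      }
      arm <- substr(reference, start, from - 1)
    } else {
      end <- to + len
      if (end > n) {
        stop(sprintf(
          "3' arm runs past the CDS end (edit ends at nt %d, need %d nt arm)",
          to, len), call. = FALSE)
      }
      arm <- substr(reference, to + 1, end)
    }
    tm <- melting_temperature(arm, params$oligo_conc, params$na_conc)
    if (tm >= params$min_arm_tm) return(list(arm = arm, tm = tm, len = len))
    len <- len + 1
    if (len > params$max_arm_len) {
      stop(sprintf(
        "%s' arm cannot reach Tm %.1f C within %d nt (edit at nt %d-%d)",
        side, params$min_arm_tm, params$max_arm_len, from, to), call. = FALSE)
    }
  }
}

#' Design a mutagenic oligo for one variant
#'
#' The oligo is `5' arm + mutant codon(s) + 3' arm` on the sense strand of
#' the supplied CDS; for a proximal double the unmodified reference sequence
#' between the two codons is carried inside the edited span. Arms grow
#' outward from `min_arm_len` until their nearest-neighbor Tm reaches
#' `min_arm_tm`.
#'
#' @param variant A variant string (`"K59Q"` or `"K59Q+I62A"`) or a one-row
#'   tibble with a `variant` column. Positions are 1-based codons of
#'   `reference_cds`.
#' @param reference_cds Character scalar, the reference coding sequence.
#' @param params An [oligo_params()] list.
#' @param usage Codon usage tibble for replacement-codon choice.
#' @return One-row tibble: `name`, `variant`, `pool` (`single`/`double`),
#'   `sequence`, `start_nt`, `end_nt` (edited span, 1-based inclusive
#'   reference coordinates), `arm5_len`, `arm3_len`, `arm5_tm`, `arm3_tm`.
#' @export
design_oligo <- function(variant, reference_cds, params = oligo_params(),
                         usage = codon_usage_table()) {
  if (is.data.frame(variant)) variant <- variant$variant[1]
  subs <- parse_variant(variant)
  if (nrow(subs) > 2) stop("at most two substitutions per oligo", call. = FALSE)
  if (anyDuplicated(subs$position) > 0) {
    stop("substitution positions must be distinct", call. = FALSE)
  }
  codons <- split_codons(reference_cds)
  if (any(subs$position > length(codons))) {
    stop("variant position outside the CDS", call. = FALSE)
  }
  ref_aa <- codon_to_aa(codons[subs$position])
  if (!all(ref_aa == subs$wt)) {
    stop(sprintf("reference mismatch: CDS encodes %s at position(s) %s",
                 paste(ref_aa, collapse = ","),
                 paste(subs$position, collapse = ",")), call. = FALSE)
  }
  new_codons <- vapply(seq_len(nrow(subs)), function(i) {
    choose_codon(subs$aa[i], codons[subs$position[i]], usage)
  }, character(1))

  cmin <- min(subs$position); cmax <- max(subs$position)
  from_nt <- 3 * cmin - 2
  to_nt <- 3 * cmax
  span <- codons[cmin:cmax]
  span[subs$position - cmin + 1] <- new_codons
  core <- paste0(span, collapse = "")

  arm5 <- grow_arm(reference_cds, from_nt, to_nt, "5", params)
  arm3 <- grow_arm(reference_cds, from_nt, to_nt, "3", params)
  oligo <- paste0(arm5$arm, core, arm3$arm)
  if (nchar(oligo) > params$max_oligo_len) {
    stop(sprintf(
      "oligo for %s is %d nt, exceeding the %d nt maximum (codons %d-%d)",
      variant, nchar(oligo), params$max_oligo_len, cmin, cmax), call. = FALSE)
  }
  tibble::tibble(name = variant, variant = variant,
                 pool = if (nrow(subs) == 2) "double" else "single",
                 sequence = oligo,
                 start_nt = from_nt, end_nt = to_nt,
                 arm5_len = arm5$len, arm3_len = arm3$len,
                 arm5_tm = arm5$tm, arm3_tm = arm3$tm)
}

#' Design the oligo pools for a whole library
#'
#' One oligo per designed single and one per *proximal* double; distal
#' doubles carry no oligo (they arise from two sequential single-oligo
#' rounds of nicking mutagenesis).
#'
#' @param design A `dsm_design`.
#' @param reference_cds Reference CDS whose codons match the design's
#'   positions and wild types.
#' @inheritParams design_oligo
#' @param pools Which pools to build: `"single"`, `"double"`, or both
#'   (default).
#' @return Tibble of oligo records (see [design_oligo()]).
#' @export
design_oligos <- function(design, reference_cds, params = oligo_params(),
                          usage = codon_usage_table(),
                          pools = c("single", "double")) {
  pools <- match.arg(pools, several.ok = TRUE)
  targets <- character(0)
  if ("single" %in% pools) {
    targets <- c(targets, enumerate_singles(design)$variant)
  }
  if ("double" %in% pools) {
    doubles <- enumerate_doubles(design)
    targets <- c(targets, doubles$variant[doubles$pool == "proximal"])
  }
  purrr::map_dfr(targets, design_oligo, reference_cds = reference_cds,
                 params = params, usage = usage)
}

#' Apply an oligo to a reference CDS in silico
#'
#' Verification oracle for oligo designs: both homology arms must occur
#' exactly once in the reference; the span between them is replaced by the
#' oligo's edited core.
#'
#' @param oligo One-row tibble from [design_oligo()] (or a list with
#'   `sequence`, `arm5_len`, `arm3_len`).
#' @param reference_cds Character scalar reference CDS.
#' @return The mutated CDS (character scalar).
#' @export
apply_oligo <- function(oligo, reference_cds) {
  if (is.data.frame(oligo)) oligo <- as.list(oligo[1, ])
  seq <- oligo$sequence
  arm5 <- substr(seq, 1, oligo$arm5_len)
  arm3 <- substr(seq, nchar(seq) - oligo$arm3_len + 1, nchar(seq))
  core <- substr(seq, oligo$arm5_len + 1, nchar(seq) - oligo$arm3_len)
  hit5 <- locate_unique(reference_cds, arm5, "5' arm")
  hit3 <- locate_unique(reference_cds, arm3, "3' arm")
  if (hit3 <= hit5) stop("arms map in the wrong order", call. = FALSE)
  paste0(substr(reference_cds, 1, hit5 + nchar(arm5) - 1),
         core,
         substr(reference_cds, hit3, nchar(reference_cds)))
}

locate_unique <- function(reference, pattern, what) {
  hits <- gregexpr(pattern, reference, fixed = TRUE)[[1]]
  if (hits[1] == -1) {
    stop(sprintf("%s not found in reference", what), call. = FALSE)
  }
  if (length(hits) > 1) {
    stop(sprintf("%s matches the reference %d times: ambiguous edit",
                 what, length(hits)), call. = FALSE)
  }
  as.integer(hits[1])
}

#' Export oligo pools as FASTA plus TSV manifests
#'
#' One FASTA and one TSV manifest per `pool` value. Pools with no members
#' are skipped with a message.
#'
#' @param oligos Oligo tibble from [design_oligos()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default `"oligos"`).
#' @return Tibble `pool`, `n`, `fasta`, `manifest`, invisibly.
#' @export
export_pools <- function(oligos, dir, prefix = "oligos") {
  stopifnot(nrow(oligos) > 0)
  if (anyDuplicated(oligos$name) > 0) {
    stop("duplicate oligo names: ",
         paste(unique(oligos$name[duplicated(oligos$name)]), collapse = ", "),
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- purrr::map_dfr(c("single", "double"), function(pool) {
    sub <- oligos[oligos$pool == pool, ]
    if (nrow(sub) == 0) {
      message("pool '", pool, "' is empty; no files written")
      return(NULL)
    }
    fasta <- file.path(dir, sprintf("%s_%s.fasta", prefix, pool))
    manifest <- file.path(dir, sprintf("%s_%s.tsv", prefix, pool))
    xs <- Biostrings::DNAStringSet(stats::setNames(sub$sequence, sub$name))
    Biostrings::writeXStringSet(xs, fasta)
    readr::write_tsv(sub, manifest)
    tibble::tibble(pool = pool, n = nrow(sub), fasta = fasta,
                   manifest = manifest)
  })
  invisible(out)
}
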