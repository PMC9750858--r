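# Seeded synthetic-data generators: toy genes and designs, amplicon reads,
# dose-response curves and blank replicates. Every generator is
# deterministic at a fixed seed and emits its ground truth.

#' Generate a random reference CDS
#'
#' A random coding sequence starting with ATG, with no internal stop codons
#' and no repeated 15-mers (so any >= 15 nt oligo homology arm maps to a
#' single site).
#'
#' @param n_codons Number of codons, >= 20.
#' @param seed Integer seed.
#' @param unique_kmer k-mer length forced unique (default 15).
#' @return List of class `synthetic_reference`: `cds`, `protein`,
#'   `n_codons`, `seed`.
#' @export
make_reference <- function(n_codons, seed, unique_kmer = 15) {
  stopifnot(n_codons >= 20)
  codons <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  codons <- setdiff(codons, "ATG") # reserve ATG for the start
  withr::with_seed(seed, {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    out <- character(n_codons)
    out[1] <- "ATG"
    prefix <- "ATG"
    for (i in seq(2, n_codons)) {
      placed <- FALSE
      for (codon in sample(codons)) {
        cand <- paste0(prefix, codon)
        kmers <- tail_kmers(cand, unique_kmer, n_new = 3)
        if (!any(vapply(kmers, function(k) !is.null(seen[[k]]),
                        logical(1)))) {
          for (k in kmers) seen[[k]] <- TRUE
          out[i] <- codon
          prefix <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not satisfy the unique k-mer constraint at codon ", i,
             call. = FALSE)
      }
    }
  })
  cds <- paste0(out, collapse = "")
  structure(list(cds = cds, protein = translate_cds(cds),
                 n_codons = n_codons, seed = seed),
            class = "synthetic_reference")
}

#' A toy design over a synthetic reference
#'
#' Picks `n_positions` spread evenly across the reference (avoiding the
#' first and last few codons so homology arms fit) and builds default
#' allele sets.
#'
#' @param reference A `synthetic_reference` (or character CDS).
#' @param n_positions Number of designed positions.
#' @param global_exclusions Passed to [build_allele_sets()].
#' @param window Proximity window (default 8).
#' @param margin Codons left untouched at each end (default 15).
#' @return A `dsm_design`.
#' @export
toy_design <- function(reference, n_positions = 5,
                       global_exclusions = c("C", "P"), window = 8,
                       margin = 15) {
  cds <- if (inherits(reference, "synthetic_reference")) reference$cds else
    reference
  protein <- translate_cds(cds)
  n <- nchar(protein)
  stopifnot(n - 2 * margin >= n_positions)
  pos <- unique(round(seq(margin + 1, n - margin,
                          length.out = n_positions)))
  wt <- strsplit(protein, "")[[1]][pos]
  build_allele_sets(tibble::tibble(position = pos, wt = wt),
                    global_exclusions = global_exclusions, window = window)
}

#' Simulate amplicon reads from a designed library
#'
#' Emits `coverage` full-length reads per designed variant (and per the
#' wild type, when `include_wt`), realized through the same codon-choice
#' rule as oligo design, with iid per-base substitution errors at
#' `error_rate`. A withheld fraction of designed variants produces zero
#' reads; the truth table records every variant's intended read count.
#'
#' @param design A `dsm_design`.
#' @param reference A `synthetic_reference` or character CDS.
#' @param coverage Reads per included variant (default 30).
#' @param error_rate Per-base substitution error probability (default 0).
#' @param withheld_fraction Fraction of designed variants (singles and
#'   doubles jointly) receiving zero reads (default 0).
#' @param seed Integer seed.
#' @param include_wt Also emit wild-type reads (default `TRUE`).
#' @param usage Codon usage for mutant codon realization.
#' @return List of class `read_simulation`: `reads` (tibble `read_id`,
#'   `sequence`, `true_variant`), `truth` (tibble `variant`, `tier`,
#'   `withheld`, `n_reads`), `seed`, `error_rate`, `coverage`.
#' @export
simulate_reads <- function(design, reference, coverage = 30,
                           error_rate = 0, withheld_fraction = 0, seed,
                           include_wt = TRUE,
                           usage = codon_usage_table()) {
  stopifnot(coverage >= 1, error_rate >= 0, error_rate <= 1,
            withheld_fraction >= 0, withheld_fraction < 1)
  cds <- if (inherits(reference, "synthetic_reference")) reference$cds else
    reference
  codons <- split_codons(cds)
  singles <- enumerate_singles(design)
  doubles <- enumerate_doubles(design)
  variants <- dplyr::bind_rows(
    tibble::tibble(variant = singles$variant, tier = "single"),
    tibble::tibble(variant = doubles$variant, tier = "double"))

  withr::with_seed(seed, {
    n_withheld <- round(withheld_fraction * nrow(variants))
    withheld_idx <- if (n_withheld > 0)
      sample(nrow(variants), n_withheld) else integer(0)
    variants$withheld <- seq_len(nrow(variants)) %in% withheld_idx
    variants$n_reads <- ifelse(variants$withheld, 0L, as.integer(coverage))

    # mutant CDS per variant via the codon-choice rule
    seqs <- purrr::map_chr(variants$variant, function(v) {
      subs <- parse_variant(v)
      cd <- codons
      for (i in seq_len(nrow(subs))) {
        cd[subs$position[i]] <- choose_codon(subs$aa[i],
                                             cd[subs$position[i]], usage)
      }
      paste0(cd, collapse = "")
    })

    src <- rep(seq_len(nrow(variants)), variants$n_reads)
    reads <- tibble::tibble(
      read_id = sprintf("read%06d", seq_along(src)),
      sequence = seqs[src],
      true_variant = variants$variant[src])
    if (include_wt) {
      wt_reads <- tibble::tibble(
        read_id = sprintf("wt%06d", seq_len(coverage)),
        sequence = cds, true_variant = "WT")
      reads <- dplyr::bind_rows(reads, wt_reads)
    }
    if (error_rate > 0 && nrow(reads) > 0) {
      reads$sequence <- add_read_errors(reads$sequence, error_rate)
    }
  })
  structure(list(reads = reads, truth = variants, seed = seed,
                 error_rate = error_rate, coverage = coverage),
            class = "read_simulation")
}

# iid per-base substitutions to a random different base
add_read_errors <- function(seqs, rate) {
  lens <- nchar(seqs)
  total <- sum(lens)
  err <- which(stats::runif(total) < rate)
  if (length(err) == 0) return(seqs)
  offsets <- cumsum(c(0, lens[-length(lens)]))
  read_of <- findInterval(err - 1, offsets)
  pos_in <- err - offsets[read_of]
  bases <- c("A", "C", "G", "T")
  for (k in seq_along(err)) {
    i <- read_of[k]; p <- pos_in[k]
    old <- substr(seqs[i], p, p)
    new <- sample(setdiff(bases, old), 1)
    substr(seqs[i], p, p) <- new
  }
  seqs
}

#' Write simulated reads as FASTQ
#'
#' Constant quality (`I` = Q40); the seed and error rate are echoed in a
#' header comment on each read id line.
#'
#' @param sim A `read_simulation`.
#' @param path Output path (plain or `.gz`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sim, path) {
  meta <- sprintf("seed=%d error_rate=%g", sim$seed, sim$error_rate)
  con <- file(path, "w")
  on.exit(close(con))
  qual <- vapply(nchar(sim$reads$sequence),
                 function(n) strrep("I", n), character(1))
  writeLines(paste0("@", sim$reads$read_id, " ", meta, "\n",
                    sim$reads$sequence, "\n+\n", qual), con)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ path (plain or `.gz`).
#' @return Tibble `read_id`, `sequence`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(read_id = sub(" .*", "", names(x)),
                 sequence = unname(as.character(x)))
}

#' Write a reference as FASTA
#'
#' @param reference A `synthetic_reference` or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  if (inherits(reference, "synthetic_reference")) {
    x <- stats::setNames(reference$cds,
                         sprintf("synthetic_reference seed=%d",
                                 reference$seed))
  } else {
    x <- reference
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' Simulate a 4PL dose-response table
#'
#' Responses are the four-parameter logistic curve plus iid Gaussian noise;
#' the generating parameters are recorded as attributes for recovery
#' studies.
#'
#' @param ec50 True EC50 (same units as `concentrations`).
#' @param hill,bottom,top Remaining 4PL truth (defaults 1, 0, 1).
#' @param concentrations Positive, sorted concentration grid (default 8
#'   half-log steps around 5e-8).
#' @param noise_sd Gaussian noise SD in response units; the conventional
#'   "5% noise" on a 0-1 curve is `noise_sd = 0.05` (default).
#' @param replicates Technical replicates per concentration (default 3).
#' @param seed Integer seed.
#' @return Tibble `concentration`, `replicate`, `response`, with attribute
#'   `truth` (named list of the generating parameters and seed).
#' @export
simulate_curve <- function(ec50, hill = 1, bottom = 0, top = 1,
                           concentrations = 10^seq(-9, -5.5, 0.5),
                           noise_sd = 0.05, replicates = 3, seed) {
  stopifnot(all(concentrations > 0), !is.unsorted(concentrations))
  grid <- tidyr::expand_grid(concentration = concentrations,
                             replicate = seq_len(replicates))
  mu <- fourpl(grid$concentration, bottom, top, log10(ec50), hill)
  withr::with_seed(seed, {
    grid$response <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
  })
  attr(grid, "truth") <- list(ec50 = ec50, hill = hill, bottom = bottom,
                              top = top, noise_sd = noise_sd, seed = seed)
  grid
}

#' Simulate blank-replicate responses
#'
#' @param n Number of blank wells.
#' @param mean,sd Blank distribution parameters.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_blanks <- function(n, mean = 0.05, sd = 0.01, seed) {
  withr::with_seed(seed, stats::rnorm(n, mean, sd))
}
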