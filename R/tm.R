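# Nearest-neighbor duplex melting temperature (unified NN parameter set,
# SantaLucia 1998), used to size oligo homology arms.

# dH in kcal/mol, dS in cal/(mol K), 5'->3' dimers; complements share values.
nn_params <- local({
  dimers <- c("AA", "AT", "TA", "CA", "GT", "CT", "GA", "CG", "GC", "GG")
  dH <- c(-7.9, -7.2, -7.2, -8.5, -8.4, -7.8, -8.2, -10.6, -9.8, -8.0)
  dS <- c(-22.2, -20.4, -21.3, -22.7, -22.4, -21.0, -22.2, -27.2, -24.4, -19.9)
  comp <- function(x) chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]),
                                                   collapse = ""))
  all_dimers <- c(dimers, vapply(dimers, comp, character(1)))
  list(dH = stats::setNames(c(dH, dH), all_dimers)[unique(all_dimers)],
       dS = stats::setNames(c(dS, dS), all_dimers)[unique(all_dimers)])
})

#' Nearest-neighbor melting temperature
#'
#' Duplex Tm from unified nearest-neighbor thermodynamics with terminal
#' initiation corrections, an entropic monovalent-salt correction of
#' `0.368 * (N - 1) * ln([Na+])`, and the strand-concentration term
#' `R * ln(CT / 4)` for non-self-complementary duplexes with both strands at
#' equal concentration.
#'
#' @param seq Nucleotide sequence (ACGT only, length >= 8).
#' @param oligo_conc Total strand concentration CT in mol/L (default 5e-7,
#'   i.e. 0.5 uM).
#' @param na_conc Monovalent cation concentration in mol/L (default 1, the
#'   standard state of the nearest-neighbor tables).
#' @return Tm in degrees Celsius.
#' @export
melting_temperature <- function(seq, oligo_conc = 5e-7, na_conc = 1) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  if (nchar(seq) < 8) {
    stop("sequence shorter than 8 nt: nearest-neighbor Tm is not meaningful",
         call. = FALSE)
  }
  if (grepl("[^ACGT]", seq)) {
    stop("sequence contains non-ACGT characters", call. = FALSE)
  }
  n <- nchar(seq)
  dimers <- substring(seq, seq_len(n - 1), seq_len(n - 1) + 1)
  dH <- sum(nn_params$dH[dimers])
  dS <- sum(nn_params$dS[dimers])
  for (term in c(substr(seq, 1, 1), substr(seq, n, n))) {
    if (term %in% c("G", "C")) {
      dH <- dH + 0.1; dS <- dS - 2.8
    } else {
      dH <- dH + 2.3; dS <- dS + 4.1
    }
  }
  dS <- dS + 0.368 * (n - 1) * log(na_conc)
  tm_k <- dH * 1000 / (dS + 1.987 * log(oligo_conc / 4))
  tm_k - 273.15
}
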