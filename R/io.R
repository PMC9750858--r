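# Readers for tidy dose-response tables (CSV) and source-data workbooks
# (XLSX, via readxl when available).

#' Read a tidy dose-response table
#'
#' Expected columns (case-insensitive, extras kept): `receptor`, `ligand`,
#' `concentration`, `response`, and optionally `matrix`, `unit`,
#' `replicate`. CSV by default; `.xlsx` files are read with readxl using
#' an optional sheet name.
#'
#' @param path CSV or XLSX path.
#' @param sheet Sheet name or index for workbooks.
#' @param col_map Optional named character vector renaming source columns
#'   to the expected names, e.g. `c(conc_nM = "concentration")`.
#' @return Tibble with at least `concentration` and `response`.
#' @export
read_dose_response <- function(path, sheet = NULL, col_map = NULL) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading workbooks requires the readxl package", call. = FALSE)
    }
    tab <- readxl::read_excel(path, sheet = sheet)
  } else {
    tab <- readr::read_csv(path, show_col_types = FALSE)
  }
  names(tab) <- tolower(names(tab))
  if (!is.null(col_map)) {
    for (from in names(col_map)) {
      names(tab)[names(tab) == tolower(from)] <- col_map[[from]]
    }
  }
  need <- c("concentration", "response")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("dose-response table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(tab)
}

#' Read a per-position allele table
#'
#' TSV with header `position`, `wt`, `aa` (one row per allowed
#' substitution) and optionally `ddg`.
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_allele_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("position", "wt", "aa") %in% names(tab)))
  tab
}

#' Build a design directly from an allele table
#'
#' Groups an allele table into per-position sets and validates them as a
#' `dsm_design` via explicit overrides.
#'
#' @param alleles Tibble `position`, `wt`, `aa` (see
#'   [read_allele_table()]).
#' @param window Proximity window (default 8).
#' @return A `dsm_design`.
#' @export
design_from_allele_table <- function(alleles, window = 8) {
  pos <- dplyr::distinct(alleles[c("position", "wt")])
  pos <- dplyr::arrange(pos, .data$position)
  sets <- split(alleles$aa, alleles$position)
  build_allele_sets(pos, global_exclusions = character(0),
                    overrides = sets[as.character(pos$position)],
                    window = window)
}
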