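# Cross-reactivity / selectivity matrices from per-(receptor, ligand) EC50
# estimates, with censored "> max tested" entries.

#' Fold-selectivity matrix across receptors and ligands
#'
#' For each receptor, fold-selectivity of an off-target ligand is
#' `EC50_off / EC50_on` against the receptor's declared on-target ligand.
#' Censored off-target entries (no response up to the highest tested
#' concentration) propagate as lower bounds `> bound / EC50_on`. A receptor
#' is classified *selective* when every off-target fold (or bound) is at
#' least `fold_threshold` (default 10).
#'
#' @param fits Data frame with columns `receptor`, `ligand`, `ec50`
#'   (numeric; for censored rows the highest tested concentration), and
#'   optionally `censored` (logical, default `FALSE`).
#' @param on_target Named character vector mapping receptor to its
#'   on-target ligand.
#' @param fold_threshold Minimum fold for the selective classification
#'   (default 10).
#' @return Object of class `selectivity_matrix`: list with `folds` (tibble
#'   `receptor`, `ligand`, `ec50`, `censored`, `on_target`, `fold`,
#'   `fold_label`) and `classification` (tibble `receptor`, `min_fold`,
#'   `selective`).
#' @examples
#' fits <- data.frame(receptor = "R1", ligand = c("diazinon", "azinphos"),
#'                    ec50 = c(43e-9, 1.1e-6))
#' selectivity_matrix(fits, c(R1 = "diazinon"))$classification
#' @export
selectivity_matrix <- function(fits, on_target, fold_threshold = 10) {
  fits <- tibble::as_tibble(fits)
  stopifnot(all(c("receptor", "ligand", "ec50") %in% names(fits)))
  if (!"censored" %in% names(fits)) fits$censored <- FALSE
  stopifnot(all(fits$ec50 > 0))
  receptors <- unique(fits$receptor)
  missing_on <- setdiff(receptors, names(on_target))
  if (length(missing_on) > 0) {
    stop("no on-target ligand declared for receptor(s): ",
         paste(missing_on, collapse = ", "), call. = FALSE)
  }

  folds <- purrr::map_dfr(receptors, function(r) {
    sub <- fits[fits$receptor == r, ]
    on <- sub[sub$ligand == on_target[[r]], ]
    if (nrow(on) != 1 || on$censored) {
      stop(sprintf("receptor %s lacks a finite on-target EC50", r),
           call. = FALSE)
    }
    dplyr::mutate(sub,
      on_target = .data$ligand == on_target[[r]],
      fold = .data$ec50 / on$ec50,
      fold_label = dplyr::if_else(.data$censored,
                                  sprintf("> %.3g", .data$fold),
                                  sprintf("%.3g", .data$fold)))
  })
  classification <- dplyr::summarise(
    dplyr::group_by(folds[!folds$on_target, ], .data$receptor),
    min_fold = min(.data$fold),
    selective = all(.data$fold >= fold_threshold))
  structure(list(folds = folds, classification = classification,
                 fold_threshold = fold_threshold),
            class = "selectivity_matrix")
}

#' @export
print.selectivity_matrix <- function(x, ...) {
  cat(sprintf("<selectivity_matrix> %d receptors x %d ligands (threshold %gx)\n",
              length(unique(x$folds$receptor)),
              length(unique(x$folds$ligand)), x$fold_threshold))
  print(x$classification)
  invisible(x)
}

#' @rdname selectivity_matrix
#' @param x A `selectivity_matrix`.
#' @param ... Unused.
#' @method tidy selectivity_matrix
#' @export
tidy.selectivity_matrix <- function(x, ...) x$folds

#' @rdname selectivity_matrix
#' @method glance selectivity_matrix
#' @export
glance.selectivity_matrix <- function(x, ...) x$classification

#' Heatmap of fold-selectivities
#'
#' @param object A `selectivity_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot selectivity_matrix
#' @export
autoplot.selectivity_matrix <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(.data$ligand, .data$receptor,
                               fill = log10(.data$fold))) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$fold_label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "log10 fold") +
    ggplot2::theme_minimal()
}

#' Write a selectivity matrix as TSV
#'
#' @param x A `selectivity_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selectivity <- function(x, path) {
  readr::write_tsv(x$folds, path)
  invisible(path)
}
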