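# Ligand-panel chemical similarity: atom-pair fingerprints, Tanimoto
# matrix, agglomerative clustering with deterministic leaf order.

#' Read a SMILES panel file
#'
#' `.smi` format: one molecule per line, `SMILES<whitespace>id`.
#'
#' @param path Path to the file.
#' @return Tibble `id`, `smiles`.
#' @export
read_smiles <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- stringr::str_split_fixed(trimws(lines), "\\s+", 2)
  if (any(parts[, 2] == "")) {
    stop("every .smi line needs 'SMILES id'", call. = FALSE)
  }
  tibble::tibble(id = parts[, 2], smiles = parts[, 1])
}

#' Compute fingerprints for a ligand panel
#'
#' Default scheme `"atompair"`: sparse atom-pair descriptor sets (the
#' descriptor family behind ChemMine-style small-molecule clustering).
#' Scheme `"apfp1024"` folds the same descriptors into a fixed 1024-bit
#' bitset. The scheme id is recorded on the result since different
#' descriptor settings give different similarity values.
#'
#' @param panel Tibble `id`, `smiles` (see [read_smiles()]), or a named
#'   character vector of SMILES.
#' @param scheme `"atompair"` (sparse sets, default) or `"apfp1024"`.
#' @return A `fingerprint_set`: tibble `id`, `features` (list-column of
#'   sorted unique feature codes), with attributes `scheme` and `nbits`
#'   (`NA` for sparse sets).
#' @export
fingerprint_panel <- function(panel, scheme = c("atompair", "apfp1024")) {
  scheme <- match.arg(scheme)
  if (is.character(panel)) {
    panel <- tibble::tibble(id = names(panel), smiles = unname(panel))
  }
  stopifnot(all(c("id", "smiles") %in% names(panel)),
            !anyDuplicated(panel$id))
  smis <- stats::setNames(panel$smiles, panel$id)
  parsed <- purrr::imap(smis, function(s, id) {
    tryCatch(suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(s, id))),
             error = function(e) NULL)
  })
  bad <- names(parsed)[purrr::map_lgl(parsed, is.null)]
  if (length(bad) > 0) {
    stop("unparseable SMILES for ligand(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  aps <- purrr::map(parsed, function(sdf) {
    ap <- ChemmineR::sdf2ap(sdf[[1]])
    sort(unique(ap@AP))
  })
  nbits <- NA_integer_
  if (scheme == "apfp1024") {
    nbits <- 1024L
    aps <- purrr::map(aps, function(d) sort(unique(as.integer(d %% 1024))))
  }
  structure(tibble::tibble(id = panel$id, features = unname(aps)),
            class = c("fingerprint_set", "tbl_df", "tbl", "data.frame"),
            scheme = scheme, nbits = nbits)
}

#' Tanimoto coefficient of two fingerprints
#'
#' `|A intersect B| / |A union B|` over fingerprint features. Accepts
#' either two 0/1 bit vectors of equal length or two sparse feature sets
#' (vectors of feature codes). Two empty fingerprints compare as 1 with a
#' warning.
#'
#' @param a,b Fingerprints: equal-length 0/1 (or logical) vectors, or
#'   sparse feature-code vectors with `sparse = TRUE`.
#' @param sparse Treat `a` and `b` as sparse feature sets (default: decide
#'   from content — vectors containing values other than 0/1 are sparse).
#' @return Tanimoto coefficient in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 1, 0, 1, 1, 0, 0), c(1, 0, 1, 1, 0, 0, 0)) # 0.4
#' @export
tanimoto <- function(a, b, sparse = NULL) {
  if (is.null(sparse)) {
    sparse <- !(all(a %in% c(0, 1)) && all(b %in% c(0, 1)))
  }
  if (sparse) {
    a <- unique(a); b <- unique(b)
    ni <- length(intersect(a, b))
    nu <- length(union(a, b))
  } else {
    if (length(a) != length(b)) {
      stop("fingerprint lengths differ: ", length(a), " vs ", length(b),
           call. = FALSE)
    }
    a <- as.logical(a); b <- as.logical(b)
    ni <- sum(a & b)
    nu <- sum(a | b)
  }
  if (nu == 0) {
    warning("both fingerprints empty; Tanimoto defined as 1", call. = FALSE)
    return(1)
  }
  ni / nu
}

#' Pairwise Tanimoto similarity matrix for a ligand panel
#'
#' @param panel A `fingerprint_set` (from [fingerprint_panel()]), a tibble
#'   `id`, `smiles`, or a named character vector of SMILES.
#' @param scheme Fingerprint scheme, passed to [fingerprint_panel()] when
#'   `panel` is not already a `fingerprint_set`.
#' @return A `similarity_matrix`: square numeric matrix with ligand ids as
#'   dimnames, unit diagonal, attribute `scheme`.
#' @export
similarity_matrix <- function(panel, scheme = "atompair") {
  fps <- if (inherits(panel, "fingerprint_set")) panel else
    fingerprint_panel(panel, scheme)
  n <- nrow(fps)
  m <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        m[i, j] <- m[j, i] <- tanimoto(fps$features[[i]], fps$features[[j]],
                                       sparse = TRUE)
      }
    }
  }
  dimnames(m) <- list(fps$id, fps$id)
  structure(m, class = c("similarity_matrix", "matrix", "array"),
            scheme = attr(fps, "scheme"))
}

#' @rdname similarity_matrix
#' @param x A `similarity_matrix`.
#' @param ... Unused.
#' @method tidy similarity_matrix
#' @export
tidy.similarity_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble::as_tibble(as.data.frame.table(m, responseName = "tanimoto",
                                        stringsAsFactors = FALSE)) |>
    stats::setNames(c("ligand1", "ligand2", "tanimoto"))
}

#' Cluster a ligand panel by Tanimoto distance
#'
#' Agglomerative clustering on distance `1 - T` (average linkage by
#' default). Ligands are pre-sorted lexicographically by id before
#' clustering so the result is invariant to input order, with ties broken
#' by id.
#'
#' @param sim A `similarity_matrix`.
#' @param method Linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return A `panel_clustering`: list with `hclust`, `leaf_order`
#'   (character), `distance` (the `dist` used), `method`.
#' @export
cluster_panel <- function(sim, method = "average") {
  stopifnot(inherits(sim, "similarity_matrix"))
  ids <- sort(rownames(sim))
  m <- unclass(sim)[ids, ids, drop = FALSE]
  d <- stats::as.dist(1 - m)
  hc <- stats::hclust(d, method = method)
  structure(list(hclust = hc, leaf_order = hc$labels[hc$order],
                 distance = d, method = method),
            class = "panel_clustering")
}

#' @export
print.panel_clustering <- function(x, ...) {
  cat(sprintf("<panel_clustering> %d ligands, %s linkage\n",
              length(x$leaf_order), x$method))
  cat("leaf order:", paste(x$leaf_order, collapse = ", "), "\n")
  invisible(x)
}

#' Export a panel clustering as a Newick tree
#'
#' @param clustering A `panel_clustering`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(clustering, path) {
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  invisible(path)
}

#' Similarity heatmap for a ligand panel
#'
#' Tiles ordered by the clustering leaf order.
#'
#' @param object A `similarity_matrix`.
#' @param clustering Optional `panel_clustering` providing the ordering.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot similarity_matrix
#' @export
autoplot.similarity_matrix <- function(object, clustering = NULL, ...) {
  ord <- if (is.null(clustering)) rownames(object) else clustering$leaf_order
  tbl <- tidy.similarity_matrix(object)
  tbl$ligand1 <- factor(tbl$ligand1, levels = ord)
  tbl$ligand2 <- factor(tbl$ligand2, levels = ord)
  ggplot2::ggplot(tbl, ggplot2::aes(.data$ligand1, .data$ligand2,
                                    fill = .data$tanimoto)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#f7fbff", high = "#08306b",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Tanimoto") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
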