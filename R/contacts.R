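# Contact-based proposal of candidate positions from a receptor-ligand
# complex structure.

#' Protein residues in close contact with a bound ligand
#'
#' Returns every protein residue with at least one heavy atom within
#' `cutoff` angstroms of any heavy atom of the named ligand het group.
#' This reproduces the structure-guided step that proposes binding-pocket
#' positions for saturation mutagenesis (for PYR1, the residues contacting
#' abscisic acid in the receptor-ligand-phosphatase complex).
#'
#' Hydrogens are ignored and only alternate location `A` (or blank) atoms
#' are used. The result is independent of atom order.
#'
#' @param structure Path to a PDB or mmCIF file, or a `bio3d` `pdb` object.
#' @param ligand Three-letter het code of the ligand (e.g. `"ABA"`).
#' @param cutoff Heavy-atom distance cutoff in angstroms (inclusive).
#'   Default 4.5.
#' @param chain Optional protein chain filter (character vector).
#' @param ligand_chain Optional ligand chain filter.
#' @param offset Integer added to structure author residue numbers to map
#'   them onto reference protein numbering (default 0).
#' @return Sorted integer vector of residue indices (reference numbering).
#' @export
contact_positions <- function(structure, ligand, cutoff = 4.5,
                              chain = NULL, ligand_chain = NULL,
                              offset = 0L) {
  stopifnot(is.numeric(cutoff), cutoff > 0)
  pdb <- read_structure(structure)
  atoms <- pdb$atom
  # drop hydrogens and non-primary altlocs
  elem <- atoms$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(gsub("[0-9]", "", atoms$elety), 1, 1)
  }
  keep <- toupper(elem) != "H" & (is.na(atoms$alt) | atoms$alt %in% c("", "A"))
  atoms <- atoms[keep, , drop = FALSE]

  is_lig <- atoms$resid == ligand
  if (!is.null(ligand_chain)) is_lig <- is_lig & atoms$chain %in% ligand_chain
  if (!any(is_lig)) {
    stop(sprintf("ligand not found: no '%s' het group in structure", ligand),
         call. = FALSE)
  }
  is_prot <- atoms$type == "ATOM"
  if (!is.null(chain)) is_prot <- is_prot & atoms$chain %in% chain
  if (!any(is_prot)) stop("structure contains no protein atoms", call. = FALSE)

  lig_xyz <- as.matrix(atoms[is_lig, c("x", "y", "z")])
  prot <- atoms[is_prot, , drop = FALSE]
  prot_xyz <- as.matrix(prot[, c("x", "y", "z")])

  # all-pairs distances protein x ligand; modest sizes, do it densely
  d2 <- outer(rowSums(prot_xyz^2), rowSums(lig_xyz^2), "+") -
    2 * tcrossprod(prot_xyz, lig_xyz)
  near <- apply(d2 <= cutoff^2 + 1e-9, 1, any)
  sort(unique(as.integer(prot$resno[near]))) + as.integer(offset)
}

read_structure <- function(structure) {
  if (inherits(structure, "pdb")) return(structure)
  stopifnot(is.character(structure), length(structure) == 1)
  if (!file.exists(structure)) {
    stop("structure file not found: ", structure, call. = FALSE)
  }
  reader <- if (grepl("\\.cif$", structure, ignore.case = TRUE)) {
    bio3d::read.cif
  } else {
    bio3d::read.pdb
  }
  tryCatch(suppressWarnings(reader(structure)),
           error = function(e) {
             stop("failed to parse structure file: ", conditionMessage(e),
                  call. = FALSE)
           })
}
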