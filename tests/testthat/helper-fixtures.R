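# Shared fixtures, all generated in code.

# small design with explicit allele sets (sizes under full control)
tiny_design <- function(positions, wt, sets, window = 8) {
  overrides <- stats::setNames(sets, as.character(positions))
  build_allele_sets(data.frame(position = positions, wt = wt),
                    overrides = overrides, window = window)
}

# brute-force enumeration oracle: all singles and all position-pair doubles
# straight from expand.grid, independent of the package's enumeration code
brute_force_variants <- function(positions, sets) {
  singles <- do.call(rbind, lapply(seq_along(positions), function(i) {
    if (length(sets[[i]]) == 0) return(NULL)
    data.frame(position = positions[i], aa = sets[[i]])
  }))
  doubles <- NULL
  if (length(positions) >= 2) {
    idx <- utils::combn(seq_along(positions), 2)
    doubles <- do.call(rbind, lapply(seq_len(ncol(idx)), function(k) {
      i <- idx[1, k]; j <- idx[2, k]
      if (length(sets[[i]]) == 0 || length(sets[[j]]) == 0) return(NULL)
      g <- expand.grid(aa1 = sets[[i]], aa2 = sets[[j]],
                       stringsAsFactors = FALSE)
      data.frame(p1 = positions[i], aa1 = g$aa1,
                 p2 = positions[j], aa2 = g$aa2)
    }))
  }
  list(singles = singles, doubles = doubles)
}

# minimal PDB text with protein CA/CB atoms and a ligand het group at
# chosen coordinates
write_tiny_pdb <- function(path, protein, ligand, ligand_code = "LIG") {
  # protein: data.frame(resno, x, y, z); ligand: data.frame(x, y, z)
  fmt <- function(rec, serial, name, resn, chain, resno, x, y, z, elem) {
    sprintf(
      "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, serial, name, "", resn, chain, resno, "", x, y, z, 1, 0, elem)
  }
  lines <- character(0)
  serial <- 1
  for (i in seq_len(nrow(protein))) {
    lines <- c(lines, fmt("ATOM", serial, " CA", "ALA", "A",
                          protein$resno[i], protein$x[i], protein$y[i],
                          protein$z[i], "C"))
    serial <- serial + 1
  }
  for (i in seq_len(nrow(ligand))) {
    lines <- c(lines, fmt("HETATM", serial, " C1", ligand_code, "B",
                          900, ligand$x[i], ligand$y[i], ligand$z[i], "C"))
    serial <- serial + 1
  }
  writeLines(c(lines, "END"), path)
  path
}

# noiseless 4PL responses
fourpl_truth <- function(x, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (ec50 / x)^hill)
}
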