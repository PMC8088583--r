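# Small in-code fixtures shared across test files.

toy_atoms <- function(m, resno = rep(1L, m), name = rep("CA", m),
                      element = rep("C", m), hydrogen = rep(FALSE, m)) {
  data.frame(serial = seq_len(m), atom_name = name, residue_name = "GLY",
             residue_number = resno, chain_id = "A", element = element,
             is_hydrogen = hydrogen, stringsAsFactors = FALSE)
}

toy_ensemble <- function(X, m = nrow(X) / 3, aligned = TRUE, ...) {
  coord_ensemble(toy_atoms(m, ...), X, aligned = aligned)
}

# A 20-atom single residue: 10 heavy (incl. the 4 backbone atoms N, CA, C, O)
# and 10 hydrogens.
twenty_atom_residue <- function(n = 5L, seed = 1L) {
  set.seed(seed)
  nm <- c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ", "OXT",
          paste0("H", 1:10))
  el <- c("N", "C", "C", "O", "C", "C", "C", "C", "N", "O", rep("H", 10))
  atoms <- data.frame(serial = 1:20, atom_name = nm, residue_name = "LYS",
                      residue_number = 1L, chain_id = "A", element = el,
                      is_hydrogen = el == "H", stringsAsFactors = FALSE)
  coord_ensemble(atoms, matrix(rnorm(60 * n), 60, n), aligned = TRUE)
}

# Write one minimal PDB file (fixed columns) for parser-facing tests that
# need content bio3d did not itself produce.
write_raw_pdb <- function(path, lines) writeLines(lines, path)

# wwPDB v3.3 fixed columns: serial 7-11, name 13-16, altLoc 17, resName
# 18-20, chain 22, resSeq 23-26, iCode 27, x/y/z 31-54, occ 55-60, B 61-66,
# element 77-78.
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          record = "ATOM", element = "C", altloc = " ") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altloc, resname, chain, resno, x, y, z,
          1, 0, element)
}
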