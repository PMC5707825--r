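# Shared fixture builders for the test suite. Everything is generated in
# code; no binary or downloaded data.

# A small two-residue PDB text with one water, used by parser tests.
tiny_pdb_text <- function() {
  h <- make_helix(3)
  lines <- write_pdb(h)
  c(lines[!grepl("^(TER|END)", lines)][1:10],  # residues 1-2 (5 atoms each)
    "HETATM   99  O   HOH A 301      20.000  20.000  20.000  1.00  0.00           O",
    "TER", "END")
}

# Coordinates of a named atom in a structure.
atom_xyz <- function(structure, resno, name, chain = "A") {
  at <- structure$atoms
  row <- at[at$resno == resno & at$name == name & at$chain == chain, ]
  as.numeric(row[1, c("x", "y", "z")])
}

# A single free-standing atom as a one-row atom table (for pair_overlap).
free_atom <- function(name, element, xyz, resname = "LIG", vdw = NULL) {
  row <- data.frame(serial = 1L, name = name, altloc = "", resname = resname,
                    chain = "A", resno = 1L, icode = "",
                    x = xyz[1], y = xyz[2], z = xyz[3], occ = 1,
                    element = element, hetero = FALSE,
                    stringsAsFactors = FALSE)
  row$vdw <- if (is.null(vdw)) rotaclash:::radius_for(element) else vdw
  row
}

# Canonical signature of a clash table, for set comparisons.
clash_signature <- function(clashes) {
  if (!nrow(clashes)) return("")
  paste(sort(sprintf("%s>%s:%d:%s@%.6f", clashes$atom, clashes$partner_chain,
                     clashes$partner_resno, clashes$partner_atom,
                     clashes$overlap_A)), collapse = ";")
}
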