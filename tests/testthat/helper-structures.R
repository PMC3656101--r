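## write an atom table (readStructure layout) as a minimal mmCIF file,
## independent of the package's readers
writeMmcifFixture <- function(atoms, path) {
  rows <- sprintf("%s %d %s %s %s %s %s %d %s %.3f %.3f %.3f %.2f 1",
                  atoms$type, atoms$eleno, atoms$elesy, atoms$elety,
                  ifelse(nzchar(atoms$alt), atoms$alt, "."), atoms$resid,
                  atoms$chain, atoms$resno,
                  ifelse(nzchar(atoms$insert), atoms$insert, "?"),
                  atoms$x, atoms$y, atoms$z, atoms$o)
  writeLines(c("data_toy", "#", "loop_",
               "_atom_site.group_PDB", "_atom_site.id",
               "_atom_site.type_symbol", "_atom_site.label_atom_id",
               "_atom_site.label_alt_id", "_atom_site.label_comp_id",
               "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
               "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
               "_atom_site.Cartn_y", "_atom_site.Cartn_z",
               "_atom_site.occupancy", "_atom_site.pdbx_PDB_model_num",
               rows, "#"), path)
  invisible(path)
}

## toy PDB written to a temp file, returning the path
toyFile <- function(chains, contacts = NULL) {
  path <- tempfile(fileext = ".pdb")
  toyStructurePDB(chains, contacts, path = path)
  path
}

residueNumbers <- function(interface, side = c("a", "b")) {
  side <- match.arg(side)
  if (side == "a") sort(interface@residues_a$resno)
  else sort(interface@residues_b$resno)
}
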