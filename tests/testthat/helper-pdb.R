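# hand-rolled ATOM lines for parser tests (wwPDB v3.30 fixed columns)
pdb_line <- function(serial, name, resn, chain, resno, x, y, z,
                     b = 0, o = 1, alt = "", icode = "",
                     element = substr(name, 1, 1), record = "ATOM") {
  fmt_name <- if (nchar(name) >= 4) name else sprintf(" %-3s", name)
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, fmt_name, substr(paste0(alt, " "), 1, 1), resn,
          chain, resno, substr(paste0(icode, " "), 1, 1), x, y, z, o, b,
          element)
}

# one backbone-only residue (4 atoms) at an offset
pdb_residue <- function(resn, chain, resno, serial0 = 1, dx = 0, b = 0) {
  c(pdb_line(serial0,     "N",  resn, chain, resno, dx + 0.0, 0.8, 0.0, b),
    pdb_line(serial0 + 1, "CA", resn, chain, resno, dx + 1.2, 0.0, 0.0, b),
    pdb_line(serial0 + 2, "C",  resn, chain, resno, dx + 2.5, 0.8, 0.0, b),
    pdb_line(serial0 + 3, "O",  resn, chain, resno, dx + 3.6, 0.3, 0.0, b))
}

gly_pdb_text <- function() paste(pdb_residue("GLY", "A", 1), collapse = "\n")

# three backbone-only glycines with chosen B-factors, 5 A apart
tri_gly_pdb_text <- function(b = c(90, 60, 90)) {
  paste(c(pdb_residue("GLY", "A", 1, 1, 0, b[1]),
          pdb_residue("GLY", "A", 2, 5, 5, b[2]),
          pdb_residue("GLY", "A", 3, 9, 10, b[3])), collapse = "\n")
}
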