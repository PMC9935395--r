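# Fixture builders used across test files. Everything is generated in code;
# no binary data ships with the package.

# a minimal hand-written PDB: one chain, two Calpha-only residues
two_residue_pdb <- function(path = tempfile(fileext = ".pdb"), b = 85.30) {
  writeLines(c(
    sprintf("ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00%6.2f           C", b),
    sprintf("ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00%6.2f           C", b),
    "END"), path)
  path
}

# random two-chain blob with CA (+CB) atoms; chains overlap enough to have
# interfaces at typical cutoffs
random_two_chain <- function(seed, n_res = 8, atoms_per_res = 2, spread = 12) {
  set.seed(seed)
  mk <- function(ch, offset) {
    n <- n_res * atoms_per_res
    tibble::tibble(
      chain = ch,
      resno = rep(seq_len(n_res), each = atoms_per_res), insert = "",
      resid = "GLY",
      elety = rep(c("CA", "CB")[seq_len(atoms_per_res)], n_res),
      element = "C",
      x = rnorm(n, offset, spread / 2), y = rnorm(n, 0, spread / 2),
      z = rnorm(n, 0, spread / 2), b = 80, plddt = 80)
  }
  complexforge:::new_structure("rand", dplyr::bind_rows(mk("A", 0), mk("B", spread)))
}

# structure with chain A = 1 CA at origin and chain B = n_close CAs at 5 A
# plus n_far CAs far away: exactly n_close Calpha pairs under 8 A
counted_contact_structure <- function(n_close, n_far = 5) {
  mk_row <- function(ch, i, x) tibble::tibble(
    chain = ch, resno = i, insert = "", resid = "GLY", elety = "CA",
    element = "C", x = x, y = 0.01 * i, z = 0, b = 90, plddt = 90)
  at <- dplyr::bind_rows(
    mk_row("A", 1, 0),
    dplyr::bind_rows(lapply(seq_len(n_close), function(i) mk_row("B", i, 5))),
    dplyr::bind_rows(lapply(seq_len(n_far), function(i) mk_row("B", n_close + i, 50))))
  complexforge:::new_structure("contacts", at)
}
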