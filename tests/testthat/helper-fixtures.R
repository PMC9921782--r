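# Fixture builders: tiny structure files and molecule tables generated in
# code at test time.

write_fixture <- function(lines, ext, dir = withr::local_tempdir(.local_envir = parent.frame()),
                          stem = "mol") {
  path <- file.path(dir, paste0(stem, ".", ext))
  writeLines(lines, path)
  path
}

sdf_methane_lines <- function(title = "methane") {
  c(title,
    "  fixture",
    "",
    "  5  4  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.6300    0.6300    0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.6300   -0.6300    0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.6300    0.6300   -0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.6300   -0.6300   -0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0",
    "  1  3  1  0",
    "  1  4  1  0",
    "  1  5  1  0",
    "M  END",
    "$$$$")
}

pdb_water_lines <- function() {
  c("HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "HETATM    2  H1  HOH A   1       0.960   0.000   0.000  1.00  0.00           H",
    "HETATM    3  H2  HOH A   1      -0.240   0.930   0.000  1.00  0.00           H",
    "END")
}

# water PDB with blank element columns, forcing the atom-name fallback
pdb_noelem_lines <- function(names = c("O", "H1", "H2")) {
  vapply(seq_along(names), function(i) {
    sprintf("HETATM%5d %-4s HOH A   1     %7.3f %7.3f %7.3f  1.00  0.00",
            i, names[i], i * 0.5, 0, 0)
  }, character(1))
}

mol2_chloromethane_lines <- function() {
  c("@<TRIPOS>MOLECULE",
    "chloromethane",
    " 5 4 1",
    "SMALL",
    "USER_CHARGES",
    "@<TRIPOS>ATOM",
    "      1 C1          0.0000    0.0000    0.0000 C.3     1 LIG         0.0000",
    "      2 H1          0.6300    0.6300    0.6300 H       1 LIG         0.0000",
    "      3 H2         -0.6300   -0.6300    0.6300 H       1 LIG         0.0000",
    "      4 H3         -0.6300    0.6300   -0.6300 H       1 LIG         0.0000",
    "      5 Cl1         1.0000   -1.0000   -1.0000 Cl      1 LIG         0.0000",
    "@<TRIPOS>BOND",
    "     1 1 2 1",
    "     2 1 3 1",
    "     3 1 4 1",
    "     4 1 5 1")
}

prmtop_methane_lines <- function(with_atomic_number = TRUE) {
  lines <- c(
    "%VERSION  VERSION_STAMP = V0001.000  DATE = 01/01/20  00:00:00",
    "%FLAG TITLE",
    "%FORMAT(20a4)",
    "methane",
    "%FLAG POINTERS",
    "%FORMAT(10I8)",
    "       5       1       4       0       0       0       0       0       0       0",
    "       0       1       0       0       0       0       0       0       0       0",
    "       0       0       0       0       0       0       0       0       0       0",
    "       0",
    "%FLAG ATOM_NAME",
    "%FORMAT(20a4)",
    "C1  H1  H2  H3  H4")
  if (with_atomic_number) {
    lines <- c(lines,
               "%FLAG ATOMIC_NUMBER",
               "%FORMAT(10I8)",
               "       6       1       1       1       1")
  }
  c(lines,
    "%FLAG MASS",
    "%FORMAT(5E16.8)",
    "  1.20100000E+01  1.00800000E+00  1.00800000E+00  1.00800000E+00  1.00800000E+00")
}

# deterministic 3-molecule table: benzene, chloroform-like, phosphine-like
tiny_records <- function() {
  molecule_table(
    id = c("m1", "m2", "m3"),
    counts = list(c(C = 6L, H = 6L), c(C = 1L, H = 1L, Cl = 3L),
                  c(P = 1L, H = 3L)),
    pmv = c(142.9, 110.0, 80.0),
    dg_method = c(-3.2, -5.0, -1.0),
    dg_exp = c(-3.8, -4.2, -0.5),
    dg_exp_unc = 0.1)
}

expect_model_equal <- function(m1, m2, tol = 0) {
  expect_identical(m1$kind, m2$kind)
  expect_identical(m1$element_order, m2$element_order)
  if (tol == 0) {
    expect_identical(m1$a, m2$a)
    expect_identical(m1$b, m2$b)
    expect_identical(m1$c, m2$c)
  } else {
    expect_equal(m1$a, m2$a, tolerance = tol)
    expect_equal(m1$b, m2$b, tolerance = tol)
    expect_equal(m1$c, m2$c, tolerance = tol)
  }
}
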