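test_that("a written structure reads back structurally equal", {
  s <- toy_with_pocket()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  s2 <- read_structure(f)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_equal(s2$atoms$resno, s$atoms$resno)
  expect_equal(s2$atoms$resname, s$atoms$resname)
  expect_equal(s2$atoms$atom, s$atoms$atom)
  expect_equal(s2$atoms$het, s$atoms$het)
  # PDB precision: coordinates to 3 decimals
  expect_lt(max(abs(coords(s2) - coords(s))), 1e-3 + 1e-9)
  # second round trip is exact
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s2, f2)
  s3 <- read_structure(f2)
  expect_identical(coords(s3), coords(s2))
})

test_that("alternate locations collapse to the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000  -1.200  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       0.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       1.500   0.000   0.000  0.40  0.00           C",
    "ATOM      4  C   ALA A   1       0.000   0.000   1.200  1.00  0.00           C",
    "END"), f)
  s <- read_structure(f)
  ca <- s$atoms[s$atoms$atom == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 0)          # the 0.60 conformer
  expect_equal(ca$occ, 0.6)
})

test_that("altloc ties keep the first conformer encountered", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   5       2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA BGLY A   5       9.000   0.000   0.000  0.50  0.00           C",
    "END"), f)
  s <- read_structure(f)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$x, 2)
})

test_that("waters and hydrogens are dropped on read", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  H   GLY A   1       0.500   0.500   0.000  1.00  0.00           H",
    "HETATM    3  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O",
    "HETATM    4  C1  FAD A 102       8.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  s <- read_structure(f)
  expect_equal(nrow(s$atoms), 2L)
  expect_false(any(s$atoms$resname == "HOH"))
  expect_false(any(s$atoms$element == "H"))
})

test_that("mmCIF and PDB encodings of the same atoms load identically", {
  fcif <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_toy",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.auth_atom_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "ATOM 1 C CA GLY A 1 ? 1.000 2.000 3.000 1.00",
    "ATOM 2 C CA ALA A 2 ? 4.000 5.000 6.000 1.00",
    "HETATM 3 C C1 FAD A 10 ? 7.000 8.000 9.000 1.00",
    "#"), fcif)
  s <- read_structure(fcif)
  expect_identical(s$source_format, "cif")
  expect_equal(s$atoms$resno, c(1L, 2L, 10L))
  expect_equal(s$atoms$het, c(FALSE, FALSE, TRUE))
  expect_equal(coords(s)[2, ], c(4, 5, 6), ignore_attr = TRUE)
  fpdb <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, fpdb)
  s2 <- read_structure(fpdb)
  expect_equal(s2$atoms[, c("chain", "resno", "resname", "atom", "het")],
               s$atoms[, c("chain", "resno", "resname", "atom", "het")])
  expect_identical(coords(s2), coords(s))
})

test_that("chain sequence extraction honours planted author numbering", {
  s <- make_toy_structure(10, sequence = "ACDEFGHIKL", numbering_offset = 10L)
  cs <- extract_chain_sequence(s, "A")
  expect_equal(cs$sequence, "ACDEFGHIKL")
  expect_equal(cs$numbering_map, 11:20)
  expect_error(extract_chain_sequence(s, "Z"), "available")
  g <- make_toy_structure(1, sequence = "G", numbering_offset = 41L)
  cg <- extract_chain_sequence(g, "A")
  expect_equal(cg$sequence, "G")
  expect_equal(cg$numbering_map, 42L)
})

test_that("ligand listing follows the het-code dictionary", {
  s <- make_toy_structure(20, ligands = list(
    list(het_code = "COA", anchor = 5, offset = c(5, 0, 0)),
    list(het_code = "UQ5", anchor = 15, offset = c(5, 0, 0))), seed = 2)
  lig <- list_ligands(s)
  expect_length(lig, 2L)
  cats <- vapply(lig, `[[`, "", "category")
  expect_setequal(cats, c("CoA", "UQ-like"))
  expect_length(list_ligands(s, categories = "CoA"), 1L)
  # categorization is a pure function of the dictionary; atoms untouched
  custom <- default_ligand_dict()
  custom[["UQ-like"]] <- character()
  lig2 <- list_ligands(s, dict = custom)
  expect_setequal(vapply(lig2, `[[`, "", "category"), c("CoA", "other"))
  expect_identical(lapply(lig2, function(l) l$atoms[, c("x", "y", "z")]),
                   lapply(lig, function(l) l$atoms[, c("x", "y", "z")]))
  # no heteroresidues -> empty list
  expect_length(list_ligands(make_toy_structure(5)), 0L)
})

test_that("small substrates are ligands of category other, ions are not", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  O1  OXY A 101       5.000   0.000   0.000  1.00  0.00           O",
    "HETATM    3  O2  OXY A 101       6.200   0.000   0.000  1.00  0.00           O",
    "HETATM    4 MG    MG A 102       9.000   9.000   9.000  1.00  0.00          MG",
    "END"), f)
  s <- read_structure(f)
  lig <- list_ligands(s)
  expect_length(lig, 1L)
  expect_equal(lig[[1]]$het_code, "OXY")
  expect_equal(lig[[1]]$category, "other")
  expect_length(list_ligands(s, include_ions = TRUE), 2L)
})
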