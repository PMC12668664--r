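test_that("a minimal single-atom PDB parses to one chain/residue/atom", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00 10.00           C",
    "END"), f)
  m <- parse_structure(f)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 1)
  expect_equal(m$atoms$chain, "A")
  expect_equal(m$atoms$resno, 1L)
  expect_equal(unlist(m$atoms[, c("x", "y", "z")], use.names = FALSE),
               c(1, 2, 3))
})

test_that("write -> parse round-trips names, numbers and coordinates to 1e-3", {
  toy <- build_toy_complex()$model
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(toy, f)
  m2 <- parse_structure(f)
  expect_equal(nrow(m2$atoms), nrow(toy$atoms))
  expect_equal(m2$atoms$resno, toy$atoms$resno)
  expect_equal(m2$atoms$atom, toy$atoms$atom)
  expect_equal(m2$atoms$resid, toy$atoms$resid)
  expect_lt(max(abs(coords_of(m2$atoms) - coords_of(toy$atoms))), 1e-3)
  expect_equal(count_protein_residues(m2), count_protein_residues(toy))
})

test_that("mmCIF atom_site loops parse to the same model as PDB", {
  toy <- build_ideal_helix(4, backbone = TRUE)
  f <- withr::local_tempfile(fileext = ".cif")
  a <- toy$atoms
  lines <- c("data_toy", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                      "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                      "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                      "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")),
             sprintf("ATOM %d %s %s . %s A 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s A %s 1",
                     seq_len(nrow(a)), a$element, a$atom, a$resid, a$resno,
                     a$x, a$y, a$z, a$resno, a$resid, a$atom))
  writeLines(lines, f)
  m <- parse_structure(f)
  expect_equal(nrow(m$atoms), nrow(a))
  expect_lt(max(abs(coords_of(m$atoms) - coords_of(a))), 1e-3)
})

test_that("unparseable and empty files raise parse errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(parse_structure(f), "ATOM|parse")
  expect_error(parse_structure(file.path(tempdir(), "no-such-file.pdb")),
               "not found")
})

test_that("waters are excluded by default and HETATM keeps its flag", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C",
    "HETATM    2  O   HOH B 101       5.000   0.000   0.000  1.00 10.00           O",
    "HETATM    3 ZN    ZN B 102       9.000   0.000   0.000  1.00 10.00          ZN",
    "END"), f)
  m <- parse_structure(f)
  expect_false(any(m$atoms$resid == "HOH"))
  expect_true(m$atoms$het[m$atoms$resid == "ZN"])
  expect_equal(count_protein_residues(m), 1L)
  m2 <- parse_structure(f, keep_waters = TRUE)
  expect_true(any(m2$atoms$resid == "HOH"))
})

test_that("altloc keeps the highest-occupancy conformer, ties go to A", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CB AALA A   1       0.000   1.000   0.000  0.50 10.00           C",
    "ATOM      4  CB BALA A   1       0.000   2.000   0.000  0.50 10.00           C",
    "END"), f)
  m <- parse_structure(f)
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$x[m$atoms$atom == "CA"], 1)   # higher occupancy wins
  expect_equal(m$atoms$y[m$atoms$atom == "CB"], 1)   # tie -> altloc A
})

test_that("protein-residue counting ignores chain order", {
  m <- helix_bundle(c(12, 30, 7))
  perm <- m$atoms[order(match(m$atoms$chain, c("C", "A", "B"))), ]
  m2 <- structure_model(perm, id = "permuted")
  expect_equal(count_protein_residues(m2), count_protein_residues(m))
  expect_equal(count_protein_residues(m), 49L)
})

test_that("role heuristics recover the designed chain architecture", {
  m <- helix_bundle(c(275, 99, 9, 220, 214), chains = c("H", "B", "P", "Y", "L"))
  map <- assign_roles(m)
  expect_equal(map$roles[["H"]], "mhc_heavy")
  expect_equal(map$roles[["B"]], "beta2m")
  expect_equal(map$roles[["P"]], "peptide")
  expect_equal(map$roles[["Y"]], "ab_heavy")
  expect_equal(map$roles[["L"]], "ab_light")
  # receptor complexes: one chain left after MHC assembly
  m2 <- helix_bundle(c(275, 99, 9, 200), chains = c("H", "B", "P", "K"))
  expect_equal(assign_roles(m2)$roles[["K"]], "receptor")
})

test_that("ambiguous assignments error with candidates and hints always win", {
  m <- helix_bundle(c(9, 9), chains = c("P", "Q"))
  expect_error(assign_roles(m), "ambiguous.*P, Q|ambiguous")
  map <- assign_roles(m, hints = c(P = "peptide", Q = "other"))
  expect_equal(map$roles[["P"]], "peptide")
  expect_equal(map$roles[["Q"]], "other")
})

test_that("atom selection honours role, segment range, and heavy_only", {
  m <- helix_bundle(c(275, 9), chains = c("H", "P"), backbone = TRUE)
  map <- assign_roles(m, hints = c(H = "mhc_heavy", P = "peptide"))
  pep <- select_atoms(m, map, "peptide")
  expect_equal(length(unique(pep$resno)), 9)
  seg <- select_atoms(m, map, "mhc_heavy", segment = "alpha2_1")
  expect_equal(sort(unique(seg$resno)), 141:155)
  expect_error(select_atoms(m, map, "receptor"), "no chain")
  expect_error(select_atoms(m, map, "mhc_heavy", segment = "nope"),
               "unknown segment")
  # hydrogens excluded under heavy_only
  a <- m$atoms[1, ]; a$atom <- "H"; a$element <- "H"
  mh <- structure_model(rbind(m$atoms, a), id = "with-h")
  sel <- select_atoms(mh, map, "mhc_heavy")
  expect_false(any(sel$element == "H"))
  expect_true(any(select_atoms(mh, map, "mhc_heavy",
                               heavy_only = FALSE)$element == "H"))
})

test_that("multi-character chain ids are rejected for fixed-column PDB", {
  a <- make_atoms(3, chain = "AB")
  m <- structure_model(a, id = "wide")
  expect_error(write_pdb(m, tempfile(fileext = ".pdb")), "mmCIF")
})
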