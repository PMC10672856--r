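# PDB/mmCIF reading, gap bridging, PDB writing, FASTA round trips

test_that("a minimal hand-written PDB reads back as a 5-residue trace", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(mini_pdb_lines(), f)
  traces <- read_structure(f)
  expect_length(traces, 1)
  tr <- traces[[1]]
  expect_s3_class(tr, "catrace")
  expect_equal(length(tr), 5)
  expect_equal(tr$residue_numbers, 1:5)
  expect_false(tr$broken)
  expect_equal(tr$plddt, c(81.3, 79.0, 85.2, 90.1, 77.7))
})

test_that("altlocs resolve to the highest occupancy", {
  xyz <- cbind(seq(0, 15.2, by = 3.8), 0, 0)
  lines <- c(
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            1, 1, xyz[1, 1], 0, 0, 1.0, 50.0),
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            2, 2, xyz[2, 1], 0, 0, 1.0, 50.0),
    # residue 3: altloc A occupancy 0.4 at y=5, altloc B occupancy 0.6 at y=0
    sprintf("ATOM  %5d  CA AALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            3, 3, xyz[3, 1], 5.0, 0, 0.4, 50.0),
    sprintf("ATOM  %5d  CA BALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            4, 3, xyz[3, 1], 0.0, 0, 0.6, 50.0),
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            5, 4, xyz[4, 1], 0, 0, 1.0, 50.0),
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            6, 5, xyz[5, 1], 0, 0, 1.0, 50.0))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  tr <- read_structure(f)[[1]]
  expect_equal(length(tr), 5)
  expect_equal(tr$coords[3, 2], 0.0)  # highest occupancy kept
})

test_that("B-factors outside [0,100] disable pLDDT", {
  lines <- sub("81.30", "141.3", mini_pdb_lines()[1], fixed = TRUE)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(lines, mini_pdb_lines()[-1]), f)
  tr <- read_structure(f)[[1]]
  expect_null(tr$plddt)
  expect_error(confidence_profile(tr), "pLDDT")
})

test_that("gap bridging interpolates short gaps and flags long ones", {
  xyz <- cbind(seq(0, 3.8 * 19, by = 3.8), 0, 0)
  tr <- ca_trace(xyz[-(10:11), ], residue_numbers = (1:20)[-(10:11)])
  expect_true(tr$broken)  # before bridging
  fixed <- bridge_gaps(tr, max_bridge = 3)
  expect_false(fixed$broken)
  expect_equal(length(fixed), 20)
  expect_equal(fixed$coords[10, 1], xyz[10, 1], tolerance = 1e-9)

  tr2 <- ca_trace(rbind(xyz[1:5, ], sweep(xyz[1:5, ], 2, c(200, 0, 0), "+")),
                  residue_numbers = c(1:5, 36:40))
  fixed2 <- bridge_gaps(tr2, max_bridge = 3)
  expect_true(fixed2$broken)

  clean <- ca_trace(xyz)
  expect_identical(bridge_gaps(clean)$coords, clean$coords)
})

test_that("PDB round trip preserves coordinates to 1e-3 and chain order is canonical", {
  tr <- generate_knot(knot_recipe("3_1", n_points = 60, seed = 3))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trace_pdb(tr, f)
  back <- read_structure(f)[[1]]
  expect_equal(back$coords, tr$coords, tolerance = 1e-3)

  # two chains: selection order must not matter
  f2 <- withr::local_tempfile(fileext = ".pdb")
  tr2 <- ca_trace(sweep(tr$coords, 2, c(100, 0, 0), "+"), chain_id = "B")
  l1 <- readLines(f)
  write_trace_pdb(tr2, f2)
  l2 <- readLines(f2)
  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(grep("^ATOM", l1, value = TRUE),
               grep("^ATOM", l2, value = TRUE), "END"), f3)
  ab <- read_structure(f3, chain = c("A", "B"))
  ba <- read_structure(f3, chain = c("B", "A"))
  expect_identical(lapply(ab, `[[`, "chain_id"),
                   lapply(ba, `[[`, "chain_id"))
  expect_identical(ab[[1]]$coords, ba[[1]]$coords)
})

test_that("FASTA round trips and rejects non-canonical residues", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">one", "MKVLLYG"), f)
  recs <- read_fasta(f)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$sequence, "MKVLLYG")

  recs3 <- data.frame(id = c("a", "b", "c"),
                      sequence = c("MKV", "GGGGSGGGGS", "ACDEFGHIKLMNPQRSTVWY"))
  f3 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs3, f3)
  back <- read_fasta(f3)
  expect_equal(back$sequence, recs3$sequence)
  expect_equal(back$id, recs3$id)

  fx <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">bad", "MKXV"), fx)
  expect_error(read_fasta(fx), "non-canonical")
})

test_that("span_length counts closed intervals inclusively", {
  expect_equal(span_length(c(74, 99)), 26L)
  expect_equal(span_length(c(5, 5)), 1L)
  expect_error(span_length(c(9, 5)))
})

test_that("a minimal hand-written mmCIF reads like its PDB twin", {
  lines <- c(
    "data_synthetic", "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
             "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
             "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
             "auth_comp_id", "auth_asym_id", "auth_atom_id",
             "pdbx_PDB_model_num")),
    sprintf("ATOM %d C CA . ALA A 1 %d ? %.3f 0.000 0.000 1.00 %.2f ? %d ALA A CA 1",
            1:5, 1:5, seq(0, 15.2, by = 3.8),
            c(81.3, 79, 85.2, 90.1, 77.7), 1:5))
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(lines, f)
  tr <- suppressWarnings(read_structure(f))[[1]]
  expect_equal(length(tr), 5)
  expect_equal(tr$coords[, 1], seq(0, 15.2, by = 3.8), tolerance = 1e-6)
  expect_equal(tr$plddt, c(81.3, 79, 85.2, 90.1, 77.7))
})

test_that("xyz text round-trips and feeds the classifier", {
  tre <- generate_knot(knot_recipe("3_1", n_points = 60, seed = 12))
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(tre$coords, f)
  back <- read_xyz(f)
  expect_equal(back, tre$coords, tolerance = 1e-12)
  expect_equal(classify_knot(back, seed = 3)$notation, "3_1")
})
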