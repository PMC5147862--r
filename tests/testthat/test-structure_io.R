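# minimal hand-written PDB fixture: chain A (2 residues), chain B (1 residue)
minimal_pdb <- paste(c(
  "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  GLY A   1       1.500   0.000   0.000  1.00  0.00           C",
  "ATOM      3  N   ALA A   2       3.000   0.000   0.000  1.00  0.00           N",
  "ATOM      4  CA  ALA A   2       4.500   0.000   0.000  1.00  0.00           C",
  "ATOM      5  CB  ALA A   2       5.500   1.000   0.000  1.00  0.00           C",
  "TER",
  "ATOM      6  N   SER B  10       0.000   5.000   0.000  1.00  0.00           N",
  "ATOM      7  CA  SER B  10       1.500   5.000   0.000  1.00  0.00           C",
  "TER", "END"), collapse = "\n")

test_that("parse_structure keeps both chains with author numbering", {
  cx <- parse_structure(minimal_pdb, "A", "B", structure_id = "mini")
  res <- complex_residues(cx)
  expect_equal(sum(res$role == "ras"), 2)
  expect_equal(sum(res$role == "effector"), 1)
  expect_equal(res$resno[res$role == "effector"], 10)
  expect_equal(attr(cx, "structure_id"), "mini")
  # lossless for heavy atoms
  expect_equal(nrow(cx), 7)
  # residue iteration order equals file order
  expect_equal(res$res_name[res$role == "ras"], c("GLY", "ALA"))
})

test_that("missing chain raises a named-chain-not-found error", {
  expect_error(parse_structure(minimal_pdb, "Z", "B"),
               class = "raseffector_error_chain_not_found")
  expect_error(parse_structure(minimal_pdb, "A", "Q"),
               class = "raseffector_error_chain_not_found")
})

test_that("text without atom records is rejected as malformed", {
  expect_error(parse_structure("HEADER    NOTHING\nEND\n", "A", "B"),
               class = "raseffector_error_malformed_input")
})

test_that("hydrogens, waters and non-protein HETATM groups are removed", {
  txt <- paste(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  H   GLY A   1       0.500   0.500   0.000  1.00  0.00           H",
    "HETATM    3  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "HETATM    4 MG    MG A 102       8.000   8.000   8.000  1.00  0.00          MG",
    "HETATM    5 SE   MSE A   2       2.000   0.000   0.000  1.00  0.00          SE",
    "ATOM      6  CA  ALA B   1       0.000   3.000   0.000  1.00  0.00           C",
    "END"), collapse = "\n")
  cx <- parse_structure(txt, "A", "B")
  expect_equal(nrow(cx), 3)  # GLY N, MSE SE, ALA CA
  expect_true("MSE" %in% cx$res_name)
  res <- complex_residues(cx, "ras")
  expect_equal(res$aa, c("G", "M"))  # selenomethionine maps to Met
})

test_that("altloc policy keeps highest occupancy, ties broken by smallest id", {
  txt <- paste(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AALA A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1       8.000   0.000   0.000  0.50  0.00           C",
    "ATOM      5  CA  GLY B   1       0.000   3.000   0.000  1.00  0.00           C",
    "END"), collapse = "\n")
  cx <- parse_structure(txt, "A", "B")
  ras <- cx[cx$role == "ras", ]
  expect_equal(nrow(ras), 2)
  expect_equal(ras$x[ras$atom_name == "CA"], 9.0)   # higher occupancy wins
  expect_equal(ras$x[ras$atom_name == "CB"], 1.0)   # tie -> altloc A
})

test_that("multi-model files honour model_index", {
  one_model <- function(z) paste(c(
    sprintf("ATOM      1  CA  GLY A   1       0.000   0.000%8.3f  1.00  0.00           C", z),
    sprintf("ATOM      2  CA  GLY B   1       0.000   3.000%8.3f  1.00  0.00           C", z)),
    collapse = "\n")
  txt <- paste(c("MODEL        1", one_model(0), "ENDMDL",
                 "MODEL        2", one_model(5), "ENDMDL", "END"),
               collapse = "\n")
  cx1 <- parse_structure(txt, "A", "B", model_index = 1)
  cx2 <- parse_structure(txt, "A", "B", model_index = 2)
  expect_equal(unique(cx1$z), 0)
  expect_equal(unique(cx2$z), 5)
  expect_error(parse_structure(txt, "A", "B", model_index = 3),
               class = "raseffector_error_malformed_input")
})

test_that("generator fixtures round-trip through write and parse", {
  toy <- make_toy_complex(list(
    list(ras_index = 2, eff_index = 3, distance = 3.2, category = "ms")
  ), chain_lengths = c(5, 5))
  cx <- parse_structure(toy$pdb_text, "A", "B")
  cx2 <- parse_structure(write_complex_pdb(cx), "A", "B")
  expect_equal(nrow(cx2), nrow(cx))
  expect_equal(round(cx2$x, 3), round(cx$x, 3))
  expect_equal(round(cx2$y, 3), round(cx$y, 3))
  expect_equal(round(cx2$z, 3), round(cx$z, 3))
  expect_equal(cx2$atom_name, cx$atom_name)
  # re-serialization is idempotent
  expect_identical(write_complex_pdb(cx2), write_complex_pdb(cx))
})

# helper: relabel the chains of a toy complex so two complexes can share a
# file; serial numbers are offset to stay unique after concatenation
relabel_chains <- function(pdb_text, from, to, serial_offset = 1000) {
  lines <- strsplit(pdb_text, "\n")[[1]]
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  ch <- substr(lines[is_atom], 22, 22)
  for (k in seq_along(from)) ch[ch == from[k]] <- to[k]
  substr(lines[is_atom], 22, 22) <- ch
  serial <- as.integer(substr(lines[is_atom], 7, 11)) + serial_offset
  substr(lines[is_atom], 7, 11) <- sprintf("%5d", serial)
  paste(lines, collapse = "\n")
}

test_that("enumerate_chain_pairs matches sequences and honours pairing groups", {
  toy <- make_toy_complex(list(), chain_lengths = c(6, 4),
                          ras_seq = "GAVLIM", eff_seq = "FWYS")
  # single pair
  pairs <- enumerate_chain_pairs(toy$pdb_text,
                                 ras_sequences = c(rasx = "GAVLIM"),
                                 effector_sequences = c(effx = "FWYS"))
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$ras_chain, "A")
  expect_equal(pairs$effector_chain, "B")
  expect_false(pairs$flagged)

  # two copies in one file: pairing file resolves to 2 pairs, otherwise all 4
  # combinations are flagged for review
  copy2 <- relabel_chains(toy$pdb_text, c("A", "B"), c("C", "D"))
  both <- paste(sub("\nTER\nEND$", "\nTER", toy$pdb_text), copy2, sep = "\n")
  p_grouped <- enumerate_chain_pairs(both,
                                     ras_sequences = c(rasx = "GAVLIM"),
                                     effector_sequences = c(effx = "FWYS"),
                                     pairing = list(c("A", "B"), c("C", "D")))
  expect_equal(nrow(p_grouped), 2)
  expect_equal(p_grouped$ras_chain, c("A", "C"))
  expect_equal(p_grouped$effector_chain, c("B", "D"))
  expect_false(any(p_grouped$flagged))

  p_free <- enumerate_chain_pairs(both,
                                  ras_sequences = c(rasx = "GAVLIM"),
                                  effector_sequences = c(effx = "FWYS"))
  expect_equal(nrow(p_free), 4)
  expect_true(all(p_free$flagged))

  # no match -> empty, not an error
  none <- enumerate_chain_pairs(toy$pdb_text,
                                ras_sequences = c(rasx = "KKKKKK"),
                                effector_sequences = c(effx = "EEEE"))
  expect_equal(nrow(none), 0)

  # chain matching both sides -> ambiguity error
  expect_error(
    enumerate_chain_pairs(toy$pdb_text,
                          ras_sequences = c(rasx = "GAVLIM"),
                          effector_sequences = c(effx = "GAVLIM")),
    class = "raseffector_error_ambiguous_chain")
})
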