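# Synthetic fixtures: toy two-chain complexes with planted contacts, toy
# alignments synchronized with them, planted-block matrices, and simulated
# titrations. Every generator returns machine-checkable ground truth next to
# its artifact, and all randomness flows from explicit seeds.
#
# Toy geometry: each residue carries the minimal atom template N, CA, C, O
# plus one side-chain pseudo-atom CB, spaced 15 A apart along x within a
# residue and 60 A apart along y between residues; the two chains sit 1000 A
# apart. A planted contact relocates one effector atom to the specified
# distance (along z) from the chosen RAS atom, which leaves every non-planted
# inter-chain atom pair > 8 A away (twice the contact cutoff) by
# construction. Physically realistic stereochemistry is deliberately not
# attempted.

.toy_atoms <- c("N", "CA", "C", "O", "CB")
.toy_elements <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")

toy_atom_position <- function(chain_offset, res_index, atom_name) {
  c(chain_offset + 15 * (match(atom_name, .toy_atoms) - 1),
    60 * (res_index - 1),
    0)
}

planted_atom_names <- function(category) {
  if (!category %in% c("mm", "ms", "sm", "ss")) {
    stop_raseff(sprintf("unknown contact category '%s'", category), "spec_conflict")
  }
  # mm uses backbone O (RAS) vs backbone N (effector) so planted distances
  # <= 3.5 A also exercise the backbone hydrogen-bond flag
  c(ras = if (substr(category, 1, 1) == "m") "O" else "CB",
    eff = if (substr(category, 2, 2) == "m") "N" else "CB")
}

#' Generate a toy two-chain complex with planted contacts
#'
#' Builds PDB-format text for a RAS-like chain A and an effector-like chain B
#' (all-alanine residues on the minimal N/CA/C/O/CB template) in which each
#' planted residue pair realises exactly its specified inter-atom distance
#' between atoms of the requested main-chain/side-chain classes, while every
#' non-planted inter-chain atom pair is more than 8 A apart.
#'
#' @param specs List of planted-contact specs, each a list with
#'   `ras_index`, `eff_index` (1-based residue positions), `distance` (A) and
#'   `category` (`"mm"`, `"ms"`, `"sm"`, `"ss"`).
#' @param chain_lengths Integer pair `(n_ras, n_eff)` (default `c(5, 5)`).
#' @param structure_id Identifier stamped on parsed results.
#' @param cutoff Cutoff used to compute the ground-truth contact list
#'   (default 4.0 A).
#' @param ras_seq,eff_seq Optional one-letter sequences for the two chains
#'   (lengths must equal `chain_lengths`); default poly-alanine.
#' @return List with `pdb_text`, `ground_truth` (tibble of residue pairs that
#'   must appear at the cutoff: `ras_resno`, `eff_resno`, `category`,
#'   `distance`, `hbond_like`), `planted` (all specs incl. those beyond the
#'   cutoff) and `structure_id`.
#' @export
make_toy_complex <- function(specs, chain_lengths = c(5, 5),
                             structure_id = "toy", cutoff = 4.0,
                             ras_seq = NULL, eff_seq = NULL) {
  n_ras <- chain_lengths[1]; n_eff <- chain_lengths[2]
  ras_seq <- ras_seq %||% strrep("A", n_ras)
  eff_seq <- eff_seq %||% strrep("A", n_eff)
  if (nchar(ras_seq) != n_ras || nchar(eff_seq) != n_eff) {
    stop_raseff("sequence lengths must equal chain_lengths", "spec_conflict")
  }
  res3 <- list(
    A = bio3d::aa123(strsplit(ras_seq, "")[[1]]),
    B = bio3d::aa123(strsplit(eff_seq, "")[[1]])
  )
  specs <- purrr::map(specs, function(s) {
    if (s$distance <= 0) stop_raseff("planted distance must be positive", "spec_conflict")
    if (s$distance > 6) {
      stop_raseff("planted distances above 6 A would violate the 8 A decoy separation",
                  "spec_conflict")
    }
    if (s$ras_index < 1 || s$ras_index > n_ras || s$eff_index < 1 || s$eff_index > n_eff) {
      stop_raseff("planted residue index outside chain length", "spec_conflict")
    }
    s
  })

  # base positions
  atoms <- tidyr::expand_grid(
    chain = c("A", "B"),
    res_index = seq_len(max(n_ras, n_eff)),
    atom_name = .toy_atoms
  ) |>
    filter((.data$chain == "A" & .data$res_index <= n_ras) |
             (.data$chain == "B" & .data$res_index <= n_eff)) |>
    arrange(.data$chain, .data$res_index, match(.data$atom_name, .toy_atoms))
  pos <- purrr::pmap(atoms, function(chain, res_index, atom_name) {
    toy_atom_position(if (chain == "A") 0 else 1000, res_index, atom_name)
  })
  atoms$x <- vapply(pos, `[`, double(1), 1)
  atoms$y <- vapply(pos, `[`, double(1), 2)
  atoms$z <- vapply(pos, `[`, double(1), 3)

  moved <- character()
  for (s in specs) {
    an <- planted_atom_names(s$category)
    ras_i <- which(atoms$chain == "A" & atoms$res_index == s$ras_index &
                     atoms$atom_name == an[["ras"]])
    eff_i <- which(atoms$chain == "B" & atoms$res_index == s$eff_index &
                     atoms$atom_name == an[["eff"]])
    key <- paste0("B", s$eff_index, ":", an[["eff"]])
    if (key %in% moved) {
      stop_raseff(sprintf("conflicting specs: effector atom %s demanded at two positions", key),
                  "spec_conflict")
    }
    moved <- c(moved, key)
    atoms$x[eff_i] <- atoms$x[ras_i]
    atoms$y[eff_i] <- atoms$y[ras_i]
    atoms$z[eff_i] <- atoms$z[ras_i] + s$distance
  }

  fmt <- function(i) {
    nm <- atoms$atom_name[i]
    nm4 <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, nm4, res3[[atoms$chain[i]]][atoms$res_index[i]],
            atoms$chain[i], atoms$res_index[i],
            atoms$x[i], atoms$y[i], atoms$z[i], 1, 0,
            .toy_elements[[nm]])
  }
  ia <- which(atoms$chain == "A"); ib <- which(atoms$chain == "B")
  pdb_text <- paste(c(vapply(ia, fmt, character(1)), "TER",
                      vapply(ib, fmt, character(1)), "TER", "END"),
                    collapse = "\n")

  planted <- purrr::map_dfr(specs, function(s) {
    tibble(ras_resno = s$ras_index, eff_resno = s$eff_index,
           category = s$category, distance = s$distance,
           hbond_like = s$category == "mm" & s$distance <= 3.5)
  })
  if (nrow(planted) == 0) {
    planted <- tibble(ras_resno = integer(), eff_resno = integer(),
                      category = character(), distance = double(),
                      hbond_like = logical())
  }
  ground_truth <- planted[planted$distance <= cutoff, ]

  list(pdb_text = pdb_text, ground_truth = ground_truth, planted = planted,
       structure_id = structure_id)
}

#' Toy two-row alignment placing a chain at given reference positions
#'
#' Builds an alignment whose reference row is an ungapped poly-alanine
#' stretch numbered from `ref_start`, with the toy chain's sequence starting
#' at reference number `first_label`; positions of the toy row outside its
#' sequence are gaps. Residue `i` of the chain then maps to reference label
#' `first_label + i - 1`.
#'
#' @param chain_length Number of residues in the toy chain.
#' @param first_label Reference number of the chain's first residue.
#' @param ref_start First reference number of the reference row.
#' @param ref_end Last reference number (default `first_label + chain_length + 4`).
#' @param reference_row,row_name Row names.
#' @return List with `alignment` (an `msa_alignment`), `reference` (from
#'   [reference_numbering()]) and `row_name`.
#' @export
make_toy_alignment <- function(chain_length, first_label, ref_start = 1,
                               ref_end = first_label + chain_length + 4,
                               reference_row = "REF", row_name = "TOY") {
  if (first_label < ref_start || first_label + chain_length - 1 > ref_end) {
    stop_raseff("chain does not fit between ref_start and ref_end", "spec_conflict")
  }
  n_cols <- ref_end - ref_start + 1
  offset <- first_label - ref_start
  ref_row <- strrep("A", n_cols)
  toy_row <- paste0(strrep("-", offset), strrep("A", chain_length),
                    strrep("-", n_cols - offset - chain_length))
  rows <- setNames(c(ref_row, toy_row), c(reference_row, row_name))
  aln <- structure(list(rows = rows, length = n_cols), class = "msa_alignment")
  list(alignment = aln,
       reference = reference_numbering(aln, reference_row, ref_start),
       row_name = row_name)
}

#' Simulate a fluorescence polarization titration
#'
#' Signals are the quadratic-isotherm model values plus i.i.d. Gaussian noise
#' (standing in for instrument error); `noise_sd = 0` yields exact model
#' values. Deterministic for a fixed seed.
#'
#' @param kd_true Generating dissociation constant, uM.
#' @param receptor_total Labeled receptor concentration, uM (default 1).
#' @param n_points Number of log-spaced concentrations (default 24).
#' @param conc_range Concentration span in uM (default `c(0.05, 100)`).
#' @param noise_sd Gaussian noise standard deviation, a.u. (default 0).
#' @param seed Integer seed for the noise draw.
#' @param p_free,p_bound Signal endpoints (defaults 0 and 1).
#' @param ras,effector Optional pair labels.
#' @return A `titration_curve` with simulated signals; the generating
#'   parameters are stored in `attr(, "truth")`.
#' @export
make_titration <- function(kd_true, receptor_total = 1, n_points = 24,
                           conc_range = c(0.05, 100), noise_sd = 0, seed = 1,
                           p_free = 0, p_bound = 1,
                           ras = NA_character_, effector = NA_character_) {
  if (kd_true <= 0) stop_raseff("kd_true must be positive", "domain")
  des <- titration_design(n_points, conc_range, receptor_total, ras, effector)
  mu <- model_signal(des, kd_true, p_free, p_bound)
  signal <- if (noise_sd > 0) {
    mu + with_seed(seed, rnorm(length(mu), sd = noise_sd))
  } else mu
  out <- titration_curve(des$ligand_total, signal, receptor_total, ras, effector)
  attr(out, "truth") <- list(kd = kd_true, p_free = p_free, p_bound = p_bound,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Planted-block integer matrix with known regions
#'
#' Zero everywhere except rectangular blocks of constant count; the returned
#' ground truth lists each block's exact cell set for region-recovery tests.
#'
#' @param blocks List of block specs, each a list with `row_span` and
#'   `col_span` (inclusive index pairs) and `count`.
#' @param shape Matrix dimensions `(rows, cols)`.
#' @return List with `matrix` (dimnames = indices as labels) and `truth`
#'   (list of per-block cell tibbles with `row`, `col`).
#' @export
make_planted_matrix <- function(blocks, shape = c(30, 30)) {
  m <- matrix(0L, shape[1], shape[2],
              dimnames = list(as.character(seq_len(shape[1])),
                              as.character(seq_len(shape[2]))))
  occupied <- matrix(FALSE, shape[1], shape[2])
  truth <- list()
  for (b in blocks) {
    r <- b$row_span[1]:b$row_span[2]
    cc <- b$col_span[1]:b$col_span[2]
    if (min(r) < 1 || max(r) > shape[1] || min(cc) < 1 || max(cc) > shape[2]) {
      stop_raseff("block outside matrix shape", "spec_conflict")
    }
    if (any(occupied[r, cc])) {
      stop_raseff("overlapping planted blocks", "spec_conflict")
    }
    occupied[r, cc] <- TRUE
    m[r, cc] <- as.integer(b$count)
    truth <- c(truth, list(tidyr::expand_grid(row = r, col = cc)))
  }
  list(matrix = m, truth = truth)
}

#' Write a full synthetic fixture set to a directory
#'
#' Emits toy PDB complexes, a matching pair of toy alignments, a simulated
#' titration TSV and JSON ground-truth files — everything needed to exercise
#' the pipeline end to end without downloads.
#'
#' @param dir Output directory.
#' @param seed Integer seed for the simulated titration.
#' @return Invisible character vector of files written.
#' @export
write_fixture_set <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  toy <- make_toy_complex(list(
    list(ras_index = 1, eff_index = 1, distance = 3.0, category = "mm"),
    list(ras_index = 2, eff_index = 2, distance = 3.8, category = "ss")
  ))
  f <- file.path(dir, "toy_complex.pdb")
  writeLines(toy$pdb_text, f); files <- c(files, f)
  f <- file.path(dir, "toy_complex_truth.json")
  jsonlite::write_json(toy$ground_truth, f, digits = NA, pretty = TRUE)
  files <- c(files, f)

  aln <- make_toy_alignment(5, first_label = 37, reference_row = "HRAS",
                            row_name = "TOY_RAS")
  f <- file.path(dir, "toy_ras_alignment.fasta")
  writeLines(c(paste0(">HRAS\n", aln$alignment$rows[["HRAS"]]),
               paste0(">TOY_RAS\n", aln$alignment$rows[["TOY_RAS"]])), f)
  files <- c(files, f)

  cur <- make_titration(kd_true = 0.238, noise_sd = 0.02, seed = seed)
  f <- file.path(dir, "titration.tsv")
  readr::write_tsv(tibble(ligand_total_uM = cur$ligand_total,
                          polarization = cur$signal), f)
  files <- c(files, f)
  invisible(files)
}
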