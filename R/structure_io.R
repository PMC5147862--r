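# Parsing of two-chain complex structures from PDB text.
#
# The internal representation is deliberately tabular: a `ras_complex` is a
# tibble of heavy atoms (one row per atom, file order preserved) carrying a
# `role` column ("ras" / "effector") plus a `structure_id` attribute, so the
# rest of the pipeline can use ordinary dplyr verbs.

# residue names treated as water
.water_resnames <- c("HOH", "WAT", "DOD", "H2O")

# modified amino acids retained in the protein chains, mapped to a parent
# one-letter code; all other HETATM groups (nucleotides, ions, ligands such
# as GNP/GDP/MG) are excluded from contact analysis
.modified_aa <- c(
  MSE = "M", SEP = "S", TPO = "T", PTR = "Y", CSO = "C", MLY = "K",
  HYP = "P", KCX = "K", CME = "C", PCA = "E"
)

one_letter_code <- function(res_name) {
  out <- rep(NA_character_, length(res_name))
  mod <- res_name %in% names(.modified_aa)
  out[mod] <- unname(.modified_aa[res_name[mod]])
  std <- !mod
  if (any(std)) {
    out[std] <- suppressWarnings(bio3d::aa321(res_name[std]))
  }
  out
}

read_pdb_atoms <- function(pdb_text, model_index = 1) {
  if (!any(grepl("^(ATOM|HETATM)", strsplit(pdb_text, "\n", fixed = TRUE)[[1]]))) {
    stop_raseff("PDB text contains no ATOM/HETATM records", "malformed_input")
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(pdb_text, tf)
  pdb <- tryCatch(
    bio3d::read.pdb(tf, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop_raseff(paste0("failed to parse PDB text: ", conditionMessage(e)),
                                    "malformed_input")
  )
  at <- tibble::as_tibble(pdb$atom)
  n_models <- nrow(pdb$xyz)
  if (model_index < 1 || model_index > n_models) {
    stop_raseff(sprintf("model_index %d out of range: file has %d model(s)",
                        model_index, n_models), "malformed_input")
  }
  if (model_index > 1) {
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  at |>
    mutate(
      icode = blank_to_empty(.data$insert),
      altloc = blank_to_empty(.data$alt),
      element = blank_to_empty(.data$elesy),
      occupancy = ifelse(is.na(.data$o), 1, .data$o)
    ) |>
    select(record = "type", atom_name = "elety", "altloc", res_name = "resid",
           chain = "chain", resno = "resno", "icode",
           "x", "y", "z", "occupancy", "element")
}

is_hydrogen <- function(element, atom_name) {
  el <- toupper(element)
  (el %in% c("H", "D")) | (el == "" & grepl("^[0-9]*[HD]", atom_name))
}

# altloc policy: per (residue, atom name) keep the conformer with the highest
# occupancy; ties broken by lexicographically smallest altloc id
resolve_altlocs <- function(atoms) {
  atoms |>
    mutate(.ord = dplyr::row_number()) |>
    group_by(.data$chain, .data$resno, .data$icode, .data$atom_name) |>
    arrange(dplyr::desc(.data$occupancy), .data$altloc, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$.ord) |>
    select(-".ord")
}

clean_atoms <- function(atoms) {
  atoms <- atoms |>
    filter(!(.data$res_name %in% .water_resnames)) |>
    filter(!is_hydrogen(.data$element, .data$atom_name)) |>
    filter(.data$record == "ATOM" | .data$res_name %in% names(.modified_aa))
  resolve_altlocs(atoms)
}

#' Parse a two-chain complex from PDB text
#'
#' Reads standard PDB `ATOM`/`HETATM` records (wwPDB v3.3 columns) and returns
#' the heavy atoms of one RAS chain and one effector chain as a single tibble.
#' Hydrogens, waters and non-protein HETATM groups (nucleotides, ions) are
#' dropped; modified amino acids such as selenomethionine are retained and
#' mapped to their parent residue. When alternate locations are present, the
#' conformer with the highest occupancy is kept (ties: smallest altloc id).
#' Author residue numbering and insertion codes are preserved throughout.
#'
#' @param pdb_text Character scalar of PDB-format text (or a vector of lines).
#' @param ras_chain_id Single chain identifier of the RAS-side chain.
#' @param effector_chain_id Single chain identifier of the effector chain.
#' @param model_index 1-based model to use for multi-model (NMR) entries;
#'   default the first model.
#' @param structure_id Free-form identifier attached to the result, typically
#'   a PDB code plus chain-pair tag.
#' @return A tibble of class `ras_complex` with one row per heavy atom and
#'   columns `role` (`"ras"`/`"effector"`), `chain`, `resno`, `icode`,
#'   `res_name`, `atom_name`, `element`, `x`, `y`, `z`, `occupancy`, `altloc`,
#'   in file order. The structure id is kept in `attr(, "structure_id")`.
#' @examples
#' toy <- make_toy_complex(list(list(ras_index = 1, eff_index = 1,
#'                                   distance = 3.5, category = "mm")))
#' cx <- parse_structure(toy$pdb_text, "A", "B")
#' dplyr::count(cx, role)
#' @export
parse_structure <- function(pdb_text, ras_chain_id, effector_chain_id,
                            model_index = 1, structure_id = "complex") {
  pdb_text <- paste(pdb_text, collapse = "\n")
  atoms <- clean_atoms(read_pdb_atoms(pdb_text, model_index))
  if (nrow(atoms) == 0) {
    stop_raseff("selected model contains no usable heavy atoms", "malformed_input")
  }
  for (id in c(ras_chain_id, effector_chain_id)) {
    if (!id %in% atoms$chain) {
      stop_raseff(sprintf("chain '%s' not found in structure (chains present: %s)",
                          id, paste(sort(unique(atoms$chain)), collapse = ", ")),
                  "chain_not_found")
    }
  }
  out <- atoms |>
    filter(.data$chain %in% c(ras_chain_id, effector_chain_id)) |>
    mutate(role = ifelse(.data$chain == ras_chain_id, "ras", "effector")) |>
    select("role", "chain", "resno", "icode", "res_name", "atom_name",
           "element", "x", "y", "z", "occupancy", "altloc")
  if (!any(out$role == "ras") || !any(out$role == "effector")) {
    stop_raseff("both chains must contain at least one residue", "malformed_input")
  }
  attr(out, "structure_id") <- structure_id
  class(out) <- c("ras_complex", class(out))
  out
}

#' Residue table of a parsed complex
#'
#' Collapses the atom table of a [parse_structure()] result to one row per
#' residue, in file order.
#'
#' @param complex A `ras_complex` tibble.
#' @param role Optional filter, `"ras"` or `"effector"`.
#' @return Tibble with columns `role`, `chain`, `resno`, `icode`, `res_name`,
#'   `aa` (one-letter code), `n_atoms`.
#' @export
complex_residues <- function(complex, role = NULL) {
  res <- complex |>
    group_by(.data$role, .data$chain, .data$resno, .data$icode, .data$res_name) |>
    summarise(n_atoms = dplyr::n(), .groups = "drop")
  # restore file order
  ord <- complex |>
    distinct(.data$chain, .data$resno, .data$icode) |>
    mutate(.ord = dplyr::row_number())
  res <- res |>
    left_join(ord, by = c("chain", "resno", "icode")) |>
    arrange(.data$.ord) |>
    mutate(aa = one_letter_code(.data$res_name)) |>
    select("role", "chain", "resno", "icode", "res_name", "aa", "n_atoms")
  if (!is.null(role)) res <- res[res$role == role, ]
  res
}

#' One-letter sequence of a chain in a parsed complex
#'
#' @inheritParams complex_residues
#' @param role `"ras"` or `"effector"`.
#' @return Character scalar; unknown residues appear as `"X"`.
#' @export
chain_sequence <- function(complex, role) {
  aa <- complex_residues(complex, role = role)$aa
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# sequence match used by enumerate_chain_pairs: exact substring containment in
# either direction, or >= min_identity over the shorter length by local
# alignment
sequence_matches <- function(chain_seq, ref_seq, min_identity = 0.95) {
  if (nchar(chain_seq) == 0 || nchar(ref_seq) == 0) return(FALSE)
  if (grepl(chain_seq, ref_seq, fixed = TRUE) || grepl(ref_seq, chain_seq, fixed = TRUE)) {
    return(TRUE)
  }
  aln <- Biostrings::pairwiseAlignment(chain_seq, ref_seq, type = "local",
                                       substitutionMatrix = NULL,
                                       gapOpening = 10, gapExtension = 4)
  Biostrings::nmatch(aln) / min(nchar(chain_seq), nchar(ref_seq)) >= min_identity
}

#' Enumerate candidate RAS/effector chain pairs in a PDB file
#'
#' Crystal entries often hold more than one copy of the biological complex in
#' the asymmetric unit. This helper extracts the sequence of every chain in
#' the selected model, matches each against user-supplied RAS and effector
#' reference sequences (exact substring either way, or at least 95% identity
#' over the shorter length), and reports candidate chain pairs. When a
#' `pairing` list assigns chains to complex groups, pairs are formed within
#' groups; otherwise all cross combinations are returned and flagged for
#' manual review whenever more than one complex is present.
#'
#' @param pdb_text PDB-format text.
#' @param ras_sequences Named character vector of one-letter RAS sequences.
#' @param effector_sequences Named character vector of effector sequences.
#' @param pairing Optional list of character vectors, each holding the chain
#'   ids of one biological complex group.
#' @param model_index 1-based model selector.
#' @param min_identity Identity threshold for fuzzy matches (default 0.95).
#' @return Tibble with columns `ras_chain`, `effector_chain`, `ras_name`,
#'   `effector_name`, `flagged`, sorted by chain ids; zero rows when no pair
#'   matches.
#' @export
enumerate_chain_pairs <- function(pdb_text, ras_sequences, effector_sequences,
                                  pairing = NULL, model_index = 1,
                                  min_identity = 0.95) {
  pdb_text <- paste(pdb_text, collapse = "\n")
  atoms <- clean_atoms(read_pdb_atoms(pdb_text, model_index))
  chains <- unique(atoms$chain)
  seqs <- vapply(chains, function(ch) {
    aa <- one_letter_code(atoms$res_name[!duplicated(paste(atoms$chain, atoms$resno, atoms$icode)) &
                                           atoms$chain == ch])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1))

  match_side <- function(side_seqs) {
    lapply(seqs, function(s) {
      names(side_seqs)[vapply(side_seqs, sequence_matches, logical(1),
                              chain_seq = s, min_identity = min_identity)]
    })
  }
  ras_hits <- match_side(ras_sequences)
  eff_hits <- match_side(effector_sequences)

  both <- chains[lengths(ras_hits) > 0 & lengths(eff_hits) > 0]
  if (length(both) > 0) {
    stop_raseff(sprintf("chain(s) %s match both a RAS and an effector sequence",
                        paste(both, collapse = ", ")), "ambiguous_chain")
  }
  ras_chains <- sort(chains[lengths(ras_hits) > 0])
  eff_chains <- sort(chains[lengths(eff_hits) > 0])
  if (length(ras_chains) == 0 || length(eff_chains) == 0) {
    return(tibble(ras_chain = character(), effector_chain = character(),
                  ras_name = character(), effector_name = character(),
                  flagged = logical()))
  }

  mk_row <- function(r, e, flagged) {
    tibble(ras_chain = r, effector_chain = e,
           ras_name = ras_hits[[r]][1], effector_name = eff_hits[[e]][1],
           flagged = flagged)
  }

  if (!is.null(pairing)) {
    rows <- purrr::map_dfr(pairing, function(grp) {
      r <- intersect(ras_chains, grp); e <- intersect(eff_chains, grp)
      tidyr::expand_grid(r = r, e = e) |>
        purrr::pmap_dfr(function(r, e) mk_row(r, e, FALSE))
    })
  } else {
    flag <- length(ras_chains) > 1 || length(eff_chains) > 1
    rows <- tidyr::expand_grid(r = ras_chains, e = eff_chains) |>
      purrr::pmap_dfr(function(r, e) mk_row(r, e, flag))
  }
  arrange(rows, .data$ras_chain, .data$effector_chain)
}

#' Serialize a parsed complex back to PDB text
#'
#' Writes fixed-column `ATOM` records for the atoms of a `ras_complex`, RAS
#' chain first, `TER` separated. Used for round-trip checks and fixtures.
#'
#' @param complex A `ras_complex` tibble.
#' @return Character scalar of PDB text.
#' @export
write_complex_pdb <- function(complex) {
  fmt_atom <- function(i, a, serial_offset = 0) {
    name <- a$atom_name[i]
    name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i + serial_offset, name4, ifelse(a$altloc[i] == "", " ", a$altloc[i]),
            a$res_name[i], a$chain[i], a$resno[i],
            ifelse(a$icode[i] == "", " ", a$icode[i]),
            a$x[i], a$y[i], a$z[i], a$occupancy[i], 0, a$element[i])
  }
  ras <- complex[complex$role == "ras", ]
  eff <- complex[complex$role == "effector", ]
  lines <- c(
    vapply(seq_len(nrow(ras)), fmt_atom, character(1), a = ras),
    "TER",
    vapply(seq_len(nrow(eff)), fmt_atom, character(1), a = eff,
           serial_offset = nrow(ras)),
    "TER", "END"
  )
  paste(lines, collapse = "\n")
}
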