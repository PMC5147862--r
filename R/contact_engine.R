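# Intermolecular contact computation. A contact is a RAS-residue/effector-
# residue pair with at least one heavy-atom pair at Euclidean distance <= the
# cutoff (4.0 A by default, boundary inclusive). Each atom pair is classified
# by whether the partner atoms are backbone (N, CA, C, O, OXT) or side chain,
# giving the four categories mm/ms/sm/ss (first letter = RAS side).

.main_chain_atoms <- c("N", "CA", "C", "O", "OXT")

# common heavy-atom names across the 20 standard residues; anything else is
# still treated as side chain, with a warning
.known_atoms <- c(
  .main_chain_atoms,
  "CB", "CG", "CG1", "CG2", "CD", "CD1", "CD2", "CE", "CE1", "CE2", "CE3",
  "CZ", "CZ2", "CZ3", "CH2", "ND1", "ND2", "NE", "NE1", "NE2", "NZ", "NH1",
  "NH2", "OD1", "OD2", "OE1", "OE2", "OG", "OG1", "OH", "SD", "SG", "SE"
)

#' Classify an atom as main chain or side chain
#'
#' Backbone atoms `N`, `CA`, `C`, `O` (and terminal `OXT`) are main chain;
#' everything from `CB` outward is side chain. Glycine therefore contributes
#' no side-chain atoms. Unrecognised atom names default to side chain with a
#' warning.
#'
#' @param res_name 3-letter residue code(s) (used only for diagnostics).
#' @param atom_name PDB atom name(s).
#' @return Character vector, `"main_chain"` or `"side_chain"`.
#' @examples
#' classify_atom("GLU", "CA")
#' classify_atom("GLU", "OE1")
#' @export
classify_atom <- function(res_name, atom_name) {
  unknown <- !(atom_name %in% .known_atoms)
  if (any(unknown)) {
    warn_raseff(sprintf("unknown atom name(s) treated as side chain: %s",
                        paste(unique(atom_name[unknown]), collapse = ", ")),
                "unknown_atom")
  }
  ifelse(atom_name %in% .main_chain_atoms, "main_chain", "side_chain")
}

#' Intermolecular residue contacts of a complex
#'
#' For every RAS-residue x effector-residue pair, counts heavy-atom pairs at
#' Euclidean distance `<= cutoff` (inclusive) and splits the count into the
#' four main-chain/side-chain categories. A record is emitted only for pairs
#' with at least one qualifying atom pair. `mm_hbond_like` marks pairs with a
#' backbone N-to-backbone O distance of at most 3.5 A in either direction — a
#' geometric proxy for the backbone hydrogen bonds typical of intermolecular
#' beta-sheet contacts; it decorates the record and never filters it.
#'
#' @param complex A `ras_complex` from [parse_structure()].
#' @param cutoff Distance cutoff in Angstrom (default 4.0).
#' @return Tibble of class `contact_records` sorted by (RAS residue, effector
#'   residue): `structure_id`, `ras_resno`, `ras_icode`, `ras_res_name`,
#'   `eff_resno`, `eff_icode`, `eff_res_name`, `min_distance`,
#'   `atom_pairs_total`, `mm`, `ms`, `sm`, `ss`, `mm_hbond_like`.
#' @export
compute_contacts <- function(complex, cutoff = 4.0) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    stop_raseff("cutoff must be a single positive distance in Angstrom", "domain")
  }
  sid <- attr(complex, "structure_id") %||% "complex"
  ras <- complex[complex$role == "ras", ]
  eff <- complex[complex$role == "effector", ]
  empty <- tibble(
    structure_id = character(), ras_resno = integer(), ras_icode = character(),
    ras_res_name = character(), eff_resno = integer(), eff_icode = character(),
    eff_res_name = character(), min_distance = double(),
    atom_pairs_total = integer(), mm = integer(), ms = integer(),
    sm = integer(), ss = integer(), mm_hbond_like = logical()
  )
  if (nrow(ras) == 0 || nrow(eff) == 0) {
    class(empty) <- c("contact_records", class(empty))
    return(empty)
  }

  a <- as.matrix(ras[, c("x", "y", "z")])
  b <- as.matrix(eff[, c("x", "y", "z")])
  # squared cross-distance matrix (n_ras x n_eff)
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  # candidate pairs with a little slack, then exact re-evaluation of the
  # distance per pair so the inclusive boundary is decided by the same
  # arithmetic as a direct all-pairs computation
  hit <- which(d2 <= cutoff^2 + 1e-6, arr.ind = TRUE)
  if (nrow(hit) > 0) {
    delta <- a[hit[, 1], , drop = FALSE] - b[hit[, 2], , drop = FALSE]
    dist <- sqrt(rowSums(delta^2))
    ok <- dist <= cutoff
    hit <- hit[ok, , drop = FALSE]
    dist <- dist[ok]
  } else {
    dist <- double()
  }
  if (nrow(hit) == 0) {
    class(empty) <- c("contact_records", class(empty))
    return(empty)
  }

  ras_cls <- suppressWarnings(classify_atom(ras$res_name, ras$atom_name))
  eff_cls <- suppressWarnings(classify_atom(eff$res_name, eff$atom_name))
  pairs <- tibble(
    ras_resno = ras$resno[hit[, 1]], ras_icode = ras$icode[hit[, 1]],
    ras_res_name = ras$res_name[hit[, 1]],
    eff_resno = eff$resno[hit[, 2]], eff_icode = eff$icode[hit[, 2]],
    eff_res_name = eff$res_name[hit[, 2]],
    distance = dist,
    category = paste0(substr(ras_cls[hit[, 1]], 1, 1),
                      substr(eff_cls[hit[, 2]], 1, 1)),
    hbond_like = (ras$atom_name[hit[, 1]] == "N" & eff$atom_name[hit[, 2]] == "O" |
                    ras$atom_name[hit[, 1]] == "O" & eff$atom_name[hit[, 2]] == "N") &
      dist <= 3.5
  )
  out <- pairs |>
    group_by(.data$ras_resno, .data$ras_icode, .data$ras_res_name,
             .data$eff_resno, .data$eff_icode, .data$eff_res_name) |>
    summarise(
      min_distance = min(.data$distance),
      atom_pairs_total = dplyr::n(),
      mm = sum(.data$category == "mm"),
      ms = sum(.data$category == "ms"),
      sm = sum(.data$category == "sm"),
      ss = sum(.data$category == "ss"),
      mm_hbond_like = any(.data$hbond_like),
      .groups = "drop"
    ) |>
    mutate(structure_id = sid) |>
    arrange(.data$ras_resno, .data$ras_icode, .data$eff_resno, .data$eff_icode) |>
    select("structure_id", dplyr::everything())
  class(out) <- c("contact_records", class(out))
  out
}

#' Write a per-complex contact table as TSV
#'
#' @param contacts A `contact_records` tibble.
#' @param path Output file path.
#' @return The table, invisibly.
#' @export
write_contacts_tsv <- function(contacts, path) {
  readr::write_tsv(as_tibble(contacts), path)
  invisible(contacts)
}
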