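# Independent oracles used across the suite. These deliberately avoid the
# package's vectorised code paths: plain nested loops and root bisection.

# Brute-force all-atom-pairs contact reference: O(n^2) loops, direct distance
# formula, inclusive cutoff.
brute_force_contacts <- function(complex, cutoff) {
  ras <- complex[complex$role == "ras", ]
  eff <- complex[complex$role == "effector", ]
  main <- c("N", "CA", "C", "O", "OXT")
  recs <- list()
  for (i in seq_len(nrow(ras))) {
    for (j in seq_len(nrow(eff))) {
      d <- sqrt((ras$x[i] - eff$x[j])^2 + (ras$y[i] - eff$y[j])^2 +
                  (ras$z[i] - eff$z[j])^2)
      if (d <= cutoff) {
        key <- paste(ras$resno[i], ras$icode[i], eff$resno[j], eff$icode[j],
                     sep = "|")
        cat_r <- if (ras$atom_name[i] %in% main) "m" else "s"
        cat_e <- if (eff$atom_name[j] %in% main) "m" else "s"
        hb <- ((ras$atom_name[i] == "N" && eff$atom_name[j] == "O") ||
                 (ras$atom_name[i] == "O" && eff$atom_name[j] == "N")) && d <= 3.5
        r <- recs[[key]]
        if (is.null(r)) {
          r <- list(ras_resno = ras$resno[i], ras_icode = ras$icode[i],
                    eff_resno = eff$resno[j], eff_icode = eff$icode[j],
                    min_distance = d, total = 0L,
                    mm = 0L, ms = 0L, sm = 0L, ss = 0L, hb = FALSE)
        }
        r$min_distance <- min(r$min_distance, d)
        r$total <- r$total + 1L
        cat_name <- paste0(cat_r, cat_e)
        r[[cat_name]] <- r[[cat_name]] + 1L
        r$hb <- r$hb || hb
        recs[[key]] <- r
      }
    }
  }
  if (length(recs) == 0) {
    return(data.frame(ras_resno = integer(), ras_icode = character(),
                      eff_resno = integer(), eff_icode = character(),
                      min_distance = double(), total = integer(),
                      mm = integer(), ms = integer(), sm = integer(),
                      ss = integer(), hb = logical()))
  }
  out <- do.call(rbind, lapply(recs, as.data.frame))
  out <- out[order(out$ras_resno, out$ras_icode, out$eff_resno, out$eff_icode), ]
  rownames(out) <- NULL
  out
}

# Random two-chain atom cloud as a ras_complex tibble: overlapping boxes so
# contacts actually occur. Independent of make_toy_complex.
random_complex <- function(n_res_per_chain = 8, atoms_per_res = 4, id = "rnd") {
  mk_chain <- function(role, chain, origin) {
    n_atoms <- n_res_per_chain * atoms_per_res
    tibble::tibble(
      role = role, chain = chain,
      resno = rep(seq_len(n_res_per_chain), each = atoms_per_res),
      icode = "",
      res_name = "ALA",
      atom_name = rep(c("N", "CA", "O", "CB")[seq_len(atoms_per_res)],
                      n_res_per_chain),
      element = "C",
      x = runif(n_atoms, origin[1], origin[1] + 20),
      y = runif(n_atoms, origin[2], origin[2] + 20),
      z = runif(n_atoms, origin[3], origin[3] + 20),
      occupancy = 1, altloc = ""
    )
  }
  out <- rbind(mk_chain("ras", "A", c(0, 0, 0)),
               mk_chain("effector", "B", c(4, 4, 4)))
  attr(out, "structure_id") <- id
  class(out) <- c("ras_complex", class(out))
  out
}

# compare contact_records against the brute-force reference, field by field
expect_contacts_equal_oracle <- function(contacts, oracle) {
  expect_equal(nrow(contacts), nrow(oracle))
  if (nrow(oracle) == 0) return(invisible())
  expect_equal(contacts$ras_resno, oracle$ras_resno)
  expect_equal(contacts$eff_resno, oracle$eff_resno)
  expect_equal(contacts$atom_pairs_total, oracle$total)
  expect_equal(contacts$mm, oracle$mm)
  expect_equal(contacts$ms, oracle$ms)
  expect_equal(contacts$sm, oracle$sm)
  expect_equal(contacts$ss, oracle$ss)
  expect_equal(contacts$min_distance, oracle$min_distance, tolerance = 1e-12)
  expect_equal(contacts$mm_hbond_like, oracle$hb)
}

# Bisection root of the mass-action equilibrium K_d = (R_t - x)(E_t - x) / x
# on x in (0, min(R_t, E_t)]; independent of the closed-form quadratic.
bisect_fraction_bound <- function(rt, et, kd, tol = 1e-12) {
  if (et == 0) return(0)
  if (kd == 0) return(min(rt, et) / rt)
  f <- function(x) (rt - x) * (et - x) - kd * x
  root <- uniroot(f, lower = 0, upper = min(rt, et), tol = tol)$root
  root / rt
}

# Three-structure fixture emulating the central recognition block: mm-dominated
# contacts at RAS rows 37-39 x effector columns 66-69, plus one weak decoy
# cell outside the block. Returns everything build_matrix needs.
r1_fixture <- function() {
  ras_aln <- make_toy_alignment(5, first_label = 37, reference_row = "HRAS",
                                row_name = "TOY")
  eff_aln <- make_toy_alignment(5, first_label = 66, reference_row = "CRAF",
                                row_name = "TOY")
  # planted (ras residue, eff residue) mm contacts per structure; ras
  # residues 1..3 -> rows 37..39, eff residues 1..4 -> cols 66..69; cells are
  # shared across structures so per-structure counts exceed 1 inside the block
  plan <- list(
    s1 = list(c(1, 1), c(2, 2), c(3, 3)),
    s2 = list(c(1, 1), c(2, 2), c(3, 4)),
    s3 = list(c(1, 1), c(2, 2), c(3, 3))
  )
  contacts <- list(); ras_maps <- list(); eff_maps <- list()
  for (sid in names(plan)) {
    specs <- lapply(plan[[sid]], function(p) {
      list(ras_index = p[1], eff_index = p[2], distance = 3.0, category = "mm")
    })
    # side-chain contacts in the top cell of the block (mm still dominates)
    # and one weak decoy at row 41 x col 70, present in s1 only
    if (sid %in% c("s1", "s2")) {
      specs <- c(specs, list(
        list(ras_index = 1, eff_index = 1, distance = 3.8, category = "ss")))
    }
    if (sid == "s1") {
      specs <- c(specs, list(
        list(ras_index = 5, eff_index = 5, distance = 3.5, category = "ss")))
    }
    toy <- make_toy_complex(specs, chain_lengths = c(5, 5), structure_id = sid)
    cx <- parse_structure(toy$pdb_text, "A", "B", structure_id = sid)
    contacts[[sid]] <- compute_contacts(cx, 4.0)
    ras_maps[[sid]] <- map_chain(complex_residues(cx, "ras"),
                                 ras_aln$alignment, "TOY",
                                 reference = ras_aln$reference)
    eff_maps[[sid]] <- map_chain(complex_residues(cx, "effector"),
                                 eff_aln$alignment, "TOY",
                                 reference = eff_aln$reference)
  }
  list(contacts = contacts, ras_maps = ras_maps, eff_maps = eff_maps,
       ras_aln = ras_aln, eff_aln = eff_aln)
}
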