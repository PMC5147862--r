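# small helper: one toy structure with given planted contacts, mapped onto
# reference frames starting at row 37 / col 66
toy_mapped <- function(specs, sid) {
  ras_aln <- make_toy_alignment(5, first_label = 37, reference_row = "HRAS",
                                row_name = "TOY")
  eff_aln <- make_toy_alignment(5, first_label = 66, reference_row = "CRAF",
                                row_name = "TOY")
  toy <- make_toy_complex(specs, chain_lengths = c(5, 5), structure_id = sid)
  cx <- parse_structure(toy$pdb_text, "A", "B", structure_id = sid)
  list(contacts = compute_contacts(cx, 4.0),
       ras_map = map_chain(complex_residues(cx, "ras"), ras_aln$alignment,
                           "TOY", reference = ras_aln$reference),
       eff_map = map_chain(complex_residues(cx, "effector"), eff_aln$alignment,
                           "TOY", reference = eff_aln$reference))
}

test_that("per-structure mode counts complexes, atom-pairs mode counts pairs", {
  spec_37_68 <- list(list(ras_index = 1, eff_index = 3, distance = 3.0,
                          category = "mm"))
  a <- toy_mapped(spec_37_68, "s1")
  b <- toy_mapped(spec_37_68, "s2")
  contacts <- dplyr::bind_rows(a$contacts, b$contacts)
  maps_r <- list(s1 = a$ras_map, s2 = b$ras_map)
  maps_e <- list(s1 = a$eff_map, s2 = b$eff_map)

  m_ps <- build_matrix(contacts, maps_r, maps_e, mode = "per-structure")
  expect_equal(m_ps$counts["37", "68"], 2L)
  expect_equal(m_ps$n_structures, 2)
  expect_true(all(m_ps$counts <= m_ps$n_structures))

  # one structure with mm=2 (two residue pairs... use one pair with 2 mm + 1 ss)
  specs <- list(
    list(ras_index = 2, eff_index = 2, distance = 3.0, category = "mm"),
    list(ras_index = 2, eff_index = 2, distance = 3.8, category = "ss")
  )
  d <- toy_mapped(specs, "s3")
  m_ap <- build_matrix(d$contacts, list(s3 = d$ras_map), list(s3 = d$eff_map),
                       mode = "atom-pairs")
  expect_equal(m_ap$counts["38", "67"], 2L)
  m_ps2 <- build_matrix(d$contacts, list(s3 = d$ras_map), list(s3 = d$eff_map),
                        mode = "per-structure")
  expect_equal(m_ps2$counts["38", "67"], 1L)
})

test_that("zero structures is an error", {
  expect_error(build_matrix(list(), list(), list()),
               class = "raseffector_error_empty_input")
})

test_that("conservation and category closure hold in atom-pairs mode", {
  fx <- r1_fixture()
  contacts <- dplyr::bind_rows(fx$contacts)
  m <- build_matrix(contacts, fx$ras_maps, fx$eff_maps, mode = "atom-pairs")
  expect_equal(sum(m$counts), sum(contacts$atom_pairs_total))
  closure <- m$categories$mm + m$categories$ms + m$categories$sm + m$categories$ss
  expect_identical(unname(closure), unname(m$counts))
})

test_that("structure input order does not change the matrix or regions", {
  fx <- r1_fixture()
  m1 <- build_matrix(dplyr::bind_rows(fx$contacts),
                     fx$ras_maps, fx$eff_maps)
  m2 <- build_matrix(dplyr::bind_rows(rev(fx$contacts)),
                     rev(fx$ras_maps), rev(fx$eff_maps))
  expect_identical(m1$counts, m2$counts)
  expect_identical(m1$categories, m2$categories)
  r1 <- detect_regions(m1); r2 <- detect_regions(m2)
  expect_identical(r1$region, r2$region)
  expect_identical(r1$cells, r2$cells)
})

test_that("unmappable residues are skipped and reported, never new rows", {
  fx <- r1_fixture()
  contacts <- dplyr::bind_rows(fx$contacts)
  # forge one contact at a residue number absent from the maps
  bogus <- contacts[1, ]
  bogus$ras_resno <- 999L
  expect_warning(
    m <- build_matrix(dplyr::bind_rows(contacts, bogus),
                      fx$ras_maps, fx$eff_maps),
    class = "raseffector_warning_unmappable_contacts")
  expect_equal(nrow(m$skip_report), 1)
  expect_false("999" %in% m$row_labels)
})

test_that("detect_regions recovers planted blocks exactly", {
  # k = 1..5 planted blocks, default parameters
  for (k in 1:5) {
    blocks <- lapply(seq_len(k), function(i) {
      list(row_span = c(1 + (i - 1) * 6, 2 + (i - 1) * 6),
           col_span = c(1 + (i - 1) * 6, 2 + (i - 1) * 6), count = 2 + i)
    })
    pm <- make_planted_matrix(blocks, shape = c(32, 32))
    regs <- detect_regions(pm$matrix)
    expect_equal(nrow(regs), k)
    got <- lapply(seq_len(nrow(regs)), function(i) {
      cells <- regs$cells[[i]][, c("row", "col")]
      cells[order(cells$row, cells$col), ]
    })
    want <- lapply(pm$truth, function(tt) {
      tt <- as.data.frame(tt); tt[order(tt$row, tt$col), ]
    })
    # regions are ranked by total count; compare as sets of cell sets
    sig <- function(cells) paste(cells$row, cells$col, collapse = ";")
    expect_setequal(vapply(got, sig, ""), vapply(want, sig, ""))
  }
})

test_that("region labels rank by total count and empty matrices give none", {
  expect_equal(nrow(detect_regions(matrix(0, 10, 10))), 0)
  pm <- make_planted_matrix(list(
    list(row_span = c(1, 2), col_span = c(1, 2), count = 2),   # total 8
    list(row_span = c(10, 11), col_span = c(10, 11), count = 5) # total 20
  ), shape = c(20, 20))
  regs <- detect_regions(pm$matrix)
  expect_equal(regs$region, c("R1", "R2"))
  expect_equal(regs$total_count, c(20, 8))
  # single block: total_count equals the planted sum
  pm1 <- make_planted_matrix(list(
    list(row_span = c(3, 4), col_span = c(5, 6), count = 3)), shape = c(10, 10))
  r <- detect_regions(pm1$matrix)
  expect_equal(nrow(r), 1)
  expect_equal(r$total_count, 12)
})

test_that("bridge joins blocks across small gaps", {
  m <- matrix(0L, 10, 10)
  m[1:2, 1:2] <- 3L
  m[1:2, 5:6] <- 3L  # gap of 2 empty columns
  expect_equal(nrow(detect_regions(m, min_count = 2, min_cells = 3, bridge = 0)), 2)
  expect_equal(nrow(detect_regions(m, min_count = 2, min_cells = 3, bridge = 2)), 1)
})

test_that("hotspot report flags the central block rows as main-chain dominated", {
  fx <- r1_fixture()
  m <- build_matrix(dplyr::bind_rows(fx$contacts), fx$ras_maps, fx$eff_maps)
  # matrix maxima fall inside rows 37-39 x cols 66-69
  top <- which(m$counts == max(m$counts), arr.ind = TRUE)
  expect_true(all(m$row_labels[top[, 1]] %in% as.character(37:39)))
  expect_true(all(m$col_labels[top[, 2]] %in% as.character(66:69)))

  regs <- detect_regions(m)
  expect_gte(nrow(regs), 1)
  rep <- hotspot_report(m, regs, top_k = 5)
  r1_cells <- rep$top_cells[rep$top_cells$region == "R1", ]
  expect_true(all(c("37", "38") %in% r1_cells$row_label))
  expect_true(all(r1_cells$dominant[r1_cells$row_label %in% c("37", "38")] == "mm"))
  expect_true(all(r1_cells$frac_structures <= 1))

  # marginal conservation: row totals sum to the total cell mass
  expect_equal(sum(rep$row_marginals$total), sum(m$counts))
  expect_equal(sum(rep$col_marginals$total), sum(m$counts))

  # empty region list -> header-only report
  empty_rep <- hotspot_report(m, detect_regions(matrix(0, 2, 2)))
  expect_equal(nrow(empty_rep$top_cells), 0)
})

test_that("tidy and outputs round-trip the matrix content", {
  fx <- r1_fixture()
  m <- build_matrix(dplyr::bind_rows(fx$contacts), fx$ras_maps, fx$eff_maps,
                    mode = "atom-pairs")
  long <- tidy(m)
  expect_equal(sum(long$count), sum(m$counts))
  dir <- withr::local_tempdir()
  files <- write_matrix_outputs(m, dir, regions = detect_regions(m))
  expect_true(all(file.exists(files)))
  counts_back <- readr::read_tsv(file.path(dir, "interaction_matrix_counts.tsv"),
                                 show_col_types = FALSE)
  expect_equal(sum(counts_back[, -1]), sum(m$counts))
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})

test_that("the shipped region annotation is labeling-only metadata", {
  ann <- read_region_annotation()
  expect_true(all(c("R1", "R2", "R3") %in% names(ann$regions)))
  expect_equal(sort(unlist(ann$regions$R1$rows)), c(37, 38, 39))
  expect_equal(sort(unlist(ann$regions$R1$cols)), 66:69)
})
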