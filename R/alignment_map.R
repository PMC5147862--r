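# Alignment handling: the multiple sequence alignments are curated inputs,
# pre-synchronized with the superposed structures by the user. This module
# never re-aligns; it only maps structure residues onto alignment columns and
# alignment columns onto the common reference numbering (HRAS numbering on the
# RAS side, CRAF numbering on the effector side).

#' Parse a multiple sequence alignment
#'
#' Auto-detects aligned FASTA (leading `>`) versus Clustal (header line)
#' dialects. Sequences are upper-cased and `.` gap characters normalised to
#' `-`.
#'
#' @param text Alignment text (character scalar or vector of lines).
#' @return An object of class `msa_alignment`: a list with `rows` (named
#'   character vector of gapped sequences) and `length` (column count).
#' @examples
#' aln <- parse_alignment(">A\nAC-D\n>B\nACED\n")
#' aln$length
#' @export
parse_alignment <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  first <- lines[grepl("\\S", lines)][1]
  if (is.na(first)) stop_raseff("empty alignment text", "malformed_input")
  is_fasta <- startsWith(trimws(first), ">")

  if (is_fasta) {
    # check raggedness up front so we can raise a classed error
    hdr <- grep("^>", lines)
    if (length(hdr) == 0) stop_raseff("no FASTA records found", "malformed_input")
    names_raw <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
    bounds <- c(hdr, length(lines) + 1L)
    seqs <- vapply(seq_along(hdr), function(i) {
      body <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
      gsub("\\s", "", paste(body[!grepl("^>", body)], collapse = ""))
    }, character(1))
  } else {
    # Clustal: normalise header/blank-line layout, then delegate to Biostrings
    if (!grepl("^CLUSTAL", trimws(first), ignore.case = TRUE)) {
      stop_raseff("text is neither aligned FASTA nor Clustal", "malformed_input")
    }
    body <- lines[-match(first, lines)]
    body <- body[grepl("\\S", body)]
    # drop conservation lines (only space/*/:/.)
    body <- body[!grepl("^[\\s*:.]*$", body, perl = TRUE)]
    tf <- tempfile(fileext = ".aln")
    on.exit(unlink(tf), add = TRUE)
    writeLines(c("CLUSTAL W multiple sequence alignment", "", "", body), tf)
    aln <- tryCatch(
      Biostrings::readAAMultipleAlignment(tf, format = "clustal"),
      error = function(e) {
        msg <- conditionMessage(e)
        cls <- if (grepl("unequal", msg)) "ragged_alignment" else "malformed_input"
        stop_raseff(paste0("failed to parse Clustal alignment: ", msg), cls)
      }
    )
    seqs <- as.character(aln)
    names_raw <- names(seqs)
  }

  if (anyDuplicated(names_raw)) {
    stop_raseff(sprintf("duplicate row name(s): %s",
                        paste(unique(names_raw[duplicated(names_raw)]), collapse = ", ")),
                "duplicate_row")
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1) {
    stop_raseff("alignment rows have unequal lengths", "ragged_alignment")
  }
  rows <- toupper(gsub(".", "-", seqs, fixed = TRUE))
  names(rows) <- names_raw
  structure(list(rows = rows, length = unname(widths[1])), class = "msa_alignment")
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat(sprintf("<msa_alignment: %d rows x %d columns>\n", length(x$rows), x$length))
  for (nm in head(names(x$rows), 10)) {
    cat(sprintf("  %-12s %s\n", nm, substr(x$rows[[nm]], 1, 60)))
  }
  invisible(x)
}

# columns (0-based) of the non-gap positions of a row
row_positions <- function(row_seq) {
  chars <- strsplit(row_seq, "")[[1]]
  which(chars != "-") - 1L
}

#' Reference numbering of alignment columns
#'
#' Numbers the non-gap columns of a reference row consecutively from
#' `start_number` (e.g. HRAS numbering from Met-1). Gap columns in the
#' reference row carry no number and are labeled by the nearest preceding
#' number plus an insertion suffix (`"31A"`, `"31B"`, ...).
#'
#' @param alignment An `msa_alignment`.
#' @param reference_row Name of the reference row.
#' @param start_number Author number of the first reference residue.
#' @return Tibble with one row per alignment column: `column` (0-based),
#'   `label` (character reference label), `number` (integer, `NA` on
#'   insertion columns), `is_reference` (logical).
#' @export
reference_numbering <- function(alignment, reference_row, start_number = 1) {
  if (!reference_row %in% names(alignment$rows)) {
    stop_raseff(sprintf("reference row '%s' not in alignment", reference_row),
                "row_not_found")
  }
  chars <- strsplit(alignment$rows[[reference_row]], "")[[1]]
  n <- length(chars)
  if (n == 0 || all(chars == "-")) {
    return(tibble(column = integer(), label = character(),
                  number = integer(), is_reference = logical()))
  }
  number <- rep(NA_integer_, n)
  number[chars != "-"] <- seq.int(start_number, length.out = sum(chars != "-"))
  label <- character(n)
  last <- start_number - 1L
  ins <- 0L
  for (i in seq_len(n)) {
    if (chars[i] != "-") {
      last <- number[i]; ins <- 0L
      label[i] <- as.character(last)
    } else {
      ins <- ins + 1L
      label[i] <- paste0(last, LETTERS[ins])
    }
  }
  tibble(column = seq_len(n) - 1L, label = label, number = number,
         is_reference = chars != "-")
}

# exhaustive offset scan of chain sequence against the ungapped row, allowing
# overhang on either end; returns best (offset, matches, overlap)
best_offset <- function(chain_seq, row_ungapped) {
  a <- strsplit(chain_seq, "")[[1]]
  b <- strsplit(row_ungapped, "")[[1]]
  n <- length(a); m <- length(b)
  best <- list(offset = NA_integer_, matches = -1L, overlap = 0L)
  for (o in seq.int(-(n - 1L), m - 1L)) {
    i1 <- max(1L, 1L - o); i2 <- min(n, m - o)
    if (i2 < i1) next
    idx <- i1:i2
    matches <- sum(a[idx] == b[idx + o])
    if (matches > best$matches) {
      best <- list(offset = o, matches = matches, overlap = length(idx))
    }
  }
  best
}

#' Map structure residues onto alignment columns
#'
#' Assigns each residue of a parsed chain to the alignment column of its
#' matching position in the named row. Matching is by exact ungapped substring
#' (left-most placement on ties, with a warning); failing that, an exhaustive
#' offset scan is used and accepted when identity over the aligned overlap is
#' at least `min_identity`. Structure residues overhanging the row (e.g.
#' expression tags) are dropped with a warning.
#'
#' @param chain Residue tibble for one chain, as returned by
#'   [complex_residues()] (needs columns `resno`, `icode`, `aa`).
#' @param alignment An `msa_alignment`.
#' @param row_name Row holding this protein's sequence.
#' @param reference A reference-numbering tibble from [reference_numbering()],
#'   attached to the map for downstream matrix labeling (optional).
#' @param min_identity Identity threshold for inexact placements.
#' @return Object of class `alignment_map`: list with `protein_name`,
#'   `residues` (tibble `resno`, `icode`, `aa`, `column`) and `reference`.
#' @export
map_chain <- function(chain, alignment, row_name, reference = NULL,
                      min_identity = 0.95) {
  if (!row_name %in% names(alignment$rows)) {
    stop_raseff(sprintf("row '%s' not in alignment", row_name), "row_not_found")
  }
  if ("aa" %in% names(chain)) {
    aa <- chain$aa
  } else {
    aa <- one_letter_code(chain$res_name)
  }
  aa[is.na(aa)] <- "X"
  chain_seq <- paste(aa, collapse = "")
  row_seq <- alignment$rows[[row_name]]
  cols <- row_positions(row_seq)
  ungapped <- gsub("-", "", row_seq, fixed = TRUE)
  n <- nchar(chain_seq)

  hits <- gregexpr(chain_seq, ungapped, fixed = TRUE)[[1]]
  if (hits[1] != -1) {
    if (length(hits) > 1) {
      warn_raseff(sprintf("sequence of '%s' matches row at %d positions; using left-most",
                          row_name, length(hits)), "ambiguous_placement")
    }
    offset <- hits[1] - 1L
    keep <- seq_len(n)
  } else {
    best <- best_offset(chain_seq, ungapped)
    identity <- best$matches / best$overlap
    if (!is.finite(identity) || identity < min_identity) {
      a <- strsplit(chain_seq, "")[[1]]
      b <- strsplit(ungapped, "")[[1]]
      o <- if (is.na(best$offset)) 0L else best$offset
      idx <- max(1L, 1L - o):min(n, length(b) - o)
      bad <- idx[a[idx] != b[idx + o]]
      first_bad <- if (length(bad)) bad[1] else 1L
      stop_raseff(sprintf(
        "chain sequence does not match alignment row '%s' (best identity %.1f%%); first conflicting residue: %s%d",
        row_name, 100 * max(identity, 0), aa[first_bad], chain$resno[first_bad]),
        "sequence_mismatch")
    }
    offset <- best$offset
    keep <- which(seq_len(n) + offset >= 1L & seq_len(n) + offset <= nchar(ungapped))
    if (length(keep) < n) {
      warn_raseff(sprintf("%d unmatched leading/trailing residue(s) dropped for row '%s'",
                          n - length(keep), row_name), "overhang_dropped")
    }
    mism <- best$overlap - best$matches
    if (mism > 0) {
      warn_raseff(sprintf("row '%s': placed with %d mismatch(es) (identity %.1f%%)",
                          row_name, mism, 100 * best$matches / best$overlap),
                  "inexact_placement")
    }
  }

  residues <- tibble(
    resno = chain$resno[keep],
    icode = if ("icode" %in% names(chain)) chain$icode[keep] else "",
    aa = aa[keep],
    column = cols[keep + offset]
  )
  structure(list(protein_name = row_name, residues = residues,
                 reference = reference),
            class = "alignment_map")
}

#' @export
print.alignment_map <- function(x, ...) {
  cat(sprintf("<alignment_map: %s, %d residues mapped%s>\n", x$protein_name,
              nrow(x$residues),
              if (is.null(x$reference)) "" else ", reference attached"))
  invisible(x)
}

#' Column/reference correspondence table for an alignment
#'
#' Tabulates, for every alignment column, the reference label and the residue
#' character of each row — the synchronized frame onto which all structures
#' are projected.
#'
#' @inheritParams reference_numbering
#' @return Tibble with `column_index` (0-based), `reference_label`, and one
#'   character column per alignment row.
#' @export
alignment_reference_table <- function(alignment, reference_row, start_number = 1) {
  ref <- reference_numbering(alignment, reference_row, start_number)
  chars <- lapply(alignment$rows, function(s) strsplit(s, "")[[1]])
  out <- tibble(column_index = ref$column, reference_label = ref$label)
  for (nm in names(chars)) out[[nm]] <- chars[[nm]]
  out
}

#' Write the column/reference table as TSV
#'
#' @inheritParams alignment_reference_table
#' @param path Output file path.
#' @return The table, invisibly.
#' @export
write_alignment_map_tsv <- function(alignment, reference_row, path,
                                    start_number = 1) {
  tab <- alignment_reference_table(alignment, reference_row, start_number)
  readr::write_tsv(tab, path)
  invisible(tab)
}
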