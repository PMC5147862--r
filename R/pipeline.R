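# End-to-end workflows tying the stages together: the structural workflow
# (parse -> map -> contacts -> matrix -> regions -> report) and the affinity
# workflow (read titrations -> fit -> publication-shaped K_d table).

default_run_config <- function() {
  list(cutoff = 4.0, mode = "per-structure",
       region = list(min_count = 2, min_cells = 3, bridge = 1))
}

merge_config <- function(config) {
  base <- default_run_config()
  utils::modifyList(base, config)
}

#' Run the interaction-matrix workflow
#'
#' Executes parse -> alignment mapping -> contact computation -> matrix
#' aggregation -> region detection -> hotspot report for a set of complex
#' structures, optionally writing all tabular outputs to a directory. Errors
#' at any stage are re-raised with the stage name and offending structure id.
#'
#' @param config A list (or path to a JSON file) with elements:
#'   \describe{
#'     \item{structures}{list of entries, each with `pdb_text` *or* `path`,
#'       `id`, `ras_chain`, `effector_chain`, `ras_row`, `effector_row`, and
#'       optional `model_index`.}
#'     \item{ras_alignment, effector_alignment}{alignment text, a file path,
#'       or an `msa_alignment` object.}
#'     \item{ras_reference, effector_reference}{lists with `row` and `start`
#'       giving the reference row name and its first author number.}
#'     \item{cutoff}{contact cutoff in A (default 4.0).}
#'     \item{mode}{`"per-structure"` or `"atom-pairs"`.}
#'     \item{region}{list `min_count`, `min_cells`, `bridge`.}
#'     \item{out_dir}{optional output directory.}
#'   }
#' @return List with `matrix` (an `interaction_matrix`), `regions`, `report`,
#'   `contacts` (combined contact records) and `skip_report`.
#' @export
run_matrix_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  }
  config <- merge_config(config)
  if (length(config$structures %||% list()) == 0) {
    stop_raseff("config lists no structures", "empty_input")
  }
  if (is.null(config$ras_alignment) || is.null(config$effector_alignment)) {
    stop_raseff("both RAS and effector alignments are required", "empty_input")
  }

  stage <- function(name, id, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("[stage %s | %s] %s", name, id, conditionMessage(e)),
                   class = class(e)[1], parent = e)
    })
  }

  load_alignment <- function(x, what) {
    if (inherits(x, "msa_alignment")) return(x)
    txt <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
    stage("parse_alignment", what, parse_alignment(txt))
  }
  ras_aln <- load_alignment(config$ras_alignment, "ras")
  eff_aln <- load_alignment(config$effector_alignment, "effector")
  ras_refspec <- config$ras_reference %||% list(row = names(ras_aln$rows)[1], start = 1)
  eff_refspec <- config$effector_reference %||% list(row = names(eff_aln$rows)[1], start = 1)
  ras_ref <- reference_numbering(ras_aln, ras_refspec$row, ras_refspec$start %||% 1)
  eff_ref <- reference_numbering(eff_aln, eff_refspec$row, eff_refspec$start %||% 1)

  contacts <- list(); ras_maps <- list(); eff_maps <- list()
  for (st in config$structures) {
    id <- st$id %||% "structure"
    txt <- if (!is.null(st$pdb_text)) st$pdb_text else readLines(st$path)
    cx <- stage("parse_structure", id,
                parse_structure(txt, st$ras_chain, st$effector_chain,
                                model_index = st$model_index %||% 1,
                                structure_id = id))
    ras_maps[[id]] <- stage("map_chain", id,
                            map_chain(complex_residues(cx, "ras"), ras_aln,
                                      st$ras_row, reference = ras_ref))
    eff_maps[[id]] <- stage("map_chain", id,
                            map_chain(complex_residues(cx, "effector"), eff_aln,
                                      st$effector_row, reference = eff_ref))
    contacts[[id]] <- stage("compute_contacts", id,
                            compute_contacts(cx, cutoff = config$cutoff))
  }

  all_contacts <- dplyr::bind_rows(contacts)
  mat <- stage("build_matrix", "all",
               build_matrix(all_contacts, ras_maps, eff_maps, mode = config$mode))
  regions <- stage("detect_regions", "all",
                   detect_regions(mat,
                                  min_count = config$region$min_count,
                                  min_cells = config$region$min_cells,
                                  bridge = config$region$bridge))
  report <- hotspot_report(mat, regions)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_contacts_tsv(all_contacts, file.path(config$out_dir, "contacts.tsv"))
    write_matrix_outputs(mat, config$out_dir, regions = regions)
    readr::write_tsv(report$top_cells, file.path(config$out_dir, "hotspots.tsv"))
  }
  list(matrix = mat, regions = regions, report = report,
       contacts = all_contacts, skip_report = mat$skip_report)
}

#' Run the affinity workflow over a batch of titrations
#'
#' Fits every titration in the manifest with the quadratic isotherm and
#' assembles the fitted K_d values into a publication-shaped wide table
#' (rows = effector domains, columns = RAS proteins). Curves that fail to fit
#' leave an `NA` cell and a reason in the diagnostics, without aborting the
#' batch.
#'
#' @param manifest A tibble/data frame with columns `ras`, `effector` and
#'   either `file` (TSV path, see [read_titration_tsv()]) or `curve`
#'   (list-column of `titration_curve` objects); alternatively the path to a
#'   JSON manifest with entries `{file, ras, effector}`.
#' @param receptor_total Receptor concentration used when reading files, uM.
#' @param out_dir Optional directory for the K_d table TSV and per-fit JSON
#'   diagnostics.
#' @return List with `kd_table` (wide tibble, effectors x RAS), `fits`
#'   (named list of `binding_fit`), `diagnostics` (long tibble with `ras`,
#'   `effector`, `kd`, `stderr_kd`, `converged`, `error`).
#' @export
run_affinity_pipeline <- function(manifest, receptor_total = 1, out_dir = NULL) {
  if (is.character(manifest) && length(manifest) == 1) {
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE) |> as_tibble()
  }
  manifest <- as_tibble(manifest)
  if (nrow(manifest) == 0) stop_raseff("empty titration manifest", "empty_input")
  if (!all(c("ras", "effector") %in% names(manifest))) {
    stop_raseff("manifest needs ras and effector columns", "malformed_input")
  }

  diag <- purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    curve <- tryCatch({
      if ("curve" %in% names(manifest)) {
        row$curve[[1]]
      } else {
        if (!file.exists(row$file)) {
          stop_raseff(sprintf("titration file not found: %s", row$file), "named_file")
        }
        read_titration_tsv(row$file, receptor_total = receptor_total,
                           ras = row$ras, effector = row$effector)
      }
    }, raseffector_error = function(e) e)
    if (inherits(curve, "error")) {
      return(tibble(ras = row$ras, effector = row$effector, kd = NA_real_,
                    stderr_kd = NA_real_, converged = NA,
                    error = conditionMessage(curve), fit = list(NULL)))
    }
    fit <- tryCatch(fit_titration(curve), error = function(e) e)
    if (inherits(fit, "error")) {
      tibble(ras = row$ras, effector = row$effector, kd = NA_real_,
             stderr_kd = NA_real_, converged = NA,
             error = conditionMessage(fit), fit = list(NULL))
    } else {
      tibble(ras = row$ras, effector = row$effector, kd = fit$kd,
             stderr_kd = fit$stderr_kd, converged = fit$converged,
             error = NA_character_, fit = list(fit))
    }
  })

  canon <- reference_kd_table()
  eff_levels <- union(unique(canon$effector), unique(diag$effector))
  ras_levels <- union(unique(canon$ras), unique(diag$ras))
  kd_table <- diag |>
    mutate(effector = factor(.data$effector,
                             levels = intersect(eff_levels, .data$effector)),
           ras = factor(.data$ras, levels = intersect(ras_levels, .data$ras))) |>
    select("effector", "ras", "kd") |>
    tidyr::pivot_wider(names_from = "ras", values_from = "kd") |>
    arrange(.data$effector) |>
    mutate(effector = as.character(.data$effector))

  fits <- setNames(diag$fit, paste(diag$ras, diag$effector, sep = "/"))
  diagnostics <- select(diag, -"fit")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(kd_table, file.path(out_dir, "kd_table.tsv"))
    jsonlite::write_json(diagnostics, file.path(out_dir, "fit_diagnostics.json"),
                         digits = NA, pretty = TRUE)
  }
  list(kd_table = kd_table, fits = fits, diagnostics = diagnostics)
}
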