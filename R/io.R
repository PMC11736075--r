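#' Read a sample genotype table
#'
#' Reads a delimited (CSV or TSV, inferred from the extension) table with one
#' row per sample: the metadata columns `sample_id`, `tree_id`, `location`,
#' `cohort`, `putative_cultivar`, `pomological_cultivar`, `trueness`, `ploidy`,
#' followed by one column per panel marker holding colon-separated AFLs
#' (`"0"` = null call). Row order is preserved: downstream molecular-group
#' identifiers are assigned from first appearance in file order, so the file
#' order is part of the dataset's identity.
#'
#' @param path Path to the table.
#' @param panel Marker panel ([default_marker_panel()] by default).
#' @return A sample tibble: the metadata columns plus one list-column per
#'   marker, each element a sorted integer vector of AFLs (empty = null call).
#' @export
read_sample_table <- function(path, panel = default_marker_panel()) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  missing_markers <- setdiff(marker_names(panel), names(raw))
  if (length(missing_markers) > 0L) {
    abort(sprintf("sample table is missing marker column(s): %s",
                  paste(missing_markers, collapse = ", ")),
          class = "ssr_schema_error")
  }
  missing_meta <- setdiff("sample_id", names(raw))
  if (length(missing_meta) > 0L) {
    abort("sample table is missing the sample_id column", class = "ssr_schema_error")
  }
  if (anyDuplicated(raw$sample_id)) {
    dups <- unique(raw$sample_id[duplicated(raw$sample_id)])
    abort(sprintf("duplicate sample_id(s): %s", paste(dups, collapse = ", ")),
          class = "ssr_duplicate_error")
  }
  out <- tibble(
    sample_id = raw$sample_id,
    tree_id = raw[["tree_id"]] %||% NA_character_,
    location = raw[["location"]] %||% NA_character_,
    cohort = raw[["cohort"]] %||% NA_character_,
    putative_cultivar = raw[["putative_cultivar"]] %||% NA_character_,
    pomological_cultivar = raw[["pomological_cultivar"]] %||% NA_character_,
    trueness = raw[["trueness"]] %||% NA_character_,
    ploidy = suppressWarnings(as.integer(raw[["ploidy"]] %||% NA_character_))
  )
  if (!all(is.na(out$cohort) | out$cohort %in% valid_cohorts())) {
    bad <- setdiff(unique(stats::na.omit(out$cohort)), valid_cohorts())
    abort(sprintf("unknown cohort label(s): %s", paste(bad, collapse = ", ")),
          class = "ssr_schema_error")
  }
  for (m in marker_names(panel)) {
    out[[m]] <- purrr::imap(raw[[m]], function(cell, i) {
      parse_one_allele_field(if (is.na(cell)) "0" else cell,
                             context = sprintf("row %d, column %s", i, m))
    })
  }
  out
}

#' Write a sample genotype table
#'
#' Inverse of [read_sample_table()]: marker list-columns are serialized back to
#' colon-separated ascending AFL strings with `"0"` for null calls, so a
#' read/write round trip is lossless.
#'
#' @param samples Sample tibble.
#' @param path Output path (`.csv` or `.tsv`).
#' @param panel Marker panel; defines marker-column order in the output.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path, panel = default_marker_panel()) {
  flat <- samples[intersect(sample_meta_cols(), names(samples))]
  for (m in marker_names(panel)) {
    flat[[m]] <- format_allele_field(samples[[m]])
  }
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(flat, path, progress = FALSE)
  } else {
    readr::write_csv(flat, path, progress = FALSE)
  }
  invisible(path)
}

#' Write a consensus genotype table
#'
#' Serializes a consensus table (one row per molecular group, from
#' [build_consensus()]) to CSV, mirroring the column roles of published
#' genebank fingerprint tables: cultivar name, group identifier, aggregated
#' trueness-to-type code, ploidy, then one column per marker with
#' colon-joined ascending AFLs (`"0"` for a null consensus call).
#'
#' @param consensus Consensus tibble from [build_consensus()].
#' @param path Output CSV path.
#' @param panel Marker panel; defines marker-column order.
#' @return `path`, invisibly.
#' @export
write_consensus_table <- function(consensus, path, panel = default_marker_panel()) {
  stopifnot(nrow(consensus) > 0L)
  meta <- intersect(c("cultivar_name", "group_id", "trueness", "ploidy", "n_samples"),
                    names(consensus))
  flat <- consensus[meta]
  for (m in marker_names(panel)) {
    flat[[m]] <- format_allele_field(consensus[[m]])
  }
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}

#' Read a consensus genotype table written by [write_consensus_table()]
#'
#' @param path CSV path.
#' @param panel Marker panel.
#' @return A consensus tibble with marker list-columns.
#' @export
read_consensus_table <- function(path, panel = default_marker_panel()) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"), progress = FALSE)
  missing_markers <- setdiff(marker_names(panel), names(raw))
  if (length(missing_markers) > 0L) {
    abort(sprintf("consensus table is missing marker column(s): %s",
                  paste(missing_markers, collapse = ", ")),
          class = "ssr_schema_error")
  }
  out <- raw[setdiff(names(raw), marker_names(panel))]
  if ("ploidy" %in% names(out)) out$ploidy <- suppressWarnings(as.integer(out$ploidy))
  if ("n_samples" %in% names(out)) out$n_samples <- suppressWarnings(as.integer(out$n_samples))
  out <- as_tibble(out)
  for (m in marker_names(panel)) {
    out[[m]] <- purrr::imap(raw[[m]], function(cell, i) {
      parse_one_allele_field(if (is.na(cell)) "0" else cell,
                             context = sprintf("row %d, column %s", i, m))
    })
  }
  out
}
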