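#' Read a marker-panel definition
#'
#' A marker panel lists the SSR markers of a fingerprinting assay in reporting
#' order, with a locus-type flag per marker (`single`, `multi`, or `unknown`)
#' and, optionally, a cross-cohort shift-correction rule (see
#' [shift_correct()]). Panels are stored as YAML; the default panel shipped
#' with the package is the 17-marker apple set, where Hi02c07 and CH04e05 are
#' flagged multi-locus and GD12 unknown.
#'
#' @param path Path to a panel YAML file.
#' @return A tibble with one row per marker and columns `marker`,
#'   `locus_type`, `forward_primer`, `reverse_primer`, `shift_window_low`,
#'   `shift_window_high`, `shift_bp`, `shift_cohort`. Row order is the panel's
#'   reporting order and defines marker-column order in all output tables.
#' @examples
#' panel <- default_marker_panel()
#' panel$marker
#' @export
read_marker_panel <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$markers) || length(raw$markers) == 0L) {
    abort("panel file contains no markers", class = "ssr_panel_error")
  }
  rows <- purrr::map(raw$markers, function(m) {
    if (is.null(m$name) || !nzchar(m$name)) {
      abort("panel marker with empty name", class = "ssr_panel_error")
    }
    lt <- m$locus_type %||% "unknown"
    if (!lt %in% c("single", "multi", "unknown")) {
      abort(sprintf("marker %s: invalid locus_type '%s'", m$name, lt),
            class = "ssr_panel_error")
    }
    sr <- m$shift_rule
    if (!is.null(sr) && sr$window_low_bp >= sr$window_high_bp) {
      abort(sprintf("marker %s: shift window is empty", m$name),
            class = "ssr_panel_error")
    }
    tibble(
      marker = m$name,
      locus_type = lt,
      forward_primer = m$forward_primer %||% NA_character_,
      reverse_primer = m$reverse_primer %||% NA_character_,
      shift_window_low = if (is.null(sr)) NA_integer_ else as.integer(sr$window_low_bp),
      shift_window_high = if (is.null(sr)) NA_integer_ else as.integer(sr$window_high_bp),
      shift_bp = if (is.null(sr)) NA_integer_ else as.integer(sr$shift_bp),
      shift_cohort = if (is.null(sr)) NA_character_ else sr$affected_cohort
    )
  })
  panel <- bind_rows(rows)
  if (anyDuplicated(panel$marker)) {
    abort("duplicate marker names in panel", class = "ssr_panel_error")
  }
  panel
}

.panel_cache <- new.env(parent = emptyenv())

#' @rdname read_marker_panel
#' @export
default_marker_panel <- function() {
  if (is.null(.panel_cache$panel)) {
    .panel_cache$panel <- read_marker_panel(
      system.file("extdata", "marker_panel.yaml",
                  package = "ssrcurate", mustWork = TRUE))
  }
  .panel_cache$panel
}

#' Marker names of a panel, in reporting order
#'
#' @param panel A marker-panel tibble from [read_marker_panel()].
#' @return Character vector of marker names.
#' @export
marker_names <- function(panel) {
  panel$marker
}

# Metadata columns of a sample table, in canonical order.
sample_meta_cols <- function() {
  c("sample_id", "tree_id", "location", "cohort",
    "putative_cultivar", "pomological_cultivar", "trueness", "ploidy")
}

valid_cohorts <- function() c("P2009_2014", "P2017_2021")
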