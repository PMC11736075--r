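#' Run the full curation pipeline
#'
#' Executes, in the order a genebank inventory is curated: pairwise distances
#' over all samples, clustering into molecular groups, inter-cohort shift
#' correction, replay of the curation directives, consensus-genotype
#' construction, trueness aggregation, and the reciprocal consensus-vs-
#' individual validation. All stage outputs are written as plain CSV (plus a
#' line-oriented audit log and a JSON run manifest), so each stage can be
#' inspected and re-run independently; given identical inputs and parameters
#' the data outputs are byte-identical across runs.
#'
#' @param samples Sample tibble (from [read_sample_table()] or
#'   [emit_samples()]), or a path to a sample CSV/TSV.
#' @param out_dir Output directory, created if needed.
#' @param panel Marker panel.
#' @param tolerance_bp Allele matching tolerance in bp (default 1).
#' @param cutoff Clustering cutoff (default 0.25).
#' @param directives Optional directives tibble or YAML path.
#' @param census_window_bp Artefact-removal window for [ploidy_adjust()]
#'   (default 1).
#' @param force Overwrite existing outputs (default `FALSE`; refusing to
#'   overwrite silently keeps prior runs intact).
#' @return Invisibly, a list with `membership`, `shift_report`, `audit`,
#'   `consensus`, `trueness`, `match`, and `manifest`.
#' @export
run_pipeline <- function(samples, out_dir, panel = default_marker_panel(),
                         tolerance_bp = 1L, cutoff = 0.25, directives = NULL,
                         census_window_bp = 1L, force = FALSE) {
  if (is.character(samples) && length(samples) == 1L) {
    samples <- read_sample_table(samples, panel)
  }
  if (is.character(directives) && length(directives) == 1L) {
    directives <- read_directives(directives)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- file.path(out_dir, c("membership.csv", "shift_report.csv",
                                  "audit.log", "consensus.csv", "trueness.csv",
                                  "match_report.csv", "manifest.json"))
  existing <- outputs[file.exists(outputs)]
  if (length(existing) > 0L && !force) {
    abort(sprintf("output(s) already exist (use force = TRUE): %s",
                  paste(basename(existing), collapse = ", ")),
          class = "ssr_pipeline_error")
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "ssr_pipeline_error", parent = e)
    })
  }

  d <- stage("distance", ssr_distance(samples, panel, tolerance_bp))
  membership <- stage("cluster", ssr_cluster(d, cutoff))
  sh <- stage("harmonize", shift_correct(samples, membership, panel))
  samples <- sh$samples
  audit <- sprintf("shift_correct %s @ %s: %d -> %d",
                   sh$report$sample_id, sh$report$marker,
                   sh$report$old_afl, sh$report$new_afl)
  overrides <- NULL
  if (!is.null(directives) && nrow(directives) > 0L) {
    cur <- stage("directives", apply_directives(samples, membership, directives))
    samples <- cur$samples
    membership <- cur$membership
    overrides <- cur$ploidy_overrides
    audit <- c(audit, cur$audit)
  }
  consensus <- stage("consensus",
                     build_consensus(samples, membership, panel, tolerance_bp,
                                     census_window_bp, overrides))
  trueness <- stage("trueness", group_trueness(samples, membership))
  match_rep <- stage("match", reciprocal_match(consensus, samples, panel))

  readr::write_csv(membership, outputs[1], progress = FALSE)
  readr::write_csv(sh$report, outputs[2], progress = FALSE)
  writeLines(audit, outputs[3])
  write_consensus_table(consensus, outputs[4], panel)
  readr::write_csv(trueness, outputs[5], progress = FALSE)
  readr::write_csv(tidy(match_rep), outputs[6], progress = FALSE)

  manifest <- list(
    package = "ssrcurate",
    version = as.character(utils::packageVersion("ssrcurate")),
    n_samples = nrow(samples),
    n_groups = dplyr::n_distinct(membership$group_id),
    params = list(tolerance_bp = tolerance_bp, cutoff = cutoff,
                  census_window_bp = census_window_bp),
    n_directives = if (is.null(directives)) 0L else nrow(directives),
    directives_hash = if (is.null(directives)) NA else
      rlang::hash(directives[c("verb", "target", "args")]),
    panel_markers = marker_names(panel),
    fraction_assignable = match_rep$fraction_assignable,
    outputs = basename(outputs))
  jsonlite::write_json(manifest, outputs[7], auto_unbox = TRUE, pretty = TRUE)

  invisible(list(membership = membership, shift_report = sh$report,
                 audit = audit, consensus = consensus, trueness = trueness,
                 match = match_rep, manifest = manifest))
}
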