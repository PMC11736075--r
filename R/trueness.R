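#' Aggregate per-sample trueness-to-type codes to one cultivar code
#'
#' Trueness-to-type codes express whether an accession is authentically the
#' named cultivar: `"1"` true-to-type, `"2"` true-to-type (group/mutant),
#' `"5"` true-to-type with reservations, `"R"` reference cultivar (treated as
#' `"1"`), `"3"` not determined, `"4"` not assessed (no usable fruit), `"0"`
#' tree deceased before assessment. Per cultivar, the replicate samples'
#' codes are combined as follows: `"R"` is first substituted by `"1"`; if any
#' true-to-type code is present the best one wins in the preference order
#' `"1" > "5" > "2"`; otherwise the more common of `"3"`/`"4"` is taken
#' (tie: `"3"`, the weaker claim); `"0"` only survives when it is the sole
#' information. The aggregation is order-invariant and idempotent.
#'
#' @param codes Character vector of per-sample codes (non-empty; values in
#'   `0,1,2,3,4,5,R`).
#' @return A single aggregated code.
#' @examples
#' aggregate_trueness(c("4", "1", "5"))
#' aggregate_trueness(c("3", "4", "4"))
#' @export
aggregate_trueness <- function(codes) {
  codes <- as.character(codes)
  if (length(codes) == 0L) {
    abort("cannot aggregate an empty set of trueness codes", class = "ssr_trueness_error")
  }
  admissible <- c("0", "1", "2", "3", "4", "5", "R")
  if (!all(codes %in% admissible)) {
    abort(sprintf("inadmissible trueness code(s): %s",
                  paste(setdiff(unique(codes), admissible), collapse = ", ")),
          class = "ssr_trueness_error")
  }
  codes[codes == "R"] <- "1"
  for (preferred in c("1", "5", "2")) {
    if (preferred %in% codes) return(preferred)
  }
  n3 <- sum(codes == "3")
  n4 <- sum(codes == "4")
  if (n3 + n4 > 0L) {
    return(if (n4 > n3) "4" else "3")
  }
  "0"
}

#' Reciprocal matching of consensus against individual profiles
#'
#' A consensus genotype is *assignable* when it is identical — exact allele-set
#' equality at every panel marker, no sizing tolerance — to at least one
#' individual sample profile in the dataset, i.e. it corresponds to an actual
#' accession that can be sampled as reference material. Consensus genotypes
#' matching no individual profile are *synthetic*: optimal compilations of
#' replicate evidence that no single tree exhibits.
#'
#' @param consensus Consensus tibble from [build_consensus()].
#' @param samples Sample tibble of individual profiles.
#' @param panel Marker panel.
#' @return An object of class `ssr_match`: list with `report` (tibble
#'   `group_id`, `cultivar_name`, `assignable`, `matched_sample_id`),
#'   `fraction_assignable`, `n_assignable`, `n_groups`. [tidy()] returns the
#'   per-group report, [glance()] the one-row summary.
#' @export
reciprocal_match <- function(consensus, samples, panel = default_marker_panel()) {
  profile_key <- function(tab) {
    keys <- purrr::map(marker_names(panel), function(m)
      purrr::map_chr(tab[[m]], call_key))
    do.call(paste, c(keys, sep = "|"))
  }
  sample_keys <- profile_key(samples)
  cons_keys <- profile_key(consensus)
  hit <- match(cons_keys, sample_keys)
  report <- tibble(
    group_id = consensus$group_id,
    cultivar_name = consensus[["cultivar_name"]] %||% NA_character_,
    assignable = !is.na(hit),
    matched_sample_id = ifelse(is.na(hit), NA_character_, samples$sample_id[hit])
  )
  structure(list(report = report,
                 n_groups = nrow(report),
                 n_assignable = sum(report$assignable),
                 fraction_assignable = mean(report$assignable)),
            class = "ssr_match")
}

#' @export
print.ssr_match <- function(x, ...) {
  cat(sprintf(
    "# reciprocal match: %d of %d consensus genotypes (%.1f%%) identical to an individual profile\n",
    x$n_assignable, x$n_groups, 100 * x$fraction_assignable))
  invisible(x)
}

#' Tidy / summarise a reciprocal match report
#'
#' @param x An `ssr_match` object.
#' @param ... Unused.
#' @return `tidy()`: the per-group report tibble; `glance()`: a one-row
#'   summary with `n_groups`, `n_assignable`, `n_synthetic`,
#'   `fraction_assignable`.
#' @method tidy ssr_match
#' @export
tidy.ssr_match <- function(x, ...) x$report

#' @rdname tidy.ssr_match
#' @method glance ssr_match
#' @export
glance.ssr_match <- function(x, ...) {
  tibble(n_groups = x$n_groups,
         n_assignable = x$n_assignable,
         n_synthetic = x$n_groups - x$n_assignable,
         fraction_assignable = x$fraction_assignable)
}

#' Plot assignable vs synthetic consensus counts
#'
#' @param object An `ssr_match` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ssr_match
#' @export
autoplot.ssr_match <- function(object, ...) {
  df <- tibble(status = c("assignable", "synthetic"),
               n = c(object$n_assignable, object$n_groups - object$n_assignable))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$status, y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "consensus genotypes",
                  title = "Reciprocal consensus validation",
                  subtitle = sprintf("%.1f%% assignable to an actual accession",
                                     100 * object$fraction_assignable)) +
    ggplot2::theme_minimal()
}

#' Per-group aggregated trueness table
#'
#' Convenience wrapper: aggregates the member samples' trueness codes for
#' every molecular group.
#'
#' @param samples Sample tibble.
#' @param membership Membership tibble.
#' @return Tibble `group_id`, `trueness`, `n_samples`.
#' @export
group_trueness <- function(samples, membership) {
  left_join(membership, samples[, c("sample_id", "trueness")], by = "sample_id") |>
    group_by(.data$group_id) |>
    summarise(
      trueness = if (all(is.na(.data$trueness))) NA_character_ else
        aggregate_trueness(.data$trueness[!is.na(.data$trueness)]),
      n_samples = dplyr::n(),
      .groups = "drop")
}
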