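#' Cluster samples into molecular groups
#'
#' Single-linkage clustering at a distance cutoff: molecular groups are the
#' connected components of the graph that joins every sample pair with
#' distance `<= cutoff` (inclusive). At the default 25% cutoff, profiles that
#' are 75-100% identical end up in the same group. Groups receive `MD_####`
#' identifiers (zero-padded, widening naturally past 9999) in order of the
#' first appearance of their earliest member in the input sample order, so
#' identifiers are deterministic for a given input file.
#'
#' @param dist An `ssr_dist` object from [ssr_distance()].
#' @param cutoff Distance cutoff in `(0, 1)` (default 0.25).
#' @param start_index First group number (default 1).
#' @param id_width Zero-padding width of the group number (default 4).
#' @return A membership tibble with columns `sample_id`, `group_id`, in input
#'   sample order.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_cultivars = 5, seed = 1)
#' sim <- emit_samples(generate_truth(cfg), cfg)
#' d <- ssr_distance(sim$samples)
#' ssr_cluster(d)
#' }
#' @export
ssr_cluster <- function(dist, cutoff = 0.25, start_index = 1L, id_width = 4L) {
  stopifnot(inherits(dist, "ssr_dist") || (is.matrix(dist) && isSymmetric(unclass(dist))))
  stopifnot(cutoff > 0, cutoff < 1)
  adj <- unclass(dist) <= cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  assign_group_ids(tibble(sample_id = rownames(dist), component = as.integer(comp)),
                   start_index = start_index, id_width = id_width)
}

#' Assign MD_#### identifiers to clustered components
#'
#' Components are numbered by the position of their earliest member in the
#' input order, starting at `start_index`, and formatted as `MD_` plus a
#' zero-padded integer (`MD_0001`, ...; indices beyond the padding width widen
#' naturally, e.g. `MD_10000`).
#'
#' @param membership Tibble with columns `sample_id` and `component` (integer
#'   component labels in input row order).
#' @param start_index First group number (default 1).
#' @param id_width Zero-padding width (default 4).
#' @return Tibble with columns `sample_id`, `group_id`.
#' @export
assign_group_ids <- function(membership, start_index = 1L, id_width = 4L) {
  first_seen <- unique(membership$component)  # order of first appearance
  number <- match(membership$component, first_seen) + start_index - 1L
  tibble(sample_id = membership$sample_id,
         group_id = md_id(number, id_width))
}

md_id <- function(number, id_width = 4L) {
  sprintf(paste0("MD_%0", id_width, "d"), as.integer(number))
}

#' Bar chart of molecular-group sizes
#'
#' @param membership Membership tibble from [ssr_cluster()].
#' @param max_groups Show at most this many groups, largest first (default 40).
#' @return A ggplot object.
#' @export
plot_group_sizes <- function(membership, max_groups = 40L) {
  sizes <- membership |>
    count(.data$group_id, name = "n_samples") |>
    arrange(dplyr::desc(.data$n_samples)) |>
    utils::head(max_groups)
  ggplot2::ggplot(sizes, ggplot2::aes(
    x = stats::reorder(.data$group_id, -.data$n_samples),
    y = .data$n_samples)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "molecular group", y = "samples",
                  title = "Replicate samples per molecular group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6))
}
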