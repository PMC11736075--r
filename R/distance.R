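#' Tolerance-aware count of common alleles between two allele sets
#'
#' Counts how many alleles of `a` can be paired with alleles of `b` such that
#' each pair differs by at most `tolerance_bp` and every allele is used at most
#' once — the size of a maximum bipartite matching under the sizing-tolerance
#' relation. The tolerance absorbs the typical +/-1 bp technical variation of
#' capillary fragment sizing. Matching (rather than transitive binning)
#' prevents a 1 bp chain such as 100/101/102 from inflating the shared-allele
#' count.
#'
#' @param a,b Integer vectors of AFLs (possibly empty).
#' @param tolerance_bp Non-negative integer matching tolerance in bp
#'   (default 1).
#' @return Integer count of matched allele pairs.
#' @examples
#' common_allele_count(c(100, 102), c(100, 110), tolerance_bp = 1)
#' @export
common_allele_count <- function(a, b, tolerance_bp = 1L) {
  stopifnot(tolerance_bp >= 0L)
  a <- as_allele_set(a)
  b <- as_allele_set(b)
  i <- 1L; j <- 1L; m <- 0L
  # Greedy two-pointer sweep over sorted sets; optimal for interval tolerance
  # (verified against brute-force enumeration in the test suite).
  while (i <= length(a) && j <= length(b)) {
    if (abs(a[i] - b[j]) <= tolerance_bp) {
      m <- m + 1L; i <- i + 1L; j <- j + 1L
    } else if (a[i] < b[j]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  m
}

#' Dice-Sorensen distance between two genotype profiles
#'
#' The pairwise distance between two multi-marker SSR profiles is one minus
#' the Dice-Sorensen similarity computed over all panel markers:
#' \deqn{d = 1 - \frac{2 \sum \mathrm{common\ alleles}}{\sum \mathrm{alleles}_1 + \sum \mathrm{alleles}_2}}
#' with tolerance-aware allele matching (see [common_allele_count()]).
#' Markers that are null in both profiles contribute nothing; a marker null in
#' only one profile contributes that profile's allele count to the denominator
#' only, so allelic dropout is penalized.
#'
#' @param p1,p2 Named lists (or one-row slices of a sample tibble's marker
#'   columns) mapping marker name to an integer AFL vector.
#' @param panel Marker panel defining which markers enter the sums.
#' @param tolerance_bp Allele matching tolerance in bp (default 1).
#' @return Distance in `[0, 1]`.
#' @examples
#' p1 <- list(CH01h01 = c(100L, 102L))
#' p2 <- list(CH01h01 = c(100L, 110L))
#' panel <- default_marker_panel()[default_marker_panel()$marker == "CH01h01", ]
#' pairwise_distance(p1, p2, panel = panel)
#' @export
pairwise_distance <- function(p1, p2, panel = default_marker_panel(),
                              tolerance_bp = 1L) {
  common <- 0L
  denom <- 0L
  for (m in marker_names(panel)) {
    a <- as_allele_set(p1[[m]])
    b <- as_allele_set(p2[[m]])
    if (length(a) == 0L && length(b) == 0L) next
    denom <- denom + length(a) + length(b)
    common <- common + common_allele_count(a, b, tolerance_bp)
  }
  if (denom == 0L) {
    abort("distance undefined: both profiles are entirely null",
          class = "ssr_undefined_distance")
  }
  1 - (2 * common) / denom
}

#' Pairwise distance matrix over a sample table
#'
#' Computes the full symmetric Dice-Sorensen distance matrix between all
#' samples (compiled kernel; identical by construction to calling
#' [pairwise_distance()] on every pair). A pair in which both profiles are
#' entirely null has no defined distance; such pairs are set to 1.0 and
#' reported with a warning rather than aborting the run.
#'
#' @param samples Sample tibble (from [read_sample_table()] or
#'   [emit_samples()]).
#' @param panel Marker panel.
#' @param tolerance_bp Allele matching tolerance in bp (default 1).
#' @return An object of class `ssr_dist`: the distance matrix with sample ids
#'   as dimnames, plus attributes `tolerance_bp` and `undefined_pairs`.
#'   Use [tidy()] for a long pair table and [autoplot()] for the distance
#'   distribution.
#' @export
ssr_distance <- function(samples, panel = default_marker_panel(),
                         tolerance_bp = 1L) {
  stopifnot(nrow(samples) >= 2L)
  mk <- marker_names(panel)
  n <- nrow(samples)
  nm <- length(mk)
  lens <- matrix(0L, n, nm)
  blocks <- vector("list", n * nm)
  k <- 1L
  for (m in seq_len(nm)) {
    col <- samples[[mk[m]]]
    for (i in seq_len(n)) {
      v <- as_allele_set(col[[i]])
      lens[i, m] <- length(v)
      blocks[[(m - 1L) * n + i]] <- v
    }
  }
  # sample-major concatenation with 0-based offsets
  starts <- matrix(0L, n, nm)
  alleles <- integer(sum(lens))
  off <- 0L
  for (i in seq_len(n)) {
    for (m in seq_len(nm)) {
      v <- blocks[[(m - 1L) * n + i]]
      starts[i, m] <- off
      if (length(v)) alleles[(off + 1L):(off + length(v))] <- v
      off <- off + length(v)
    }
  }
  res <- .dist_matrix_cpp(alleles, starts, lens, as.integer(tolerance_bp))
  d <- res$d
  dimnames(d) <- list(samples$sample_id, samples$sample_id)
  und <- res$undefined_pairs
  if (nrow(und) > 0L) {
    warn(sprintf(
      "%d sample pair(s) have entirely null profiles on both sides; their distance was set to 1.0",
      nrow(und)))
  }
  structure(d, class = c("ssr_dist", "matrix", "array"),
            tolerance_bp = as.integer(tolerance_bp),
            undefined_pairs = und)
}

#' @export
print.ssr_dist <- function(x, ...) {
  cat(sprintf("# SSR Dice-Sorensen distance matrix: %d samples, tolerance %d bp\n",
              nrow(x), attr(x, "tolerance_bp")))
  off <- x[upper.tri(x)]
  cat(sprintf("# off-diagonal distances: min %.3f, median %.3f, max %.3f\n",
              min(off), stats::median(off), max(off)))
  invisible(x)
}

#' Tidy a distance matrix into a long pair table
#'
#' @param x An `ssr_dist` object.
#' @param ... Unused.
#' @return A tibble with columns `sample_1`, `sample_2`, `distance`, one row
#'   per unordered sample pair.
#' @method tidy ssr_dist
#' @export
tidy.ssr_dist <- function(x, ...) {
  ids <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(sample_1 = ids[idx[, 1]],
         sample_2 = ids[idx[, 2]],
         distance = x[idx]) |>
    arrange(.data$sample_1, .data$sample_2)
}

#' @rdname tidy.ssr_dist
#' @method glance ssr_dist
#' @export
glance.ssr_dist <- function(x, ...) {
  off <- x[upper.tri(x)]
  tibble(n_samples = nrow(x),
         n_pairs = length(off),
         tolerance_bp = attr(x, "tolerance_bp"),
         min_distance = min(off),
         median_distance = stats::median(off),
         max_distance = max(off),
         n_undefined_pairs = nrow(attr(x, "undefined_pairs")))
}

#' Plot the pairwise distance distribution
#'
#' Histogram of all off-diagonal pairwise distances with the clustering cutoff
#' marked; the valley between the replicate mode (near 0) and the
#' between-cultivar mode motivates the cutoff choice.
#'
#' @param object An `ssr_dist` object.
#' @param cutoff Cutoff to mark (default 0.25).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ssr_dist
#' @export
autoplot.ssr_dist <- function(object, cutoff = 0.25, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey35") +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "pairwise Dice-Sorensen distance", y = "sample pairs",
                  title = "Pairwise distance distribution",
                  subtitle = sprintf("clustering cutoff %.2f", cutoff)) +
    ggplot2::theme_minimal()
}
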