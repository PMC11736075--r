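# Independent oracles and fixture builders used across the suite.

# Brute-force maximum matching between two allele sets under |x - y| <= tol:
# exhaustive recursion over all pairings, independent of the greedy sweep in
# the package.
brute_force_common <- function(a, b, tol) {
  a <- sort(unique(as.integer(a)))
  b <- sort(unique(as.integer(b)))
  rec <- function(i, used_b) {
    if (i > length(a)) return(0L)
    best <- rec(i + 1L, used_b)  # leave a[i] unmatched
    for (j in seq_along(b)) {
      if (!used_b[j] && abs(a[i] - b[j]) <= tol) {
        used_b2 <- used_b
        used_b2[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used_b2))
      }
    }
    best
  }
  rec(1L, rep(FALSE, length(b)))
}

random_allele_set <- function(max_n = 5L, lo = 95L, hi = 120L) {
  n <- sample(0:max_n, 1L)
  if (n == 0L) integer(0) else sort(sample(lo:hi, n))
}

# Build a sample tibble from a list of per-sample profiles (named lists of
# marker -> AFL vector); markers absent from a profile become null calls.
fixture_samples <- function(profiles, panel = default_marker_panel(),
                            ids = NULL, cohort = "P2017_2021", ploidy = 2L,
                            trueness = "1", pomological = NULL) {
  n <- length(profiles)
  ids <- ids %||% sprintf("S%03d", seq_len(n))
  out <- tibble::tibble(
    sample_id = ids,
    tree_id = paste0("T", seq_len(n)),
    location = "L1",
    cohort = rep_len(cohort, n),
    putative_cultivar = NA_character_,
    pomological_cultivar = rep_len(pomological %||% NA_character_, n),
    trueness = rep_len(trueness, n),
    ploidy = rep_len(as.integer(ploidy), n))
  for (m in marker_names(panel)) {
    out[[m]] <- lapply(profiles, function(p) {
      v <- p[[m]]
      if (is.null(v)) integer(0) else sort(unique(as.integer(v)))
    })
  }
  out
}

# Random full profiles over the whole panel (every marker called).
random_profiles <- function(n, panel = default_marker_panel(), lo = 90L, hi = 260L) {
  lapply(seq_len(n), function(i) {
    p <- lapply(marker_names(panel), function(m) sort(sample(lo:hi, 2L)))
    names(p) <- marker_names(panel)
    p
  })
}

# Partition of profiles into exact-equality classes (brute force, string keys).
equality_partition <- function(samples, panel = default_marker_panel()) {
  keys <- do.call(paste, c(lapply(marker_names(panel), function(m)
    vapply(samples[[m]], function(a) paste(a, collapse = ":"), "")), sep = "|"))
  match(keys, unique(keys))
}

`%||%` <- rlang::`%||%`
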