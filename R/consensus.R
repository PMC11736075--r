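#' Tally the observed calls of a group at one marker
#'
#' Counts how many samples of a molecular group show each distinct observed
#' call (allele set) at a marker; the null call is counted as its own
#' category. These multiplicities drive the most-frequent-call consensus rule.
#'
#' @param calls List of integer AFL vectors (one per group sample).
#' @return A tibble with columns `call` (list-column of allele sets), `key`
#'   (serialized call) and `n`, in order of first appearance; `sum(n)` equals
#'   the group size.
#' @export
tally_calls <- function(calls) {
  stopifnot(length(calls) > 0L)
  keys <- purrr::map_chr(calls, call_key)
  first <- !duplicated(keys)
  tibble(call = purrr::map(calls[first], as_allele_set),
         key = keys[first],
         n = as.integer(table(factor(keys, levels = keys[first]))))
}

#' Consensus call for one marker from tallied group calls
#'
#' Implements the most-frequent-call rule with three refinements that mirror
#' how replicate fingerprints are curated:
#'
#' * **Missing-value fill** — if the modal call is null but at least one
#'   sample amplified, the most frequent non-null call is taken instead
#'   (flag `missing-filled`).
#' * **Heterozygous preference** — if a (minority) call is a strict superset
#'   of the current consensus and every extra allele differs from every
#'   consensus allele by more than `tolerance_bp`, the richer call wins: the
#'   smaller call is most plausibly the same genotype with one allele not
#'   scored, whereas an extra allele within tolerance would be a sizing
#'   artefact (flag `heterozygous-preference`). Applied after the fill rule,
#'   and repeatedly until no richer call qualifies.
#' * **Ties** — equally frequent candidate calls that are within tolerance of
#'   each other (same size, alleles pairwise within `tolerance_bp`) are
#'   treated as sizing variants of one call and collapse to the variant with
#'   the smaller AFLs; otherwise the first-seen candidate is kept. Either way
#'   the marker is flagged `unresolved` for manual review.
#'
#' @param counts Tally tibble from [tally_calls()].
#' @param tolerance_bp Sizing tolerance in bp (default 1).
#' @return A list with `alleles` (integer vector) and `flags` (character
#'   vector, possibly empty).
#' @examples
#' counts <- tally_calls(list(c(221L), c(221L), c(221L), c(221L, 231L), c(221L, 231L)))
#' consensus_alleles(counts)
#' @export
consensus_alleles <- function(counts, tolerance_bp = 1L) {
  stopifnot(nrow(counts) > 0L)
  flags <- character(0)

  pick_modal <- function(tab) {
    top <- tab[tab$n == max(tab$n), ]
    if (nrow(top) == 1L) return(list(call = top$call[[1L]], tied = FALSE))
    # tie: collapse within-tolerance sizing variants to the smaller AFLs
    if (all_within_tolerance(top$call, tolerance_bp)) {
      ord <- order(purrr::map_chr(top$call, function(a)
        paste(sprintf("%04d", a), collapse = ":")))
      list(call = top$call[[ord[1L]]], tied = TRUE)
    } else {
      list(call = top$call[[1L]], tied = TRUE)  # modal-by-first-seen
    }
  }

  modal <- pick_modal(counts)
  if (modal$tied) flags <- c(flags, "unresolved")
  consensus <- modal$call

  # missing-value fill: a null modal call yields to any amplified call
  if (length(consensus) == 0L) {
    nonnull <- counts[purrr::map_int(counts$call, length) > 0L, ]
    if (nrow(nonnull) > 0L) {
      m2 <- pick_modal(nonnull)
      if (m2$tied && !"unresolved" %in% flags) flags <- c(flags, "unresolved")
      consensus <- m2$call
      flags <- c(flags, "missing-filled")
    }
  }

  # heterozygous preference: a strict superset whose extra alleles are all
  # clearly distinct (> tolerance) from the current consensus wins
  repeat {
    sup <- counts[purrr::map_lgl(counts$call, function(c) {
      length(c) > length(consensus) &&
        all(consensus %in% c) &&
        all(purrr::map_lgl(setdiff(c, consensus), function(extra)
          length(consensus) == 0L || all(abs(extra - consensus) > tolerance_bp)))
    }), ]
    if (nrow(sup) == 0L) break
    sup <- sup[order(-sup$n, -purrr::map_int(sup$call, length)), ]
    consensus <- sup$call[[1L]]
    flags <- c(flags, "heterozygous-preference")
  }

  list(alleles = as_allele_set(consensus), flags = unique(flags))
}

# TRUE when every pair of calls has the same size and matches allele-for-
# allele within tolerance (i.e. they are sizing variants of one call).
all_within_tolerance <- function(calls, tolerance_bp) {
  sizes <- purrr::map_int(calls, length)
  if (length(unique(sizes)) > 1L) return(FALSE)
  for (i in seq_along(calls)) {
    for (j in seq_len(i - 1L)) {
      if (common_allele_count(calls[[i]], calls[[j]], tolerance_bp) < sizes[i]) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Census of AFLs across a set of consensus genotypes
#'
#' Counts, per marker, in how many consensus genotypes each AFL occurs. The
#' census is the evidence base for artefact removal in [ploidy_adjust()]:
#' an AFL carried by exactly one genotype, sitting right next to a widespread
#' AFL, is the signature of a chromatogram-processing artefact.
#'
#' @param consensus Consensus tibble (marker list-columns).
#' @param panel Marker panel.
#' @return Tibble with columns `marker`, `afl`, `n_genotypes`.
#' @export
afl_census <- function(consensus, panel = default_marker_panel()) {
  purrr::map(marker_names(panel), function(m) {
    afls <- unlist(consensus[[m]])
    if (length(afls) == 0L) {
      return(tibble(marker = character(), afl = integer(), n_genotypes = integer()))
    }
    tab <- table(afls)
    tibble(marker = m, afl = as.integer(names(tab)), n_genotypes = as.integer(tab))
  }) |> bind_rows()
}

#' Remove ploidy-inconsistent artefact alleles from consensus calls
#'
#' A diploid genotype should carry at most two alleles at a single-locus
#' marker. Where a diploid consensus call has more, any allele that is unique
#' to this genotype in the dataset-wide census *and* lies within `window_bp`
#' of a non-unique allele of the same call is removed as a sizing artefact
#' (flag `ploidy-adjusted`). Multi-locus markers are exempt — supernumerary
#' alleles there are genuine — and ploidy is never inferred from allele
#' counts: triploid or unknown-ploidy calls are left intact. If removing all
#' qualifying artefact candidates still leaves more than two alleles, the
#' call is left unaltered and flagged `unresolved` for manual review.
#'
#' @param consensus Consensus tibble from [build_consensus()] (or assembled by
#'   hand with `group_id`, `ploidy`, and marker list-columns).
#' @param census AFL census from [afl_census()]; by default computed from
#'   `consensus` itself.
#' @param panel Marker panel (supplies the `locus_type` exemptions).
#' @param window_bp Default comparison window in bp (1); per-group/per-marker
#'   overrides of up to 2 bp may be supplied via `overrides` (typically from
#'   `adjust_allele` curation directives).
#' @param overrides Optional tibble `group_id`, `marker`, `window_bp`.
#' @return The consensus tibble with adjusted calls and an updated `flags`
#'   list-column (per-marker flag records, see [build_consensus()]).
#' @export
ploidy_adjust <- function(consensus, census = NULL,
                          panel = default_marker_panel(), window_bp = 1L,
                          overrides = NULL) {
  if (is.null(census)) census <- afl_census(consensus, panel)
  if (!"flags" %in% names(consensus)) {
    consensus$flags <- rep(list(empty_flags()), nrow(consensus))
  }
  single <- panel$marker[panel$locus_type == "single"]
  for (i in seq_len(nrow(consensus))) {
    ploidy <- consensus$ploidy[i]
    if (is.na(ploidy) || ploidy != 2L) next
    for (m in single) {
      call <- consensus[[m]][[i]]
      if (length(call) <= 2L) next
      win <- window_bp
      if (!is.null(overrides) && nrow(overrides) > 0L) {
        ov <- overrides[overrides$group_id == consensus$group_id[i] &
                          overrides$marker == m, ]
        if (nrow(ov) > 0L) win <- max(ov$window_bp)
      }
      cen <- census[census$marker == m, ]
      n_of <- function(a) {
        hit <- cen$n_genotypes[cen$afl == a]
        if (length(hit) == 0L) 0L else hit[[1L]]
      }
      counts <- purrr::map_int(call, n_of)
      unique_here <- counts <= 1L
      artefact <- purrr::map_lgl(seq_along(call), function(k) {
        unique_here[k] &&
          any(!unique_here & abs(call - call[k]) <= win & call != call[k])
      })
      if (any(artefact) && sum(!artefact) <= 2L) {
        consensus[[m]][[i]] <- call[!artefact]
        consensus$flags[[i]] <- bind_rows(
          consensus$flags[[i]], tibble(marker = m, flag = "ploidy-adjusted"))
      } else {
        consensus$flags[[i]] <- bind_rows(
          consensus$flags[[i]], tibble(marker = m, flag = "unresolved"))
      }
    }
  }
  consensus
}

empty_flags <- function() tibble(marker = character(), flag = character())

#' Build consensus genotype profiles for all molecular groups
#'
#' For each molecular group, tallies the observed calls per marker
#' ([tally_calls()]), derives the consensus call ([consensus_alleles()]), and
#' finally removes ploidy-inconsistent artefact alleles against the
#' dataset-wide census ([ploidy_adjust()]). The cultivar name attached to each
#' group is the group's modal pomological determination, falling back to the
#' modal holder-provided (putative) name, and finally to the group id itself.
#' Trueness-to-type codes of the member samples are aggregated with
#' [aggregate_trueness()]; group ploidy is the modal recorded ploidy.
#'
#' @param samples Sample tibble (after harmonization).
#' @param membership Membership tibble (`sample_id`, `group_id`).
#' @param panel Marker panel.
#' @param tolerance_bp Sizing tolerance in bp (default 1).
#' @param census_window_bp Default artefact-removal window (default 1).
#' @param ploidy_overrides Optional per-group window overrides (see
#'   [apply_directives()]).
#' @return A consensus tibble, one row per group in order of group id first
#'   appearance: `group_id`, `cultivar_name`, `trueness`, `ploidy`,
#'   `n_samples`, one list-column per marker, and `flags` (list-column of
#'   per-marker flag tibbles). Use [consensus_flags()] for a flat flag table.
#' @export
build_consensus <- function(samples, membership, panel = default_marker_panel(),
                            tolerance_bp = 1L, census_window_bp = 1L,
                            ploidy_overrides = NULL) {
  tab <- left_join(samples, membership, by = "sample_id")
  if (anyNA(tab$group_id)) {
    abort("every sample must have a group assignment", class = "ssr_consensus_error")
  }
  gids <- unique(membership$group_id)
  rows <- purrr::map(gids, function(gid) {
    grp <- tab[tab$group_id == gid, ]
    out <- tibble(
      group_id = gid,
      cultivar_name = group_cultivar_name(grp, gid),
      trueness = if (all(is.na(grp$trueness))) NA_character_ else
        aggregate_trueness(grp$trueness[!is.na(grp$trueness)]),
      ploidy = modal_value(grp$ploidy),
      n_samples = nrow(grp)
    )
    flags <- empty_flags()
    for (m in marker_names(panel)) {
      res <- consensus_alleles(tally_calls(grp[[m]]), tolerance_bp)
      out[[m]] <- list(res$alleles)
      if (length(res$flags) > 0L) {
        flags <- bind_rows(flags, tibble(marker = m, flag = res$flags))
      }
    }
    out$flags <- list(flags)
    out
  })
  consensus <- bind_rows(rows)
  ploidy_adjust(consensus, census = afl_census(consensus, panel), panel = panel,
                window_bp = census_window_bp, overrides = ploidy_overrides)
}

group_cultivar_name <- function(grp, gid) {
  pom <- modal_value(grp$pomological_cultivar)
  if (!is.na(pom)) return(pom)
  put <- modal_value(grp$putative_cultivar)
  if (!is.na(put)) return(put)
  gid
}

# Modal non-NA value; first-seen wins ties; NA when all missing.
modal_value <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA)
  tab <- table(factor(x, levels = unique(x)))
  best <- names(tab)[which.max(tab)]
  if (is.numeric(x)) as.integer(best) else best
}

#' Flat table of consensus review flags
#'
#' @param consensus Consensus tibble from [build_consensus()].
#' @return Tibble with columns `group_id`, `marker`, `flag`, one row per rule
#'   firing.
#' @export
consensus_flags <- function(consensus) {
  purrr::map2(consensus$group_id, consensus$flags, function(gid, fl) {
    if (nrow(fl) == 0L) return(NULL)
    mutate(fl, group_id = gid, .before = 1L)
  }) |> bind_rows() -> out
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble(group_id = character(), marker = character(), flag = character()))
  }
  out
}
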