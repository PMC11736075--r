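#' Correct systematic cross-cohort allele-size shifts
#'
#' Capillary sizing can differ systematically between genotyping campaigns:
#' for the default apple panel, marker CH02g09 shows a 2 bp offset between the
#' 2009-2014 and 2017-2021 cohorts, predominantly at AFLs of 122-140 bp.
#' Within each molecular group that contains samples from both cohorts, an
#' affected-cohort AFL `a` inside the rule window is raised to `a + shift_bp`
#' when (i) some same-group sample from the other cohort shows `a + shift_bp`
#' at the same marker, and (ii) `a` itself is not seen in the other cohort
#' (so values already consistent across cohorts are never touched, which also
#' makes the correction idempotent). Only the rule's marker, window, and
#' affected cohort are ever modified.
#'
#' @param samples Sample tibble.
#' @param membership Membership tibble (`sample_id`, `group_id`) from
#'   [ssr_cluster()].
#' @param panel Marker panel; the rule is taken from its `shift_rule` fields.
#' @param marker Marker to correct; defaults to the (single) panel marker that
#'   carries a shift rule. No-op (empty report) when no rule exists.
#' @return A list with class `ssr_shift`: `samples` (corrected tibble) and
#'   `report`, a tibble of edits (`sample_id`, `marker`, `old_afl`, `new_afl`).
#' @export
shift_correct <- function(samples, membership, panel = default_marker_panel(),
                          marker = NULL) {
  if (is.null(marker)) {
    marker <- panel$marker[!is.na(panel$shift_bp)]
    if (length(marker) == 0L) {
      return(structure(list(samples = samples,
                            report = empty_shift_report()),
                       class = "ssr_shift"))
    }
    marker <- marker[[1L]]
  }
  rule <- panel[panel$marker == marker, ]
  if (nrow(rule) != 1L || is.na(rule$shift_bp)) {
    abort(sprintf("marker %s has no shift rule in the panel", marker),
          class = "ssr_shift_error")
  }
  lo <- rule$shift_window_low
  hi <- rule$shift_window_high
  shift <- rule$shift_bp
  affected <- rule$shift_cohort

  tab <- left_join(samples, membership, by = "sample_id")
  edits <- list()
  for (gid in unique(tab$group_id)) {
    rows <- which(tab$group_id == gid)
    coh <- tab$cohort[rows]
    is_aff <- !is.na(coh) & coh == affected
    is_other <- !is.na(coh) & coh != affected
    if (!any(is_aff) || !any(is_other)) next
    ref <- sort(unique(unlist(tab[[marker]][rows[is_other]])))
    for (r in rows[is_aff]) {
      call <- tab[[marker]][[r]]
      if (length(call) == 0L) next
      fix <- call >= lo & call <= hi & !(call %in% ref) & ((call + shift) %in% ref)
      if (any(fix)) {
        for (a in call[fix]) {
          edits[[length(edits) + 1L]] <- tibble(
            sample_id = tab$sample_id[r], marker = marker,
            old_afl = as.integer(a), new_afl = as.integer(a + shift))
        }
        tab[[marker]][[r]] <- as_allele_set(ifelse(fix, call + shift, call))
      }
    }
  }
  samples_out <- tab[setdiff(names(tab), "group_id")]
  report <- if (length(edits)) bind_rows(edits) else empty_shift_report()
  structure(list(samples = samples_out, report = report), class = "ssr_shift")
}

empty_shift_report <- function() {
  tibble(sample_id = character(), marker = character(),
         old_afl = integer(), new_afl = integer())
}

#' @export
print.ssr_shift <- function(x, ...) {
  cat(sprintf("# shift correction: %d AFL edit(s) across %d sample(s)\n",
              nrow(x$report), dplyr::n_distinct(x$report$sample_id)))
  invisible(x)
}

#' Read a curation-directives file
#'
#' Manual curation steps (removing mislabelled samples, reassigning samples to
#' another molecular group, splitting a group that lumped distinct cultivars,
#' widening the artefact-removal window for one group/marker) are expressed as
#' a declarative YAML list of `{verb, target, args}` entries so that every
#' manual decision is replayed — and audited — on each run.
#'
#' @param path YAML file: a list of entries with fields `verb` (one of
#'   `remove_sample`, `reassign_sample`, `split_group`, `adjust_allele`),
#'   `target` (a sample or group id), and verb-specific `args`.
#' @return A tibble with columns `verb`, `target`, `args` (list-column).
#' @export
read_directives <- function(path) {
  raw <- yaml::read_yaml(path)
  verbs <- c("remove_sample", "reassign_sample", "split_group", "adjust_allele")
  rows <- purrr::imap(raw, function(d, i) {
    if (is.null(d$verb) || !d$verb %in% verbs) {
      abort(sprintf("directive %d: unknown verb '%s'", i, d$verb %||% "<missing>"),
            class = "ssr_directive_error")
    }
    if (is.null(d$target)) {
      abort(sprintf("directive %d: missing target", i), class = "ssr_directive_error")
    }
    tibble(verb = d$verb, target = as.character(d$target),
           args = list(d$args %||% list()))
  })
  bind_rows(rows)
}

#' Apply curation directives to a dataset
#'
#' Replays a directives table against the samples and group membership:
#' `remove_sample` deletes the record, `reassign_sample` moves a sample to the
#' named group, `split_group` partitions a group into new groups (fresh
#' `MD_####` ids continuing after the current maximum), and `adjust_allele`
#' records a per-group/per-marker override of the artefact-removal comparison
#' window used by [ploidy_adjust()]. Every mutation is logged in order.
#'
#' @param samples Sample tibble.
#' @param membership Membership tibble (`sample_id`, `group_id`).
#' @param directives Directives tibble from [read_directives()] (or built in
#'   code with the same columns).
#' @return A list with class `ssr_curation`: `samples`, `membership`,
#'   `audit` (character vector, one line per mutation), and
#'   `ploidy_overrides` (tibble `group_id`, `marker`, `window_bp`).
#' @export
apply_directives <- function(samples, membership, directives) {
  audit <- character(0)
  overrides <- tibble(group_id = character(), marker = character(),
                      window_bp = integer())
  for (i in seq_len(nrow(directives))) {
    verb <- directives$verb[i]
    target <- directives$target[i]
    args <- directives$args[[i]]
    if (verb == "remove_sample") {
      if (!target %in% samples$sample_id) {
        abort(sprintf("directive %d (remove_sample): unknown sample '%s'", i, target),
              class = "ssr_directive_error")
      }
      samples <- samples[samples$sample_id != target, ]
      membership <- membership[membership$sample_id != target, ]
      audit <- c(audit, sprintf("remove_sample %s", target))
    } else if (verb == "reassign_sample") {
      if (!target %in% membership$sample_id) {
        abort(sprintf("directive %d (reassign_sample): unknown sample '%s'", i, target),
              class = "ssr_directive_error")
      }
      new_group <- args$group_id %||% args$group %||%
        abort(sprintf("directive %d (reassign_sample): missing args$group_id", i),
              class = "ssr_directive_error")
      old_group <- membership$group_id[membership$sample_id == target]
      membership$group_id[membership$sample_id == target] <- new_group
      audit <- c(audit, sprintf("reassign_sample %s: %s -> %s", target, old_group, new_group))
    } else if (verb == "split_group") {
      members <- membership$sample_id[membership$group_id == target]
      if (length(members) == 0L) {
        abort(sprintf("directive %d (split_group): unknown group '%s'", i, target),
              class = "ssr_directive_error")
      }
      parts <- args$parts %||%
        abort(sprintf("directive %d (split_group): missing args$parts", i),
              class = "ssr_directive_error")
      parts <- purrr::map(parts, as.character)
      flat <- unlist(parts)
      if (anyDuplicated(flat) || !setequal(flat, members)) {
        abort(sprintf(
          "directive %d (split_group): parts do not partition group '%s'", i, target),
          class = "ssr_directive_error")
      }
      next_no <- max_md_number(membership$group_id) + seq_along(parts)
      new_ids <- md_id(next_no)
      for (k in seq_along(parts)) {
        membership$group_id[membership$sample_id %in% parts[[k]]] <- new_ids[k]
      }
      audit <- c(audit, sprintf("split_group %s -> %s", target,
                                paste(new_ids, collapse = ", ")))
    } else if (verb == "adjust_allele") {
      marker <- args$marker %||%
        abort(sprintf("directive %d (adjust_allele): missing args$marker", i),
              class = "ssr_directive_error")
      win <- as.integer(args$window_bp %||% 2L)
      if (win > 2L) {
        abort(sprintf("directive %d (adjust_allele): window_bp above 2 bp not allowed", i),
              class = "ssr_directive_error")
      }
      overrides <- bind_rows(overrides,
                             tibble(group_id = target, marker = marker, window_bp = win))
      audit <- c(audit, sprintf("adjust_allele %s @ %s: window %d bp", target, marker, win))
    }
  }
  structure(list(samples = samples, membership = membership,
                 audit = audit, ploidy_overrides = overrides),
            class = "ssr_curation")
}

max_md_number <- function(group_ids) {
  nos <- suppressWarnings(as.integer(sub("^MD_", "", unique(group_ids))))
  nos <- nos[!is.na(nos)]
  if (length(nos) == 0L) 0L else max(nos)
}

#' Generate removal directives from an exclusion vocabulary
#'
#' Genebank inventories contain trees that are not cultivars at all —
#' rootstock shoots, crab apples, wild apples — which are removed before
#' consensus building. This helper turns the pomological determination column
#' into `remove_sample` directives by case-insensitive substring match against
#' an exclusion vocabulary.
#'
#' @param samples Sample tibble.
#' @param vocabulary Character vector of excluded determinations (substrings).
#' @return Directives tibble suitable for [apply_directives()].
#' @export
exclusion_directives <- function(samples,
                                 vocabulary = c("rootstock", "crab apple",
                                                "wild apple", "unterlage",
                                                "wildapfel", "holzapfel")) {
  pat <- paste(vocabulary, collapse = "|")
  hit <- !is.na(samples$pomological_cultivar) &
    stringr::str_detect(tolower(samples$pomological_cultivar), tolower(pat))
  tibble(verb = rep("remove_sample", sum(hit)),
         target = samples$sample_id[hit],
         args = rep(list(list()), sum(hit)))
}
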