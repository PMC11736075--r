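#' Configuration for the synthetic genebank generator
#'
#' Describes a simulated multi-site fingerprinting campaign: a set of distinct
#' cultivar genotypes, a variable number of replicate samples per cultivar,
#' two genotyping cohorts, and the noise processes that separate an emitted
#' sample from its cultivar's true genotype. Every noise event is written to
#' an error ledger, so the noise-free dataset can be reconstructed exactly and
#' every pipeline stage can be scored against ground truth.
#'
#' @param n_cultivars Number of cultivars (default 50).
#' @param samples_per_cultivar Inclusive range of replicate counts per
#'   cultivar, drawn uniformly (default `c(1, 73)`, the replicate range seen
#'   in large genebank inventories).
#' @param ploidy_probs Named probabilities over ploidy levels 2 and 3
#'   (default 90% diploid, 10% triploid).
#' @param pool_size_range Range of distinct alleles per marker pool
#'   (default `c(8, 25)`).
#' @param pool_bp_range AFL range of the allele pools in bp (default
#'   `c(90, 260)`); a marker carrying a shift rule draws its pool around the
#'   rule window instead, so the shift process is exercised.
#' @param jitter_prob Per-allele probability of a +/-1 bp sizing jitter
#'   (default 0.01).
#' @param dropout_prob Per-marker probability of a null call (default 0.02).
#' @param swap_prob Per-sample probability of a label swap: the sample keeps
#'   its cultivar's name but carries another cultivar's profile
#'   (default 0.002).
#' @param cohort_split Fraction of samples assigned to the earlier cohort
#'   `P2009_2014` (default 0.37, the split of a two-campaign inventory).
#' @param shift_sim Simulate the systematic 2 bp inter-cohort offset at the
#'   panel's shift-rule marker (default `TRUE`).
#' @param mutant_prob Probability that a cultivar is a mutant/sport: a
#'   distinct name sharing an earlier cultivar's genotype (default 0.03).
#'   Mutants are molecularly inseparable from their parent; recovery metrics
#'   treat parent plus mutants as one molecular class.
#' @param tolerance_bp,cutoff Clustering parameters the simulation is meant to
#'   be analysed with; genotype distinctness is enforced against them.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A validated `ssr_sim_config` list.
#' @export
sim_config <- function(n_cultivars = 50L,
                       samples_per_cultivar = c(1L, 73L),
                       ploidy_probs = c("2" = 0.9, "3" = 0.1),
                       pool_size_range = c(8L, 25L),
                       pool_bp_range = c(90L, 260L),
                       jitter_prob = 0.01,
                       dropout_prob = 0.02,
                       swap_prob = 0.002,
                       cohort_split = 0.37,
                       shift_sim = TRUE,
                       mutant_prob = 0.03,
                       tolerance_bp = 1L,
                       cutoff = 0.25,
                       seed = 1L) {
  probs <- c(jitter_prob, dropout_prob, swap_prob, cohort_split, mutant_prob)
  stopifnot(all(probs >= 0 & probs <= 1),
            n_cultivars >= 1L,
            samples_per_cultivar[1] >= 1L,
            samples_per_cultivar[2] >= samples_per_cultivar[1],
            pool_size_range[1] >= 2L,
            pool_size_range[2] >= pool_size_range[1],
            pool_bp_range[2] > pool_bp_range[1],
            abs(sum(ploidy_probs) - 1) < 1e-8,
            cutoff > 0, cutoff < 1, tolerance_bp >= 0L)
  structure(list(
    n_cultivars = as.integer(n_cultivars),
    samples_per_cultivar = as.integer(samples_per_cultivar),
    ploidy_probs = ploidy_probs,
    pool_size_range = as.integer(pool_size_range),
    pool_bp_range = as.integer(pool_bp_range),
    jitter_prob = jitter_prob,
    dropout_prob = dropout_prob,
    swap_prob = swap_prob,
    cohort_split = cohort_split,
    shift_sim = isTRUE(shift_sim),
    mutant_prob = mutant_prob,
    tolerance_bp = as.integer(tolerance_bp),
    cutoff = cutoff,
    seed = as.integer(seed)
  ), class = "ssr_sim_config")
}

#' Generate ground-truth cultivar genotypes and a sampling frame
#'
#' Draws per-marker allele pools, then cultivar genotypes from them (diploid
#' or triploid; multi-locus markers may carry a supernumerary allele), and the
#' sampling frame: which samples exist, which cultivar each belongs to, and
#' its cohort/location metadata. Genotype distinctness is enforced by
#' rejection: each accepted genotype must have Dice-Sorensen distance above
#' the clustering cutoff from every previous one, evaluated with the matching
#' tolerance widened by 2 bp so that +/-1 bp sizing jitter on either side can
#' never pull two cultivars within the cutoff. Mutant cultivars bypass the
#' check — they share their parent's genotype by design.
#'
#' @param config An `ssr_sim_config` from [sim_config()].
#' @param panel Marker panel.
#' @return An `ssr_truth` list: `cultivars` (tibble with `cultivar`,
#'   `molecular_class`, `ploidy`, marker list-columns), `assignment` (tibble
#'   `sample_id`, `cultivar`, `molecular_class`, `tree_id`, `location`,
#'   `cohort`, `trueness`, `ploidy`), `pools`, `config`, `panel`.
#' @export
generate_truth <- function(config, panel = default_marker_panel()) {
  stopifnot(inherits(config, "ssr_sim_config"))
  set.seed(config$seed)
  mk <- marker_names(panel)

  pools <- purrr::map(seq_along(mk), function(m) {
    if (!is.na(panel$shift_bp[m])) {
      # centre the pool on the shift window so the offset process has material
      lo <- panel$shift_window_low[m] - 4L
      hi <- panel$shift_window_high[m] + 6L
    } else {
      lo <- config$pool_bp_range[1]
      hi <- config$pool_bp_range[2]
    }
    size <- resample(config$pool_size_range[1]:config$pool_size_range[2], 1L)
    size <- min(size, hi - lo + 1L)
    sort(sample(lo:hi, size))
  })
  names(pools) <- mk

  draw_genotype <- function(ploidy) {
    calls <- purrr::map(seq_along(mk), function(m) {
      k <- ploidy
      if (panel$locus_type[m] == "multi" && stats::runif(1) < 0.3) k <- k + 1L
      as_allele_set(resample(pools[[m]], k, replace = TRUE))
    })
    names(calls) <- mk
    calls
  }

  cultivars <- vector("list", config$n_cultivars)
  accepted <- list()  # non-mutant genotypes, for the distinctness check
  for (i in seq_len(config$n_cultivars)) {
    name <- sprintf("CV_%03d", i)
    if (i > 1L && length(accepted) > 0L && stats::runif(1) < config$mutant_prob) {
      parent <- accepted[[sample(length(accepted), 1L)]]
      cultivars[[i]] <- list(cultivar = paste0(name, "_sport"),
                             molecular_class = parent$molecular_class,
                             ploidy = parent$ploidy, calls = parent$calls)
      next
    }
    ploidy <- as.integer(sample(names(config$ploidy_probs), 1L,
                                prob = config$ploidy_probs))
    ok <- FALSE
    for (attempt in seq_len(1000L)) {
      g <- draw_genotype(ploidy)
      distinct <- all(purrr::map_lgl(accepted, function(prev) {
        pairwise_distance(g, prev$calls, panel,
                          tolerance_bp = config$tolerance_bp + 2L) > config$cutoff
      }))
      if (distinct) { ok <- TRUE; break }
    }
    if (!ok) {
      abort("allele pools too small to produce distinct cultivar genotypes",
            class = "ssr_sim_config_error")
    }
    entry <- list(cultivar = name, molecular_class = name,
                  ploidy = ploidy, calls = g)
    cultivars[[i]] <- entry
    accepted[[length(accepted) + 1L]] <- entry
  }

  cultivar_tbl <- tibble(
    cultivar = purrr::map_chr(cultivars, "cultivar"),
    molecular_class = purrr::map_chr(cultivars, "molecular_class"),
    ploidy = purrr::map_int(cultivars, "ploidy"))
  for (m in mk) {
    cultivar_tbl[[m]] <- purrr::map(cultivars, function(cv) cv$calls[[m]])
  }

  n_rep <- resample(config$samples_per_cultivar[1]:config$samples_per_cultivar[2],
                    config$n_cultivars, replace = TRUE)
  trueness_codes <- c("1", "2", "3", "4", "5", "R", "0")
  trueness_probs <- c(0.55, 0.10, 0.12, 0.08, 0.10, 0.03, 0.02)
  assignment <- tibble(
    cultivar = rep(cultivar_tbl$cultivar, n_rep),
    molecular_class = rep(cultivar_tbl$molecular_class, n_rep),
    ploidy = rep(cultivar_tbl$ploidy, n_rep))
  n <- nrow(assignment)
  assignment <- mutate(
    assignment,
    sample_id = sprintf("S%05d", seq_len(n)),
    tree_id = sprintf("T%05d", seq_len(n)),
    location = sample(sprintf("L%d", 1:8), n, replace = TRUE),
    cohort = ifelse(stats::runif(n) < config$cohort_split,
                    "P2009_2014", "P2017_2021"),
    trueness = sample(trueness_codes, n, replace = TRUE, prob = trueness_probs),
    .before = 1L)

  structure(list(cultivars = cultivar_tbl, assignment = assignment,
                 pools = pools, config = config, panel = panel),
            class = "ssr_truth")
}

#' @export
print.ssr_truth <- function(x, ...) {
  cat(sprintf("# synthetic truth: %d cultivars (%d molecular classes), %d samples, seed %d\n",
              nrow(x$cultivars), dplyr::n_distinct(x$cultivars$molecular_class),
              nrow(x$assignment), x$config$seed))
  invisible(x)
}

#' Noise-free samples implied by a synthetic truth
#'
#' Each sample carries exactly its assigned cultivar's true genotype; this is
#' the reference the error ledger reverts to.
#'
#' @param truth An `ssr_truth` from [generate_truth()].
#' @return A sample tibble.
#' @export
truth_samples <- function(truth) {
  mk <- marker_names(truth$panel)
  cv_idx <- match(truth$assignment$cultivar, truth$cultivars$cultivar)
  out <- tibble(
    sample_id = truth$assignment$sample_id,
    tree_id = truth$assignment$tree_id,
    location = truth$assignment$location,
    cohort = truth$assignment$cohort,
    putative_cultivar = truth$assignment$cultivar,
    pomological_cultivar = truth$assignment$cultivar,
    trueness = truth$assignment$trueness,
    ploidy = truth$assignment$ploidy)
  for (m in mk) {
    out[[m]] <- truth$cultivars[[m]][cv_idx]
  }
  out
}

#' Emit noisy samples from a synthetic truth
#'
#' Applies, per sample and in this order: a label swap (with probability
#' `swap_prob` the sample keeps its metadata but carries a random other
#' cultivar's profile), the systematic inter-cohort sizing offset (earlier
#' cohort reports `a - shift_bp` for true alleles whose offset value falls in
#' the rule window), per-allele +/-1 bp jitter, and per-marker dropout. Every
#' event is appended to the ledger as the affected marker's call before and
#' after the event, so [revert_ledger()] reproduces the noise-free dataset
#' exactly.
#'
#' @param truth An `ssr_truth` from [generate_truth()].
#' @param config The simulation config (defaults to the one inside `truth`).
#' @return An `ssr_sim` list: `samples` (sample tibble), `ledger` (tibble
#'   `sample_id`, `marker`, `kind`, `old`, `new`, `detail`), `truth`.
#' @export
emit_samples <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "ssr_truth"))
  set.seed(config$seed + 1L)
  panel <- truth$panel
  mk <- marker_names(panel)
  samples <- truth_samples(truth)
  n <- nrow(samples)

  shift_marker <- panel$marker[!is.na(panel$shift_bp)]
  has_shift <- config$shift_sim && length(shift_marker) == 1L
  if (has_shift) {
    rule <- panel[panel$marker == shift_marker, ]
  }

  led <- list()
  log_event <- function(sid, marker, kind, old, new, detail = NA_character_) {
    led[[length(led) + 1L]] <<- tibble(
      sample_id = sid, marker = marker, kind = kind,
      old = call_key(old), new = call_key(new), detail = detail)
  }

  classes <- truth$cultivars$molecular_class
  for (i in seq_len(n)) {
    sid <- samples$sample_id[i]

    # label swap: profile of a different molecular class under this label
    if (config$swap_prob > 0 && stats::runif(1) < config$swap_prob) {
      own_class <- samples$putative_cultivar[i]
      own_class <- truth$cultivars$molecular_class[
        match(own_class, truth$cultivars$cultivar)]
      donor_rows <- which(classes != own_class)
      if (length(donor_rows) > 0L) {
        don <- donor_rows[sample(length(donor_rows), 1L)]
        for (m in mk) {
          old <- samples[[m]][[i]]
          new <- truth$cultivars[[m]][[don]]
          if (!identical(old, new)) {
            log_event(sid, m, "swap", old, new,
                      detail = truth$cultivars$cultivar[don])
            samples[[m]][[i]] <- new
          }
        }
      }
    }

    # systematic inter-cohort sizing offset at the shift marker
    if (has_shift && identical(samples$cohort[i], rule$shift_cohort)) {
      call <- samples[[shift_marker]][[i]]
      if (length(call) > 0L) {
        obs <- call - rule$shift_bp
        move <- obs >= rule$shift_window_low & obs <= rule$shift_window_high
        if (any(move)) {
          new <- as_allele_set(ifelse(move, obs, call))
          log_event(sid, shift_marker, "shift", call, new)
          samples[[shift_marker]][[i]] <- new
        }
      }
    }

    for (m in mk) {
      call <- samples[[m]][[i]]
      # per-allele sizing jitter
      if (config$jitter_prob > 0 && length(call) > 0L) {
        hit <- stats::runif(length(call)) < config$jitter_prob
        if (any(hit)) {
          delta <- sample(c(-1L, 1L), length(call), replace = TRUE)
          new <- as_allele_set(ifelse(hit, call + delta, call))
          log_event(sid, m, "jitter", call, new,
                    detail = paste(call[hit], collapse = ":"))
          samples[[m]][[i]] <- new
          call <- new
        }
      }
      # per-marker dropout
      if (config$dropout_prob > 0 && length(call) > 0L &&
          stats::runif(1) < config$dropout_prob) {
        log_event(sid, m, "dropout", call, integer(0))
        samples[[m]][[i]] <- integer(0)
      }
    }
  }

  ledger <- if (length(led)) bind_rows(led) else
    tibble(sample_id = character(), marker = character(), kind = character(),
           old = character(), new = character(), detail = character())
  structure(list(samples = samples, ledger = ledger, truth = truth),
            class = "ssr_sim")
}

#' @export
print.ssr_sim <- function(x, ...) {
  cat(sprintf("# synthetic dataset: %d samples; ledger: %d noise event(s) (%s)\n",
              nrow(x$samples), nrow(x$ledger),
              paste(sprintf("%s=%d", names(table(x$ledger$kind)),
                            as.integer(table(x$ledger$kind))), collapse = ", ")))
  invisible(x)
}

#' Revert every ledger event, reproducing the noise-free dataset
#'
#' Replays the error ledger backwards: for each sample, each event's marker
#' cell is restored to its pre-event call, most recent event first. The
#' result is identical to [truth_samples()] — the ledger fully explains every
#' difference between emitted and true data.
#'
#' @param samples Emitted sample tibble.
#' @param ledger Error ledger from [emit_samples()].
#' @return The reverted sample tibble.
#' @export
revert_ledger <- function(samples, ledger) {
  if (nrow(ledger) == 0L) return(samples)
  for (r in rev(seq_len(nrow(ledger)))) {
    i <- match(ledger$sample_id[r], samples$sample_id)
    samples[[ledger$marker[r]]][[i]] <- parse_one_allele_field(ledger$old[r])
  }
  samples
}

#' Score pipeline outputs against synthetic ground truth
#'
#' Computes (i) the adjusted Rand index between the recovered molecular
#' groups and the true molecular classes (mutants count as their parent's
#' class; a swapped sample counts as its profile donor's class, since its
#' profile — the only thing the pipeline sees — is the donor's); (ii) the
#' fraction of molecular classes whose consensus genotype equals the true
#' genotype exactly at every marker; and (iii) swap-detection recall: the
#' fraction of swapped samples placed in their profile donor's group.
#'
#' @param sim An `ssr_sim` from [emit_samples()].
#' @param membership Membership tibble from [ssr_cluster()] (possibly after
#'   curation).
#' @param consensus Consensus tibble from [build_consensus()]; may be `NULL`
#'   to skip the recovery fraction.
#' @return A one-row tibble: `ari`, `consensus_recovery`, `swap_recall`,
#'   `n_classes`, `n_groups`, `n_swapped`.
#' @export
evaluate_recovery <- function(sim, membership, consensus = NULL) {
  stopifnot(inherits(sim, "ssr_sim"))
  truth <- sim$truth
  mk <- marker_names(truth$panel)
  ass <- truth$assignment

  # effective class: the class whose profile the sample actually carries
  swaps <- sim$ledger |>
    filter(.data$kind == "swap") |>
    distinct(.data$sample_id, .data$detail)
  eff_class <- ass$molecular_class
  sw_idx <- match(swaps$sample_id, ass$sample_id)
  eff_class[sw_idx] <- truth$cultivars$molecular_class[
    match(swaps$detail, truth$cultivars$cultivar)]

  ord <- match(ass$sample_id, membership$sample_id)
  stopifnot(!anyNA(ord))
  grp <- membership$group_id[ord]
  ari <- adjusted_rand(eff_class, grp)

  # modal group per class (excluding swapped-in profiles)
  recovery <- NA_real_
  if (!is.null(consensus)) {
    classes <- unique(eff_class)
    hits <- purrr::map_lgl(classes, function(cl) {
      rows <- which(eff_class == cl)
      g <- names(sort(table(grp[rows]), decreasing = TRUE))[1L]
      ci <- match(g, consensus$group_id)
      if (is.na(ci)) return(FALSE)
      def <- match(cl, truth$cultivars$molecular_class)  # class-defining cultivar
      all(purrr::map_lgl(mk, function(m)
        identical(consensus[[m]][[ci]], truth$cultivars[[m]][[def]])))
    })
    recovery <- mean(hits)
  }

  swap_recall <- NA_real_
  if (nrow(swaps) > 0L) {
    donor_class <- truth$cultivars$molecular_class[
      match(swaps$detail, truth$cultivars$cultivar)]
    swap_recall <- mean(purrr::map2_lgl(swaps$sample_id, donor_class,
      function(sid, cl) {
        donors <- setdiff(ass$sample_id[eff_class == cl], swaps$sample_id)
        if (length(donors) == 0L) return(NA)
        donor_grp <- names(sort(table(
          membership$group_id[match(donors, membership$sample_id)]),
          decreasing = TRUE))[1L]
        identical(membership$group_id[match(sid, membership$sample_id)], donor_grp)
      }), na.rm = TRUE)
  }

  tibble(ari = ari,
         consensus_recovery = recovery,
         swap_recall = swap_recall,
         n_classes = dplyr::n_distinct(eff_class),
         n_groups = dplyr::n_distinct(grp),
         n_swapped = nrow(swaps))
}

# Adjusted Rand index with the convention that identical partitions (including
# the degenerate single-cluster case, where the index is 0/0) score 1.0.
adjusted_rand <- function(a, b) {
  ct <- table(a, b)
  if (all(colSums(ct > 0) <= 1L) && all(rowSums(ct > 0) <= 1L)) return(1.0)
  mclust::adjustedRandIndex(a, b)
}

# sample() that never interprets a length-1 vector as 1:n
resample <- function(x, ...) x[sample.int(length(x), ...)]
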