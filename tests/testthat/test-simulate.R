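test_that("simulation is fully deterministic given the seed", {
  cfg <- sim_config(n_cultivars = 5, samples_per_cultivar = c(1, 5), seed = 7)
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1$cultivars, t2$cultivars)
  expect_identical(t1$assignment, t2$assignment)
  s1 <- emit_samples(t1)
  s2 <- emit_samples(t2)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$ledger, s2$ledger)
})

test_that("true cultivar genotypes are pairwise distinct beyond the cutoff", {
  cfg <- sim_config(n_cultivars = 12, mutant_prob = 0, seed = 3)
  truth <- generate_truth(cfg)
  panel <- truth$panel
  mk <- marker_names(panel)
  for (i in 1:11) {
    for (j in (i + 1):12) {
      p1 <- lapply(mk, function(m) truth$cultivars[[m]][[i]])
      p2 <- lapply(mk, function(m) truth$cultivars[[m]][[j]])
      names(p1) <- names(p2) <- mk
      expect_gt(pairwise_distance(p1, p2, panel, tolerance_bp = 1L), cfg$cutoff)
    }
  }
})

test_that("zero-noise samples equal their cultivar's true genotype", {
  cfg <- sim_config(n_cultivars = 6, samples_per_cultivar = c(2, 4),
                    jitter_prob = 0, dropout_prob = 0, swap_prob = 0,
                    shift_sim = FALSE, mutant_prob = 0, seed = 11)
  truth <- generate_truth(cfg)
  sim <- emit_samples(truth)
  expect_identical(sim$samples, truth_samples(truth))
  expect_equal(nrow(sim$ledger), 0L)
})

test_that("forced noise behaves as configured", {
  # jitter probability 1: every allele off by exactly 1 bp
  cfg <- sim_config(n_cultivars = 3, samples_per_cultivar = c(2, 2),
                    jitter_prob = 1, dropout_prob = 0, swap_prob = 0,
                    shift_sim = FALSE, mutant_prob = 0, seed = 5)
  truth <- generate_truth(cfg)
  sim <- emit_samples(truth)
  clean <- truth_samples(truth)
  mk <- marker_names(truth$panel)
  for (i in seq_len(nrow(sim$samples))) {
    for (m in mk) {
      obs <- sim$samples[[m]][[i]]
      tru <- clean[[m]][[i]]
      # every observed allele is within 1 bp of a true allele, none identical set
      expect_true(all(vapply(obs, function(a) min(abs(a - tru)) <= 1L, logical(1))))
    }
  }
  # dropout probability 1: everything null
  cfg2 <- sim_config(n_cultivars = 2, samples_per_cultivar = c(2, 2),
                     jitter_prob = 0, dropout_prob = 1, swap_prob = 0,
                     shift_sim = FALSE, mutant_prob = 0, seed = 5)
  sim2 <- emit_samples(generate_truth(cfg2))
  for (m in marker_names(default_marker_panel())) {
    expect_true(all(lengths(sim2$samples[[m]]) == 0L))
  }
})

test_that("the ledger fully explains every difference: revert reproduces clean data", {
  cfg <- sim_config(n_cultivars = 8, samples_per_cultivar = c(1, 10),
                    jitter_prob = 0.15, dropout_prob = 0.1, swap_prob = 0.05,
                    shift_sim = TRUE, mutant_prob = 0.1, seed = 23)
  truth <- generate_truth(cfg)
  sim <- emit_samples(truth)
  expect_gt(nrow(sim$ledger), 0L)
  reverted <- revert_ledger(sim$samples, sim$ledger)
  expect_identical(reverted, truth_samples(truth))
})

test_that("the simulated inter-cohort offset is repaired by shift correction", {
  cfg <- sim_config(n_cultivars = 10, samples_per_cultivar = c(4, 8),
                    jitter_prob = 0, dropout_prob = 0, swap_prob = 0,
                    shift_sim = TRUE, mutant_prob = 0, cohort_split = 0.5, seed = 41)
  truth <- generate_truth(cfg)
  sim <- emit_samples(truth)
  shifted <- sim$ledger[sim$ledger$kind == "shift", ]
  expect_gt(nrow(shifted), 0L)
  d <- ssr_distance(sim$samples)
  membership <- ssr_cluster(d)
  fixed <- shift_correct(sim$samples, membership)
  clean <- truth_samples(truth)
  # every edit is a +2 bp move out of the rule window
  expect_gt(nrow(fixed$report), 0L)
  expect_true(all(fixed$report$new_afl - fixed$report$old_afl == 2L))
  expect_true(all(fixed$report$old_afl >= 122L & fixed$report$old_afl <= 140L))
  # correction strictly reduces the disagreement with the noise-free data;
  # cells where the offset made two alleles collide, or shifted a whole
  # chain, cannot be reconstructed from within-group evidence and may remain
  n_diff <- function(samples) {
    sum(vapply(seq_len(nrow(samples)), function(i)
      !identical(samples$CH02g09[[i]], clean$CH02g09[[i]]), logical(1)))
  }
  expect_lt(n_diff(fixed$samples), n_diff(sim$samples))
  # unambiguous single-allele offsets with other-cohort evidence are repaired
  ass <- truth$assignment
  has_evidence <- function(sid) {
    cv <- ass$cultivar[ass$sample_id == sid]
    any(ass$cultivar == cv & ass$cohort == "P2017_2021")
  }
  simple <- vapply(seq_len(nrow(shifted)), function(k) {
    old <- parse_allele_field(shifted$old[k])[[1]]
    new <- parse_allele_field(shifted$new[k])[[1]]
    length(new) == length(old) && sum(old != new) == 1L &&
      has_evidence(shifted$sample_id[k])
  }, logical(1))
  for (k in which(simple)) {
    i <- match(shifted$sample_id[k], fixed$samples$sample_id)
    expect_identical(fixed$samples$CH02g09[[i]], clean$CH02g09[[i]])
  }
})

test_that("swapped samples cluster with their profile donor and are scored as such", {
  cfg <- sim_config(n_cultivars = 10, samples_per_cultivar = c(4, 6),
                    jitter_prob = 0, dropout_prob = 0, swap_prob = 0.15,
                    shift_sim = FALSE, mutant_prob = 0, seed = 19)
  truth <- generate_truth(cfg)
  sim <- emit_samples(truth)
  swaps <- unique(sim$ledger$sample_id[sim$ledger$kind == "swap"])
  expect_gt(length(swaps), 0L)
  membership <- ssr_cluster(ssr_distance(sim$samples))
  metrics <- evaluate_recovery(sim, membership)
  expect_equal(metrics$ari, 1.0)        # swaps counted as their donor's class
  expect_equal(metrics$swap_recall, 1.0)
  expect_equal(metrics$n_swapped, length(swaps))
})

test_that("noise-free recovery is perfect, including the degenerate one-class case", {
  cfg <- sim_config(n_cultivars = 8, samples_per_cultivar = c(1, 6),
                    jitter_prob = 0, dropout_prob = 0, swap_prob = 0,
                    shift_sim = FALSE, mutant_prob = 0, seed = 2)
  sim <- emit_samples(generate_truth(cfg))
  membership <- ssr_cluster(ssr_distance(sim$samples))
  cons <- build_consensus(sim$samples, membership)
  metrics <- evaluate_recovery(sim, membership, cons)
  expect_equal(metrics$ari, 1.0)
  expect_equal(metrics$consensus_recovery, 1.0)

  # a single cultivar yields one group; agreement is 1.0 by convention
  cfg1 <- sim_config(n_cultivars = 1, samples_per_cultivar = c(5, 5),
                     jitter_prob = 0, dropout_prob = 0, swap_prob = 0,
                     shift_sim = FALSE, mutant_prob = 0, seed = 2)
  sim1 <- emit_samples(generate_truth(cfg1))
  mem1 <- ssr_cluster(ssr_distance(sim1$samples))
  expect_equal(evaluate_recovery(sim1, mem1)$ari, 1.0)
})

test_that("mutants share their parent's genotype and molecular class", {
  cfg <- sim_config(n_cultivars = 30, mutant_prob = 0.5,
                    samples_per_cultivar = c(1, 2), seed = 13)
  truth <- generate_truth(cfg)
  sports <- which(truth$cultivars$cultivar != truth$cultivars$molecular_class)
  expect_gt(length(sports), 0L)
  mk <- marker_names(truth$panel)
  for (i in sports) {
    parent <- match(truth$cultivars$molecular_class[i], truth$cultivars$cultivar)
    for (m in mk) {
      expect_identical(truth$cultivars[[m]][[i]], truth$cultivars[[m]][[parent]])
    }
  }
})
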