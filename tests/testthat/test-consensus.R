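test_that("tally counts each distinct observed call, null included", {
  tl <- tally_calls(list(221L, 221L, c(221L, 231L)))
  expect_equal(tl$n, c(2L, 1L))
  expect_equal(tl$key, c("221", "221:231"))
  tl_null <- tally_calls(list(integer(0), integer(0), integer(0)))
  expect_equal(tl_null$n, 3L)
  expect_equal(tl_null$key, "0")
  expect_equal(sum(tally_calls(list(c(100L, 104L)))$n), 1L)
})

test_that("the heterozygous-preference rule picks the richer call beyond tolerance", {
  # majority 221, minority 221:231 (difference > 1 bp): richer call wins
  counts <- tally_calls(list(221L, 221L, 221L, c(221L, 231L), c(221L, 231L)))
  res <- consensus_alleles(counts, tolerance_bp = 1L)
  expect_equal(res$alleles, c(221L, 231L))
  expect_true("heterozygous-preference" %in% res$flags)

  # multi-locus style: {115,150} majority, {109,115,150} minority, 109 clearly distinct
  counts2 <- tally_calls(c(rep(list(c(115L, 150L)), 4), rep(list(c(109L, 115L, 150L)), 2)))
  res2 <- consensus_alleles(counts2, tolerance_bp = 1L)
  expect_equal(res2$alleles, c(109L, 115L, 150L))

  # an extra allele within tolerance is a sizing artefact: majority stands
  counts3 <- tally_calls(c(rep(list(c(221L)), 3), list(c(221L, 222L))))
  res3 <- consensus_alleles(counts3, tolerance_bp = 1L)
  expect_equal(res3$alleles, 221L)
  expect_length(res3$flags, 0L)

  # a disjoint minority call can never overwrite the majority
  counts4 <- tally_calls(c(rep(list(c(200L, 210L)), 3), list(c(150L, 160L))))
  expect_equal(consensus_alleles(counts4, 1L)$alleles, c(200L, 210L))
})

test_that("a null modal call is filled from the most frequent amplified call", {
  counts <- tally_calls(c(rep(list(integer(0)), 5), list(140L)))
  res <- consensus_alleles(counts, 1L)
  expect_equal(res$alleles, 140L)
  expect_true("missing-filled" %in% res$flags)
  # all null stays null
  expect_equal(consensus_alleles(tally_calls(rep(list(integer(0)), 4)), 1L)$alleles,
               integer(0))
})

test_that("frequency ties resolve deterministically and are flagged", {
  # within tolerance: sizing variants collapse to the smaller AFL
  res <- consensus_alleles(tally_calls(c(rep(list(200L), 3), rep(list(201L), 3))), 1L)
  expect_equal(res$alleles, 200L)
  expect_true("unresolved" %in% res$flags)
  # beyond tolerance: first-seen call kept, still flagged
  res2 <- consensus_alleles(tally_calls(c(rep(list(200L), 2), rep(list(250L), 2))), 1L)
  expect_equal(res2$alleles, 200L)
  expect_true("unresolved" %in% res2$flags)
})

make_consensus_row <- function(call, marker = "CH04f10", ploidy = 2L,
                               group_id = "MD_0001") {
  panel <- default_marker_panel()
  out <- tibble::tibble(group_id = group_id, cultivar_name = "X",
                        trueness = "1", ploidy = as.integer(ploidy),
                        n_samples = 1L)
  for (m in marker_names(panel)) out[[m]] <- list(integer(0))
  out[[marker]][[1]] <- as.integer(call)
  out
}

census_for <- function(marker, afl, n) {
  tibble::tibble(marker = marker, afl = as.integer(afl), n_genotypes = as.integer(n))
}

test_that("ploidy adjustment removes dataset-unique neighbours of widespread alleles", {
  cons <- make_consensus_row(c(222L, 224L, 245L))
  census <- census_for("CH04f10", c(222L, 224L, 245L), c(1L, 40L, 12L))
  out <- ploidy_adjust(cons, census, window_bp = 2L)
  expect_equal(out$CH04f10[[1]], c(224L, 245L))
  expect_equal(consensus_flags(out)$flag, "ploidy-adjusted")
  # at the default 1 bp window the 2 bp neighbour is out of reach: flagged only
  out1 <- ploidy_adjust(cons, census, window_bp = 1L)
  expect_equal(out1$CH04f10[[1]], c(222L, 224L, 245L))
  expect_equal(consensus_flags(out1)$flag, "unresolved")
  # per-group directive override widens the window to 2 bp
  ov <- tibble::tibble(group_id = "MD_0001", marker = "CH04f10", window_bp = 2L)
  out2 <- ploidy_adjust(cons, census, window_bp = 1L, overrides = ov)
  expect_equal(out2$CH04f10[[1]], c(224L, 245L))
})

test_that("ploidy adjustment exempts multi-locus markers, triploids, and real alleles", {
  # Hi02c07 is multi-locus: a 3-allele diploid call is genuine
  cons_multi <- make_consensus_row(c(109L, 115L, 150L), marker = "Hi02c07")
  census <- census_for("Hi02c07", c(109L, 115L, 150L), c(1L, 30L, 30L))
  out <- ploidy_adjust(cons_multi, census, window_bp = 2L)
  expect_equal(out$Hi02c07[[1]], c(109L, 115L, 150L))
  expect_equal(nrow(consensus_flags(out)), 0L)

  # triploid calls with 3 alleles are never altered (ploidy is not inferred)
  cons_tri <- make_consensus_row(c(222L, 224L, 245L), ploidy = 3L)
  out_tri <- ploidy_adjust(cons_tri, census_for("CH04f10", c(222L, 224L, 245L),
                                                c(1L, 40L, 12L)), window_bp = 2L)
  expect_equal(out_tri$CH04f10[[1]], c(222L, 224L, 245L))

  # all alleles widespread: nothing to remove, flagged for review
  cons_ws <- make_consensus_row(c(200L, 250L, 300L))
  out_ws <- ploidy_adjust(cons_ws, census_for("CH04f10", c(200L, 250L, 300L),
                                              c(10L, 10L, 10L)), window_bp = 2L)
  expect_equal(out_ws$CH04f10[[1]], c(200L, 250L, 300L))
  expect_equal(consensus_flags(out_ws)$flag, "unresolved")
})

test_that("consensus of identical replicates is the shared profile, unflagged", {
  set.seed(31)
  prof <- random_profiles(1)[[1]]
  for (k in c(1L, 3L, 7L)) {
    samples <- fixture_samples(rep(list(prof), k))
    membership <- tibble::tibble(sample_id = samples$sample_id, group_id = "MD_0001")
    cons <- build_consensus(samples, membership)
    for (m in marker_names(default_marker_panel())) {
      expect_identical(cons[[m]][[1]], sort(unique(as.integer(prof[[m]]))))
    }
    expect_equal(nrow(consensus_flags(cons)), 0L)
  }
})

test_that("mixed per-marker rules compose within one group and each firing is flagged", {
  base <- list(CH01h01 = 221L, CH02d08 = integer(0), GD147 = c(300L, 310L))
  rich <- list(CH01h01 = c(221L, 231L), CH02d08 = 140L, GD147 = c(300L, 310L))
  samples <- fixture_samples(c(rep(list(base), 3), rep(list(rich), 2)))
  membership <- tibble::tibble(sample_id = samples$sample_id, group_id = "MD_0001")
  cons <- build_consensus(samples, membership)
  expect_equal(cons$CH01h01[[1]], c(221L, 231L))  # heterozygous preference
  expect_equal(cons$CH02d08[[1]], 140L)           # missing fill
  expect_equal(cons$GD147[[1]], c(300L, 310L))    # plain majority
  fl <- consensus_flags(cons)
  expect_setequal(fl$flag[fl$marker == "CH01h01"], "heterozygous-preference")
  expect_true("missing-filled" %in% fl$flag[fl$marker == "CH02d08"])
})

test_that("cultivar naming falls back from pomology to putative name to group id", {
  prof <- random_profiles(1)[[1]]
  samples <- fixture_samples(rep(list(prof), 3),
                             pomological = c("Jakob Fischer", "Jakob Fischer", NA))
  samples$putative_cultivar <- c("x", "y", "z")
  membership <- tibble::tibble(sample_id = samples$sample_id, group_id = "MD_0001")
  expect_equal(build_consensus(samples, membership)$cultivar_name, "Jakob Fischer")
  samples$pomological_cultivar <- NA_character_
  expect_equal(build_consensus(samples, membership)$cultivar_name, "x")
  samples$putative_cultivar <- NA_character_
  expect_equal(build_consensus(samples, membership)$cultivar_name, "MD_0001")
})

test_that("replicate-rich noisy groups recover the true genotype", {
  # 73 replicates of one cultivar with 5% per-marker dropout
  cfg <- sim_config(n_cultivars = 1, samples_per_cultivar = c(73L, 73L),
                    jitter_prob = 0, dropout_prob = 0.05, swap_prob = 0,
                    shift_sim = FALSE, mutant_prob = 0, seed = 77)
  sim <- emit_samples(generate_truth(cfg))
  membership <- tibble::tibble(sample_id = sim$samples$sample_id, group_id = "MD_0001")
  cons <- build_consensus(sim$samples, membership)
  for (m in marker_names(default_marker_panel())) {
    expect_identical(cons[[m]][[1]], sim$truth$cultivars[[m]][[1]])
  }
})
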