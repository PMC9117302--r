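test_that("marker filtering applies the missing / MAF / het thresholds", {
  # missing in 6 of 10 lines: 0.6 > 0.50 -> removed
  g_miss <- mk_one_marker(c(rep(NA, 6), rep("A", 2), rep("B", 2)))
  expect_equal(nrow(filter_markers(g_miss)), 0L)

  # complete, 50/50, no H -> retained under defaults
  g_ok <- mk_one_marker(c(rep("A", 5), rep("B", 5)))
  expect_equal(nrow(filter_markers(g_ok)), 1L)

  # 8 A, 1 B, 1 H: MAF = (1 + 0.5) / 10 = 0.15 < 0.30 -> removed
  g_maf <- mk_one_marker(c(rep("A", 8), "B", "H"))
  out <- filter_markers(g_maf)
  expect_equal(nrow(out), 0L)
  rep <- curation_report(out)
  expect_equal(rep$value[rep$metric == "n_removed_maf"], 1)

  # boundary semantics: retain at equality
  g_edge <- mk_one_marker(c(rep(NA, 5), rep("A", 3), rep("B", 2)))
  # missing exactly 0.5; MAF = 2/5 = 0.4; het 0
  expect_equal(nrow(filter_markers(g_edge)), 1L)

  # heterozygosity rule
  g_het <- mk_one_marker(c(rep("A", 4), rep("B", 4), rep("H", 2)))
  expect_equal(nrow(filter_markers(g_het)), 0L)       # 20% H > 10%
  expect_equal(nrow(filter_markers(g_het, max_het = 0.2)), 1L)
})

test_that("filtering with thresholds (1, 0, 1) is the identity", {
  sim <- small_ril(seed = 4, n_lines = 30, n_chrom = 1, length_mbp = 40)
  obs <- degrade_calls(sim$geno, 0.4, 0.05, 0.02, seed = 5)
  out <- filter_markers(obs, 1, 0, 1)
  expect_equal(calls_matrix(out), calls_matrix(obs))
})

test_that("filter rejects bad input", {
  g <- mk_one_marker(c("A", "B"))
  expect_error(filter_markers(g[0, ]), "empty")
  expect_error(filter_markers(g, max_missing = 1.2), "\\[0, 1\\]")
})

test_that("phasing recodes progeny by parental origin and drops uninformative markers", {
  g <- mk_geno(list(
    P1 = c("ref", "alt", "alt", NA,    "H"),
    P2 = c("alt", "ref", "alt", "ref", "alt"),
    L1 = c("ref", "ref", "ref", "ref", "ref"),
    L2 = c("alt", "alt", "H",   "alt", "alt")
  ))
  ph <- phase_to_parents(g, "P1", "P2")
  # markers 3 (monomorphic), 4 (parent missing), 5 (parent het) dropped
  expect_equal(ph$marker_id, c("m1", "m2"))
  expect_equal(ph$L1, c("A", "B"))    # ref is parent A at m1, parent B at m2
  expect_equal(ph$L2, c("B", "A"))
  expect_false(any(c("P1", "P2") %in% line_ids(ph)))
  expect_error(phase_to_parents(g, "P1", "nope"), "unknown parent")
})

test_that("double-crossover counting follows the flanking-agreement rule", {
  # A A B A A -> one event at position 3
  g1 <- mk_geno(list(L1 = c("A", "A", "B", "A", "A")))
  expect_equal(count_double_crossovers(g1, "line")$n_dxo, 1)
  per_marker <- count_double_crossovers(g1, "marker")
  expect_equal(per_marker$n_dxo, c(0, 0, 1, 0, 0))

  # uniform line -> none
  g2 <- mk_geno(list(L1 = rep("A", 4)))
  expect_equal(count_double_crossovers(g2, "line")$n_dxo, 0)

  # a block of two is not a double crossover
  g3 <- mk_geno(list(L1 = c("A", "A", "B", "B", "A", "A")))
  expect_equal(count_double_crossovers(g3, "line")$n_dxo, 0)

  # missing and H calls are skipped as flanks
  g4 <- mk_geno(list(L1 = c("A", NA, "B", "H", "A")))
  expect_equal(count_double_crossovers(g4, "line")$n_dxo, 1)

  # events never cross a chromosome boundary
  g5 <- mk_geno(list(L1 = c("A", "A", "B", "A", "A")),
                chrom = c("c1", "c1", "c2", "c2", "c2"))
  expect_equal(count_double_crossovers(g5, "line")$n_dxo, 0)
})

test_that("reverse-phase markers are flipped and random outliers removed", {
  sim <- small_ril(seed = 8, n_lines = 100, n_chrom = 1, length_mbp = 60)
  g <- sim$geno
  cm0 <- calls_matrix(g)
  lines <- line_ids(g)
  # invert the phase of marker 15
  flip <- ifelse(cm0[15, ] == "A", "B", ifelse(cm0[15, ] == "B", "A",
                                               cm0[15, ]))
  for (j in seq_along(lines)) g[[lines[j]]][15] <- flip[[j]]
  # randomise marker 20 with respect to its neighbours
  set.seed(99)
  noise <- sample(c("A", "B"), length(lines), replace = TRUE)
  for (j in seq_along(lines)) g[[lines[j]]][20] <- noise[[j]]

  out <- correct_phase_and_outliers(g)
  rep <- curation_report(out)
  expect_equal(rep$value[rep$metric == "n_phase_flipped"], 1)
  expect_equal(rep$value[rep$metric == "n_outliers_removed"], 1)
  expect_false(g$marker_id[20] %in% out$marker_id)
  restored <- calls_matrix(out)[15, ]
  expect_equal(restored, cm0[15, ])

  # a clean table is a fixed point
  out2 <- correct_phase_and_outliers(sim$geno)
  rep2 <- curation_report(out2)
  expect_equal(sum(rep2$value[rep2$metric %in%
                                c("n_phase_flipped", "n_outliers_removed")]), 0)
  expect_equal(calls_matrix(out2), calls_matrix(sim$geno))
})

test_that("imputation fills runs by the stated rules", {
  # same flanks: fill the run
  expect_equal(rilqtl:::impute_call_vector(c("A", NA, NA, "A"), 1,
                                           TRUE, TRUE, TRUE, FALSE),
               rep("A", 4))
  # different flanks, zone 1: symmetric fill leaving the central zone
  expect_equal(rilqtl:::impute_call_vector(c("A", rep(NA, 5), "B"), 1,
                                           TRUE, TRUE, TRUE, FALSE),
               c("A", "A", "A", NA, "B", "B", "B"))
  # a 2-cell run between different flanks stays inside the zone
  expect_equal(rilqtl:::impute_call_vector(c("A", NA, NA, "B"), 1,
                                           TRUE, TRUE, TRUE, FALSE),
               c("A", NA, NA, "B"))
  # terminal runs stay missing by default, fill when enabled
  expect_equal(rilqtl:::impute_call_vector(c(NA, NA, "A"), 1,
                                           TRUE, TRUE, TRUE, FALSE),
               c(NA, NA, "A"))
  expect_equal(rilqtl:::impute_call_vector(c(NA, NA, "A"), 1,
                                           TRUE, TRUE, TRUE, TRUE),
               rep("A", 3))
  # H flanks block filling and H calls are never touched
  expect_equal(rilqtl:::impute_call_vector(c("A", NA, "H", NA, "A"), 1,
                                           TRUE, TRUE, TRUE, FALSE),
               c("A", NA, "H", NA, "A"))
  # residual double crossovers are repaired
  expect_equal(rilqtl:::impute_call_vector(c("A", "A", "B", "A", "A"), 1,
                                           TRUE, TRUE, TRUE, FALSE),
               rep("A", 5))
})

test_that("imputation is idempotent and confined to chromosomes", {
  sim <- small_ril(seed = 12, n_lines = 60, n_chrom = 2, length_mbp = 60)
  obs <- degrade_calls(sim$geno, 0.3, 0.02, 0.01, seed = 13)
  imp1 <- impute_gbsi(obs)
  imp2 <- impute_gbsi(imp1)
  expect_identical(calls_matrix(imp1), calls_matrix(imp2))

  # a lone chromosome-terminal missing cell must not borrow a flank from
  # the next chromosome
  g <- mk_geno(list(L1 = c("A", "A", NA, NA, "B", "B")),
               chrom = rep(c("c1", "c2"), each = 3))
  out <- impute_gbsi(g)
  expect_equal(out$L1, c("A", "A", NA, NA, "B", "B"))
})

test_that("the curation chain repairs degradation without inflating double crossovers", {
  sim <- small_ril(seed = 31, n_lines = 120, n_chrom = 2, length_mbp = 100)
  truth <- sim$geno
  obs <- degrade_calls(truth, missing_rate = 0.3, het_rate = 0,
                       miscall_rate = 0.01, seed = 32)
  cur <- curate_markers(obs)
  d_before <- count_double_crossovers(obs, "line")$n_dxo
  d_after <- count_double_crossovers(cur, "line")$n_dxo
  expect_true(all(d_after <= d_before))

  # imputed cells agree with simulation truth
  keep <- match(cur$marker_id, obs$marker_id)
  cm_obs <- calls_matrix(obs)[keep, ]
  cm_cur <- calls_matrix(cur)
  cm_truth <- calls_matrix(truth)[match(cur$marker_id, truth$marker_id), ]
  was_imputed <- is.na(cm_obs) & !is.na(cm_cur)
  expect_gt(sum(was_imputed), 1000)
  expect_gt(mean(cm_cur[was_imputed] == cm_truth[was_imputed]), 0.95)

  # report reconciles marker counts
  rep <- curation_report(cur)
  n_in <- rep$value[rep$step == "filter" & rep$metric == "n_input"]
  removed <- sum(rep$value[rep$metric %in%
                             c("n_removed_missing", "n_removed_maf",
                               "n_removed_het", "n_outliers_removed")])
  expect_equal(n_in - removed, nrow(cur))
})
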