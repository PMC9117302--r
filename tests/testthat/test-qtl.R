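test_that("trait preparation averages replicates then environments", {
  ph <- tibble::tibble(
    line = c("L1", "L1", "L1", "L2", "L2"),
    trait = "HED",
    env = c("e1", "e1", "e2", "e1", "e2"),
    value = c(3, 5, 6, 4, 6)
  )
  v <- prepare_trait_values(ph, "HED")
  # L1: e1 replicates average to 4, then (4 + 6) / 2 = 5
  expect_equal(v$value[v$line == "L1"], 5)
  expect_equal(v$value[v$line == "L2"], 5)

  v1 <- prepare_trait_values(ph, "HED", environments = "e1")
  expect_equal(v1$value, c(4, 4))

  v2 <- prepare_trait_values(ph, "HED", min_env = 2)
  expect_equal(nrow(v2), 2L)
  expect_error(prepare_trait_values(ph, "absent"), "no phenotype records")
})

test_that("TS and LOD convert exactly by 2 ln 10", {
  expect_equal(ts_to_lod(23.0259), 5, tolerance = 1e-4)
  expect_equal(ts_to_lod(0), 0)
  expect_equal(ts_to_lod(2 * log(10)), 1)
  expect_equal(lod_to_ts(ts_to_lod(17.3)), 17.3)
  expect_error(ts_to_lod(-1), "non-negative")
})

test_that("the single-marker statistic matches hand least squares", {
  g <- c("A", "A", "A", "B", "B", "B")
  y <- c(10, 11, 12, 14, 15, 16)
  # RSS_full = 2 + 2 = 4; RSS_reduced = 28; TS = 6 ln 7
  expect_equal(single_marker_ts(g, y, min_lines = 2), 6 * log(7))

  # equal class means: RSS ratio 1, TS = 0
  expect_equal(single_marker_ts(g, c(1, 2, 3, 1, 2, 3), min_lines = 2), 0)

  # one class empty -> NA; too few lines -> NA
  expect_true(is.na(single_marker_ts(rep("A", 6), y, min_lines = 2)))
  expect_true(is.na(single_marker_ts(g, y, min_lines = 20)))

  # zero residual variance is an error
  expect_error(single_marker_ts(g, c(1, 1, 1, 2, 2, 2), min_lines = 2),
               "zero residual variance")

  # a covariate perfectly collinear with the marker absorbs its effect
  expect_equal(single_marker_ts(g, y, covariate = g, min_lines = 2), 0)
})

test_that("TS is invariant to affine transformation of the phenotype", {
  set.seed(7)
  for (i in 1:5) {
    g <- sample(c("A", "B", "H", NA), 60, replace = TRUE,
                prob = c(0.45, 0.45, 0.05, 0.05))
    y <- rnorm(60)
    if (sum(g %in% c("A", "B")) < 25) next
    t1 <- single_marker_ts(g, y)
    t2 <- single_marker_ts(g, 3.7 * y - 11)
    expect_equal(t1, t2)
  }
})

test_that("the vectorised scan agrees with the per-marker statistic", {
  sim <- small_ril(seed = 50, n_lines = 80, n_chrom = 1, length_mbp = 50)
  g <- sim$geno
  set.seed(51)
  y <- stats::setNames(rnorm(80), line_ids(g))
  prof <- genome_scan(g, y)
  cm <- calls_matrix(g)
  direct <- vapply(seq_len(nrow(cm)), function(i) {
    single_marker_ts(cm[i, ], y[colnames(cm)])
  }, numeric(1))
  expect_equal(prof$ts, direct)
  expect_equal(prof$lod, prof$ts / (2 * log(10)))
})

test_that("a planted QTL peaks at its marker and vanishes under its own covariate", {
  lay <- toy_layout(2, 100)
  sim <- simulate_ril(sim_config(
    lay, n_lines = 200, generation = 6, marker_spacing_mbp = 2,
    qtls = tibble::tibble(trait = "T", chrom = "chr1", pos_bp = 50e6,
                          effect = 1, h2 = 0.3),
    seed = 52))
  ph <- simulate_phenotypes(sim, "T")
  vals <- prepare_trait_values(ph, "T")
  prof <- genome_scan(sim$geno, vals, trait = "T")
  qtl_marker <- sim$qtls$marker_id[1]
  peak_pos <- prof$pos_bp[which.max(prof$ts)]
  true_pos <- sim$geno$pos_bp[sim$geno$marker_id == qtl_marker]
  expect_lt(abs(peak_pos - true_pos), 10e6)

  prof_cov <- genome_scan(sim$geno, vals, covariate = qtl_marker, trait = "T")
  expect_true(is.na(prof_cov$ts[prof_cov$marker_id == qtl_marker]))
  near <- abs(prof_cov$pos_bp - true_pos) < 20e6 & prof_cov$chrom == "chr1"
  expect_lt(max(prof_cov$ts[near], na.rm = TRUE),
            max(prof$ts, na.rm = TRUE) / 4)
})

test_that("permutation thresholds are monotone, reproducible, and guarded", {
  sim <- small_ril(seed = 53, n_lines = 60, n_chrom = 1, length_mbp = 40)
  set.seed(54)
  y <- stats::setNames(rnorm(60), line_ids(sim$geno))
  thr1 <- permutation_thresholds(sim$geno, y, n_perm = 200, seed = 9)
  thr2 <- permutation_thresholds(sim$geno, y, n_perm = 200, seed = 9)
  expect_equal(thr1$ts_threshold, thr2$ts_threshold)
  expect_true(all(diff(thr1$ts_threshold) >= 0))   # alpha decreasing
  expect_error(permutation_thresholds(sim$geno, y, n_perm = 50), "at least 100")
  g <- glance(thr1)
  expect_equal(g$n_perm, 200)
})

test_that("peak calling applies the fall-off and exclusion rules", {
  mk_prof <- function(ts, mbp = seq_along(ts) * 10, chrom = "chr1") {
    out <- tibble::tibble(
      marker_id = paste0("m", seq_along(ts)), chrom = chrom,
      pos_bp = mbp * 1e6 - 5e5, mbp = as.integer(mbp), n = 100,
      mean_a = 2, mean_b = 1, ts = ts, lod = ts_to_lod(ts))
    class(out) <- c("scan_profile", class(out))
    attr(out, "trait") <- "HED"
    out
  }
  # spec-style toy: fall-off 0.8 * 30 = 24 keeps markers 3-4 only
  pk <- call_peaks(mk_prof(c(1, 6, 30, 25, 23, 6, 1)), 23,
                   population = "TxHd")
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$peak_mbp, 30L)
  expect_equal(c(pk$start_mbp, pk$end_mbp), c(30L, 40L))
  expect_equal(pk$qtl_name, "HED.TxHd.30")
  expect_equal(pk$high_parent, "A")
  expect_equal(pk$effect, 1)

  # flat profile below threshold: nothing
  expect_equal(nrow(call_peaks(mk_prof(rep(5, 7)), 23)), 0L)

  # two summits 60 Mbp apart fall inside one exclusion zone: one peak;
  # 200 Mbp apart: both reported
  ts2 <- c(30, 1, 1, 1, 1, 1, 28)
  expect_equal(nrow(call_peaks(mk_prof(ts2, mbp = c(1:6, 7) * 10), 23)), 1L)
  expect_equal(nrow(call_peaks(mk_prof(ts2, mbp = c(1:6 * 10, 260)), 23)), 2L)

  # ties break to the lowest coordinate
  pk_tie <- call_peaks(mk_prof(c(1, 30, 30, 1)), 23)
  expect_equal(pk_tie$peak_mbp[1], 20L)

  # intervals contain their peak and never overlap
  set.seed(60)
  for (i in 1:5) {
    prof <- mk_prof(pmax(rnorm(40, 10, 8), 0), mbp = seq_len(40) * 5)
    pk <- call_peaks(prof, 20, exclusion_mbp = 20)
    if (nrow(pk) == 0) next
    expect_true(all(pk$start_mbp <= pk$peak_mbp & pk$peak_mbp <= pk$end_mbp))
    if (nrow(pk) > 1) {
      o <- order(pk$start_mbp)
      expect_true(all(pk$start_mbp[o][-1] > pk$end_mbp[o][-nrow(pk)]))
    }
  }
})

test_that("QTL GFF export round-trips intervals and names", {
  prof <- tibble::tibble(
    marker_id = paste0("m", 1:5), chrom = "chr4A",
    pos_bp = c(280, 300, 318, 330, 350) * 1e6 - 5e5,
    mbp = c(280L, 300L, 318L, 330L, 350L), n = 100,
    mean_a = 10, mean_b = 12.6, ts = c(1, 20, 30, 24.5, 2),
    lod = ts_to_lod(c(1, 20, 30, 24.5, 2)))
  class(prof) <- c("scan_profile", class(prof))
  attr(prof, "trait") <- "HED"
  pk <- call_peaks(prof, 18.5, population = "TxHd")
  expect_equal(pk$qtl_name, "HED.TxHd.318")
  expect_equal(pk$high_parent, "B")
  expect_equal(pk$effect, 2.6)

  p <- withr::local_tempfile(fileext = ".gff3")
  export_qtl_gff(pk, p)
  back <- read_qtl_gff(p)
  expect_equal(back$chrom, pk$chrom)
  expect_equal(back$start_mbp, pk$start_mbp)
  expect_equal(back$end_mbp, pk$end_mbp)
  expect_equal(back$ID, pk$qtl_name)

  # empty list still writes a valid header-only file
  p2 <- withr::local_tempfile(fileext = ".gff3")
  export_qtl_gff(pk[0, ], p2)
  expect_equal(readLines(p2)[1], "##gff-version 3")
  expect_equal(nrow(read_qtl_gff(p2)), 0L)
})
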